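#!/usr/bin/env Rscript
# The alignment effect depends on the external tissue: with the default
# exterior the non-constricting cells align with AP; matching the exterior
# aspect ratio to the plate removes the alignment (mean angle ~45 deg); a
# square exterior strengthens it. Writes results/supp_geometry/.
library(nfvm)

args <- commandArgs(trailingOnly = TRUE)
tier <- if ("--tier" %in% args) args[which(args == "--tier") + 1] else "smoke"
res <- run_experiment("supp_geometry", tier = tier, seeds = 1:2,
                      out_dir = "results/supp_geometry")
print(res$tables$pooled)
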