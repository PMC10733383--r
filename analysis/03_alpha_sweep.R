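#!/usr/bin/env Rscript
# Vary the aspect ratio alpha = Ny/Nx of the constricting region at fixed
# cell count: cells align with AP for wide regions (alpha < 1), with the
# perpendicular axis for tall regions (alpha > 1), and elongate more the
# further alpha is from 1. Writes results/fig3ef/.
library(nfvm)

args <- commandArgs(trailingOnly = TRUE)
tier <- if ("--tier" %in% args) args[which(args == "--tier") + 1] else "smoke"
res <- run_experiment("fig3ef_alpha_sweep", tier = tier, seeds = 1L,
                      out_dir = "results/fig3ef")
print(res$tables$pooled)
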