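#!/usr/bin/env Rscript
# Sweep the constriction probability P_c and measure the relaxed plate's
# central length and width, normalized by the zero-constriction reference:
# both shrink monotonically with P_c, and partial constriction shrinks the
# tissue less than full constriction. Writes results/fig3d/.
library(nfvm)

args <- commandArgs(trailingOnly = TRUE)
tier <- if ("--tier" %in% args) args[which(args == "--tier") + 1] else "smoke"
res <- run_experiment("fig3d_pc_sweep", tier = tier, seeds = 1:2,
                      out_dir = "results/fig3d")
print(res$tables$pooled)
cat(sprintf("length and width monotone: %s / %s\n",
            res$summary$length_monotone, res$summary$width_monotone))
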