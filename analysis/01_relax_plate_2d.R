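#!/usr/bin/env Rscript
# Relax the 2D neural-plate tissue at P_c = 0.5 and quantify the passive
# response of the non-constricting cells: their apical area drops by ~9%
# and their elongation axes align with the AP axis (angle histogram peaked
# at 0 degrees). Writes per-cell tables and the pooled summary under
# results/fig3bc/. Uses the reduced (smoke) lattice by default; pass
# "--tier full" for the original 100x60 geometry.
library(nfvm)

args <- commandArgs(trailingOnly = TRUE)
tier <- if ("--tier" %in% args) args[which(args == "--tier") + 1] else "smoke"
res <- run_experiment("fig3b_relax", tier = tier, seeds = 1:3,
                      out_dir = "results/fig3bc")
cat(sprintf("mean angle to AP: %.1f deg (sd %.1f), mean elongation %.2f\n",
            res$summary$mean_angle, res$summary$sd_angle,
            res$summary$mean_kappa))
cat(sprintf("non-constricting plate area ratio: %.3f\n",
            res$summary$area_ratio))
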