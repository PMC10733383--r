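#!/usr/bin/env Rscript
# 3D prism-cell monolayer with a ~3-cell-wide constricting hinge band,
# periodic along AP: partial constriction (P_c = 0.5) already produces a
# shallow apical furrow; full constriction deepens it. Writes the depth
# table and cross-section profiles under results/fig3hij/.
library(nfvm)

args <- commandArgs(trailingOnly = TRUE)
tier <- if ("--tier" %in% args) args[which(args == "--tier") + 1] else "smoke"
res <- run_experiment("fig3hij_3d", tier = tier, seeds = 1L,
                      out_dir = "results/fig3hij")
print(res$tables$pooled)
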