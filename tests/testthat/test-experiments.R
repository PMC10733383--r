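test_that("unknown experiment names are rejected with the registry listing", {
  expect_error(run_experiment("fig99_nope"), "registry.*fig3d_pc_sweep")
  expect_true(all(c("fig3b_relax", "fig3d_pc_sweep", "fig3ef_alpha_sweep",
                    "supp_geometry", "supp_hinges", "fig3hij_3d") %in%
                    list_experiments()))
})

test_that("experiment bundles are written and byte-reproducible", {
  d1 <- file.path(tempdir(), "exp1")
  d2 <- file.path(tempdir(), "exp2")
  r1 <- run_experiment("fig3b_relax", tier = "smoke", seeds = 1L,
                       out_dir = d1)
  r2 <- run_experiment("fig3b_relax", tier = "smoke", seeds = 1L,
                       out_dir = d2)
  expect_true(file.exists(file.path(d1, "config.json")))
  expect_true(file.exists(file.path(d1, "summary.json")))
  expect_true(file.exists(file.path(d1, "per_seed.csv")))
  # identical configuration -> byte-identical summaries and tables
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))
  expect_identical(readLines(file.path(d1, "cell_stats.csv")),
                   readLines(file.path(d2, "cell_stats.csv")))
  cfg <- jsonlite::fromJSON(file.path(d1, "config.json"))
  expect_true(cfg$scaled_down)
  expect_match(cfg$config_hash, "^[0-9a-f]{32}$")
  # the smoke run reproduces the alignment direction of effect
  expect_lt(r1$summary$mean_angle, 45)
})
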