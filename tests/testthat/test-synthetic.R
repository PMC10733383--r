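small_params <- function(...) {
  tissue_gen_params(n_cells = 60L, width = 256L, height = 256L,
                    target_aspect = 1.5, seed = 7L, ...)
}

test_that("tissue generation is a pure function of its parameters", {
  p <- small_params(f_c = 0.4)
  t1 <- generate_polygonal_tissue(p)
  t2 <- generate_polygonal_tissue(p)
  expect_identical(t1$polygons, t2$polygons)
  expect_identical(t1$truth, t2$truth)
  expect_error(tissue_gen_params(n_cells = 1000L, width = 100L,
                                 height = 100L), "infeasible")
})

test_that("constricted fraction controls area bimodality and dispersion", {
  t0 <- generate_polygonal_tissue(small_params(f_c = 0))
  t5 <- generate_polygonal_tissue(small_params(f_c = 0.5, area_ratio = 0.2))
  cv0 <- unname(dispersion_stats(t0$truth$area)["cv"])
  cv5 <- unname(dispersion_stats(t5$truth$area)["cv"])
  expect_gt(cv5, cv0)
  # constricted cells hit the target area ratio (loosely)
  ratio <- mean(t5$truth$area[t5$truth$constricted]) /
    mean(t5$truth$area[!t5$truth$constricted])
  expect_lt(ratio, 0.45)
  # interspersion: most small cells have at least one large neighbor
  img <- render_label_image(t5)
  adj <- img$junction_truth
  small_ids <- t5$truth$cell[t5$truth$constricted]
  has_large <- vapply(small_ids, function(id) {
    nb <- c(adj$cell_b[adj$cell_a == id], adj$cell_a[adj$cell_b == id])
    any(!(nb %in% small_ids))
  }, logical(1))
  expect_gt(mean(has_large), 0.5)
})

test_that("rendered labels reproduce the generated geometry", {
  tis <- generate_polygonal_tissue(small_params(f_c = 0.3))
  img <- render_label_image(tis)
  rm <- region_shape_metrics(img)
  merged <- merge(rm, tis$truth, by = "cell")
  big <- merged[merged$n_pixels >= 300 & !merged$degenerate, ]
  expect_gt(nrow(big), 10)
  expect_lt(max(abs(big$aspect_ratio.x / big$aspect_ratio.y - 1)), 0.05)
  # the 1-px junction carving removes a boundary strip, so measured pixel
  # areas sit just below the polygon areas but track them tightly
  expect_true(all(big$area.x < big$area.y))
  expect_gt(cor(big$area.x, big$area.y), 0.98)
})

test_that("rasterized polygons agree with exact polygon measures", {
  # pure rasterization fidelity (no junction carving): pixel-count area
  # within 3% of the shoelace area for regions >= 200 px
  set.seed(11)
  for (k in 1:5) {
    poly <- random_convex_polygon() * 12 + 30
    a_exact <- polygon_measures(poly)[["area"]]
    if (a_exact < 200) next
    W <- ceiling(max(poly[, 1])) + 2L
    H <- ceiling(max(poly[, 2])) + 2L
    gx <- rep(seq_len(W), each = H)
    gy <- rep(seq_len(H), W)
    lab <- matrix(0L, H, W)
    inside <- nfvm:::points_in_polygon(gx, gy, poly)
    lab[cbind(gy[inside], gx[inside])] <- 1L
    rm <- region_shape_metrics(label_image(lab))
    expect_equal(rm$area, a_exact, tolerance = 0.03)
  }
})

test_that("junction intensity model is recovered from the rendered channel", {
  # shorter junctions brighter (b > 0): negative length-intensity relation
  tis <- generate_polygonal_tissue(small_params(f_c = 0.4,
                                                intensity_b = 2,
                                                intensity_noise_sd = 3))
  img <- render_label_image(tis)
  ji <- junction_intensities(img)
  j <- merge(ji$junctions, img$junction_truth,
             by = c("cell_a", "cell_b"))
  expect_gt(nrow(j), 20)
  expect_lt(cor(j$length_px.x, j$mean_intensity), -0.3)
  expect_gt(cor(j$mean_intensity, j$intensity), 0.8)
  # b = 0, no noise: every junction reads exactly the base level
  tis0 <- generate_polygonal_tissue(small_params(f_c = 0.3,
                                                 intensity_b = 0,
                                                 intensity_noise_sd = 0))
  img0 <- render_label_image(tis0)
  ji0 <- junction_intensities(img0, dilation_radius = 0L)
  expect_true(all(abs(ji0$junctions$mean_intensity -
                        tis0$params$intensity_a) < 1e-9))
})

test_that("hinge-band tissues show elevated area heterogeneity in the band", {
  p <- tissue_gen_params(n_cells = 80L, width = 320L, height = 320L,
                         seed = 21L,
                         hinge_band = list(center_frac = 0.5,
                                           width_frac = 0.4,
                                           fc_in = 0.5, fc_out = 0))
  tt <- generate_polygonal_tissue(p)$truth
  cv_h <- unname(dispersion_stats(tt$area[tt$in_hinge])["cv"])
  cv_n <- unname(dispersion_stats(tt$area[!tt$in_hinge])["cv"])
  expect_gt(cv_h, cv_n)
})

test_that("synthetic area tracks drift to their class targets", {
  # noiseless: classification recovers every label
  p0 <- track_gen_params(n_cells = 40L, f_ac = 1, f_ae = 0,
                         change_ac = -0.5, noise_sd = 0, seed = 2L)
  g0 <- generate_area_tracks(p0)
  cl0 <- classify_apical_dynamics(g0$tracks)
  expect_true(all(cl0$tracks$class == "AC"))
  # the drift endpoint matches the target change exactly without noise
  a <- subset(g0$tracks, cell_id == 1)$area
  expect_equal(a[length(a)] / a[1], 0.5, tolerance = 1e-12)
  # mixed classes with multiplicative noise: >= 95% recovery
  p <- track_gen_params(n_cells = 40L, f_ac = 0.3, f_ae = 0.3,
                        change_ac = -0.4, change_ae = 0.4,
                        noise_sd = 0.05, n_timepoints = 20L, seed = 3L)
  g <- generate_area_tracks(p)
  cl <- classify_apical_dynamics(g$tracks)
  agree <- mean(as.character(cl$tracks$class) ==
                  g$truth$true_class[match(cl$tracks$cell_id,
                                           g$truth$cell_id)])
  expect_gte(agree, 0.95)
  # determinism
  expect_identical(generate_area_tracks(p)$tracks, g$tracks)
})
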