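rect_image <- function(w = 40L, h = 20L, pad = 5L) {
  lab <- matrix(0L, h + 2L * pad, w + 2L * pad)
  lab[pad + seq_len(h), pad + seq_len(w)] <- 1L
  label_image(lab)
}

test_that("second-moment metrics recover rectangle and disc shapes", {
  rm <- region_shape_metrics(rect_image(40L, 20L))
  expect_equal(rm$aspect_ratio, 2, tolerance = 0.01)
  expect_equal(rm$orientation_deg, 0)
  expect_equal(rm$area, 800)
  # rotated rectangle: orientation folded into [0, 90]
  rm90 <- region_shape_metrics(rect_image(20L, 40L))
  expect_equal(rm90$orientation_deg, 90)
  # filled disc: isotropic
  n <- 61L
  xy <- expand.grid(r = 1:n, c = 1:n)
  lab <- matrix(0L, n, n)
  lab[as.matrix(xy[(xy$r - 31)^2 + (xy$c - 31)^2 <= 25^2, ])] <- 1L
  rmd <- region_shape_metrics(label_image(lab))
  expect_equal(rmd$aspect_ratio, 1, tolerance = 0.02)
  expect_gt(rmd$solidity, 0.95)
})

test_that("tiny regions are flagged degenerate and excluded from shape columns", {
  lab <- matrix(0L, 10, 10)
  lab[5, 5:6] <- 1L
  lab[2:8, 2:3] <- 2L
  rm <- region_shape_metrics(label_image(lab))
  expect_true(rm$degenerate[rm$cell == 1])
  expect_true(is.na(rm$aspect_ratio[rm$cell == 1]))
  expect_false(rm$degenerate[rm$cell == 2])
  expect_error(region_shape_metrics(label_image(matrix(0L, 5, 5))),
               "no labeled regions")
})

test_that("pixel areas scale with the physical pixel size", {
  img <- rect_image(30L, 10L)
  img$pixel_size <- 0.31
  rm <- region_shape_metrics(img)
  expect_equal(rm$area, 300 * 0.31^2)
})

test_that("apical dynamics are classified by the 20% relative-change rule", {
  tracks <- list(a = c(1.00, 0.9, 0.70), b = c(1.00, 1.1, 1.25),
                 c = c(1.00, 1.2, 1.10), d = c(2, 1.62), e = c(2, 2.39))
  cl <- classify_apical_dynamics(tracks)
  expect_equal(as.character(cl$tracks$class),
               c("AC", "AE", "no-change", "no-change", "no-change"))
  expect_equal(unname(c(cl$frequency)), c(1L, 1L, 3L))
  # long-format input, exact threshold boundary is "no-change"
  df <- data.frame(cell_id = rep(1:2, each = 2), t = rep(1:2, 2),
                   area = c(1, 0.8, 1, 1.2))
  cl2 <- classify_apical_dynamics(df)
  expect_equal(as.character(cl2$tracks$class), c("no-change", "no-change"))
  expect_error(classify_apical_dynamics(list(x = 1)), "2 timepoints")
  expect_error(classify_apical_dynamics(list(x = c(0, 1))), "non-positive")
  # min/max baseline scores transient excursions missed by first/last;
  # the excursion with the larger relative magnitude wins (here the
  # recovery 0.5 -> 1 is +100% vs the drop 1 -> 0.5 at -50%)
  cl3 <- classify_apical_dynamics(list(x = c(1, 0.5, 1)),
                                  baseline = "min_max")
  expect_equal(as.character(cl3$tracks$class), "AE")
  cl4 <- classify_apical_dynamics(list(x = c(1, 0.6, 0.7)),
                                  baseline = "min_max")
  expect_equal(as.character(cl4$tracks$class), "AC")
})

test_that("dispersion statistics use the sample convention and scale-invariant CV", {
  d <- dispersion_stats(c(2, 4))
  expect_equal(unname(d["mean"]), 3)
  expect_equal(unname(d["sd"]), sqrt(2), tolerance = 1e-12)
  expect_equal(unname(d["cv"]), sqrt(2) / 3, tolerance = 1e-12)
  expect_equal(unname(dispersion_stats(c(1, 1, 1))["cv"]), 0)
  expect_error(dispersion_stats(numeric(0)), "at least 2")
  expect_error(dispersion_stats(c(-1, 1)), "mean is zero")
  set.seed(3)
  x <- rlnorm(50)
  for (cc in c(0.1, 3, 250)) {
    expect_equal(unname(dispersion_stats(cc * x)["cv"]),
                 unname(dispersion_stats(x)["cv"]), tolerance = 1e-12)
  }
})

# small 4-cell image: 2x2 grid of cells with 1-px boundaries
four_cell_image <- function(intensity_fill = 7) {
  lab <- matrix(0L, 21, 21)
  lab[1:10, 1:10] <- 1L
  lab[1:10, 12:21] <- 2L
  lab[12:21, 1:10] <- 3L
  lab[12:21, 12:21] <- 4L
  lab[11, ] <- 0L
  lab[, 11] <- 0L
  label_image(lab, intensity = matrix(intensity_fill, 21, 21))
}

test_that("junction quantification recovers pairs, lengths and intensities", {
  img <- four_cell_image(7)
  ji <- junction_intensities(img)
  pairs <- paste(ji$junctions$cell_a, ji$junctions$cell_b)
  expect_setequal(pairs, c("1 2", "1 3", "2 4", "3 4"))
  # constant intensity: every junction mean equals the constant
  expect_true(all(ji$junctions$mean_intensity == 7))
  expect_true(all(ji$cytoplasm$mean_intensity == 7))
  # the center pixels touch >= 3 cells: reported as vertices, not edges
  expect_gt(ji$vertices$n_pixels, 0)
  # single-cell image: empty junction table, not an error
  lone <- label_image(matrix(c(0L, 1L, 1L, 0L), 2), matrix(1, 2, 2))
  expect_equal(nrow(junction_intensities(lone)$junctions), 0)
  # missing intensity channel is an error
  expect_error(junction_intensities(label_image(matrix(1L, 3, 3))),
               "intensity")
})

test_that("label images round-trip through TIFF and PNG readers", {
  skip_if_not_installed("tiff")
  img <- four_cell_image(0.5)
  tf <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(img$labels / 65535, tf, bits.per.sample = 16L)
  back <- read_label_image(tf)
  expect_identical(back$labels, img$labels)
})
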