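test_that("hexagonal lattice cells are unit-area regular hexagons", {
  tz <- build_hex_lattice(10, 8, 4, 3)
  m <- nfvm:::tissue_measures(tz)
  expect_true(all(abs(m[, "area"] - 1) < 1e-12))
  expect_true(all(abs(m[, "perimeter"] - 3.72242) < 1e-5))
  expect_equal(unname(m[, "perimeter"]),
               rep(hex_perimeter_unit_area(), nrow(m)), tolerance = 1e-12)
  # deterministic: identical inputs give bit-identical tissues
  tz2 <- build_hex_lattice(10, 8, 4, 3)
  expect_identical(tz$pos, tz2$pos)
  expect_identical(tz$cells, tz2$cells)
})

test_that("frozen flags mark exactly the cells touching the outer boundary", {
  tz <- build_hex_lattice(9, 7, 4, 3)
  # independent recomputation: a cell is on the boundary iff one of its
  # edges belongs to no other cell
  nc <- length(tz$cells)
  ekeys <- lapply(tz$cells, function(cc) {
    j <- c(cc[-1L], cc[1L])
    paste(pmin(cc, j), pmax(cc, j))
  })
  tab <- table(unlist(ekeys))
  on_boundary <- vapply(ekeys, function(k) any(tab[k] == 1L), logical(1))
  expect_identical(tz$frozen, on_boundary)
  # frozen cells' vertices are not free
  expect_false(any(tz$free_vertex[unlist(tz$cells[tz$frozen])]))
})

test_that("plate region is centered, symmetric, and sized as specified", {
  tz <- build_hex_lattice(100, 60, 60, 20)
  plate <- tz$region == "plate"
  # 30 columns of 20 cells + 30 offset columns of 21 cells
  expect_equal(sum(plate), 1230)
  # symmetric about the AP centerline
  ys <- tz$centers[plate, "y"] - tz$plate_centerline
  expect_equal(sort(round(ys, 9)), sort(round(-ys, 9)))
  expect_false(any(tz$frozen & plate))
})

test_that("a plate larger than the tissue is rejected", {
  expect_error(build_hex_lattice(3, 3, 60, 20), "does not fit")
  expect_error(build_hex_lattice(20, 10, 19, 4), "does not fit")
})

test_that("polygon_measures gives exact areas and perimeters", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_measures(sq), c(area = 1, perimeter = 4))
  # regular hexagon of area 1: perimeter 6*sqrt(2/(3*sqrt(3)))
  s <- sqrt(2 / (3 * sqrt(3)))
  hx <- t(vapply(0:5, function(k) {
    s * c(cos(k * pi / 3), sin(k * pi / 3))
  }, numeric(2)))
  pm <- polygon_measures(hx)
  expect_equal(unname(pm["area"]), 1, tolerance = 1e-12)
  expect_equal(unname(pm["perimeter"]), 3.72242, tolerance = 1e-5)
  expect_error(polygon_measures(sq[4:1, ]), "orientation")
  expect_error(polygon_measures(sq[1:2, ]), "degenerate")
})

test_that("shoelace area agrees with Monte-Carlo rejection sampling", {
  set.seed(42)
  for (k in 1:10) {
    poly <- random_convex_polygon()
    a <- polygon_measures(poly)[["area"]]
    expect_equal(a, mc_polygon_area(poly), tolerance = 0.01)
  }
})

test_that("gyration tensor gives textbook elongation and orientation", {
  rect <- rbind(c(1, 0.5), c(-1, 0.5), c(-1, -0.5), c(1, -0.5))
  s <- shape_summary(rect, c(1, 0))
  expect_equal(s$eigenvalues, c(1, 0.25))
  expect_equal(s$kappa, 0.6)
  expect_equal(s$theta_deg, 0)
  # square: isotropic
  sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  expect_equal(shape_summary(sq)$kappa, 0)
  # tall rectangle: perpendicular to x
  tall <- rbind(c(0.5, 1), c(-0.5, 1), c(-0.5, -1), c(0.5, -1))
  expect_equal(shape_summary(tall, c(1, 0))$theta_deg, 90)
  expect_error(shape_summary(rbind(c(1, 1), c(1, 1), c(1, 1))),
               "degenerate")
})

test_that("elongation is invariant under rotation and scaling; orientation is equivariant", {
  set.seed(7)
  for (k in 1:10) {
    pts <- matrix(rnorm(16), ncol = 2) %*% matrix(c(2, 0.3, 0.1, 0.5), 2)
    s0 <- shape_summary(pts)
    phi <- runif(1, 0, 180)
    R <- matrix(c(cos(phi * pi / 180), sin(phi * pi / 180),
                  -sin(phi * pi / 180), cos(phi * pi / 180)), 2)
    s1 <- shape_summary(pts %*% t(R))
    expect_equal(s1$kappa, s0$kappa, tolerance = 1e-10)
    expect_equal(shape_summary(3.7 * pts)$kappa, s0$kappa,
                 tolerance = 1e-10)
    # theta is folded to [0, 90] (sign of the eigenvector angle is lost),
    # so rotating by phi shifts it to fold(theta + phi) or fold(theta - phi)
    expect_lt(min(abs(s1$theta_deg - fold90(s0$theta_deg + phi)),
                  abs(s1$theta_deg - fold90(s0$theta_deg - phi))), 1e-6)
  }
})

test_that("tissue JSON serialization round-trips", {
  tz <- build_hex_lattice(8, 6, 3, 2)
  tz <- assign_constriction(tz, sim_config2d("uniform", pc = 0.5, seed = 3))
  path <- tempfile(fileext = ".json")
  tissue_to_json(tz, path)
  tz2 <- tissue_from_json(path)
  expect_equal(tz2$pos, tz$pos, ignore_attr = TRUE)
  expect_identical(lapply(tz2$cells, as.integer), tz$cells)
  expect_identical(tz2$constricting, tz$constricting)
  expect_identical(tz2$frozen, tz$frozen)
  expect_equal(tz2$p0, tz$p0)
})

test_that("OFF and VTK exports are well-formed", {
  tz <- build_hex_lattice(6, 5, 3, 2)
  off <- tempfile(fileext = ".off")
  write_off(tz, off)
  lines <- readLines(off)
  expect_identical(lines[1], "OFF")
  counts <- as.integer(strsplit(lines[2], " ")[[1]])
  expect_identical(counts[1:2], c(nrow(tz$pos), length(tz$cells)))
  vtk <- tempfile(fileext = ".vtk")
  write_vtk(tz, vtk)
  vl <- readLines(vtk)
  expect_true(any(grepl("^DATASET POLYDATA", vl)))
  expect_true(any(grepl(sprintf("^POINTS %d double", nrow(tz$pos)), vl)))
})
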