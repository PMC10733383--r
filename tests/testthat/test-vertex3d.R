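# single detached unit-cube "cell" used for exact energy checks
cube_args <- function() {
  list(pos = rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1),
                   c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
       cell_ptr = c(0L, 4L), avert = 0:3, bvert = 4:7, xoff = rep(0, 4))
}

test_that("prism monolayer is built with unit volumes and the stated target perimeter", {
  tz <- build_prism_tissue()
  expect_equal(length(tz$apical), 800L)
  m <- nfvm:::tissue_measures3d(tz)
  expect_true(all(abs(m[, "volume"] - 1) < 1e-10))
  expect_equal(apical_target_perimeter(0.5, 0.5), 3.6342, tolerance = 1e-4)
  expect_equal(unique(tz$p0[!tz$constricting]),
               apical_target_perimeter(0.5, 0.5))
  expect_equal(sum(build_prism_tissue(pc = 0)$constricting), 0L)
  expect_equal(unique(tz$p0[tz$constricting]),
               0.1 * apical_target_perimeter(0.5, 0.5))
  # hinge band overlapping the frozen rows is rejected
  expect_error(build_prism_tissue(n_ap = 6, n_perp = 4, hinge_width = 3),
               "overlap")
})

test_that("3D energy matches the hand-evaluated cube", {
  a <- cube_args()
  m <- nfvm:::cell_measures3d_cpp(a$pos, a$cell_ptr, a$avert, a$bvert,
                                  a$xoff)
  expect_equal(as.vector(m), c(1, 1, 4, 4, 1))
  p0 <- apical_target_perimeter(0.5, 0.5)
  e <- nfvm:::energy3d_cpp(a$pos, a$cell_ptr, a$avert, a$bvert, a$xoff, p0,
                           0.5, 0.5, 1, 100)
  # 0.5*1 + 0.5*1 + 0.5*4 + (4 - 3.6342)^2 + 0 = 3.1338
  expect_equal(e, 3.1338, tolerance = 1e-4)
  # closed-form checks carry the ~1e-8 offset of the C1 regularization
  expect_equal(e, 3 + (4 - p0)^2, tolerance = 1e-6)
  # with p0 = 4 the perimeter term vanishes
  expect_equal(nfvm:::energy3d_cpp(a$pos, a$cell_ptr, a$avert, a$bvert,
                                   a$xoff, 4, 0.5, 0.5, 1, 100), 3,
               tolerance = 1e-6)
  # fresh tissue: volume term contributes exactly zero
  tz <- build_prism_tissue(6, 10, 3, pc = 0)
  mm <- nfvm:::tissue_measures3d(tz)
  e_tension <- sum(0.5 * mm[, 1] + 0.5 * mm[, 2] + 0.5 * mm[, 3] +
                     (mm[, 4] - tz$p0)^2)
  expect_equal(energy3d(tz), e_tension, tolerance = 1e-6)
})

test_that("3D forces match central finite differences", {
  set.seed(8)
  tz <- build_prism_tissue(4, 6, 1, pc = 0.5, seed = 2)
  tz$pos <- tz$pos + matrix(rnorm(length(tz$pos), 0, 0.02), ncol = 3)
  g <- nfvm:::grad3d_cpp(tz$pos, tz$cell_ptr, tz$avert, tz$bvert, tz$xoff,
                         tz$p0, tz$alpha, tz$beta, tz$kp, tz$kV)
  fd <- fd_grad3d(tz)
  expect_lt(max(abs(g - fd) / pmax(1, abs(fd))), 1e-5)
  # frozen-row vertices report zero force
  f <- forces3d(tz)
  expect_true(all(f[!tz$free_vertex, ] == 0))
})

test_that("energy is invariant under translation by one periodic image", {
  tz <- build_prism_tissue(6, 10, 3, pc = 0.5, seed = 3)
  e0 <- energy3d(tz)
  tz2 <- tz
  tz2$pos[, 1] <- tz2$pos[, 1] + tz2$box_lx
  expect_equal(energy3d(tz2), e0, tolerance = 1e-10)
})

test_that("flat monolayer stays flat and volumes stay near 1 after relaxation", {
  # wide enough perpendicular extent for an interior plateau away from the
  # frozen rows (which keep the initial height)
  tz <- build_prism_tissue(6, 30, 3, pc = 0)
  r <- relax3d(tz, "minimize")
  m <- nfvm:::tissue_measures3d(r$tissue)
  expect_true(all(abs(m[, "volume"] - 1) < 0.05))
  # the interior is flat to a fraction of a percent of the cell height
  # (a shallow bowl against the fixed-height boundary rows remains)
  interior <- tz$grid$iy >= 9 & tz$grid$iy <= tz$n_perp - 10
  z <- nfvm:::apical_z(r$tissue)
  expect_lt(diff(range(z[interior])) / tz$height, 5e-3)
  expect_lt(abs(furrow_profile(r$tissue)$depth), 1e-3)
})

test_that("3D relaxation is deterministic and monotone in energy", {
  tz <- build_prism_tissue(6, 12, 3, pc = 0.5, seed = 5)
  r1 <- relax3d(tz, "euler", t_end = 0.5)
  r2 <- relax3d(tz, "euler", t_end = 0.5)
  expect_identical(r1$tissue$pos, r2$tissue$pos)
  expect_true(all(diff(r1$diagnostics$energy) <= 1e-9))
})

test_that("partial hinge constriction furrows the apical surface", {
  depth_at <- function(pc) {
    tz <- build_prism_tissue(8, 24, 3, pc = pc, seed = 6)
    r <- relax3d(tz, "minimize")
    list(fp = furrow_profile(r$tissue), tz = r$tissue)
  }
  d0 <- depth_at(0)
  d5 <- depth_at(0.5)
  d1 <- depth_at(1)
  expect_lt(abs(d0$fp$depth), 1e-3)
  expect_gt(d5$fp$depth, 0)
  expect_gt(d1$fp$depth, d5$fp$depth)
  # profile symmetric about the hinge centerline; the half-cell offset of
  # every second column breaks exact mirror symmetry, so the tolerance is
  # a quarter of the profile range
  pr <- d1$fp$profile
  z <- pr$mean_apical_z
  zc <- (z + rev(z)) / 2
  expect_lt(max(abs(z - zc)), 0.25 * diff(range(z)))
  # apical elongation of non-constricting hinge cells aligns with AP
  ap <- apical_shape_stats(d5$tz)
  sel <- ap$hinge & !ap$constricting
  if (sum(sel) >= 3) expect_lt(mean(ap$theta_deg[sel]), 45)
})
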