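# 3D vertex model of hinge furrowing: a monolayer of prism cells (paired
# apical/basal polygon loops, lateral quads) with apical/basal/lateral surface
# tensions, apical perimeter elasticity and a near-incompressibility volume
# penalty, periodic along the AP axis and frozen at the rows perpendicular to
# it. Lengths are measured in units of the target cell volume^(1/3).

#' Target apical perimeter of a non-constricting cell
#'
#' The equilibrium apical perimeter of a cell without perimeter elasticity in
#' a flat hexagonal honeycomb: \eqn{2 \cdot 6^{1/3} (\alpha+\beta)^{-1/3}}.
#' @param alpha,beta Dimensionless apical and basal surface tensions.
#' @return Scalar perimeter (units of cell volume^(1/3)).
#' @export
apical_target_perimeter <- function(alpha = 0.5, beta = 0.5) {
  2 * 6^(1 / 3) * (alpha + beta)^(-1 / 3)
}

#' Build a flat prism-cell monolayer with a constricting hinge band
#'
#' Hexagonal monolayer of unit-volume prisms, `n_ap` cells along the AP (x)
#' axis with periodic boundary conditions and `n_perp` perpendicular with the
#' outermost row on each side frozen. A centered `hinge_width`-cell-wide band
#' running along AP is eligible for constriction: each band cell is flagged
#' with probability `pc` and gets a target apical perimeter reduced to
#' `factor` (default 10%) of the non-constricting value
#' [apical_target_perimeter()].
#'
#' The initial prism cross-section is the flat-equilibrium hexagon (apical
#' area \eqn{A^* = (p_0 / p_{hex})^2} with \eqn{p_{hex}} the unit-area
#' hexagon perimeter) and height \eqn{1/A^*}, so volumes are exactly 1 and
#' the zero-constriction state is stationary.
#'
#' @param n_ap,n_perp Cells along and perpendicular to AP (defaults 20, 40).
#' @param hinge_width Width of the constriction-eligible band in cell rows.
#' @param pc Constriction probability within the band.
#' @param seed RNG seed for the constriction draw.
#' @param alpha,beta,kp,kV Dimensionless tensions and moduli
#'   (defaults 0.5, 0.5, 1, 100).
#' @param factor Constricted target-perimeter fraction (default 0.10).
#' @return A `tissue3d` object.
#' @export
build_prism_tissue <- function(n_ap = 20L, n_perp = 40L, hinge_width = 3L,
                               pc = 0.5, seed = 1L, alpha = 0.5, beta = 0.5,
                               kp = 1, kV = 100, factor = 0.10) {
  p0_base <- apical_target_perimeter(alpha, beta)
  a_star <- (p0_base / hex_perimeter_unit_area())^2
  s <- hex_side() * sqrt(a_star)
  h <- 1 / a_star
  hy <- sqrt(3) * s
  hx <- 1.5 * s
  lx <- n_ap * hx
  hstart <- (n_perp - hinge_width) %/% 2L
  hinge_rows <- hstart + seq_len(hinge_width) - 1L
  if (any(hinge_rows <= 0L) || any(hinge_rows >= n_perp - 1L)) {
    stop("hinge band (rows ", min(hinge_rows), "-", max(hinge_rows),
         ") overlaps the frozen boundary rows")
  }
  grid <- expand.grid(ix = seq_len(n_ap) - 1L, iy = seq_len(n_perp) - 1L)
  grid <- grid[order(grid$iy, grid$ix), , drop = FALSE]
  rownames(grid) <- NULL
  nc <- nrow(grid)
  cx <- grid$ix * hx
  cy <- grid$iy * hy + (grid$ix %% 2L) * hy / 2
  ang <- (0:5) * pi / 3
  dx <- s * cos(ang)
  dy <- s * sin(ang)
  vx <- rep(cx, each = 6L) + rep(dx, nc)
  vy <- rep(cy, each = 6L) + rep(dy, nc)
  vxw <- vx %% lx
  xoff <- lx * round((vx - vxw) / lx)
  key2 <- paste(round(vxw, 8L), round(vy, 8L))
  uk <- !duplicated(key2)
  vid <- match(key2, key2[uk])
  napex <- sum(uk)
  # apical vertices first (z = +h/2), then the matching basal set (z = -h/2)
  pos <- rbind(cbind(vxw[uk], vy[uk], h / 2),
               cbind(vxw[uk], vy[uk], -h / 2))
  colnames(pos) <- c("x", "y", "z")
  acells <- split(vid, rep(seq_len(nc), each = 6L))
  bcells <- lapply(acells, function(cc) cc + napex)
  names(acells) <- names(bcells) <- NULL

  frozen <- grid$iy == 0L | grid$iy == n_perp - 1L
  hinge <- grid$iy %in% hinge_rows
  set.seed(seed)
  constricting <- hinge & (runif(nc) < pc)
  p0 <- rep(p0_base, nc)
  p0[constricting] <- factor * p0_base
  free_vertex <- rep(TRUE, nrow(pos))
  fv <- unique(unlist(acells[frozen]))
  free_vertex[c(fv, fv + napex)] <- FALSE

  structure(list(
    pos = pos,
    apical = acells,
    basal = bcells,
    cell_ptr = c(0L, cumsum(lengths(acells))),
    avert = unlist(acells) - 1L,
    bvert = unlist(bcells) - 1L,
    xoff = xoff,
    constricting = constricting,
    frozen = frozen,
    hinge = hinge,
    p0 = p0,
    alpha = alpha, beta = beta, kp = kp, kV = kV,
    box_lx = lx,
    grid = grid,
    centers = cbind(x = cx, y = cy),
    n_ap = n_ap, n_perp = n_perp, hinge_width = as.integer(hinge_width),
    height = h,
    free_vertex = free_vertex,
    n_apical_vertices = napex
  ), class = "tissue3d")
}

#' @export
print.tissue3d <- function(x, ...) {
  cat("tissue3d: ", length(x$apical), " prism cells (",
      sum(x$hinge), " hinge, ", sum(x$constricting), " constricting, ",
      sum(x$frozen), " frozen), periodic box Lx = ",
      signif(x$box_lx, 6), "\n", sep = "")
  invisible(x)
}

# per-cell apical/basal/lateral areas, apical perimeter, volume
tissue_measures3d <- function(tissue) {
  m <- cell_measures3d_cpp(tissue$pos, tissue$cell_ptr, tissue$avert,
                           tissue$bvert, tissue$xoff)
  colnames(m) <- c("apical_area", "basal_area", "lateral_area",
                   "apical_perimeter", "volume")
  m
}

#' Tissue energy of the 3D vertex model
#'
#' Dimensionless energy \eqn{\sum_c [\alpha a_a + \beta a_b + a_l/2 +
#' k_p (p_a - p_0)^2 + k_V (v - 1)^2]}; the 1/2 on the lateral term counts
#' each shared lateral quad once in the tissue total. Faces are
#' fan-triangulated about their vertex centroid; volumes come from the
#' divergence-theorem sum over the closed triangulated cell surface.
#'
#' @param tissue A `tissue3d`.
#' @return Scalar energy.
#' @export
energy3d <- function(tissue) {
  m <- tissue_measures3d(tissue)
  bad <- which(m[, "volume"] <= 0)
  if (length(bad) > 0L) {
    stop("non-positive volume in cell(s) ", paste(head(bad, 5L),
                                                  collapse = ", "))
  }
  energy3d_cpp(tissue$pos, tissue$cell_ptr, tissue$avert, tissue$bvert,
               tissue$xoff, tissue$p0, tissue$alpha, tissue$beta,
               tissue$kp, tissue$kV)
}

#' Per-vertex forces of the 3D vertex model
#' @param tissue A `tissue3d`.
#' @return V x 3 matrix; vertices of frozen cells have zero force.
#' @export
forces3d <- function(tissue) {
  g <- grad3d_cpp(tissue$pos, tissue$cell_ptr, tissue$avert, tissue$bvert,
                  tissue$xoff, tissue$p0, tissue$alpha, tissue$beta,
                  tissue$kp, tissue$kV)
  f <- -g
  f[!tissue$free_vertex, ] <- 0
  colnames(f) <- c("fx", "fy", "fz")
  f
}

#' Relax a 3D tissue
#'
#' Overdamped descent on [energy3d()]; `euler` mode integrates
#' \eqn{\dot r_i = -\nabla_{r_i} e} with explicit Euler, `minimize` mode runs
#' L-BFGS-B on the free vertices to `force_tol`. Frozen rows stay immobile;
#' the AP box length is fixed.
#'
#' @param tissue A `tissue3d`.
#' @param mode "minimize" or "euler".
#' @param dt,t_end Euler step and end time (defaults 1e-4, 5000).
#' @param force_tol Max-force target for minimize mode.
#' @return List: `tissue`, `diagnostics`, `converged`, `mode`.
#' @export
relax3d <- function(tissue, mode = c("minimize", "euler"), dt = 1e-4,
                    t_end = 5000, force_tol = 1e-6) {
  mode <- match.arg(mode)
  if (mode == "euler") {
    for (attempt in 1:2) {
      nsteps <- ceiling(t_end / dt)
      check <- max(1L, min(10000L, nsteps %/% 200L))
      out <- euler3d_cpp(tissue$pos, tissue$cell_ptr, tissue$avert,
                         tissue$bvert, tissue$xoff, tissue$p0, tissue$alpha,
                         tissue$beta, tissue$kp, tissue$kV,
                         tissue$free_vertex, dt, nsteps, check, 1e-9)
      if (!out$unstable) break
      if (attempt == 2L) {
        stop("3D euler relaxation unstable even after halving dt to ", dt,
             "; use a smaller time step")
      }
      warning("energy rise detected at dt = ", dt, "; retrying with dt/2")
      dt <- dt / 2
    }
    tissue$pos <- out$pos
    diag <- data.frame(time = out$time, energy = out$energy,
                       max_force = out$max_force)
    return(list(tissue = tissue, diagnostics = diag, converged = TRUE,
                mode = "euler", dt_used = dt))
  }
  # minimize mode: compiled L-BFGS descent; as in 2D, collapsed apical edges
  # of constricting cells put the minimum at a subgradient kink, where
  # energy stationarity is the convergence criterion (at_kink = TRUE)
  opt <- lbfgs3d_cpp(tissue$pos, tissue$cell_ptr, tissue$avert,
                     tissue$bvert, tissue$xoff, tissue$p0, tissue$alpha,
                     tissue$beta, tissue$kp, tissue$kV, tissue$free_vertex,
                     force_tol, 200000L)
  if (!opt$converged) {
    stop("3D minimize mode did not converge: max force ",
         signif(opt$max_force, 3), " (target ", force_tol,
         ") and energy still decreasing")
  }
  tissue$pos <- opt$pos
  diag <- data.frame(iterations = opt$iterations, energy = opt$energy,
                     max_force = opt$max_force)
  list(tissue = tissue, diagnostics = diag, converged = opt$converged,
       at_kink = opt$at_kink, mode = "minimize")
}

# mean apical z per cell
apical_z <- function(tissue) {
  vapply(tissue$apical, function(cc) mean(tissue$pos[cc, 3L]), numeric(1))
}

#' Furrow depth and cross-section profile
#'
#' Depth is the deviation of the hinge-band apical height below the smooth
#' tissue baseline, in units of cell volume^(1/3) (positive = apical
#' trough). The baseline is a quadratic fit (in the perpendicular row
#' coordinate) to the mean apical z of all non-frozen rows outside the band
#' neighborhood, which removes the shallow tissue-wide height bowl that
#' develops against the fixed boundary rows even with no constriction. The
#' profile is the AP-averaged mean apical z per perpendicular cell row.
#' Both the depth definition and the baseline fit are repository
#' conventions for quantifying what the cross-sections show.
#'
#' @param tissue A relaxed `tissue3d`.
#' @param exclude_rows Rows within this distance of the band edge are
#'   excluded from the baseline fit (default 2, skipping the furrow
#'   shoulders).
#' @return List: `depth`, `profile` (data.frame: row, y, mean_apical_z,
#'   n_cells, hinge, baseline).
#' @export
furrow_profile <- function(tissue, exclude_rows = 2) {
  z <- apical_z(tissue)
  iy <- tissue$grid$iy
  band_center <- mean(range(iy[tissue$hinge]))
  d <- abs(iy - band_center)
  # local baseline: fit the 6 rows just outside the shoulder-excluded band
  # neighborhood, so the short inward extrapolation is accurate and rows
  # near the frozen boundary (sharpest part of the bowl) stay out
  lo <- tissue$hinge_width / 2 + exclude_rows
  fit_sel <- !tissue$frozen & !tissue$hinge & d > lo & d <= lo + 6
  if (sum(fit_sel) < 12) {
    fit_sel <- !tissue$frozen & !tissue$hinge & d > lo
  }
  fit <- stats::lm(z ~ poly(d2, 2, raw = TRUE),
                   data = data.frame(z = z[fit_sel], d2 = d[fit_sel]))
  baseline_hinge <- mean(stats::predict(
    fit, newdata = data.frame(d2 = d[tissue$hinge])))
  depth <- baseline_hinge - mean(z[tissue$hinge])
  prof <- aggregate(list(mean_apical_z = z),
                    by = list(row = iy), FUN = mean)
  prof$y <- vapply(prof$row, function(r) {
    mean(tissue$centers[iy == r, "y"])
  }, numeric(1))
  prof$n_cells <- as.integer(table(iy)[as.character(prof$row)])
  prof$hinge <- prof$row %in% unique(iy[tissue$hinge])
  prof$baseline <- stats::predict(
    fit, newdata = data.frame(d2 = abs(prof$row - band_center)))
  list(depth = depth, profile = prof)
}

#' Apical-side shape statistics
#'
#' [shape_summary()] on each cell's apical vertex loop (3D gyration tensor),
#' with orientation measured against the AP axis.
#'
#' @param tissue A `tissue3d`.
#' @return data.frame: cell, hinge, constricting, frozen, kappa, theta_deg.
#' @export
apical_shape_stats <- function(tissue) {
  shp <- lapply(seq_along(tissue$apical), function(c) {
    cc <- tissue$apical[[c]]
    s <- tissue$cell_ptr[c] + seq_along(cc)
    pts <- tissue$pos[cc, , drop = FALSE]
    pts[, 1L] <- pts[, 1L] + tissue$xoff[s]
    shape_summary(pts, c(1, 0, 0))
  })
  data.frame(
    cell = seq_along(tissue$apical),
    hinge = tissue$hinge,
    constricting = tissue$constricting,
    frozen = tissue$frozen,
    kappa = vapply(shp, `[[`, numeric(1), "kappa"),
    theta_deg = vapply(shp, `[[`, numeric(1), "theta_deg")
  )
}

#' Export the apical or basal surface as OFF
#' @param tissue A `tissue3d`.
#' @param path Output file.
#' @param side "apical" or "basal".
#' @export
write_off3d <- function(tissue, path, side = c("apical", "basal")) {
  side <- match.arg(side)
  loops <- if (side == "apical") tissue$apical else tissue$basal
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(tissue$pos), length(loops)), con)
  writeLines(sprintf("%.12g %.12g %.12g", tissue$pos[, 1], tissue$pos[, 2],
                     tissue$pos[, 3]), con)
  writeLines(vapply(loops, function(cc) {
    paste(c(length(cc), cc - 1L), collapse = " ")
  }, character(1)), con)
  invisible(path)
}
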