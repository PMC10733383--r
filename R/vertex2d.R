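# 2D vertex model: constriction assignment, tissue energy/forces, overdamped
# relaxation (explicit Euler or quasi-Newton descent to the same fixed point),
# and the tissue-level measurements (plate dimensions, cell shape statistics).

#' Simulation configuration for the 2D vertex model
#'
#' @param scheme "uniform" (every plate cell constricts with probability `pc`)
#'   or "hinge" (two `band_width`-cell-wide bands at the plate's y-edges
#'   constrict with probability `ph`; the cells between them with `pc`).
#' @param pc Constriction probability (uniform scheme, or between-hinge cells).
#' @param ph Constriction probability inside the hinge bands.
#' @param band_width Hinge band width in cell rows (default 3).
#' @param factor Constricting cells' target perimeter as a fraction of the
#'   non-constricting target (default 0.10).
#' @param dt Euler time step (default 1e-4; 1e-3 is used for the 180x180
#'   tissue in the source experiments).
#' @param t_end End time for Euler relaxation (default 2000).
#' @param mode "euler" or "minimize" (quasi-Newton descent on the same
#'   energy, frozen vertices fixed, to `force_tol`).
#' @param force_tol Max-force convergence target for minimize mode.
#' @param seed RNG seed for the constriction draw.
#' @return A `sim_config2d` list.
#' @export
sim_config2d <- function(scheme = c("uniform", "hinge"), pc = 0.5, ph = 0.5,
                         band_width = 3L, factor = 0.10, dt = 1e-4,
                         t_end = 2000, mode = c("euler", "minimize"),
                         force_tol = 1e-6, seed = 1L) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  stopifnot(pc >= 0, pc <= 1, ph >= 0, ph <= 1, dt > 0,
            factor > 0, factor <= 1)
  structure(list(scheme = scheme, pc = pc, ph = ph,
                 band_width = as.integer(band_width), factor = factor,
                 dt = dt, t_end = t_end, mode = mode,
                 force_tol = force_tol, seed = as.integer(seed)),
            class = "sim_config2d")
}

#' Assign apical constriction to plate cells
#'
#' Each eligible plate cell is independently flagged constricting with its
#' scheme probability (row-major order over plate cells, reproducible under a
#' fixed seed); flagged cells have their target perimeter reduced to
#' `factor` (default 10%) of the non-constricting value. Exterior cells are
#' never flagged.
#'
#' @param tissue A `tissue2d` from [build_hex_lattice()].
#' @param config A [sim_config2d()].
#' @return The tissue with `constricting` flags and per-cell `p0` updated.
#' @export
assign_constriction <- function(tissue, config) {
  stopifnot(inherits(tissue, "tissue2d"), inherits(config, "sim_config2d"))
  plate <- which(tissue$region == "plate")
  if (length(plate) == 0L) stop("tissue has no plate region")
  prob <- if (config$scheme == "uniform") {
    rep(config$pc, length(plate))
  } else {
    # hinge bands: outermost band_width cell rows at each y-edge of the plate
    ny <- tissue$plate_spec[["ny"]]
    hy <- sqrt(3) * hex_side()
    d <- abs(tissue$centers[plate, "y"] - tissue$plate_centerline) / hy
    ifelse(d > ny / 2 - config$band_width, config$ph, config$pc)
  }
  set.seed(config$seed)
  flag <- runif(length(plate)) < prob
  tissue$constricting[] <- FALSE
  tissue$constricting[plate[flag]] <- TRUE
  base_p0 <- tissue$p0
  # re-derive the non-constricting baseline in case of reassignment
  p0_base <- max(base_p0)
  tissue$p0 <- rep(p0_base, length(tissue$cells))
  tissue$p0[tissue$constricting] <- config$factor * p0_base
  tissue$config <- config
  tissue
}

#' Tissue energy of the 2D vertex model
#'
#' Dimensionless area-and-perimeter elasticity energy
#' \eqn{e = \sum_c [(a^{(c)} - 1)^2 + k_p (p^{(c)} - p_0^{(c)})^2]},
#' summed over all cells including the frozen ring.
#'
#' @param tissue A `tissue2d`.
#' @return Scalar energy.
#' @export
energy2d <- function(tissue) {
  m <- tissue_measures(tissue)
  bad <- which(m[, "area"] <= 0)
  if (length(bad) > 0L) {
    stop("degenerate (inverted) polygon in cell(s) ",
         paste(head(bad, 5L), collapse = ", "))
  }
  energy2d_cpp(tissue$pos, tissue$cell_ptr, tissue$cvert, tissue$p0,
               tissue$kp)
}

#' Per-vertex forces of the 2D vertex model
#'
#' Analytic negative energy gradient with respect to each vertex position;
#' vertices of frozen cells are reported with zero force.
#'
#' @param tissue A `tissue2d`.
#' @return V x 2 matrix of forces.
#' @export
forces2d <- function(tissue) {
  g <- grad2d_cpp(tissue$pos, tissue$cell_ptr, tissue$cvert, tissue$p0,
                  tissue$kp)
  f <- -g
  f[!tissue$free_vertex, ] <- 0
  colnames(f) <- c("fx", "fy")
  f
}

max_force2d <- function(tissue) {
  f <- forces2d(tissue)
  if (!any(tissue$free_vertex)) return(0)
  max(sqrt(rowSums(f[tissue$free_vertex, , drop = FALSE]^2)))
}

#' Relax a 2D tissue to its energy minimum
#'
#' Overdamped gradient dynamics. In `euler` mode the vertices follow
#' \eqn{r_i(t + \Delta t) = r_i(t) - \Delta t \nabla_{r_i} e} until `t_end`;
#' an energy rise beyond 1e-9 per step triggers one retry at half the time
#' step, then an error. In `minimize` mode an L-BFGS-B quasi-Newton descent
#' on the same energy (frozen vertices fixed) runs until the maximum free
#' force drops below `force_tol`.
#'
#' @param tissue A `tissue2d` with constriction already assigned (or not, for
#'   a reference relaxation).
#' @param config A [sim_config2d()]; `mode`, `dt`, `t_end`, `force_tol` used.
#' @return List: `tissue` (relaxed), `diagnostics` (data.frame of time,
#'   energy, max_force), `converged`, `mode`.
#' @export
relax2d <- function(tissue, config = sim_config2d()) {
  stopifnot(inherits(tissue, "tissue2d"))
  if (config$mode == "euler") {
    dt <- config$dt
    for (attempt in 1:2) {
      nsteps <- ceiling(config$t_end / dt)
      check <- max(1L, min(10000L, nsteps %/% 200L))
      out <- euler2d_cpp(tissue$pos, tissue$cell_ptr, tissue$cvert,
                         tissue$p0, tissue$kp, tissue$free_vertex,
                         dt, nsteps, check, 1e-9)
      if (!out$unstable) break
      if (attempt == 2L) {
        stop("euler relaxation unstable even after halving dt to ", dt,
             ": energy increased by more than 1e-9 per step; use a smaller ",
             "time step")
      }
      warning("energy rise detected at dt = ", dt, "; retrying with dt/2")
      dt <- dt / 2
    }
    tissue$pos <- out$pos
    diag <- data.frame(time = out$time, energy = out$energy,
                       max_force = out$max_force)
    return(list(tissue = tissue, diagnostics = diag,
                converged = TRUE, mode = "euler", dt_used = dt))
  }
  # minimize mode: compiled L-BFGS (quasi-Newton) descent on the same energy.
  # Constricting cells collapse edges to zero length (vertex mergers: T1s
  # are disallowed, so merged vertices cannot rearrange); the minimum then
  # sits at a kink of the energy where the subgradient norm stays O(1), and
  # energy stationarity is the convergence criterion there (at_kink = TRUE).
  opt <- lbfgs2d_cpp(tissue$pos, tissue$cell_ptr, tissue$cvert, tissue$p0,
                     tissue$kp, tissue$free_vertex, config$force_tol,
                     200000L)
  if (!opt$converged) {
    stop("minimize mode did not converge: max force ",
         signif(opt$max_force, 3), " after ", opt$iterations,
         " L-BFGS iterations (target ", config$force_tol,
         ") and energy still decreasing")
  }
  tissue$pos <- opt$pos
  diag <- data.frame(iterations = opt$iterations, energy = opt$energy,
                     max_force = opt$max_force)
  list(tissue = tissue, diagnostics = diag, converged = opt$converged,
       at_kink = opt$at_kink, mode = "minimize")
}

# current cell centers (vertex means)
cell_centers <- function(tissue) {
  t(vapply(tissue$cells, function(cc) {
    colMeans(tissue$pos[cc, , drop = FALSE])
  }, numeric(2)))
}

# indices (into cells) of the "several centrally located cells" groups at the
# four outer edges of the plate region, chosen on the undeformed lattice grid
plate_edge_groups <- function(tissue, ngroup = 5L) {
  plate <- which(tissue$region == "plate")
  g <- tissue$grid[plate, , drop = FALSE]
  cx <- tissue$centers[plate, "x"]
  cy <- tissue$centers[plate, "y"]
  yc <- tissue$plate_centerline
  xc <- (min(cx) + max(cx)) / 2
  pick <- function(on_edge, center_dist) {
    cand <- which(on_edge)
    cand[order(center_dist[cand])][seq_len(min(ngroup, length(cand)))]
  }
  hy <- sqrt(3) * hex_side()
  list(
    left   = plate[pick(g$ix == min(g$ix), abs(cy - yc))],
    right  = plate[pick(g$ix == max(g$ix), abs(cy - yc))],
    bottom = plate[pick(cy < min(cy) + 0.6 * hy, abs(cx - xc))],
    top    = plate[pick(cy > max(cy) - 0.6 * hy, abs(cx - xc))]
  )
}

#' Central length and width of the plate region
#'
#' Length along the AP axis is the distance between the mean centers of small
#' groups of centrally located cells at the left and right plate edges; width
#' is the analogous top/bottom measurement. When a `reference` tissue (same
#' lattice, relaxed with no constriction) is given, both are normalized by
#' the reference's values.
#'
#' @param tissue Relaxed `tissue2d`.
#' @param reference Optional relaxed zero-constriction `tissue2d` on the same
#'   lattice topology.
#' @param ngroup Cells per edge group (default 5).
#' @return Named numeric vector `c(length, width)`.
#' @export
plate_dimensions <- function(tissue, reference = NULL, ngroup = 5L) {
  raw <- function(tz) {
    gr <- plate_edge_groups(tz, ngroup)
    ctr <- cell_centers(tz)
    mean_ctr <- function(idx) colMeans(ctr[idx, , drop = FALSE])
    c(length = sqrt(sum((mean_ctr(gr$right) - mean_ctr(gr$left))^2)),
      width = sqrt(sum((mean_ctr(gr$top) - mean_ctr(gr$bottom))^2)))
  }
  v <- raw(tissue)
  if (is.null(reference)) return(v)
  if (!identical(lengths(tissue$cells), lengths(reference$cells)) ||
      !identical(tissue$plate_spec, reference$plate_spec)) {
    stop("tissue and reference do not share the same lattice topology")
  }
  v / raw(reference)
}

#' Per-cell shape statistics and angle histogram
#'
#' Computes per-cell area, perimeter, gyration-tensor elongation `kappa` and
#' orientation `theta_deg` (angle to the AP axis, folded into [0, 90]), plus
#' the angle histogram, mean and standard deviation over non-constricting
#' plate cells (the population whose passive elongation the model predicts).
#'
#' @param tissue A (usually relaxed) `tissue2d`.
#' @param reference_axis Reference direction for orientation (default AP,
#'   +x).
#' @param breaks Histogram breaks in degrees.
#' @return List: `cells` (data.frame), `angle_hist` (data.frame), and
#'   `mean_angle`, `sd_angle`, `mean_kappa` over non-constricting plate
#'   cells.
#' @export
plate_cell_stats <- function(tissue, reference_axis = c(1, 0),
                             breaks = seq(0, 90, by = 10)) {
  m <- tissue_measures(tissue)
  shp <- lapply(tissue$cells, function(cc) {
    shape_summary(tissue$pos[cc, , drop = FALSE], reference_axis)
  })
  cells <- data.frame(
    cell = seq_along(tissue$cells),
    region = tissue$region,
    constricting = tissue$constricting,
    frozen = tissue$frozen,
    area = m[, "area"],
    perimeter = m[, "perimeter"],
    kappa = vapply(shp, `[[`, numeric(1), "kappa"),
    theta_deg = vapply(shp, `[[`, numeric(1), "theta_deg")
  )
  sel <- cells$region == "plate" & !cells$constricting
  th <- cells$theta_deg[sel]
  h <- hist(th, breaks = breaks, plot = FALSE)
  list(
    cells = cells,
    angle_hist = data.frame(bin_start = head(breaks, -1L),
                            bin_end = breaks[-1L], count = h$counts),
    mean_angle = mean(th),
    sd_angle = sd(th),
    mean_kappa = mean(cells$kappa[sel])
  )
}
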