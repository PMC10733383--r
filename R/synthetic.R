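# Synthetic epithelium and apical-area-track generators with ground truth.
# The tissue generator emulates segmented neural-plate-like apical surfaces:
# small (constricted) cells interspersed among larger ones with a controllable
# elongation bias, plus a junctional intensity channel in which shorter
# junctions are brighter. It is a weighted (power-diagram) tessellation built
# by direct half-plane clipping, with Lloyd centroidal iterations and a
# proportional weight controller that drives constricted cells to the target
# area ratio.

#' Parameters for the synthetic tissue generator
#'
#' @param n_cells Number of tessellation seeds (default 400).
#' @param f_c Fraction of constricted (small) cells in [0, 1].
#' @param area_ratio Target mean small/large cell area ratio (default 0.2).
#' @param target_aspect Target mean aspect ratio of the sheet's cells
#'   (elongation bias; 1 = isotropic).
#' @param orientation_deg Preferred elongation orientation in degrees
#'   (0 = along x/AP).
#' @param hinge_band Optional list(`center_frac`, `width_frac`, `fc_in`,
#'   `fc_out`): a horizontal band (fractions of image height) with its own
#'   constricted fraction inside (`fc_in`) vs outside (`fc_out`), overriding
#'   `f_c`.
#' @param intensity_a,intensity_b Junction intensity model: intensity =
#'   a - b * junction_length + noise.
#' @param intensity_noise_sd Gaussian noise s.d. of the junction intensity.
#' @param width,height Raster size in pixels.
#' @param seed RNG seed; every generator output is a pure function of the
#'   full parameter record including the seed.
#' @return A `tissue_gen_params` list.
#' @export
tissue_gen_params <- function(n_cells = 400L, f_c = 0.5, area_ratio = 0.2,
                              target_aspect = 1.6, orientation_deg = 0,
                              hinge_band = NULL,
                              intensity_a = 200, intensity_b = 2,
                              intensity_noise_sd = 5,
                              width = 512L, height = 512L, seed = 1L) {
  stopifnot(f_c >= 0, f_c <= 1, area_ratio > 0, target_aspect >= 1)
  if (width * height / n_cells < 200) {
    stop("infeasible geometry: ", n_cells, " cells on a ", width, "x",
         height, " raster leaves < 200 px per cell")
  }
  structure(list(n_cells = as.integer(n_cells), f_c = f_c,
                 area_ratio = area_ratio, target_aspect = target_aspect,
                 orientation_deg = orientation_deg, hinge_band = hinge_band,
                 intensity_a = intensity_a, intensity_b = intensity_b,
                 intensity_noise_sd = intensity_noise_sd,
                 width = as.integer(width), height = as.integer(height),
                 seed = as.integer(seed)),
            class = "tissue_gen_params")
}

# Sutherland-Hodgman clip of polygon (matrix n x 2) by half-plane
# a*x + b*y <= c
clip_halfplane <- function(poly, a, b, cc) {
  if (nrow(poly) == 0L) return(poly)
  v <- a * poly[, 1L] + b * poly[, 2L] - cc
  inside <- v <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0L, , drop = FALSE])
  n <- nrow(poly)
  jn <- c(2:n, 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    j <- jn[i]
    pts <- NULL
    if (inside[i]) pts <- poly[i, , drop = FALSE]
    if (inside[i] != inside[j]) {
      t <- v[i] / (v[i] - v[j])
      pts <- rbind(pts, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
    out[[i]] <- pts
  }
  do.call(rbind, out)
}

# power-diagram cells of weighted seeds inside rect = c(x0, y0, x1, y1);
# clips each seed's rectangle against nearest bisectors first, then any
# remaining violated ones
power_cells <- function(seeds, weights, rect, k_near = 24L) {
  n <- nrow(seeds)
  base <- rbind(c(rect[1L], rect[2L]), c(rect[3L], rect[2L]),
                c(rect[3L], rect[4L]), c(rect[1L], rect[4L]))
  s2 <- rowSums(seeds^2)
  lapply(seq_len(n), function(i) {
    d2 <- (seeds[, 1L] - seeds[i, 1L])^2 + (seeds[, 2L] - seeds[i, 2L])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    poly <- base
    bis <- function(j) {
      # keep |x-si|^2 - wi <= |x-sj|^2 - wj
      c(a = 2 * (seeds[j, 1L] - seeds[i, 1L]),
        b = 2 * (seeds[j, 2L] - seeds[i, 2L]),
        cc = s2[j] - s2[i] + weights[i] - weights[j])
    }
    for (j in head(ord, k_near)) {
      h <- bis(j)
      poly <- clip_halfplane(poly, h[1L], h[2L], h[3L])
      if (nrow(poly) == 0L) return(poly)
    }
    rest <- tail(ord, -k_near)
    if (length(rest) > 0L && nrow(poly) > 0L) {
      repeat {
        viol <- FALSE
        for (j in rest) {
          h <- bis(j)
          if (any(h[1L] * poly[, 1L] + h[2L] * poly[, 2L] > h[3L] + 1e-9)) {
            poly <- clip_halfplane(poly, h[1L], h[2L], h[3L])
            viol <- TRUE
            if (nrow(poly) == 0L) return(poly)
          }
        }
        if (!viol) break
      }
    }
    poly
  })
}

# exact area-weighted second central moments of a CCW polygon
polygon_moments <- function(poly) {
  x <- poly[, 1L]
  y <- poly[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  A <- sum(cr) / 2
  cx <- sum((x + x[j]) * cr) / (6 * A)
  cy <- sum((y + y[j]) * cr) / (6 * A)
  ixx <- sum((x^2 + x * x[j] + x[j]^2) * cr) / 12
  iyy <- sum((y^2 + y * y[j] + y[j]^2) * cr) / 12
  ixy <- sum((x * y[j] + 2 * x * y + 2 * x[j] * y[j] + x[j] * y) * cr) / 24
  cxx <- ixx / A - cx^2
  cyy <- iyy / A - cy^2
  cxy <- ixy / A - cx * cy
  S <- matrix(c(cxx, cxy, cxy, cyy), 2L)
  ev <- eigen(S, symmetric = TRUE)
  u <- ev$vectors[, 1L]
  list(area = A, centroid = c(cx, cy),
       aspect_ratio = sqrt(max(ev$values[1L], 0) /
                             max(ev$values[2L], 1e-12)),
       orientation_deg = acos(min(1, abs(u[1L]))) * 180 / pi)
}

#' Generate a synthetic polygonal tissue with ground truth
#'
#' Builds a centroidal weighted tessellation of the raster rectangle in which
#' a fraction `f_c` of cells ("constricted") are driven to `area_ratio`
#' times the area of the remaining cells, and the whole sheet is
#' anisotropically stretched to the target mean aspect ratio and
#' orientation. Ground-truth per-cell metrics are computed exactly from the
#' generated polygons (area-weighted second moments).
#'
#' @param params A [tissue_gen_params()].
#' @return List: `polygons` (CCW matrices in pixel coordinates), `truth`
#'   (data.frame cell, constricted, in_hinge, area, aspect_ratio,
#'   orientation_deg, centroid_x, centroid_y), `params`.
#' @export
generate_polygonal_tissue <- function(params) {
  stopifnot(inherits(params, "tissue_gen_params"))
  set.seed(params$seed)
  W <- params$width
  H <- params$height
  R <- params$target_aspect
  phi <- params$orientation_deg * pi / 180
  sx <- sqrt(R)
  M <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L) %*%
    diag(c(sx, 1 / sx))
  Minv <- solve(M)
  ctr <- c(W, H) / 2
  # frame rectangle: bounding box of the inverse-mapped raster corners
  corners <- rbind(c(0, 0), c(W, 0), c(W, H), c(0, H))
  fc <- t(Minv %*% (t(corners) - ctr))
  rect <- c(min(fc[, 1L]), min(fc[, 2L]), max(fc[, 1L]), max(fc[, 2L]))
  n <- params$n_cells
  seeds <- cbind(runif(n, rect[1L], rect[3L]), runif(n, rect[2L], rect[4L]))
  # constricted assignment (optionally hinge-structured, on frame y mapped
  # back to image fraction)
  if (is.null(params$hinge_band)) {
    constricted <- runif(n) < params$f_c
    in_hinge <- rep(FALSE, n)
  } else {
    hb <- params$hinge_band
    yfrac <- (seeds[, 2L] - rect[2L]) / (rect[4L] - rect[2L])
    in_hinge <- abs(yfrac - hb$center_frac) <= hb$width_frac / 2
    constricted <- runif(n) < ifelse(in_hinge, hb$fc_in, hb$fc_out)
  }
  area_tot <- (rect[3L] - rect[1L]) * (rect[4L] - rect[2L])
  a_large <- area_tot / (n * (mean(constricted) * params$area_ratio +
                                1 - mean(constricted)))
  target <- ifelse(constricted, params$area_ratio * a_large, a_large)
  weights <- rep(0, n)
  polys <- NULL
  for (it in 1:8) {
    polys <- power_cells(seeds, weights, rect)
    areas <- vapply(polys, function(p) {
      if (nrow(p) < 3L) return(0)
      abs(polygon_moments(p)$area)
    }, numeric(1))
    if (it <= 2L) {
      # Lloyd: move seeds to centroids (keeps cells compact)
      for (i in seq_len(n)) {
        if (nrow(polys[[i]]) >= 3L) {
          seeds[i, ] <- polygon_moments(polys[[i]])$centroid
        }
      }
    }
    # proportional control of power weights toward target areas
    weights <- weights + 0.8 * (target - areas) / pi
  }
  # map to image space and clip to the raster
  out_polys <- vector("list", n)
  for (i in seq_len(n)) {
    p <- polys[[i]]
    if (nrow(p) < 3L) next
    q <- t(M %*% t(p)) + rep(ctr, each = nrow(p))
    for (h in list(c(-1, 0, 0), c(1, 0, W), c(0, -1, 0), c(0, 1, H))) {
      q <- clip_halfplane(q, h[1L], h[2L], h[3L])
      if (nrow(q) == 0L) break
    }
    if (nrow(q) >= 3L) out_polys[[i]] <- q
  }
  keep <- !vapply(out_polys, is.null, logical(1))
  polys <- out_polys[keep]
  mom <- lapply(polys, polygon_moments)
  truth <- data.frame(
    cell = seq_along(polys),
    constricted = constricted[keep],
    in_hinge = in_hinge[keep],
    area = vapply(mom, `[[`, numeric(1), "area"),
    aspect_ratio = vapply(mom, `[[`, numeric(1), "aspect_ratio"),
    orientation_deg = vapply(mom, `[[`, numeric(1), "orientation_deg"),
    centroid_x = vapply(mom, function(m) m$centroid[1L], numeric(1)),
    centroid_y = vapply(mom, function(m) m$centroid[2L], numeric(1))
  )
  list(polygons = polys, truth = truth, params = params)
}

# vectorized even-odd point-in-polygon for pixel centers
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterize a synthetic tissue into a label image with intensity channel
#'
#' Fills each polygon into an integer mask (pixel centers at integer
#' coordinates; x = column, y = row), carves 1-px boundaries between cells,
#' and paints a junctional intensity channel following
#' `intensity = a - b * junction_length + N(0, noise_sd)` per junction
#' (clipped at 0); junction lengths are boundary-pixel counts. Pixels where
#' three or more cells meet get the base level `a`; cell interiors get
#' `a / 4`.
#'
#' @param tissue Output of [generate_polygonal_tissue()].
#' @return A [label_image()] with extra elements `junction_truth`
#'   (data.frame cell_a, cell_b, length_px, intensity) and `truth` carried
#'   over from the generator.
#' @export
render_label_image <- function(tissue) {
  params <- tissue$params
  set.seed(params$seed + 1L)
  W <- params$width
  H <- params$height
  lab <- matrix(0L, nrow = H, ncol = W)  # row = y, col = x
  for (i in seq_along(tissue$polygons)) {
    p <- tissue$polygons[[i]]
    xr <- pmax(1L, floor(min(p[, 1L]))):pmin(W, ceiling(max(p[, 1L])))
    yr <- pmax(1L, floor(min(p[, 2L]))):pmin(H, ceiling(max(p[, 2L])))
    if (length(xr) == 0L || length(yr) == 0L) next
    gx <- rep(xr, each = length(yr))
    gy <- rep(yr, length(xr))
    inside <- points_in_polygon(gx, gy, p)
    sel <- cbind(gy[inside], gx[inside])
    prev <- lab[sel]
    if (any(prev != 0L)) {
      stop("overlapping polygons: cell ", i, " overlaps cell ",
           prev[prev != 0L][1L])
    }
    lab[sel] <- i
  }
  # 1-px boundaries: for each differing right/down neighbor pair, zero one
  # of the two pixels on a checkerboard, so the interface line stays one
  # pixel wide and the erosion splits evenly between the two cells (a
  # one-sided rule would bias each cell's second moments)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- lab
  checker <- (outer(seq_len(H), seq_len(W), `+`) %% 2L) == 0L
  zero_mask <- matrix(FALSE, H, W)
  for (sh in list(c(1L, 0L), c(0L, 1L))) {
    nb <- pad[2:(H + 1L) + sh[1L], 2:(W + 1L) + sh[2L]]
    diffp <- nb != 0L & lab != 0L & nb != lab
    # zero this pixel on even parity, the neighbor on odd parity
    zero_mask <- zero_mask | (diffp & checker)
    shifted <- matrix(FALSE, H, W)
    src <- which(diffp & !checker, arr.ind = TRUE)
    if (nrow(src) > 0L) {
      shifted[cbind(src[, 1L] + sh[1L], src[, 2L] + sh[2L])] <- TRUE
    }
    zero_mask <- zero_mask | shifted
  }
  lab[zero_mask] <- 0L
  # intensity channel
  ints <- matrix(params$intensity_a / 4, H, W)
  bn <- .boundary_neighbor_sets(lab)
  npair <- lengths(bn$sets)
  jt <- NULL
  if (any(npair == 2L)) {
    sel <- which(npair == 2L)
    key <- vapply(bn$sets[sel], paste, character(1), collapse = "-")
    groups <- split(bn$idx[sel], key)
    jt <- do.call(rbind, lapply(names(groups), function(k) {
      ab <- as.integer(strsplit(k, "-", fixed = TRUE)[[1L]])
      len <- length(groups[[k]])
      val <- max(0, params$intensity_a - params$intensity_b * len +
                   rnorm(1, 0, params$intensity_noise_sd))
      ints[groups[[k]]] <<- val
      data.frame(cell_a = ab[1L], cell_b = ab[2L], length_px = len,
                 intensity = val)
    }))
  }
  ints[bn$idx[npair >= 3L]] <- params$intensity_a
  ints[bn$idx[npair <= 1L]] <- params$intensity_a / 4
  img <- label_image(lab, intensity = ints)
  img$junction_truth <- jt
  img$truth <- tissue$truth
  img
}

#' Parameters for the apical-area track generator
#'
#' @param n_cells Number of tracks.
#' @param f_ac,f_ae Fractions of apically constricting / expanding cells
#'   (`f_ac + f_ae <= 1`; the rest are "no-change").
#' @param change_ac,change_ae,change_none Target relative area change per
#'   class over the full recording (defaults -0.5, +0.4, 0).
#' @param noise_sd Multiplicative (log-normal) noise s.d. per timepoint.
#' @param n_timepoints Number of frames (>= 2).
#' @param mean_area Mean initial apical area (arbitrary units).
#' @param seed RNG seed.
#' @return A `track_gen_params` list.
#' @export
track_gen_params <- function(n_cells = 50L, f_ac = 0.3, f_ae = 0.3,
                             change_ac = -0.5, change_ae = 0.4,
                             change_none = 0, noise_sd = 0.05,
                             n_timepoints = 20L, mean_area = 100,
                             seed = 1L) {
  stopifnot(f_ac + f_ae <= 1, n_timepoints >= 2L)
  structure(list(n_cells = as.integer(n_cells), f_ac = f_ac, f_ae = f_ae,
                 change_ac = change_ac, change_ae = change_ae,
                 change_none = change_none, noise_sd = noise_sd,
                 n_timepoints = as.integer(n_timepoints),
                 mean_area = mean_area, seed = as.integer(seed)),
            class = "track_gen_params")
}

#' Generate synthetic apical-area tracks with ground-truth classes
#'
#' Each track drifts geometrically from its initial area to
#' `initial * (1 + change)` across the recording, with independent
#' multiplicative log-normal noise at every timepoint.
#'
#' @param params A [track_gen_params()].
#' @return List: `tracks` (long data.frame cell_id, t, area), `truth`
#'   (data.frame cell_id, true_class, true_change), `params`.
#' @export
generate_area_tracks <- function(params) {
  stopifnot(inherits(params, "track_gen_params"))
  set.seed(params$seed)
  n <- params$n_cells
  nt <- params$n_timepoints
  n_ac <- round(params$f_ac * n)
  n_ae <- round(params$f_ae * n)
  cls <- sample(rep(c("AC", "AE", "no-change"),
                    c(n_ac, n_ae, n - n_ac - n_ae)))
  change <- c(AC = params$change_ac, AE = params$change_ae,
              `no-change` = params$change_none)[cls]
  a0 <- rlnorm(n, log(params$mean_area), 0.25)
  tfrac <- (seq_len(nt) - 1) / (nt - 1)
  areas <- outer(change, tfrac, function(ch, f) (1 + ch)^f) * a0
  noise <- matrix(rlnorm(n * nt, 0, params$noise_sd), n, nt)
  areas <- areas * noise
  tracks <- data.frame(
    cell_id = rep(seq_len(n), nt),
    t = rep(seq_len(nt), each = n),
    area = as.vector(areas)
  )
  list(tracks = tracks,
       truth = data.frame(cell_id = seq_len(n), true_class = cls,
                          true_change = unname(change)),
       params = params)
}
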