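# Independent oracles and small fixtures shared across tests.

# central finite-difference gradient of the 2D tissue energy
fd_grad2d <- function(tissue, h = 1e-6) {
  g <- matrix(0, nrow(tissue$pos), 2L)
  for (i in seq_len(nrow(tissue$pos))) {
    for (d in 1:2) {
      pp <- tissue$pos
      pp[i, d] <- pp[i, d] + h
      pm <- tissue$pos
      pm[i, d] <- pm[i, d] - h
      ep <- nfvm:::energy2d_cpp(pp, tissue$cell_ptr, tissue$cvert,
                                tissue$p0, tissue$kp)
      em <- nfvm:::energy2d_cpp(pm, tissue$cell_ptr, tissue$cvert,
                                tissue$p0, tissue$kp)
      g[i, d] <- (ep - em) / (2 * h)
    }
  }
  g
}

fd_grad3d <- function(tissue, h = 1e-6, vertices = NULL) {
  if (is.null(vertices)) vertices <- seq_len(nrow(tissue$pos))
  g <- matrix(0, length(vertices), 3L)
  e_of <- function(p) {
    nfvm:::energy3d_cpp(p, tissue$cell_ptr, tissue$avert, tissue$bvert,
                        tissue$xoff, tissue$p0, tissue$alpha, tissue$beta,
                        tissue$kp, tissue$kV)
  }
  for (k in seq_along(vertices)) {
    i <- vertices[k]
    for (d in 1:3) {
      pp <- tissue$pos
      pp[i, d] <- pp[i, d] + h
      pm <- tissue$pos
      pm[i, d] <- pm[i, d] - h
      g[k, d] <- (e_of(pp) - e_of(pm)) / (2 * h)
    }
  }
  g
}

# random convex polygon: convex hull of random points, CCW
random_convex_polygon <- function(n = 12L) {
  pts <- cbind(runif(n, -2, 2), runif(n, -1, 3))
  hull <- rev(grDevices::chull(pts))
  pts[hull, , drop = FALSE]
}

# Monte-Carlo rejection-sampling area of a convex polygon
mc_polygon_area <- function(poly, n = 40000L) {
  xr <- range(poly[, 1L])
  yr <- range(poly[, 2L])
  px <- runif(n, xr[1L], xr[2L])
  py <- runif(n, yr[1L], yr[2L])
  inside <- nfvm:::points_in_polygon(px, py, poly)
  mean(inside) * diff(xr) * diff(yr)
}

# minimal hand-built single-cell tissue2d (for exact energy checks)
single_cell_tissue <- function(loop, p0 = 3.7, kp = 1) {
  loop <- as.matrix(loop)
  structure(list(
    pos = loop,
    cells = list(seq_len(nrow(loop))),
    cell_ptr = c(0L, nrow(loop)),
    cvert = seq_len(nrow(loop)) - 1L,
    region = "plate",
    constricting = FALSE,
    frozen = FALSE,
    p0 = p0,
    kp = kp,
    free_vertex = rep(TRUE, nrow(loop))
  ), class = "tissue2d")
}

fold90 <- function(theta) {
  th <- theta %% 180
  ifelse(th > 90, 180 - th, th)
}
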