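# Hexagonal-lattice tissue construction and exact polygon / shape-tensor
# geometry shared by the 2D solver, the 3D solver and the morphometrics stage.
#
# Tissues are stored in dimensionless units with unit cell target area, so the
# regular hexagon has side sqrt(2/(3*sqrt(3))) and perimeter 3.72242.
#
# Lattice layout: flat-top hexagons in columns along the AP (x) axis; every
# second column is shifted by half a cell height in y. The neural-plate region
# is the set of cells whose centers fall inside a centered N_x-by-N_y window
# (measured in cell units); because of the half-cell column offset, every
# second plate column picks up one extra cell, making the region symmetric
# about the AP axis.

#' Build a hexagonal-lattice tissue with a centered plate region
#'
#' Constructs a regular honeycomb of `npx` by `npy` unit-area hexagonal cells
#' with a centered `plate` region of `nx` by `ny` cells, shared vertices, and
#' a frozen outermost cell ring (fixed boundary conditions).
#'
#' @param npx,npy Number of cells along the AP (x) axis and perpendicular to
#'   it for the whole simulated tissue.
#' @param nx,ny Plate (neural plate region) extent in cells along x and y.
#' @param p0 Target perimeter of every cell (dimensionless); default 3.7.
#' @param kp Perimeter elasticity modulus; default 1.
#' @return A `tissue2d` object: list with vertex positions (`pos`, V x 2),
#'   cell loops (`cells`, 1-based CCW indices), flat loop storage
#'   (`cell_ptr`/`cvert`, 0-based, for the compiled kernels), per-cell
#'   `region` ("plate"/"exterior"), `constricting`, `frozen`, `p0`, grid
#'   indices, lattice centers and the free-vertex mask.
#' @export
build_hex_lattice <- function(npx, npy, nx, ny, p0 = 3.7, kp = 1) {
  if (nx + 2 > npx || ny + 2 > npy) {
    stop("plate (", nx, "x", ny, ") does not fit inside the ", npx, "x", npy,
         " tissue: need npx >= nx + 2 and npy >= ny + 2 to leave room for ",
         "the frozen boundary ring")
  }
  s <- hex_side()
  hy <- sqrt(3) * s            # cell height (y spacing within a column)
  hx <- 1.5 * s                # column spacing along x
  grid <- expand.grid(ix = seq_len(npx) - 1L, iy = seq_len(npy) - 1L)
  grid <- grid[order(grid$iy, grid$ix), , drop = FALSE]  # row-major cell order
  rownames(grid) <- NULL
  cx <- grid$ix * hx
  cy <- grid$iy * hy + (grid$ix %% 2L) * hy / 2
  nc <- nrow(grid)
  # flat-top hexagon corners, CCW
  ang <- (0:5) * pi / 3
  dx <- s * cos(ang)
  dy <- s * sin(ang)
  vx <- rep(cx, each = 6L) + rep(dx, nc)
  vy <- rep(cy, each = 6L) + rep(dy, nc)
  key <- paste(round(vx, 9L), round(vy, 9L))
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  pos <- cbind(x = vx[uk], y = vy[uk])
  cells <- split(vid, rep(seq_len(nc), each = 6L))
  names(cells) <- NULL

  # frozen ring: cells owning at least one unshared (boundary) edge
  v1 <- vid
  v2 <- vid[rep(seq(0L, nc - 1L) * 6L, each = 6L) + rep(c(2:6, 1L), nc)]
  ekey <- paste(pmin(v1, v2), pmax(v1, v2))
  eshared <- ave(ekey, ekey, FUN = length)
  frozen <- as.logical(tapply(eshared == "1",
                              rep(seq_len(nc), each = 6L), any))

  # plate membership: centers inside the centered nx-by-ny window (cell units)
  bx <- (npx - nx) %/% 2L
  x_in <- grid$ix >= bx & grid$ix <= bx + nx - 1L
  ay <- (npy - ny) %/% 2L
  yc <- (ay + (ny - 1) / 2) * hy          # plate centerline (the AP axis)
  y_in <- abs(cy - yc) <= ny * hy / 2 + 1e-9
  region <- ifelse(x_in & y_in, "plate", "exterior")

  free_vertex <- rep(TRUE, nrow(pos))
  free_vertex[unique(unlist(cells[frozen]))] <- FALSE

  structure(list(
    pos = pos,
    cells = cells,
    cell_ptr = c(0L, cumsum(lengths(cells))),
    cvert = unlist(cells) - 1L,
    region = region,
    constricting = rep(FALSE, nc),
    frozen = frozen,
    p0 = rep(as.numeric(p0), nc),
    kp = as.numeric(kp),
    grid = grid,
    centers = cbind(x = cx, y = cy),
    plate_spec = c(nx = nx, ny = ny),
    tissue_spec = c(npx = npx, npy = npy),
    plate_centerline = yc,
    free_vertex = free_vertex
  ), class = "tissue2d")
}

#' @export
print.tissue2d <- function(x, ...) {
  cat("tissue2d: ", length(x$cells), " cells (",
      sum(x$region == "plate"), " plate, ",
      sum(x$frozen), " frozen, ", sum(x$constricting), " constricting), ",
      nrow(x$pos), " vertices\n", sep = "")
  invisible(x)
}

#' Area and perimeter of a simple polygon
#'
#' Shoelace signed area (must be positive, i.e. counterclockwise loop) and
#' Euclidean perimeter of the closed loop.
#'
#' @param loop Numeric matrix (n x 2) of ordered vertices, counterclockwise.
#' @return Named numeric vector `c(area, perimeter)`.
#' @export
polygon_measures <- function(loop) {
  loop <- as.matrix(loop)
  if (nrow(loop) < 3L) stop("degenerate polygon: need at least 3 points")
  j <- c(2:nrow(loop), 1L)
  a <- 0.5 * sum(loop[, 1L] * loop[j, 1L + 1L] - loop[j, 1L] * loop[, 2L])
  if (a <= 0) {
    stop("polygon orientation error: signed area ", signif(a, 6),
         " is not positive (loop must be counterclockwise)")
  }
  p <- sum(sqrt(rowSums((loop[j, , drop = FALSE] - loop)^2)))
  c(area = a, perimeter = p)
}

# per-cell (area, perimeter) for a whole tissue, via the compiled kernel
tissue_measures <- function(tissue) {
  m <- cell_measures2d_cpp(tissue$pos, tissue$cell_ptr, tissue$cvert)
  colnames(m) <- c("area", "perimeter")
  m
}

fold_angle <- function(theta_deg) {
  th <- theta_deg %% 180
  ifelse(th > 90, 180 - th, th)
}

#' Gyration-tensor shape summary of a point set
#'
#' Computes the gyration tensor \eqn{S = (1/n) \sum (r_i - \bar r) \otimes
#' (r_i - \bar r)} about the unweighted vertex mean, the elongation
#' \eqn{\kappa = (g_1 - g_2)/(g_1 + g_2)} from its two leading eigenvalues,
#' and the orientation angle of the leading eigenvector relative to a
#' reference axis, folded into [0, 90] degrees (eigenvector sign removed).
#'
#' @param points Numeric matrix (n x 2 or n x 3) of vertex positions.
#' @param reference_axis Unit reference direction (default the AP axis, +x).
#' @return List with `S`, `eigenvalues` (decreasing), `kappa`, `theta_deg`.
#' @export
shape_summary <- function(points, reference_axis = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  d <- ncol(points)
  if (is.null(reference_axis)) reference_axis <- c(1, rep(0, d - 1L))
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  if (max(abs(x)) < 1e-14) {
    stop("degenerate point set: all points coincident, elongation undefined")
  }
  S <- crossprod(x) / nrow(points)
  ev <- eigen(S, symmetric = TRUE)
  g <- ev$values
  kappa <- (g[1L] - g[2L]) / (g[1L] + g[2L])
  u <- ev$vectors[, 1L]
  a <- reference_axis / sqrt(sum(reference_axis^2))
  cosang <- min(1, abs(sum(u * a)))
  list(S = S, eigenvalues = g, kappa = kappa,
       theta_deg = acos(cosang) * 180 / pi)
}

#' Serialize a tissue to JSON
#'
#' Writes vertices, cell loops, per-cell flags and mechanical parameters to a
#' self-contained JSON document (schema: `nfvm-tissue2d-1`).
#'
#' @param tissue A `tissue2d`.
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @export
tissue_to_json <- function(tissue, path = NULL) {
  doc <- list(
    schema = "nfvm-tissue2d-1",
    vertices = unname(tissue$pos),
    cells = tissue$cells,
    region = tissue$region,
    constricting = tissue$constricting,
    frozen = tissue$frozen,
    p0 = tissue$p0,
    kp = tissue$kp,
    plate_spec = as.list(tissue$plate_spec),
    tissue_spec = as.list(tissue$tissue_spec)
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a tissue written by [tissue_to_json()]
#' @param path JSON file path.
#' @return A `tissue2d`.
#' @export
tissue_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  stopifnot(identical(doc$schema, "nfvm-tissue2d-1"))
  cells <- if (is.matrix(doc$cells)) {
    lapply(seq_len(nrow(doc$cells)), function(i) as.integer(doc$cells[i, ]))
  } else {
    lapply(doc$cells, as.integer)
  }
  pos <- as.matrix(doc$vertices)
  colnames(pos) <- c("x", "y")
  tz <- structure(list(
    pos = pos,
    cells = cells,
    cell_ptr = c(0L, cumsum(lengths(cells))),
    cvert = unlist(cells) - 1L,
    region = doc$region,
    constricting = doc$constricting,
    frozen = doc$frozen,
    p0 = doc$p0,
    kp = doc$kp,
    plate_spec = unlist(doc$plate_spec),
    tissue_spec = unlist(doc$tissue_spec),
    free_vertex = rep(TRUE, nrow(pos))
  ), class = "tissue2d")
  tz$free_vertex[unique(unlist(cells[tz$frozen]))] <- FALSE
  tz
}

#' Export a tissue mesh as OFF
#'
#' Polygonal faces over the shared vertex set; 2D tissues are embedded at
#' z = 0.
#' @param tissue A `tissue2d`.
#' @param path Output `.off` file.
#' @export
write_off <- function(tissue, path) {
  pos <- cbind(tissue$pos, 0)[, 1:3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(pos), length(tissue$cells)), con)
  writeLines(sprintf("%.12g %.12g %.12g", pos[, 1], pos[, 2], pos[, 3]), con)
  writeLines(vapply(tissue$cells, function(cc) {
    paste(c(length(cc), cc - 1L), collapse = " ")
  }, character(1)), con)
  invisible(path)
}

#' Export a tissue mesh as legacy VTK polydata
#' @param tissue A `tissue2d`.
#' @param path Output `.vtk` file.
#' @export
write_vtk <- function(tissue, path) {
  pos <- cbind(tissue$pos, 0)[, 1:3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "nfvm tissue", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(pos))), con)
  writeLines(sprintf("%.12g %.12g %.12g", pos[, 1], pos[, 2], pos[, 3]), con)
  nidx <- sum(lengths(tissue$cells)) + length(tissue$cells)
  writeLines(sprintf("POLYGONS %d %d", length(tissue$cells), nidx), con)
  writeLines(vapply(tissue$cells, function(cc) {
    paste(c(length(cc), cc - 1L), collapse = " ")
  }, character(1)), con)
  writeLines(c(sprintf("CELL_DATA %d", length(tissue$cells)),
               "SCALARS constricting int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(tissue$constricting)), con)
  invisible(path)
}
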