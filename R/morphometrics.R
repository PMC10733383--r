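# Label-image morphometrics: the quantification stage applied to segmented
# apical surfaces. Works on 2D integer label masks (0 = boundary/background)
# with an optional registered intensity channel, and on per-cell apical-area
# time series.
#
# Note the deliberate distinction from the solvers' gyration tensor: here the
# shape tensor is the area-weighted (per-pixel) normalized second central
# moment matrix, as is standard for segmented images; the solvers use the
# unweighted vertex gyration tensor.

#' Construct a label image
#'
#' @param labels Integer matrix; 0 marks boundary/background pixels, values
#'   >= 1 are cell ids.
#' @param intensity Optional numeric matrix of identical shape.
#' @param pixel_size Optional pixel edge length in microns.
#' @param regions Optional named character vector mapping cell id to a region
#'   annotation ("hinge", "non-hinge", ...).
#' @return A `label_image`.
#' @export
label_image <- function(labels, intensity = NULL, pixel_size = NULL,
                        regions = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!is.null(intensity)) {
    intensity <- as.matrix(intensity)
    if (!identical(dim(intensity), dim(labels))) {
      stop("intensity channel shape ", paste(dim(intensity), collapse = "x"),
           " does not match label shape ", paste(dim(labels), collapse = "x"))
    }
  }
  structure(list(labels = labels, intensity = intensity,
                 pixel_size = pixel_size, regions = regions),
            class = "label_image")
}

#' Read a label mask from TIFF or PNG
#'
#' 16-bit (or 8-bit) single-channel images; pixel values are taken as integer
#' cell ids (0 = boundary/background).
#' @param path Image file (.tif/.tiff/.png).
#' @param intensity_path Optional registered intensity image.
#' @param pixel_size Optional microns per pixel.
#' @param regions Optional region annotation (see [label_image()]).
#' @return A `label_image`.
#' @export
read_label_image <- function(path, intensity_path = NULL, pixel_size = NULL,
                             regions = NULL) {
  read1 <- function(p, as_int) {
    ext <- tolower(tools::file_ext(p))
    if (ext %in% c("tif", "tiff")) {
      x <- tiff::readTIFF(p, as.is = TRUE)
    } else if (ext == "png") {
      x <- png::readPNG(p)
      # readPNG scales to [0,1]; recover integer codes from the bit depth
      x <- x * 65535
      if (max(x) < 256 && as_int) x <- x / 257
    } else {
      stop("unsupported image format: ", ext)
    }
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    if (as_int) round(x) else x
  }
  label_image(read1(path, TRUE),
              intensity = if (!is.null(intensity_path)) {
                read1(intensity_path, FALSE)
              },
              pixel_size = pixel_size, regions = regions)
}

#' Write a label image (and intensity channel) as 16-bit TIFF
#'
#' @param img A [label_image()].
#' @param path Output TIFF for the label mask.
#' @param intensity_path Optional output TIFF for the intensity channel
#'   (scaled to the 16-bit range by its maximum).
#' @export
write_label_image <- function(img, path, intensity_path = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("writing TIFF requires the 'tiff' package")
  }
  if (max(img$labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(img$labels / 65535, path, bits.per.sample = 16L)
  if (!is.null(intensity_path)) {
    if (is.null(img$intensity)) stop("label image has no intensity channel")
    sc <- max(img$intensity, 1e-12)
    tiff::writeTIFF(img$intensity / sc, intensity_path,
                    bits.per.sample = 16L)
  }
  invisible(path)
}

#' Per-cell shape metrics from a label image
#'
#' For each labeled region: pixel area (scaled by `pixel_size^2` when given),
#' boundary-pixel perimeter, aspect ratio and orientation from the
#' eigen-decomposition of the normalized second central moment matrix (the
#' ellipse with matching second moments), solidity (area / convex hull
#' area) and centroid. Regions smaller than 4 pixels are flagged degenerate
#' and get `NA` aspect ratio and orientation.
#'
#' @param img A [label_image()].
#' @param reference_axis 2-vector; orientation is measured against it and
#'   folded into [0, 90] degrees. Default the image x axis (= AP axis).
#' @return data.frame with one row per cell id.
#' @export
region_shape_metrics <- function(img, reference_axis = c(1, 0)) {
  lab <- img$labels
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) stop("no labeled regions in image")
  idx <- which(lab > 0L)
  rr <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  # x along columns, y along rows so that axis conventions match plots
  px <- as.numeric(cc)
  py <- as.numeric(rr)
  f <- factor(lab[idx], levels = ids)
  n <- as.integer(table(f))
  mx <- tapply(px, f, mean)
  my <- tapply(py, f, mean)
  # second central moments with the standard 1/12 pixel-self-variance term
  cxx <- tapply(px^2, f, mean) - mx^2 + 1 / 12
  cyy <- tapply(py^2, f, mean) - my^2 + 1 / 12
  cxy <- tapply(px * py, f, mean) - mx * my
  scale <- if (is.null(img$pixel_size)) 1 else img$pixel_size
  a <- reference_axis / sqrt(sum(reference_axis^2))
  out <- data.frame(cell = ids, n_pixels = n,
                    area = n * scale^2,
                    perimeter = NA_real_, aspect_ratio = NA_real_,
                    orientation_deg = NA_real_, solidity = NA_real_,
                    centroid_x = as.numeric(mx) * scale,
                    centroid_y = as.numeric(my) * scale,
                    degenerate = n < 4L)
  # boundary-adjacent perimeter: pixels with a 4-neighbor of different label
  pad <- matrix(-1L, nrow(lab) + 2L, ncol(lab) + 2L)
  pad[2:(nrow(lab) + 1L), 2:(ncol(lab) + 1L)] <- lab
  ctr <- pad[2:(nrow(lab) + 1L), 2:(ncol(lab) + 1L)]
  on_bnd <- (pad[1:nrow(lab), 2:(ncol(lab) + 1L)] != ctr) |
    (pad[3:(nrow(lab) + 2L), 2:(ncol(lab) + 1L)] != ctr) |
    (pad[2:(nrow(lab) + 1L), 1:ncol(lab)] != ctr) |
    (pad[2:(nrow(lab) + 1L), 3:(ncol(lab) + 2L)] != ctr)
  bidx <- which(lab > 0L & on_bnd)
  bt <- table(factor(lab[bidx], levels = ids))
  out$perimeter <- as.integer(bt) * scale
  for (k in seq_along(ids)) {
    if (out$degenerate[k]) next
    sel <- which(f == levels(f)[k])
    S <- matrix(c(cxx[k], cxy[k], cxy[k], cyy[k]), 2L)
    ev <- eigen(S, symmetric = TRUE)
    out$aspect_ratio[k] <- sqrt(ev$values[1L] / max(ev$values[2L], 1e-12))
    u <- ev$vectors[, 1L]
    out$orientation_deg[k] <- acos(min(1, abs(sum(u * a)))) * 180 / pi
    hull <- rev(grDevices::chull(px[sel], py[sel]))  # chull is clockwise
    ha <- tryCatch(polygon_measures(cbind(px[sel][hull],
                                          py[sel][hull]))[["area"]],
                   error = function(e) NA_real_)
    # hull of pixel centers underestimates the pixelated region: pad by the
    # half-pixel rim before forming the ratio
    out$solidity[k] <- if (is.na(ha) || ha <= 0) {
      1
    } else {
      min(1, n[k] / (ha + length(hull) / 2 + 1))
    }
  }
  out
}

#' Classify apical domain dynamics (AC / AE / no-change)
#'
#' Relative change of each track is (final - initial)/initial; a track is
#' apically constricting (AC) below `-threshold`, apically expanding (AE)
#' above `+threshold`, otherwise "no-change". The default 20% threshold is
#' the scoring rule used on the imaging data.
#'
#' @param tracks data.frame with columns `cell_id`, `t`, `area` (long
#'   format), or a list of numeric area vectors.
#' @param threshold Relative-change threshold (default 0.20).
#' @param baseline "first_last" (default) compares first and last frames;
#'   "min_max" scores AC from max-to-min decrease and AE from min-to-max
#'   increase.
#' @return List: `tracks` (data.frame cell_id, initial, final,
#'   relative_change, class), `frequency` (table over AC/AE/no-change).
#' @export
classify_apical_dynamics <- function(tracks, threshold = 0.20,
                                     baseline = c("first_last", "min_max")) {
  baseline <- match.arg(baseline)
  if (is.data.frame(tracks)) {
    stopifnot(all(c("cell_id", "t", "area") %in% names(tracks)))
    tracks <- tracks[order(tracks$cell_id, tracks$t), ]
    lst <- split(tracks$area, tracks$cell_id)
  } else {
    lst <- tracks
    if (is.null(names(lst))) names(lst) <- seq_along(lst)
  }
  if (any(lengths(lst) < 2L)) stop("every track needs at least 2 timepoints")
  init <- vapply(lst, `[`, numeric(1), 1L)
  fin <- vapply(lst, function(x) x[length(x)], numeric(1))
  if (any(init <= 0)) stop("non-positive initial apical area")
  rel <- if (baseline == "first_last") {
    (fin - init) / init
  } else {
    # largest forward-in-time excursion: deepest drop from a preceding
    # maximum vs highest rise from a preceding minimum; the larger
    # magnitude decides
    vapply(lst, function(x) {
      dn <- min(x / cummax(x)) - 1
      up <- max(x / cummin(x)) - 1
      if (abs(dn) >= up) dn else up
    }, numeric(1))
  }
  cls <- ifelse(rel < -threshold, "AC",
                ifelse(rel > threshold, "AE", "no-change"))
  df <- data.frame(cell_id = names(lst), initial = init, final = fin,
                   relative_change = rel,
                   class = factor(cls, levels = c("AC", "AE", "no-change")),
                   row.names = NULL)
  list(tracks = df, frequency = table(df$class))
}

#' Mean, standard deviation and coefficient of variation
#'
#' Sample (n-1) standard deviation; CV = s.d. / mean.
#' @param values Numeric vector, length >= 2.
#' @return Named vector `c(mean, sd, cv)`.
#' @export
dispersion_stats <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  s <- sd(values)
  if (m == 0) stop("mean is zero: CV undefined")
  c(mean = m, sd = s, cv = s / m)
}

# 8-connected neighbor labels of every boundary pixel, as a list keyed by
# linear index
.boundary_neighbor_sets <- function(lab) {
  nr <- nrow(lab)
  nc <- ncol(lab)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  bidx <- which(lab == 0L)
  if (length(bidx) == 0L) return(list(idx = integer(0), sets = list()))
  r <- (bidx - 1L) %% nr + 2L
  cc <- (bidx - 1L) %/% nr + 2L
  shifts <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                  c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  nb <- matrix(0L, length(bidx), 8L)
  for (k in 1:8) {
    nb[, k] <- pad[cbind(r + shifts[k, 1L], cc + shifts[k, 2L])]
  }
  sets <- apply(nb, 1L, function(v) sort(unique(v[v > 0L])),
                simplify = FALSE)
  list(idx = bidx, sets = sets)
}

#' Junction and cytoplasm intensity quantification
#'
#' Junctions are maximal sets of boundary (label 0) pixels whose 8-connected
#' neighborhood touches exactly one pair of cell ids; pixels touching three
#' or more cells are network vertices and are reported separately. Mean
#' protein intensity per junction is measured over the junction mask dilated
#' by `dilation_radius` pixels; per-cell cytoplasmic intensity over the cell
#' mask eroded by `erosion_radius` pixels.
#'
#' @param img A [label_image()] with an intensity channel.
#' @param dilation_radius Junction mask dilation in pixels (default 1).
#' @param erosion_radius Cell interior erosion in pixels (default 1).
#' @return List: `junctions` (data.frame cell_a, cell_b, length_px, length,
#'   mean_intensity), `vertices` (data.frame: n pixels, mean intensity),
#'   `cytoplasm` (data.frame cell, mean_intensity).
#' @export
junction_intensities <- function(img, dilation_radius = 1L,
                                 erosion_radius = 1L) {
  if (is.null(img$intensity)) stop("label image has no intensity channel")
  lab <- img$labels
  ints <- img$intensity
  bn <- .boundary_neighbor_sets(lab)
  npair <- lengths(bn$sets)
  scale <- if (is.null(img$pixel_size)) 1 else img$pixel_size
  pair_sel <- which(npair == 2L)
  vert_sel <- which(npair >= 3L)
  junctions <- data.frame(cell_a = integer(0), cell_b = integer(0),
                          length_px = integer(0), length = numeric(0),
                          mean_intensity = numeric(0))
  if (length(pair_sel) > 0L) {
    key <- vapply(bn$sets[pair_sel], paste, character(1), collapse = "-")
    groups <- split(bn$idx[pair_sel], key)
    dil <- function(idx) {
      if (dilation_radius < 1L) return(idx)
      nr <- nrow(lab)
      nc <- ncol(lab)
      r0 <- (idx - 1L) %% nr + 1L
      c0 <- (idx - 1L) %/% nr + 1L
      off <- expand.grid(dr = -dilation_radius:dilation_radius,
                         dc = -dilation_radius:dilation_radius)
      rr <- pmin(pmax(rep(r0, nrow(off)) + rep(off$dr, each = length(idx)),
                      1L), nr)
      cc <- pmin(pmax(rep(c0, nrow(off)) + rep(off$dc, each = length(idx)),
                      1L), nc)
      unique((cc - 1L) * nr + rr)
    }
    junctions <- do.call(rbind, lapply(names(groups), function(k) {
      ab <- as.integer(strsplit(k, "-", fixed = TRUE)[[1L]])
      idx <- groups[[k]]
      data.frame(cell_a = ab[1L], cell_b = ab[2L],
                 length_px = length(idx),
                 length = length(idx) * scale,
                 mean_intensity = mean(ints[dil(idx)]))
    }))
    junctions <- junctions[order(junctions$cell_a, junctions$cell_b), ]
    rownames(junctions) <- NULL
  }
  vertices <- data.frame(
    n_pixels = length(vert_sel),
    mean_intensity = if (length(vert_sel)) mean(ints[bn$idx[vert_sel]])
    else NA_real_)
  # eroded cell interiors
  ids <- sort(unique(lab[lab > 0L]))
  ero <- lab
  if (erosion_radius >= 1L) {
    nr <- nrow(lab)
    nc <- ncol(lab)
    for (k in seq_len(erosion_radius)) {
      pad <- matrix(0L, nr + 2L, nc + 2L)
      pad[2:(nr + 1L), 2:(nc + 1L)] <- ero
      keep <- (pad[1:nr, 2:(nc + 1L)] == ero) &
        (pad[3:(nr + 2L), 2:(nc + 1L)] == ero) &
        (pad[2:(nr + 1L), 1:nc] == ero) &
        (pad[2:(nr + 1L), 3:(nc + 2L)] == ero)
      ero[!keep] <- 0L
    }
  }
  cyto <- data.frame(cell = ids, mean_intensity = vapply(ids, function(id) {
    sel <- ero == id
    if (!any(sel)) {
      sel <- lab == id  # erosion removed the whole cell: fall back
    }
    mean(ints[sel])
  }, numeric(1)))
  list(junctions = junctions, vertices = vertices, cytoplasm = cyto)
}
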