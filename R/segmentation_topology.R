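#' Construct a segmented frame from a label matrix
#'
#' A segmented frame wraps a 2D integer label image (0 = background, each
#' positive label one cell) together with its pixel size and an optional
#' timestamp. Per-cell topology and geometry are added by
#' [analyze_frame()].
#'
#' @param labels integer matrix; non-negative, 0 reserved for background.
#' @param pixel_size physical length of one pixel edge (default 1, i.e.
#'   areas are in pixels^2).
#' @param timestamp optional frame time (e.g. hours after stratification).
#' @return a `segmented_frame` object.
#' @export
segmented_frame <- function(labels, pixel_size = 1, timestamp = NULL) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  if (is.double(labels)) {
    if (any(labels != round(labels)))
      stop("label image contains non-integer values; segmentations must be ",
           "integer-labelled")
    storage.mode(labels) <- "integer"
  }
  if (any(labels < 0L)) stop("labels must be non-negative")
  if (all(labels == 0L)) warning("label image is empty (all background)")
  structure(list(labels = labels, pixel_size = pixel_size,
                 timestamp = timestamp, adjacency = NULL, cells = NULL),
            class = "segmented_frame")
}

#' @export
print.segmented_frame <- function(x, ...) {
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat("segmented_frame:", nrow(x$labels), "x", ncol(x$labels), "px,",
      length(ids), "cells",
      if (!is.null(x$cells)) "(analysed)" else "(not analysed)", "\n")
  invisible(x)
}

#' Read a segmented label image (TIFF or PNG)
#'
#' Labels are preserved bit-exactly; greyscale 8/16-bit images are
#' supported. Multi-channel (RGB) images and floating-point TIFFs are
#' rejected: a segmentation must carry one integer label per pixel.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param pixel_size,timestamp passed to [segmented_frame()].
#' @return a `segmented_frame`.
#' @export
read_label_image <- function(path, pixel_size = 1, timestamp = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L)
      stop("multi-channel TIFF is not a label image: ", path)
    if (is.double(img) && any(img != round(img)))
      stop("floating-point TIFF is not a label image: ", path)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    if (length(dim(img)) == 3L)
      stop("RGB PNG without a palette is not a label image: ", path)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    img <- round(img * (2^depth - 1))
    attributes(img) <- list(dim = dim(img))
  } else {
    stop("unsupported label-image format: ", ext)
  }
  storage.mode(img) <- "integer"
  segmented_frame(img, pixel_size = pixel_size, timestamp = timestamp)
}

#' Write a label matrix as a 16-bit greyscale TIFF
#'
#' Inverse of [read_label_image()] for labels up to 65535; round-trips
#' bit-exactly.
#'
#' @param frame a `segmented_frame` or an integer label matrix.
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_label_image <- function(frame, path) {
  labels <- if (inherits(frame, "segmented_frame")) frame$labels else frame
  stopifnot(is.matrix(labels), max(labels) <= 65535L)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

.label_ids <- function(labels) sort(setdiff(unique(as.vector(labels)), 0L))

#' Region adjacency from a label image
#'
#' Cells i and j are adjacent iff some pixel of i is 4-connected to some
#' pixel of j. Corner-only (diagonal) contact is not adjacency: it would
#' correspond to a four-way cell junction, which both real tissue and the
#' division model exclude. Segmentations that separate cells by a
#' one-pixel background membrane are supported via `membrane = 1`, which
#' additionally links labels facing each other across a single background
#' pixel orthogonally.
#'
#' @param frame a `segmented_frame` (or label matrix).
#' @param membrane 0 (default) or 1: background thickness to bridge.
#' @return named list mapping each label to the sorted integer vector of
#'   its neighbours.
#' @export
build_adjacency <- function(frame, membrane = 0) {
  L <- if (inherits(frame, "segmented_frame")) frame$labels else frame
  stopifnot(membrane %in% c(0, 1))
  nr <- nrow(L); nc <- ncol(L)
  pairs <- rbind(
    cbind(as.vector(L[-nr, , drop = FALSE]), as.vector(L[-1, , drop = FALSE])),
    cbind(as.vector(L[, -nc, drop = FALSE]), as.vector(L[, -1, drop = FALSE])))
  if (membrane == 1 && nr > 2 && nc > 2) {
    up <- L[-c(nr - 1L, nr), , drop = FALSE]
    mid <- L[-c(1L, nr), , drop = FALSE]
    dn <- L[-c(1L, 2L), , drop = FALSE]
    sel <- mid == 0L
    pairs <- rbind(pairs, cbind(up[sel], dn[sel]))
    le <- L[, -c(nc - 1L, nc), drop = FALSE]
    mi <- L[, -c(1L, nc), drop = FALSE]
    ri <- L[, -c(1L, 2L), drop = FALSE]
    sel <- mi == 0L
    pairs <- rbind(pairs, cbind(le[sel], ri[sel]))
  }
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  pairs <- unique(rbind(pairs, pairs[, 2:1, drop = FALSE]))
  ids <- .label_ids(L)
  adj <- split(pairs[, 2L], factor(pairs[, 1L], levels = ids))
  adj <- lapply(adj, function(v) sort(unique(as.integer(v))))
  names(adj) <- as.character(ids)
  adj
}

#' Boundary-validity tiers for the cells of a frame
#'
#' Statistics on segmented tissue must exclude cells whose neighbourhood is
#' not fully captured. Three nested tiers are computed:
#' \describe{
#'   \item{interior}{the cell touches neither the image border nor
#'     background.}
#'   \item{neighbour_complete}{interior, and all neighbours interior:
#'     required wherever a neighbour's record enters a statistic (m_n,
#'     normalised area).}
#'   \item{second_order_complete}{neighbour-complete with all neighbours
#'     neighbour-complete: required when neighbours' own normalisations
#'     enter (neighbour-mean normalised area).}
#' }
#'
#' @param frame a `segmented_frame`.
#' @param adjacency optional precomputed [build_adjacency()] result.
#' @param membrane passed to [build_adjacency()] when it must be computed;
#'   with `membrane = 1` a single background pixel between cells does not
#'   count as touching background.
#' @return data frame with columns `id`, `touches_border`,
#'   `touches_background`, `interior`, `neighbour_complete`,
#'   `second_order_complete`.
#' @export
classify_validity <- function(frame, adjacency = NULL, membrane = 0) {
  L <- frame$labels
  if (is.null(adjacency)) adjacency <- build_adjacency(frame, membrane)
  ids <- .label_ids(L)
  border <- unique(c(L[1L, ], L[nrow(L), ], L[, 1L], L[, ncol(L)]))
  touches_border <- ids %in% border
  # labels 4-adjacent to a background pixel
  nr <- nrow(L); nc <- ncol(L)
  pad <- matrix(1L, nr + 2L, nc + 2L) # padding is non-background so that
  pad[2:(nr + 1L), 2:(nc + 1L)] <- L  # only true interior zeros count
  bg <- unique(c(pad[which(pad == 0L) - 1L], pad[which(pad == 0L) + 1L],
                 pad[which(pad == 0L) - (nr + 2L)],
                 pad[which(pad == 0L) + (nr + 2L)]))
  touches_background <- if (membrane == 1) rep(FALSE, length(ids))
                        else ids %in% bg
  interior <- !touches_border & !touches_background
  names(interior) <- as.character(ids)
  nc_ok <- interior & vapply(adjacency[as.character(ids)], function(nb)
    all(interior[as.character(nb)]), logical(1))
  so_ok <- nc_ok & vapply(adjacency[as.character(ids)], function(nb)
    all(nc_ok[as.character(nb)]), logical(1))
  data.frame(id = ids, touches_border = touches_border,
             touches_background = touches_background,
             interior = unname(interior),
             neighbour_complete = unname(nc_ok),
             second_order_complete = unname(so_ok))
}

#' Per-cell geometry of a segmented frame
#'
#' Area is the pixel count times `pixel_size^2`; the centroid is the mean
#' pixel-centre position; major/minor axis lengths come from the
#' eigenvalues of the second central moment tensor of the pixel
#' coordinates (each pixel treated as a unit square, so a `w x h` rectangle
#' has exactly the moments of the continuous rectangle), scaled as for the
#' equivalent ellipse. Anisotropy is major/minor; one-pixel regions are
#' reported with anisotropy 1 and flagged `degenerate`.
#'
#' @param frame a `segmented_frame`.
#' @return data frame with `id`, `area`, `centroid_x`, `centroid_y`,
#'   `major`, `minor`, `anisotropy`, `degenerate`.
#' @export
geometry <- function(frame) {
  L <- frame$labels
  ps <- frame$pixel_size
  px <- which(L > 0L)
  if (!length(px))
    return(data.frame(id = integer(0), area = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      major = numeric(0), minor = numeric(0),
                      anisotropy = numeric(0), degenerate = logical(0)))
  nr <- nrow(L)
  ids <- L[px]
  y <- (px - 1L) %% nr + 1L   # row
  x <- (px - 1L) %/% nr + 1L  # column
  f <- factor(ids, levels = .label_ids(L))
  s <- rowsum(cbind(1, x, y, x^2, y^2, x * y), f)
  npix <- s[, 1L]
  mx <- s[, 2L] / npix; my <- s[, 3L] / npix
  # population variances of pixel centres + 1/12 per-pixel square term
  sxx <- s[, 4L] / npix - mx^2 + 1 / 12
  syy <- s[, 5L] / npix - my^2 + 1 / 12
  sxy <- s[, 6L] / npix - mx * my
  tr2 <- (sxx + syy) / 2
  det <- sqrt(pmax(((sxx - syy) / 2)^2 + sxy^2, 0))
  l1 <- tr2 + det; l2 <- pmax(tr2 - det, 1e-12)
  data.frame(id = as.integer(rownames(s)),
             area = npix * ps^2,
             centroid_x = mx * ps, centroid_y = my * ps,
             major = 4 * sqrt(l1) * ps, minor = 4 * sqrt(l2) * ps,
             anisotropy = sqrt(l1 / l2),
             degenerate = npix == 1L)
}

#' Full per-cell analysis of a segmented frame
#'
#' Runs [build_adjacency()], [classify_validity()] and [geometry()] and
#' attaches the combined per-cell table to the frame.
#'
#' @param frame a `segmented_frame`.
#' @param membrane see [build_adjacency()].
#' @return the frame with `$adjacency` (named list) and `$cells` (data
#'   frame: id, n, area, centroid, axes, anisotropy, validity tiers).
#' @export
analyze_frame <- function(frame, membrane = 0) {
  stopifnot(inherits(frame, "segmented_frame"))
  adj <- build_adjacency(frame, membrane)
  val <- classify_validity(frame, adj, membrane)
  geo <- geometry(frame)
  cells <- merge(val, geo, by = "id", sort = TRUE)
  cells$n <- lengths(adj[as.character(cells$id)])
  cells <- cells[, c("id", "n", "area", "centroid_x", "centroid_y",
                     "major", "minor", "anisotropy", "degenerate",
                     "touches_border", "touches_background", "interior",
                     "neighbour_complete", "second_order_complete")]
  frame$adjacency <- adj
  frame$cells <- cells
  frame
}

.diverging_n_colour <- function(n) {
  # browns below 6, white at 6, greens above (clamped at +/-3)
  d <- pmax(pmin(n - 6, 3), -3) / 3
  r <- ifelse(d < 0, 0.55 + 0.45 * (1 + d), 1 + d * (1 - 0.15))
  g <- ifelse(d < 0, 0.35 + 0.65 * (1 + d), 1 - d * 0.35)
  b <- ifelse(d < 0, 0.10 + 0.90 * (1 + d), 1 + d * (1 - 0.15))
  cbind(pmin(pmax(r, 0), 1), pmin(pmax(g, 0), 1), pmin(pmax(b, 0), 1))
}

#' Export a per-cell heat map of a frame
#'
#' Recolours the label image by a per-cell quantity and writes a PNG. For
#' neighbour number the map diverges around 6 (browns below, white at 6,
#' greens above); other quantities use a sequential ramp. Cells that fail
#' the requested validity tier are grey; background is black. The label
#' geometry is untouched: every pixel keeps its cell, only the colour
#' changes.
#'
#' @param frame an analysed `segmented_frame` (see [analyze_frame()]).
#' @param quantity one of `"n"`, `"area"`, `"normalised_area"`,
#'   `"anisotropy"`.
#' @param out output PNG path.
#' @param tier validity tier required for a cell to be coloured
#'   (`"interior"`, `"neighbour_complete"`, `"second_order_complete"`).
#' @return `out` invisibly; the RGB array is attached as attribute
#'   `"image"`.
#' @export
export_heatmap <- function(frame, quantity = c("n", "area",
                                               "normalised_area",
                                               "anisotropy"),
                           out, tier = "neighbour_complete") {
  quantity <- match.arg(quantity)
  stopifnot(!is.null(frame$cells))
  tier <- match.arg(tier, c("interior", "neighbour_complete",
                            "second_order_complete"))
  cells <- frame$cells
  valid <- cells[[tier]]
  vals <- switch(quantity,
    n = cells$n,
    area = cells$area,
    anisotropy = cells$anisotropy,
    normalised_area = {
      adj <- frame$adjacency
      ar <- stats::setNames(cells$area, cells$id)
      vapply(seq_len(nrow(cells)), function(i) {
        nb <- adj[[as.character(cells$id[i])]]
        cells$area[i] / mean(ar[as.character(nb)])
      }, numeric(1))
    })
  cols <- matrix(0.5, nrow(cells), 3L) # grey for invalid
  if (quantity == "n") {
    cols[valid, ] <- .diverging_n_colour(vals[valid])
  } else {
    v <- vals[valid]
    u <- if (length(v) && diff(range(v)) > 0)
           (v - min(v)) / diff(range(v)) else rep(0.5, length(v))
    cols[valid, ] <- cbind(0.2 + 0.8 * u, 0.6 - 0.3 * u, 1 - 0.9 * u)
  }
  L <- frame$labels
  idx <- match(L, cells$id) # NA for background
  img <- array(0, dim = c(nrow(L), ncol(L), 3L))
  for (ch in 1:3) {
    plane <- cols[idx, ch]
    plane[is.na(plane)] <- 0
    img[, , ch] <- plane
  }
  png::writePNG(img, out)
  out <- invisible(out)
  attr(out, "image") <- img
  out
}
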