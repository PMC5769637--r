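#' Specification for a synthetic Voronoi tissue frame
#'
#' Describes a space-filling convex tessellation standing in for a
#' segmented epithelium: `n_seeds` cells rasterised on an image grid, with
#' optional Lloyd relaxation (0 = raw Poisson-Voronoi; more iterations give
#' more isotropic, evenly sized cells) and an optional linear seed-density
#' gradient mimicking a leaf's tip-to-base cell-size gradient.
#'
#' @param n_seeds number of cells (>= 4).
#' @param size image size `c(rows, cols)` in pixels.
#' @param lloyd number of Lloyd (centroidal relaxation) iterations (>= 0).
#' @param gradient linear density gradient along the row axis: seed density
#'   is proportional to `1 + gradient * row/rows` (0 = uniform).
#' @param seed integer RNG seed; generation is fully deterministic given
#'   the spec.
#' @return a `synthetic_frame_spec` list.
#' @export
synthetic_frame_spec <- function(n_seeds, size = c(256L, 256L), lloyd = 0L,
                                 gradient = 0, seed = 1L) {
  stopifnot(n_seeds >= 4L, length(size) == 2L, all(size >= 8L), lloyd >= 0L,
            gradient >= 0)
  structure(list(n_seeds = as.integer(n_seeds), size = as.integer(size),
                 lloyd = as.integer(lloyd), gradient = gradient,
                 seed = as.integer(seed)),
            class = "synthetic_frame_spec")
}

# nearest-seed label assignment on the pixel grid (pixel centres)
.rasterise_voronoi <- function(seeds, size) {
  nr <- size[1L]; nc <- size[2L]
  y <- rep(seq_len(nr) - 0.5, nc)
  x <- rep(seq_len(nc) - 0.5, each = nr)
  best <- rep(Inf, nr * nc)
  lab <- integer(nr * nc)
  for (i in seq_len(nrow(seeds))) {
    d <- (x - seeds[i, 1L])^2 + (y - seeds[i, 2L])^2
    sel <- d < best
    best[sel] <- d[sel]
    lab[sel] <- i
  }
  matrix(lab, nr, nc)
}

# generator-side region adjacency: row/column scan of the rasterised grid.
# Kept separate from build_adjacency() so the generator's ground truth and
# the extraction pipeline remain independent code paths.
.grid_adjacency <- function(L) {
  ids <- sort(setdiff(unique(as.vector(L)), 0L))
  edges <- vector("list", 2L * nrow(L) + 2L)
  k <- 0L
  for (i in seq_len(nrow(L))) {
    r <- L[i, ]
    dif <- which(r[-1] != r[-length(r)])
    if (length(dif)) { k <- k + 1L; edges[[k]] <- cbind(r[dif], r[dif + 1L]) }
    if (i < nrow(L)) {
      r2 <- L[i + 1L, ]
      dif <- which(r != r2)
      if (length(dif)) { k <- k + 1L; edges[[k]] <- cbind(r[dif], r2[dif]) }
    }
  }
  e <- do.call(rbind, edges[seq_len(k)])
  e <- e[e[, 1L] > 0L & e[, 2L] > 0L, , drop = FALSE]
  e <- unique(rbind(e, e[, 2:1]))
  adj <- split(e[, 2L], factor(e[, 1L], levels = ids))
  adj <- lapply(adj, function(v) sort(unique(as.integer(v))))
  names(adj) <- as.character(ids)
  adj
}

#' Generate a synthetic Voronoi label frame with ground truth
#'
#' Samples seed points (optionally density-graded), optionally relaxes them
#' with Lloyd iterations, rasterises the Voronoi diagram as a label image
#' and reports the generator's own ground truth: region adjacency on the
#' rasterised grid, per-cell pixel areas and neighbour counts. Should a
#' seed produce an empty raster region (seeds denser than the grid can
#' resolve), seeds are resampled with a shifted seed, with a warning, up to
#' 5 attempts.
#'
#' @param spec a [synthetic_frame_spec()].
#' @return a `synthetic_frame` list: `frame` (a [segmented_frame()]),
#'   `seeds` (final seed coordinates, columns x, y), and `truth` (list with
#'   `adjacency`, `areas`, `n`).
#' @export
voronoi_frame <- function(spec) {
  stopifnot(inherits(spec, "synthetic_frame_spec"))
  nr <- spec$size[1L]; nc <- spec$size[2L]
  for (attempt in 0:4) {
    set.seed(spec$seed + attempt)
    # rejection-sample rows for a linear density gradient
    n <- spec$n_seeds
    ys <- numeric(0)
    while (length(ys) < n) {
      cand <- stats::runif(2L * n, 0, nr)
      acc <- stats::runif(2L * n) < (1 + spec$gradient * cand / nr) /
        (1 + spec$gradient)
      ys <- c(ys, cand[acc])[seq_len(min(n, length(ys) + sum(acc)))]
    }
    seeds <- cbind(x = stats::runif(n, 0, nc), y = ys)
    L <- .rasterise_voronoi(seeds, spec$size)
    for (it in seq_len(spec$lloyd)) {
      f <- factor(as.vector(L), levels = seq_len(n))
      yy <- rep(seq_len(nr) - 0.5, nc)
      xx <- rep(seq_len(nc) - 0.5, each = nr)
      cx <- tapply(xx, f, mean)
      cy <- tapply(yy, f, mean)
      keep <- !is.na(cx)
      seeds[keep, 1L] <- cx[keep]
      seeds[keep, 2L] <- cy[keep]
      L <- .rasterise_voronoi(seeds, spec$size)
    }
    counts <- tabulate(L, nbins = n)
    if (all(counts > 0L)) {
      adj <- .grid_adjacency(L)
      return(structure(list(
        frame = segmented_frame(L),
        seeds = seeds,
        truth = list(adjacency = adj,
                     areas = stats::setNames(as.numeric(counts),
                                             seq_len(n)),
                     n = stats::setNames(lengths(adj), names(adj)))),
        class = "synthetic_frame"))
    }
    warning("empty Voronoi region at seed attempt ", attempt,
            "; resampling seeds")
  }
  stop("seeds too dense for the raster: empty regions after 5 attempts")
}

#' Specification for a synthetic division time-lapse step
#'
#' @param fraction fraction of cells dividing between the two frames
#'   (in `[0, 1]`).
#' @param contamination probability that a dividing mother triggers the
#'   co-division of one of its neighbours in the same interval, emulating
#'   tracking intervals that are too long to isolate single divisions.
#' @param min_area minimum daughter size in pixels; smaller splits are
#'   re-drawn.
#' @param max_retry retries of the division angle per mother before the
#'   mother is skipped.
#' @param seed integer RNG seed.
#' @return a `synthetic_division_spec` list.
#' @export
synthetic_division_spec <- function(fraction, contamination = 0,
                                    min_area = 12L, max_retry = 25L,
                                    seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1,
            contamination >= 0, contamination <= 1)
  structure(list(fraction = fraction, contamination = contamination,
                 min_area = as.integer(min_area),
                 max_retry = as.integer(max_retry), seed = as.integer(seed)),
            class = "synthetic_division_spec")
}

# side assignment of pixels for a straight cut through (cx, cy) at angle th
.split_side <- function(rows, cols, cy, cx, th) {
  (cols - cx) * (-sin(th)) + (rows - cy) * cos(th) >= 0
}

# connected components of a pixel set (4-connectivity); rows/cols vectors
.n_components <- function(rows, cols) {
  if (!length(rows)) return(0L)
  key <- paste(rows, cols)
  idx <- stats::setNames(seq_along(rows), key)
  comp <- integer(length(rows))
  cur <- 0L
  for (s in seq_along(rows)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      nb <- c(paste(rows[i] - 1L, cols[i]), paste(rows[i] + 1L, cols[i]),
              paste(rows[i], cols[i] - 1L), paste(rows[i], cols[i] + 1L))
      j <- idx[nb]
      j <- j[!is.na(j)]
      j <- j[comp[j] == 0L]
      if (length(j)) { comp[j] <- cur; queue <- c(queue, j) }
    }
  }
  cur
}

# check a candidate split of `sel` pixels into two daughters inside label
# matrix L: both daughters big enough, 4-connected, mutually adjacent, and
# with exactly two former neighbours adjacent to both (no four-way
# junctions at pixel level — excluded both in real tissue and the model).
.split_ok <- function(L, rows, cols, side, min_area, old_neighbours,
                      d1, d2) {
  if (sum(side) < min_area || sum(!side) < min_area) return(FALSE)
  if (.n_components(rows[side], cols[side]) != 1L) return(FALSE)
  if (.n_components(rows[!side], cols[!side]) != 1L) return(FALSE)
  r0 <- max(1L, min(rows) - 1L); r1 <- min(nrow(L), max(rows) + 1L)
  c0 <- max(1L, min(cols) - 1L); c1 <- min(ncol(L), max(cols) + 1L)
  sub <- L[r0:r1, c0:c1, drop = FALSE]
  adj <- .grid_adjacency(sub)
  a1 <- adj[[as.character(d1)]]
  a2 <- adj[[as.character(d2)]]
  if (is.null(a1) || is.null(a2)) return(FALSE)
  if (!(d2 %in% a1)) return(FALSE)
  junctions <- intersect(setdiff(a1, d2), setdiff(a2, d1))
  junctions <- intersect(junctions, old_neighbours)
  length(junctions) == 2L
}

#' Divide cells of a synthetic frame into a second time-lapse frame
#'
#' Selects a fraction of cells as mothers and splits each mother's pixel
#' set by a straight line through its centroid at a uniformly random
#' angle, giving the daughters fresh ids. Splits that would produce
#' fragments, undersized daughters or pixel-level four-way junctions are
#' re-drawn (up to `max_retry` angles; a mother that never splits cleanly
#' is left undivided). With probability `contamination`, a mother drags one
#' of its neighbours into dividing in the same interval, so that tracked
#' neighbour counts no longer reflect an isolated division.
#'
#' @param sframe a `synthetic_frame` from [voronoi_frame()] (or a
#'   `segmented_frame`).
#' @param spec a [synthetic_division_spec()].
#' @return list with `frame` (the t+1 [segmented_frame()]), `lineage`
#'   (data frame `frame_t`, `cell_id_t`, `frame_t1`, `cell_id_t1`),
#'   `events` (ground-truth log: mother and daughter ids and neighbour
#'   counts from the generator's own adjacency at both frames, plus a
#'   `neighbor_division` contamination flag) and `truth` (t+1 adjacency,
#'   areas, n).
#' @export
divide_frame <- function(sframe, spec) {
  stopifnot(inherits(spec, "synthetic_division_spec"))
  frame <- if (inherits(sframe, "synthetic_frame")) sframe$frame else sframe
  stopifnot(inherits(frame, "segmented_frame"))
  L0 <- frame$labels
  adj0 <- if (inherits(sframe, "synthetic_frame")) sframe$truth$adjacency
          else .grid_adjacency(L0)
  ids <- as.integer(names(adj0))
  set.seed(spec$seed)
  n_div <- round(spec$fraction * length(ids))
  mothers <- sort(sample(ids, n_div))
  # contamination: co-dividing neighbours
  forced <- integer(0)
  for (m in mothers) {
    if (stats::runif(1) < spec$contamination) {
      cand <- setdiff(adj0[[as.character(m)]], c(mothers, forced))
      if (length(cand)) forced <- c(forced, sample(cand, 1L))
    }
  }
  dividing <- sort(unique(c(mothers, forced)))
  L <- L0
  next_id <- max(ids)
  link <- list(); evt <- list()
  divided <- logical(length(dividing)); names(divided) <- dividing
  for (m in dividing) {
    px <- which(L == m)
    rows <- (px - 1L) %% nrow(L) + 1L
    cols <- (px - 1L) %/% nrow(L) + 1L
    cy <- mean(rows); cx <- mean(cols)
    d1 <- next_id + 1L; d2 <- next_id + 2L
    ok <- FALSE
    for (try in seq_len(spec$max_retry)) {
      th <- stats::runif(1, 0, pi)
      side <- .split_side(rows, cols, cy, cx, th)
      Ltry <- L
      Ltry[px[side]] <- d1
      Ltry[px[!side]] <- d2
      if (.split_ok(Ltry, rows, cols, side, spec$min_area,
                    adj0[[as.character(m)]], d1, d2)) {
        L <- Ltry; ok <- TRUE; break
      }
    }
    if (!ok) next
    next_id <- next_id + 2L
    divided[as.character(m)] <- TRUE
    link[[length(link) + 1L]] <-
      data.frame(frame_t = 1L, cell_id_t = m, frame_t1 = 2L,
                 cell_id_t1 = c(d1, d2))
    evt[[length(evt) + 1L]] <-
      data.frame(mother_id = m, daughter1_id = d1, daughter2_id = d2)
  }
  done <- as.integer(names(divided)[divided])
  persist <- setdiff(ids, done)
  lineage <- rbind(
    do.call(rbind, link),
    data.frame(frame_t = 1L, cell_id_t = persist, frame_t1 = 2L,
               cell_id_t1 = persist))
  lineage <- lineage[order(lineage$cell_id_t, lineage$cell_id_t1), ]
  rownames(lineage) <- NULL
  adj1 <- .grid_adjacency(L)
  events <- do.call(rbind, evt)
  if (is.null(events))
    events <- data.frame(mother_id = integer(0), daughter1_id = integer(0),
                         daughter2_id = integer(0))
  if (nrow(events)) {
    events$mother_n <- lengths(adj0[as.character(events$mother_id)])
    events$daughter1_n <- lengths(adj1[as.character(events$daughter1_id)])
    events$daughter2_n <- lengths(adj1[as.character(events$daughter2_id)])
    events$neighbor_division <- vapply(events$mother_id, function(m)
      any(adj0[[as.character(m)]] %in% done), logical(1))
  }
  ids1 <- sort(setdiff(unique(as.vector(L)), 0L))
  list(frame = segmented_frame(L, pixel_size = frame$pixel_size),
       lineage = lineage, events = events,
       truth = list(adjacency = adj1,
                    areas = stats::setNames(
                      as.numeric(tabulate(L, nbins = max(L))[ids1]), ids1),
                    n = stats::setNames(lengths(adj1), names(adj1))))
}

#' Generate an i.i.d. stream of division events under a named rule
#'
#' Draws division events directly from the closed-form per-daughter
#' distribution of a rule, without any tissue: a mother neighbour count is
#' drawn from `mother_degrees`, one daughter's count from the rule's
#' analytic matrix row, and the sibling's count follows from the `n + 4`
#' conservation law. Optionally a stated fraction of events is contaminated
#' by a +1 perturbation of one daughter, mimicking a neighbour that divided
#' in the same tracking interval.
#'
#' @param rule rule name.
#' @param mother_degrees integer vector to sample mothers from (with
#'   replacement), e.g. `rep(6, 10)` for all-hexagon mothers.
#' @param n_events number of events.
#' @param seed integer seed.
#' @param contamination fraction of events perturbed (default 0).
#' @return data frame with `mother_n`, `daughter1_n`, `daughter2_n`,
#'   `contaminated`.
#' @export
rule_event_stream <- function(rule = c("equal", "random", "pascal"),
                              mother_degrees, n_events, seed = 1L,
                              contamination = 0) {
  rule <- match.arg(rule)
  stopifnot(n_events >= 1L, all(mother_degrees >= 3L))
  set.seed(seed)
  M <- analytic_division_matrix(rule, n_max = max(mother_degrees))
  ks <- as.integer(colnames(M))
  mother_degrees <- as.integer(mother_degrees)
  mo <- mother_degrees[sample.int(length(mother_degrees), n_events,
                                  replace = TRUE)]
  d1 <- vapply(mo, function(n)
    sample(ks, 1L, prob = M[as.character(n), ]), integer(1))
  d2 <- mo + 4L - d1
  cont <- stats::runif(n_events) < contamination
  bump <- sample(c(1L, 2L), n_events, replace = TRUE)
  d1[cont & bump == 1L] <- d1[cont & bump == 1L] + 1L
  d2[cont & bump == 2L] <- d2[cont & bump == 2L] + 1L
  data.frame(mother_n = mo, daughter1_n = d1, daughter2_n = d2,
             contaminated = cont)
}
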