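#' Neighbour-number distribution with moments
#'
#' Tabulates per-cell neighbour counts into a distribution P(n) with its
#' first two moments: the mean `mu1 = <n>` and the variance
#' `mu2 = <n^2> - <n>^2`. The variance is the standard summary of how broad
#' a tissue's topological signature is; a perfectly hexagonal tissue has
#' `mu1 = 6`, `mu2 = 0`.
#'
#' @param counts integer vector of per-cell neighbour numbers, all >= 3
#'   (a count below 3 indicates an upstream extraction error and is
#'   rejected, naming the offending cell).
#' @return A `neighbor_distribution` list: `counts` (named table),
#'   `frequencies` (named, summing to 1), `mu1`, `mu2`, `n_total`.
#' @examples
#' d <- distribution_from_counts(c(5, 5, 6, 6, 6, 7, 7))
#' d$mu1  # 6
#' d$mu2  # 4/7
#' @export
distribution_from_counts <- function(counts) {
  if (length(counts) == 0L) stop("no neighbour counts supplied")
  counts <- as.integer(counts)
  bad <- which(counts < 3L)
  if (length(bad))
    stop("neighbour count < 3 for cell(s) at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": counts below 3 indicate an upstream error")
  tab <- table(factor(counts, levels = seq(min(counts), max(counts))))
  tab <- tab[tab > 0L | seq_along(tab) %in% range(which(tab > 0))]
  freq <- as.numeric(tab) / length(counts)
  names(freq) <- names(tab)
  mu1 <- mean(counts)
  mu2 <- mean(counts^2) - mu1^2
  structure(list(counts = tab, frequencies = freq,
                 mu1 = mu1, mu2 = mu2, n_total = length(counts)),
            class = "neighbor_distribution")
}

#' @export
print.neighbor_distribution <- function(x, ...) {
  cat(sprintf("neighbor_distribution over %d cells: mu1 = %.4f, mu2 = %.4f\n",
              x$n_total, x$mu1, x$mu2))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' P(n) for one class
#' @param dist a `neighbor_distribution`.
#' @param n neighbour number.
#' @return frequency of `n`-sided cells (0 if absent).
#' @export
p_n <- function(dist, n) {
  stopifnot(inherits(dist, "neighbor_distribution"))
  f <- unname(dist$frequencies[as.character(n)])
  f[is.na(f)] <- 0
  f
}

#' The alpha statistic linking P(6) and the distribution variance
#'
#' For planar cellular mosaics whose distribution peaks at n = 6, the
#' fraction of six-sided cells and the variance of the whole distribution
#' are approximately linked through a single parameter,
#' `alpha = mu2 * P(6)^2` (the Le Caer-Delannay/Lemaitre relation).
#' Tissues with broad distributions and correspondingly few hexagons keep
#' `alpha` near a semi-universal value.
#'
#' @param dist a `neighbor_distribution` with `P(6) > 0`.
#' @return the scalar `alpha`.
#' @examples
#' d <- distribution_from_counts(c(rep(6, 25), rep(5, 40), rep(7, 35)))
#' alpha_statistic(d)
#' @export
alpha_statistic <- function(dist) {
  stopifnot(inherits(dist, "neighbor_distribution"))
  p6 <- p_n(dist, 6)
  if (p6 == 0)
    stop("alpha is undefined: the distribution has no six-sided cells")
  dist$mu2 * p6^2
}

.dm_class <- function(m, events) {
  attr(m, "events") <- events
  class(m) <- c("division_matrix", class(m))
  m
}

#' Closed-form division matrices for the three split rules
#'
#' Returns the per-daughter post-mitotic neighbour-number distribution as a
#' row-stochastic matrix: entry (n, k) is the probability that a daughter of
#' an n-neighboured mother has k neighbours. With junction neighbours always
#' contributing 2 walls and the sibling 1, a daughter taking an arc of `a`
#' of the mother's `n - 2` remaining neighbours has `a + 3` neighbours, so:
#' \describe{
#'   \item{equal}{all mass on `k = n/2 + 2` (even n); 1/2 each on
#'     `(n+3)/2` and `(n+5)/2` (odd n).}
#'   \item{random}{uniform, `P(k) = 1/(n-1)` for `k` in `3..n+1`.}
#'   \item{pascal}{the Gibson-type binomial in which each daughter receives
#'     at least one non-junction neighbour and hence at least 4 walls:
#'     `P(k) = choose(n-4, k-4) / 2^(n-4)` for `k` in `4..n` (a triangular
#'     mother, which cannot satisfy the minimum, splits into `{3, 4}` with
#'     probability 1/2 each, the only arithmetically possible outcome).}
#' }
#'
#' @param rule rule name.
#' @param n_max largest mother neighbour number (rows run 3..`n_max`).
#' @return a `division_matrix` (rows sum to 1; entries outside
#'   `k` in `[3, n+1]` are 0).
#' @examples
#' analytic_division_matrix("pascal", 8)["6", "5"]  # 1/2
#' @export
analytic_division_matrix <- function(rule = c("equal", "random", "pascal"),
                                     n_max = 12L) {
  rule <- match.arg(rule)
  stopifnot(n_max >= 3L)
  ns <- 3L:n_max
  ks <- 3L:(n_max + 1L)
  m <- matrix(0, length(ns), length(ks), dimnames = list(ns, ks))
  for (n in ns) {
    row <- as.character(n)
    if (rule == "equal") {
      if (n %% 2L == 0L) {
        m[row, as.character(n / 2L + 2L)] <- 1
      } else {
        m[row, as.character((n + 3L) / 2L)] <- 0.5
        m[row, as.character((n + 5L) / 2L)] <- 0.5
      }
    } else if (rule == "random") {
      m[row, as.character(3L:(n + 1L))] <- 1 / (n - 1)
    } else {
      if (n == 3L) {
        m[row, c("3", "4")] <- 0.5
      } else {
        k <- 4L:n
        m[row, as.character(k)] <- stats::dbinom(k - 4L, n - 4L, 0.5)
      }
    }
  }
  .dm_class(m, stats::setNames(rep(NA_integer_, length(ns)), ns))
}

#' Empirical division matrix from logged division events
#'
#' Estimates the per-daughter post-mitotic neighbour-number distribution
#' from observed divisions: each division contributes its two daughters, and
#' row n entry k is (number of daughters with k neighbours) / (2 * number of
#' divisions of n-neighboured mothers). Rows with no observed events are
#' `NA` (undefined), not zero.
#'
#' Daughter counts outside `[3, mother + 1]` are impossible for an isolated
#' division; such observations (typically caused by a neighbour dividing in
#' the same tracking interval) are retained in the matrix but counted in the
#' `"flagged"` attribute.
#'
#' @param events data frame with columns `mother_n`, `daughter1_n`,
#'   `daughter2_n` (as produced by [simulate_tissue()] or
#'   [extract_division_events()]).
#' @param n_max optional largest mother class; defaults to the data range.
#' @return a `division_matrix` with per-row event counts in attribute
#'   `"events"` and the number of out-of-range daughter observations in
#'   attribute `"flagged"`.
#' @export
empirical_division_matrix <- function(events, n_max = NULL) {
  stopifnot(all(c("mother_n", "daughter1_n", "daughter2_n") %in% names(events)))
  if (nrow(events) == 0L) stop("no division events supplied")
  mo <- as.integer(events$mother_n)
  da <- cbind(as.integer(events$daughter1_n), as.integer(events$daughter2_n))
  if (is.null(n_max)) n_max <- max(mo)
  ns <- 3L:max(n_max, max(mo))
  ks <- min(3L, min(da)):max(ns + 1L, max(da))
  m <- matrix(NA_real_, length(ns), length(ks), dimnames = list(ns, ks))
  nev <- integer(length(ns)); names(nev) <- ns
  flagged <- 0L
  for (n in ns) {
    sel <- mo == n
    nev[as.character(n)] <- sum(sel)
    if (!any(sel)) next
    d <- c(da[sel, 1L], da[sel, 2L])
    flagged <- flagged + sum(d < 3L | d > n + 1L)
    tab <- table(factor(d, levels = ks))
    m[as.character(n), ] <- as.numeric(tab) / (2 * sum(sel))
  }
  out <- .dm_class(m, nev)
  attr(out, "flagged") <- flagged
  out
}

#' @export
print.division_matrix <- function(x, digits = 3, ...) {
  cat("division_matrix (rows: mother n, cols: daughter n, per-daughter",
      "probabilities)\n")
  print(round(unclass(x), digits))
  ev <- attr(x, "events")
  if (!all(is.na(ev))) cat("events per row:", paste(ev, collapse = " "), "\n")
  invisible(x)
}

#' Aboav-Weaire curve: mean neighbour count of a cell's neighbours
#'
#' For each topological class n, computes `m_n`: the average, over valid
#' n-sided cells, of the mean neighbour count of their neighbours. In many
#' cellular materials few-sided cells sit next to many-sided ones and vice
#' versa, following (in Aboav's original approximate form)
#' `m_n = 5 + 8/n`; the Weaire form `m_n = (6 - a) + (6a + mu2)/n` is also
#' available as a reference.
#'
#' @param adj adjacency: a list of integer neighbour-id vectors (indexed by
#'   cell), or a `tissue_graph`.
#' @param valid optional logical vector; a cell enters the average only if
#'   it is valid itself (its neighbours' counts are always defined by
#'   `adj`). Defaults to all cells.
#' @param reference `"aboav"` (5 + 8/n) or `"weaire"`.
#' @param a Weaire parameter (default 1), used when `reference = "weaire"`.
#' @param mu2 distribution variance for the Weaire form; defaults to the
#'   variance of the valid cells' neighbour counts.
#' @return data frame with columns `n`, `m_n`, `n_cells`, `reference`.
#' @export
aboav_curve <- function(adj, valid = NULL, reference = c("aboav", "weaire"),
                        a = 1, mu2 = NULL) {
  reference <- match.arg(reference)
  if (inherits(adj, "tissue_graph")) adj <- adjacency_list(adj)
  stopifnot(is.list(adj))
  deg <- lengths(adj)
  if (is.null(valid)) valid <- rep(TRUE, length(adj))
  stopifnot(length(valid) == length(adj))
  mean_nb <- vapply(adj, function(nb) mean(deg[nb]), numeric(1))
  n_cls <- sort(unique(deg[valid]))
  m_n <- vapply(n_cls, function(n) mean(mean_nb[valid & deg == n]), numeric(1))
  n_cells <- vapply(n_cls, function(n) sum(valid & deg == n), integer(1))
  if (is.null(mu2)) {
    d <- deg[valid]
    mu2 <- mean(d^2) - mean(d)^2
  }
  ref <- if (reference == "aboav") 5 + 8 / n_cls
         else (6 - a) + (6 * a + mu2) / n_cls
  data.frame(n = n_cls, m_n = m_n, n_cells = n_cells, reference = ref)
}

#' Lewis curve: mean (normalised) area per topological class
#'
#' Lewis' law relates a cell's neighbour number to its average area:
#' `A_n = (A0 / N) * (n - 2) / 4`, with `A0` the total tissue area and `N`
#' the cell count, so six-sided cells have exactly the mean area. When the
#' input areas are already locally normalised (area over mean neighbour
#' area), the `A0/N` prefactor is replaced by the mean of the supplied
#' values so the reference still passes through ~1 at n = 6.
#'
#' @param n integer vector of neighbour counts.
#' @param area numeric vector of (normalised) areas, > 0 where valid.
#' @param valid optional logical filter.
#' @param mode `"area"` for raw areas or `"normalised"` for locally
#'   normalised areas.
#' @return data frame with columns `n`, `mean_area`, `n_cells`, `reference`.
#' @export
lewis_curve <- function(n, area, valid = NULL, mode = c("area", "normalised")) {
  mode <- match.arg(mode)
  stopifnot(length(n) == length(area))
  if (is.null(valid)) valid <- rep(TRUE, length(n))
  valid <- valid & !is.na(area) & !is.na(n)
  if (!any(valid)) stop("no valid cells")
  stopifnot(all(area[valid] > 0))
  n_v <- n[valid]; a_v <- area[valid]
  n_cls <- sort(unique(n_v))
  mean_area <- vapply(n_cls, function(k) mean(a_v[n_v == k]), numeric(1))
  n_cells <- vapply(n_cls, function(k) sum(n_v == k), integer(1))
  scale <- if (mode == "area") sum(a_v) / length(a_v) else mean(a_v)
  data.frame(n = n_cls, mean_area = mean_area, n_cells = n_cells,
             reference = scale * (n_cls - 2) / 4)
}

.ols_panel <- function(x, y, panel) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("panel ", panel, ": fewer than 3 valid cells for regression")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(data.frame(panel = panel, slope = NA_real_, intercept = NA_real_,
                      r2 = NA_real_, n = length(x),
                      degenerate = TRUE))
  fit <- stats::lm(y ~ x)
  data.frame(panel = panel, slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             r2 = summary(fit)$r.squared, n = length(x), degenerate = FALSE)
}

#' Normalised-area relations between topology and local geometry
#'
#' Computes, per cell, the normalised area (cell area over the mean area of
#' its neighbours) and the neighbour-mean normalised area in which the
#' central cell is excluded from each neighbour's own normalisation (to
#' avoid the circularity "my neighbour is small because I am large"). Four
#' ordinary-least-squares relations are then summarised:
#' area ~ n, normalised area ~ area, normalised area ~ n, and neighbour-mean
#' normalised area ~ normalised area.
#'
#' @param adj adjacency list (or `tissue_graph`).
#' @param area per-cell areas.
#' @param valid logical: cells whose own record is trustworthy (e.g.
#'   interior cells). A cell's normalised area additionally requires all its
#'   neighbours valid; the neighbour-mean panel requires validity two
#'   neighbourhoods deep.
#' @return list with `cells` (per-cell table: `id`, `n`, `area`,
#'   `norm_area`, `nbr_norm_area`) and `panels` (OLS slope, intercept, R^2
#'   and sample size per relation; zero-variance relations are flagged
#'   `degenerate` with `NA` statistics).
#' @examples
#' adj <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
#' # three mutually adjacent cells with areas 1, 2, 3:
#' normalised_area_relations(adj, c(1, 2, 3))$cells$norm_area
#' @export
normalised_area_relations <- function(adj, area, valid = NULL) {
  if (inherits(adj, "tissue_graph")) adj <- adjacency_list(adj)
  stopifnot(is.list(adj), length(adj) == length(area))
  ncell <- length(adj)
  if (is.null(valid)) valid <- rep(TRUE, ncell)
  deg <- lengths(adj)
  # tier 1: own record valid; tier 2: all neighbours valid too
  nb_ok <- vapply(adj, function(nb) all(valid[nb]), logical(1)) & valid
  norm_area <- rep(NA_real_, ncell)
  norm_area[nb_ok] <- vapply(which(nb_ok), function(i)
    area[i] / mean(area[adj[[i]]]), numeric(1))
  # neighbour-mean normalised area, central cell excluded from each
  # neighbour's denominator; needs neighbours-of-neighbours valid
  nb2_ok <- vapply(adj, function(nb) all(nb_ok[nb]), logical(1)) & nb_ok
  nbr_norm <- rep(NA_real_, ncell)
  nbr_norm[nb2_ok] <- vapply(which(nb2_ok), function(i) {
    mean(vapply(adj[[i]], function(j) {
      others <- setdiff(adj[[j]], i)
      area[j] / mean(area[others])
    }, numeric(1)))
  }, numeric(1))
  cells <- data.frame(id = seq_len(ncell), n = deg, area = area,
                      norm_area = norm_area, nbr_norm_area = nbr_norm,
                      valid = valid)
  panels <- rbind(
    .ols_panel(cells$n[valid], cells$area[valid], "area_vs_n"),
    .ols_panel(cells$area, cells$norm_area, "norm_area_vs_area"),
    .ols_panel(cells$n, cells$norm_area, "norm_area_vs_n"),
    .ols_panel(cells$norm_area, cells$nbr_norm_area, "nbr_norm_vs_norm"))
  list(cells = cells, panels = panels)
}
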