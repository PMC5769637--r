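#' @useDynLib pavetopo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.rules <- c("equal", "random", "pascal")

.rule_code <- function(rule) {
  rule <- match.arg(rule, .rules)
  match(rule, .rules)
}

#' Create a boundary-free hexagonal tissue graph on a torus
#'
#' Builds the standard initial condition for division-rule simulations: a
#' `rows` x `cols` hexagonal lattice with periodic boundaries, so every cell
#' has exactly six distinct neighbours and the mean neighbour number is
#' exactly 6 (and stays 6 under any sequence of divisions, by Euler's
#' relation for trivalent maps on the torus).
#'
#' Cells are laid out in axial hex coordinates; each cell's neighbours are
#' stored in counter-clockwise cyclic order (a rotation system), which is
#' what makes "contiguous arc" neighbour splits at division well defined.
#'
#' @param rows,cols lattice dimensions. Dimensions so small that wrap-around
#'   would make a cell its own neighbour, or list the same cell twice in a
#'   neighbourhood, are rejected (in practice both must be >= 3, and
#'   `rows * cols >= 8`).
#' @param seed optional integer stored with the graph for bookkeeping;
#'   construction itself is deterministic.
#' @return A `tissue_graph` object. The object has reference semantics:
#'   division operations modify it in place.
#' @examples
#' g <- make_hex_torus(4, 4)
#' table(cell_degrees(g))  # all 16 cells have 6 neighbours
#' @export
make_hex_torus <- function(rows, cols, seed = NULL) {
  stopifnot(is.numeric(rows), is.numeric(cols), rows >= 2, cols >= 2)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 8L)
    stop("initial lattice must contain at least 8 cells (got ",
         rows * cols, ")")
  # counter-clockwise neighbour offsets in axial hex coordinates (dq, dr)
  dq <- c(1L, 1L, 0L, -1L, -1L, 0L)
  dr <- c(0L, -1L, -1L, 0L, 1L, 1L)
  adj <- vector("list", rows * cols)
  for (r in 0:(rows - 1L)) {
    for (q in 0:(cols - 1L)) {
      id <- r * cols + q + 1L
      nb <- ((r + dr) %% rows) * cols + ((q + dq) %% cols) + 1L
      if (anyDuplicated(nb) || any(nb == id))
        stop("lattice dimensions ", rows, "x", cols, " are too small: ",
             "wrap-around would make a cell neighbour itself or list a ",
             "neighbour twice; use at least 3x3")
      adj[[id]] <- nb
    }
  }
  ptr <- tg_new(adj, integer(rows * cols))
  structure(list(ptr = ptr, init = c(rows = rows, cols = cols), seed = seed),
            class = "tissue_graph")
}

#' Construct a tissue graph from an adjacency list
#'
#' Low-level constructor used by tests and by readers of external data. The
#' cyclic order of each entry is taken as the cell's rotation order and
#' validated for symmetry and single occurrence.
#'
#' @param adj list of integer vectors; `adj[[i]]` is the cyclic neighbour
#'   order of cell `i`.
#' @param generation optional integer vector of completed divisions per cell.
#' @return A `tissue_graph`.
#' @export
tissue_graph <- function(adj, generation = NULL) {
  stopifnot(is.list(adj), length(adj) >= 1)
  if (is.null(generation)) generation <- integer(length(adj))
  stopifnot(length(generation) == length(adj))
  g <- structure(list(ptr = tg_new(lapply(adj, as.integer),
                                   as.integer(generation)),
                      init = NULL, seed = NULL),
                 class = "tissue_graph")
  probs <- tg_validate(g$ptr)
  if (length(probs)) stop("invalid tissue graph: ", probs[[1]])
  g
}

#' @export
print.tissue_graph <- function(x, ...) {
  deg <- tg_degrees(x$ptr)
  cat("tissue_graph:", length(deg), "cells, mean neighbour number",
      format(mean(deg), digits = 4), "\n")
  invisible(x)
}

#' Number of cells in a tissue graph
#' @param g a `tissue_graph`.
#' @return integer count.
#' @export
num_cells <- function(g) tg_ncells(g$ptr)

#' Per-cell neighbour counts
#' @param g a `tissue_graph`.
#' @return integer vector, one entry per cell id.
#' @export
cell_degrees <- function(g) tg_degrees(g$ptr)

#' Per-cell completed-division counts
#' @param g a `tissue_graph`.
#' @return integer vector of generations.
#' @export
cell_generations <- function(g) tg_gen(g$ptr)

#' Cyclic adjacency (rotation system) of a tissue graph
#' @param g a `tissue_graph`.
#' @return list of integer vectors in cyclic neighbour order.
#' @export
adjacency_list <- function(g) tg_adj(g$ptr)

#' Deep-copy a tissue graph
#'
#' Tissue graphs have reference semantics; use this to keep an untouched
#' copy before dividing.
#' @param g a `tissue_graph`.
#' @return an independent `tissue_graph`.
#' @export
clone_graph <- function(g) {
  g2 <- g
  g2$ptr <- tg_clone(g$ptr)
  g2
}

#' Check rotation-system invariants
#'
#' Verifies symmetric adjacency, single occurrence of each neighbour per
#' cyclic order, and minimum degree 3.
#' @param g a `tissue_graph`.
#' @return `TRUE` invisibly, or an error describing the first problems found.
#' @export
graph_validate <- function(g) {
  probs <- tg_validate(g$ptr)
  if (length(probs)) stop("tissue graph inconsistent: ",
                          paste(probs, collapse = "; "))
  invisible(TRUE)
}

#' Divide one cell of a tissue graph
#'
#' Implements a topological cell division: a uniformly chosen starting wall
#' fixes one endpoint of the new wall, the wall's two endpoints cut two
#' interfaces whose owners (the junction neighbours) become adjacent to both
#' daughters, and the remaining `n - 2` neighbours are partitioned into two
#' contiguous arcs of sizes `a` and `n - 2 - a`, so the daughters have
#' `a + 3` and `n - 2 - a + 3` neighbours. The split `a` is drawn according
#' to the rule:
#' \describe{
#'   \item{equal}{`a = (n-2)/2` for even `n`; for odd `n` one of the two
#'     nearest-to-equal splits, each with probability 1/2.}
#'   \item{random}{`a` uniform on `0..n-2`.}
#'   \item{pascal}{`a = 1 + Binomial(n-4, 1/2)`: every non-junction
#'     neighbour independently sides with either daughter, with each
#'     daughter receiving at least one so that no daughter has fewer than
#'     4 walls (the Gibson-type binomial kernel). A triangular mother,
#'     which cannot meet the minimum, takes the only arithmetically
#'     possible split `{3, 4}`.}
#' }
#' Every division conserves `deg(d1) + deg(d2) = n + 4`, gives the two
#' junction neighbours one extra neighbour each, and leaves all other
#' neighbour counts unchanged, so the division neighbourhood's total
#' neighbour count rises by exactly 2.
#'
#' The mother's id is reused for the first daughter; the second daughter
#' receives the next free id. The graph is modified in place.
#'
#' @param g a `tissue_graph` (modified in place).
#' @param cell id of the dividing cell.
#' @param rule one of `"equal"`, `"random"`, `"pascal"`.
#' @param start_wall optional 1-based index into the mother's cyclic order
#'   forcing the starting wall (default: uniform draw). Intended for
#'   deterministic constructions and tests.
#' @param split optional forced arc size `a` in `0..n-2` (default: drawn
#'   from the rule).
#' @return Named integer vector with elements `d1`, `d2` (daughter ids),
#'   `mother_n`, `d1_n`, `d2_n` (neighbour counts) and `j1`, `j2` (junction
#'   neighbour ids).
#' @examples
#' g <- make_hex_torus(4, 4)
#' set.seed(1)
#' divide_cell(g, 1, "equal")  # a 6-cell mother always yields 5 and 5
#' @export
divide_cell <- function(g, cell, rule = c("equal", "random", "pascal"),
                        start_wall = NULL, split = NULL) {
  code <- .rule_code(rule)
  cell <- as.integer(cell)
  if (cell < 1L || cell > num_cells(g)) stop("no such cell: ", cell)
  r <- tg_divide(g$ptr, cell, code,
                 if (is.null(start_wall)) 0L else as.integer(start_wall),
                 if (is.null(split)) -1L else as.integer(split))
  names(r) <- c("d1", "d2", "mother_n", "d1_n", "d2_n", "j1", "j2")
  r
}

.events_df <- function(ev, round = NA_integer_) {
  data.frame(round = rep(as.integer(round), nrow(ev)),
             mother_n = ev[, 1L], daughter1_n = ev[, 2L],
             daughter2_n = ev[, 3L],
             daughter1 = ev[, 4L], daughter2 = ev[, 5L])
}

#' One division round without replacement
#'
#' Every cell present at the start of the round divides exactly once, in a
#' uniformly shuffled order; divisions are asynchronous, i.e. each division
#' sees the graph as updated by the previous ones. The cell count exactly
#' doubles.
#'
#' @param g a `tissue_graph` (modified in place).
#' @param rule division rule name.
#' @return The graph, invisibly, with the round's division log attached as
#'   attribute `"events"` (a data frame with columns `mother_n`,
#'   `daughter1_n`, `daughter2_n` and the daughter ids).
#' @export
run_round_without_replacement <- function(g, rule = c("equal", "random", "pascal")) {
  code <- .rule_code(rule)
  ev <- tg_run_round(g$ptr, code)
  out <- g
  attr(out, "events") <- .events_df(ev)
  invisible(out)
}

#' Random division events with replacement
#'
#' Performs `n_events` divisions, each of a cell selected uniformly from all
#' cells currently present (daughters are immediately eligible again).
#'
#' @param g a `tissue_graph` (modified in place).
#' @param rule division rule name.
#' @param n_events number of divisions (>= 0).
#' @return The graph, invisibly, with an `"events"` attribute as in
#'   [run_round_without_replacement()].
#' @export
run_events_with_replacement <- function(g, rule = c("equal", "random", "pascal"),
                                        n_events) {
  code <- .rule_code(rule)
  n_events <- as.integer(n_events)
  stopifnot(n_events >= 0L)
  ev <- if (n_events > 0L) tg_run_events(g$ptr, code, n_events)
        else matrix(integer(0), 0L, 5L)
  out <- g
  attr(out, "events") <- .events_df(ev)
  invisible(out)
}

#' Cyclic neighbour order of one cell
#' @param g a `tissue_graph`.
#' @param cell cell id.
#' @return integer vector of neighbour ids in cyclic order.
#' @export
cell_neighbors <- function(g, cell) tg_cell_adj(g$ptr, as.integer(cell))

#' Run divisions while auditing the conservation laws
#'
#' Performs `n_events` with-replacement divisions and, for every single
#' one, re-derives from the graph itself that (i) the daughters' neighbour
#' counts sum to the mother's `n + 4`, (ii) exactly two former neighbours
#' (the junction neighbours) gained exactly one neighbour while all others
#' kept their count, and (iii) the division neighbourhood's total neighbour
#' count rose by exactly 2. Degrees are recomputed from adjacency before
#' and after each division, not taken from the division's own bookkeeping.
#'
#' @param g a `tissue_graph` (modified in place).
#' @param rule division rule name.
#' @param n_events number of audited divisions.
#' @return list with `events` (data frame of logged divisions) and
#'   `violations` (count of divisions breaking any law; 0 expected).
#' @export
audit_divisions <- function(g, rule = c("equal", "random", "pascal"),
                            n_events) {
  code <- .rule_code(rule)
  res <- tg_run_events_audited(g$ptr, code, as.integer(n_events))
  ev <- res$events
  list(events = data.frame(mother_n = ev[, 1L], daughter1_n = ev[, 2L],
                           daughter2_n = ev[, 3L]),
       violations = res$violations)
}

#' Repeatedly divide the same mother in private copies of the graph
#'
#' Monte-Carlo sampler for a single cell's division outcome: each repetition
#' divides `cell` in a throw-away copy of `g`, recording the two daughter
#' neighbour counts. Used to compare realised divisions against the
#' closed-form division matrices.
#'
#' @param g a `tissue_graph` (not modified).
#' @param cell id of the mother.
#' @param rule division rule name.
#' @param reps number of repetitions.
#' @return integer matrix with columns `d1_n`, `d2_n`, one row per division.
#' @export
sample_divisions <- function(g, cell, rule = c("equal", "random", "pascal"),
                             reps) {
  code <- .rule_code(rule)
  out <- tg_sample_divisions(g$ptr, as.integer(cell), code, as.integer(reps))
  colnames(out) <- c("d1_n", "d2_n")
  out
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of a division-rule simulation.
#'
#' @param rule division rule name: `"equal"`, `"random"` or `"pascal"`.
#' @param replacement `"without"` (every cell divides once per round) or
#'   `"with"` (each event divides a uniformly chosen cell).
#' @param init integer vector `c(rows, cols)` of the initial hexagonal
#'   torus; the default 8x8 gives 64 cells.
#' @param rounds number of division rounds (without replacement); the final
#'   tissue has `rows * cols * 2^rounds` cells.
#' @param n_events number of division events (with replacement); exactly one
#'   of `rounds` / `n_events` is used depending on `replacement`.
#' @param replicates number of independent replicate simulations pooled into
#'   the final distribution; replicate `r` is seeded with `seed + r`.
#' @param seed base integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(rule = c("equal", "random", "pascal"),
                              replacement = c("without", "with"),
                              init = c(8L, 8L), rounds = 10L,
                              n_events = NULL, replicates = 1L, seed = 1L) {
  rule <- match.arg(rule)
  replacement <- match.arg(replacement)
  stopifnot(length(init) == 2L, all(init >= 2), prod(init) >= 8,
            replicates >= 1L)
  if (replacement == "without") {
    stopifnot(!is.null(rounds), rounds >= 1L)
  } else {
    stopifnot(!is.null(n_events), n_events >= 0L)
  }
  structure(list(rule = rule, replacement = replacement,
                 init = as.integer(init), rounds = as.integer(rounds),
                 n_events = if (is.null(n_events)) NULL else as.integer(n_events),
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Run a division-rule simulation
#'
#' Runs `replicates` independent simulations from a fresh hexagonal torus
#' each, pooling the final neighbour-number distribution across replicates
#' and logging every division event (mother and daughter neighbour counts)
#' for division-matrix estimation. Iterating any of the three rules quickly
#' reaches a steady-state distribution; on a torus the mean neighbour number
#' is exactly 6 throughout.
#'
#' @param config a [simulation_config()].
#' @param keep_graph keep the final graph of the last replicate (can be
#'   large; default `FALSE`).
#' @return A `tissue_sim` list with elements `config`, `distribution` (a
#'   [neighbor_distribution()] pooled over replicates), `per_round` (data
#'   frame of per-round cell counts and moments, per replicate), `events`
#'   (data frame of all logged divisions with `replicate` and `round`
#'   columns) and optionally `graph`.
#' @examples
#' sim <- simulate_tissue(simulation_config("equal", "without",
#'                                          init = c(4, 4), rounds = 4,
#'                                          replicates = 2, seed = 42))
#' sim$distribution$mu2
#' @export
simulate_tissue <- function(config, keep_graph = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  code <- .rule_code(config$rule)
  all_counts <- integer(0)
  per_round <- list()
  events <- list()
  graph <- NULL
  for (r in seq_len(config$replicates)) {
    set.seed(config$seed + r)
    g <- make_hex_torus(config$init[1L], config$init[2L])
    if (config$replacement == "without") {
      for (rd in seq_len(config$rounds)) {
        ev <- tg_run_round(g$ptr, code)
        deg <- tg_degrees(g$ptr)
        per_round[[length(per_round) + 1L]] <-
          data.frame(replicate = r, round = rd, n_cells = length(deg),
                     mu1 = mean(deg), mu2 = mean(deg^2) - mean(deg)^2)
        df <- .events_df(ev, rd)
        df$replicate <- r
        events[[length(events) + 1L]] <- df
      }
    } else {
      ev <- tg_run_events(g$ptr, code, config$n_events)
      deg <- tg_degrees(g$ptr)
      per_round[[length(per_round) + 1L]] <-
        data.frame(replicate = r, round = 1L, n_cells = length(deg),
                   mu1 = mean(deg), mu2 = mean(deg^2) - mean(deg)^2)
      df <- .events_df(ev, 1L)
      df$replicate <- r
      events[[length(events) + 1L]] <- df
    }
    all_counts <- c(all_counts, tg_degrees(g$ptr))
    if (keep_graph && r == config$replicates) graph <- g
  }
  structure(list(config = config,
                 distribution = distribution_from_counts(all_counts),
                 per_round = do.call(rbind, per_round),
                 events = do.call(rbind, events),
                 graph = graph),
            class = "tissue_sim")
}

#' @export
print.tissue_sim <- function(x, ...) {
  d <- x$distribution
  cat(sprintf("tissue_sim: %s split, %s replacement; %d cells pooled\n",
              x$config$rule, x$config$replacement, d$n_total))
  cat(sprintf("  mu1 = %.4f, mu2 = %.4f, P(6) = %.4f\n",
              d$mu1, d$mu2, d$frequencies["6"]))
  invisible(x)
}
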