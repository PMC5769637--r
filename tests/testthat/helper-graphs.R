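# Shared fixtures built in code.

# Deterministically construct a graph containing a mother cell with the
# requested neighbour count.  Degrees below 6 come from one forced split of
# a hexagonal cell; degrees above 6 from repeatedly dividing neighbours of
# the target cell with the target as a junction neighbour (junction
# neighbours gain +1 per division).
make_mother <- function(target) {
  g <- make_hex_torus(4, 6)
  if (target < 6) {
    r <- divide_cell(g, 1L, "equal", start_wall = 1, split = target - 3L)
    cell <- r[["d1"]]
  } else {
    cell <- 1L
    k <- 0
    while (cell_degrees(g)[cell] < target) {
      k <- k + 1
      nbs <- cell_neighbors(g, cell)
      y <- nbs[1 + (k %% length(nbs))]
      pos <- match(cell, cell_neighbors(g, y))
      divide_cell(g, y, "equal", start_wall = pos)
    }
  }
  graph_validate(g)
  stopifnot(cell_degrees(g)[cell] == target)
  list(g = g, cell = cell)
}

# total-variation distance between two probability vectors aligned by name
tv_dist <- function(p, q) {
  ns <- union(names(p), names(q))
  pp <- ifelse(is.na(p[ns]), 0, p[ns])
  qq <- ifelse(is.na(q[ns]), 0, q[ns])
  sum(abs(pp - qq)) / 2
}

# frequency table of a degree vector, named by n
freq_of <- function(deg) {
  tab <- table(deg)
  as.numeric(tab) -> v
  names(v) <- names(tab)
  v / sum(v)
}
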