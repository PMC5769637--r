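test_that("hexagonal torus construction gives a regular trivalent map", {
  g <- make_hex_torus(4, 4)
  expect_equal(num_cells(g), 16L)
  deg <- cell_degrees(g)
  expect_true(all(deg == 6L))
  d <- distribution_from_counts(deg)
  expect_equal(d$mu1, 6)
  expect_equal(d$mu2, 0)
  expect_silent(graph_validate(g))

  g8 <- make_hex_torus(8, 8)
  expect_equal(num_cells(g8), 64L)
  adj <- adjacency_list(g8)
  for (i in seq_along(adj)) {
    expect_equal(anyDuplicated(adj[[i]]), 0L)
    for (j in adj[[i]]) expect_true(i %in% adj[[j]])
  }
})

test_that("undersized lattices are rejected with a sizing error", {
  expect_error(make_hex_torus(2, 2), "at least 8 cells")
  expect_error(make_hex_torus(2, 4), "too small")
  expect_error(make_hex_torus(4, 2), "too small")
})

test_that("division splits follow the rule arithmetic", {
  # even mother, equal rule: always 5 and 5
  for (i in 1:5) {
    m <- make_mother(6)
    r <- divide_cell(m$g, m$cell, "equal")
    expect_setequal(unname(r[c("d1_n", "d2_n")]), c(5L, 5L))
    expect_equal(unname(r[["mother_n"]]), 6L)
  }
  # odd mother, equal rule: the unordered pair {5, 6} with probability 1
  for (i in 1:10) {
    m <- make_mother(7)
    r <- divide_cell(m$g, m$cell, "equal")
    expect_setequal(unname(r[c("d1_n", "d2_n")]), c(5L, 6L))
  }
  # triangular mother: {3, 4} under every rule
  for (rule in c("equal", "random", "pascal")) {
    m <- make_mother(3)
    r <- divide_cell(m$g, m$cell, rule)
    expect_setequal(unname(r[c("d1_n", "d2_n")]), c(3L, 4L))
  }
  # a 7-and-3 outcome (as tracked in vivo) is admissible under random split
  m <- make_mother(6)
  r <- divide_cell(m$g, m$cell, "random", split = 4L)
  expect_setequal(unname(r[c("d1_n", "d2_n")]), c(7L, 3L))
})

test_that("dividing a missing cell fails cleanly", {
  g <- make_hex_torus(3, 3)
  expect_error(divide_cell(g, 99, "equal"), "no such cell")
})

test_that("every division conserves n+4 and bumps exactly two junction neighbours", {
  set.seed(11)
  for (rule in c("equal", "random", "pascal")) {
    g <- make_hex_torus(4, 4)
    for (k in 1:60) {
      cell <- sample.int(num_cells(g), 1)
      n <- cell_degrees(g)[cell]
      nb <- cell_neighbors(g, cell)
      pre <- cell_degrees(g)[nb]
      r <- divide_cell(g, cell, rule)
      expect_identical(unname(r[["d1_n"]] + r[["d2_n"]]), unname(n + 4L))
      post <- cell_degrees(g)[nb]
      expect_identical(sum(post - pre), 2L)
      expect_identical(sort(unique(post - pre)), c(0L, 1L))
      expect_identical(sum(post - pre == 1L), 2L)
      expect_setequal(nb[post - pre == 1L], unname(r[c("j1", "j2")]))
    }
    expect_silent(graph_validate(g))
  }
})

test_that("rounds without replacement double the tissue and keep the torus mean at 6", {
  set.seed(21)
  g <- make_hex_torus(4, 4)
  gen0 <- cell_generations(g)
  out <- run_round_without_replacement(g, "equal")
  expect_equal(num_cells(g), 32L)
  expect_equal(nrow(attr(out, "events")), 16L)
  expect_true(all(cell_generations(g)[1:16] == gen0 + 1L))
  g2 <- make_hex_torus(8, 8)
  run_round_without_replacement(g2, "random")
  expect_equal(mean(cell_degrees(g2)), 6)
  run_round_without_replacement(g2, "pascal")
  expect_equal(num_cells(g2), 256L)
  expect_equal(mean(cell_degrees(g2)), 6)
  expect_silent(graph_validate(g2))
})

test_that("events with replacement add exactly one cell per division", {
  set.seed(31)
  g <- make_hex_torus(4, 4)
  out <- run_events_with_replacement(g, "equal", 0L)
  expect_equal(num_cells(g), 16L)
  expect_equal(nrow(attr(out, "events")), 0L)
  run_events_with_replacement(g, "equal", 48L)
  expect_equal(num_cells(g), 64L)
  expect_equal(mean(cell_degrees(g)), 6)
  # generations become heterogeneous under random scheduling
  g2 <- make_hex_torus(4, 4)
  run_events_with_replacement(g2, "equal", 300L)
  expect_gt(stats::var(cell_generations(g2)), 0)
  # oracle: generation counts behave like a uniform branching process --
  # expected generation spread from a multinomial-division simulation
  set.seed(32)
  oracle <- replicate(200, {
    gen <- integer(16)
    for (k in 1:300) {
      i <- sample.int(length(gen), 1)
      gen <- c(gen, gen[i] + 1L)
      gen[i] <- gen[i] + 1L
    }
    var(gen)
  })
  expect_gt(stats::var(cell_generations(g2)), min(oracle) * 0.5)
  expect_lt(stats::var(cell_generations(g2)), max(oracle) * 2)
})

test_that("simulate_tissue is reproducible and logs every division", {
  cfg <- simulation_config("equal", "without", init = c(4, 4), rounds = 3,
                           replicates = 2, seed = 7)
  s1 <- simulate_tissue(cfg)
  s2 <- simulate_tissue(cfg)
  expect_identical(s1$distribution$frequencies, s2$distribution$frequencies)
  expect_identical(s1$events, s2$events)
  expect_equal(s1$distribution$n_total, 2 * 16 * 2^3)
  expect_equal(nrow(s1$events), 2 * (16 * 2^3 - 16))
  expect_equal(s1$per_round$n_cells, rep(16 * 2^(1:3), 2))
  expect_true(all(s1$per_round$mu1 == 6))
  cfg_w <- simulation_config("pascal", "with", init = c(4, 4),
                             n_events = 100, seed = 3)
  sw <- simulate_tissue(cfg_w)
  expect_equal(sw$distribution$n_total, 116L)
})

test_that("the division-outcome sampler matches forced splits", {
  m <- make_mother(8)
  s <- sample_divisions(m$g, m$cell, "equal", 50)
  expect_true(all(s[, "d1_n"] == 6L & s[, "d2_n"] == 6L))
  expect_true(all(rowSums(s) == 12L))
  # sampling does not mutate the source graph
  expect_equal(cell_degrees(m$g)[m$cell], 8L)
})

test_that("steady state is reached within about eight rounds (equal split)", {
  set.seed(77)
  graphs <- replicate(5, make_hex_torus(8, 8), simplify = FALSE)
  pooled <- function() freq_of(unlist(lapply(graphs, cell_degrees)))
  prev <- pooled()
  tv <- numeric(8)
  for (rd in 1:8) {
    for (g in graphs) run_round_without_replacement(g, "equal")
    cur <- pooled()
    tv[rd] <- tv_dist(prev, cur)
    prev <- cur
  }
  expect_lt(tv[8], 0.01)
})
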