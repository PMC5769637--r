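test_that("neighbour distributions give exact moments and validate input", {
  d <- distribution_from_counts(rep(6, 50))
  expect_equal(p_n(d, 6), 1)
  expect_equal(d$mu1, 6)
  expect_equal(d$mu2, 0)

  d2 <- distribution_from_counts(c(5, 5, 6, 6, 6, 7, 7))
  expect_equal(d2$mu1, 6)
  expect_equal(d2$mu2, 4 / 7)
  expect_equal(sum(d2$frequencies), 1)

  expect_error(distribution_from_counts(integer(0)), "no neighbour counts")
  expect_error(distribution_from_counts(c(6, 2, 5)), "position\\(s\\) 2")

  # mu2 equals the population variance of the raw counts to machine precision
  set.seed(9)
  x <- sample(3:12, 500, replace = TRUE)
  d3 <- distribution_from_counts(x)
  expect_equal(d3$mu2, mean((x - mean(x))^2))
})

test_that("alpha statistic follows mu2 * P(6)^2 and signals P(6) = 0", {
  expect_equal(alpha_statistic(distribution_from_counts(rep(6, 10))), 0)
  d <- distribution_from_counts(c(rep(5, 25), rep(6, 25), rep(7, 50)))
  p6 <- 0.25
  mu2 <- d$mu2
  expect_equal(alpha_statistic(d), mu2 * p6^2)
  d2 <- distribution_from_counts(c(5, 5, 7, 7))
  expect_error(alpha_statistic(d2), "undefined")
})

test_that("analytic division matrices match enumeration oracles", {
  # random: enumerate the n - 1 equally likely arc splits
  for (n in c(4, 6, 9)) {
    ks <- vapply(0:(n - 2), function(a) a + 3L, integer(1))
    oracle <- table(factor(ks, levels = 3:(n + 1))) / (n - 1)
    M <- analytic_division_matrix("random", n)
    expect_equal(unname(M[as.character(n), as.character(3:(n + 1))]),
                 as.numeric(oracle))
  }
  expect_equal(unname(analytic_division_matrix("random", 6)["6", "5"]), 0.2)

  # pascal: enumerate independent sidings of the free neighbours, each
  # daughter holding one guaranteed non-junction neighbour
  for (n in c(5, 6, 8)) {
    free <- n - 4L
    grid <- as.matrix(expand.grid(rep(list(0:1), free)))
    a <- 1L + rowSums(grid)
    oracle <- table(factor(a + 3L, levels = 3:(n + 1))) / nrow(grid)
    M <- analytic_division_matrix("pascal", n)
    expect_equal(unname(M[as.character(n), as.character(3:(n + 1))]),
                 as.numeric(oracle))
  }
  expect_equal(unname(analytic_division_matrix("pascal", 6)["6", "5"]), 0.5)
  expect_equal(unname(analytic_division_matrix("pascal", 6)["3", "3"]), 0.5)

  # equal: forced splits
  M <- analytic_division_matrix("equal", 7)
  expect_equal(unname(M["6", "5"]), 1)
  expect_equal(unname(M["7", "5"]), 0.5)
  expect_equal(unname(M["7", "6"]), 0.5)

  # every rule: rows are distributions with support inside [3, n+1]
  for (rule in c("equal", "random", "pascal")) {
    M <- analytic_division_matrix(rule, 10)
    expect_equal(unname(rowSums(M)), rep(1, nrow(M)))
    for (n in 3:10) {
      ks <- as.integer(colnames(M))
      expect_true(all(M[as.character(n), ks > n + 1] == 0))
    }
  }
})

test_that("empirical matrices estimate per-daughter probabilities", {
  ev <- data.frame(mother_n = c(6, 6), daughter1_n = c(5, 5),
                   daughter2_n = c(5, 5))
  M <- empirical_division_matrix(ev)
  expect_equal(unname(M["6", "5"]), 1)
  expect_true(all(is.na(M["4", ])))  # no events: undefined, not zero
  expect_equal(unname(attr(M, "events")["6"]), 2L)

  # the tracked in vivo example: one 6 -> {7, 3} division
  M2 <- empirical_division_matrix(
    data.frame(mother_n = 6, daughter1_n = 7, daughter2_n = 3))
  expect_equal(unname(M2["6", "7"]), 0.5)
  expect_equal(unname(M2["6", "3"]), 0.5)

  # impossible daughters are retained but flagged
  M3 <- empirical_division_matrix(
    data.frame(mother_n = c(3, 3), daughter1_n = c(3, 6),
               daughter2_n = c(4, 2)))
  expect_equal(attr(M3, "flagged"), 2L)
  expect_equal(unname(M3["3", "6"]), 0.25)
  expect_equal(unname(M3["3", "2"]), 0.25)
})

test_that("sampled divisions converge to the analytic rows", {
  set.seed(41)
  for (rule in c("random", "pascal")) {
    m <- make_mother(6)
    s <- sample_divisions(m$g, m$cell, rule, 20000)
    ev <- data.frame(mother_n = 6, daughter1_n = s[, 1], daughter2_n = s[, 2])
    emp <- empirical_division_matrix(ev, n_max = 6)
    ana <- analytic_division_matrix(rule, 6)
    ks <- as.character(3:7)
    expect_lt(sum(abs(emp["6", ks] - ana["6", ks])) / 2, 0.02)
    obs <- emp["6", ks] * 2 * nrow(ev)
    keep <- ana["6", ks] > 0
    p <- suppressWarnings(
      stats::chisq.test(obs[keep], p = ana["6", ks][keep]))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("Aboav curve matches brute-force counting and the edge identity", {
  g <- make_hex_torus(4, 4)
  ab <- aboav_curve(g)
  expect_equal(ab$m_n[ab$n == 6], 6)
  expect_equal(ab$reference[ab$n == 6], 5 + 8 / 6)

  # reference forms
  ab4 <- aboav_curve(list(c(2L, 3L, 4L, 5L), c(1L, 3L, 5L), c(1L, 2L, 4L),
                          c(1L, 3L, 5L), c(1L, 2L, 4L)))
  expect_equal(ab4$reference[ab4$n == 4], 7)

  # brute force on an irregular graph
  set.seed(51)
  run_events_with_replacement(g, "random", 30)
  adj <- adjacency_list(g)
  deg <- lengths(adj)
  brute <- sapply(sort(unique(deg)), function(n) {
    cells <- which(deg == n)
    mean(sapply(cells, function(i) mean(deg[adj[[i]]])))
  })
  ab2 <- aboav_curve(g)
  expect_equal(ab2$m_n, unname(brute))

  # sum_n P(n) n m_n / sum_n P(n) n equals the edge-weighted mean degree
  w <- ab2$n_cells / sum(ab2$n_cells)
  lhs <- sum(w * ab2$n * ab2$m_n) / sum(w * ab2$n)
  edge_ends <- unlist(lapply(seq_along(adj), function(i) deg[adj[[i]]]))
  expect_equal(lhs, mean(edge_ends))
})

test_that("Lewis curve equals group-by means and is order invariant", {
  # uniform hexagonal case: curve passes through the mean area at n = 6
  lc <- lewis_curve(rep(6, 20), rep(3.5, 20))
  expect_equal(lc$mean_area, 3.5)
  expect_equal(lc$reference, 3.5)
  expect_equal(lewis_curve(c(rep(3, 3), rep(6, 3)),
                           rep(2, 6))$reference[1], 2 * 0.25)

  set.seed(61)
  n <- sample(4:9, 300, replace = TRUE)
  area <- stats::rgamma(300, shape = n)
  lc1 <- lewis_curve(n, area)
  oracle <- tapply(area, n, mean)
  expect_equal(lc1$mean_area, as.numeric(oracle[as.character(lc1$n)]))
  perm <- sample(300)
  lc2 <- lewis_curve(n[perm], area[perm])
  expect_equal(lc1, lc2)

  # normalised mode: reference passes through the mean normalised area
  lcn <- lewis_curve(rep(c(5, 6, 7), each = 5), rep(1, 15),
                     mode = "normalised")
  expect_equal(lcn$reference[lcn$n == 6], 1)
})

test_that("normalised-area relations reproduce hand-computed toys", {
  adj <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  res <- normalised_area_relations(adj, c(1, 2, 3))
  expect_equal(res$cells$norm_area, c(1 / 2.5, 2 / 2, 3 / 1.5))
  # neighbour-mean normalised area with the central cell excluded:
  # e.g. for cell 1, neighbour 2 is normalised over {3} and 3 over {2}
  expect_equal(res$cells$nbr_norm_area[1], mean(c(2 / 3, 3 / 2)))
  # n is constant here: the area-vs-n relation is degenerate, not an error
  expect_true(res$panels$degenerate[res$panels$panel == "area_vs_n"])

  # uniform areas: normalised areas all 1, zero-variance panels flagged
  res2 <- normalised_area_relations(adj, c(2, 2, 2))
  expect_true(all(res2$cells$norm_area == 1))
  expect_true(res2$panels$degenerate[res2$panels$panel == "norm_area_vs_area"])

  # fewer than three valid cells cannot be regressed
  expect_error(normalised_area_relations(adj, c(1, 2, 3),
                                         valid = c(TRUE, TRUE, FALSE)),
               "fewer than 3")
})

test_that("normalised-area regressions recover a planted slope", {
  set.seed(71)
  g <- make_hex_torus(6, 6)
  run_events_with_replacement(g, "equal", 40)
  adj <- adjacency_list(g)
  deg <- lengths(adj)
  area <- deg + stats::rnorm(length(deg), 0, 0.05) # Lewis-like: area ~ n
  res <- normalised_area_relations(adj, area)
  pan <- res$panels[res$panels$panel == "area_vs_n", ]
  expect_gt(pan$slope, 0.8)
  expect_gt(pan$r2, 0.9)
  pan2 <- res$panels[res$panels$panel == "norm_area_vs_n", ]
  expect_gt(pan2$slope, 0)
})
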