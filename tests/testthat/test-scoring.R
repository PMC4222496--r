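test_that("direction assignment matches the six-downstream worked example", {
  fx <- fig_hyp_fixture()
  d <- assign_direction(fx$hyps[["U"]], fx$states)
  expect_equal(d$direction, 1L)
  expect_equal(d$correct, 3L)
  expect_equal(d$contra, 1L)
  expect_equal(d$ambiguous, 1L)
  expect_equal(d$observed, 5L)
})

test_that("direction handles no-evidence and tie cases", {
  fx <- fig_hyp_fixture()
  h <- fx$hyps[["U"]]
  zero <- stats::setNames(integer(length(fx$states)), names(fx$states))
  d <- assign_direction(h, zero)
  expect_equal(d, list(direction = 0L, correct = 0L, contra = 0L,
                       ambiguous = 0L, observed = 0L))

  # 2 implied-up vs 2 implied-down: tie -> none, correct = tied count
  tie <- c("r(A)" = 1L, "r(B)" = 1L, "r(D)" = 1L, "r(F)" = -1L,
           "r(C)" = 0L, "r(E)" = 0L)
  # A up (+edge) and F down (+edge) imply up/down; B up (+edge) implies up;
  # D up (-edge) implies down -> 2 vs 2
  d <- assign_direction(h, tie)
  expect_equal(d$direction, 0L)
  expect_equal(d$correct, 2L)
  expect_equal(d$contra, 2L)
  expect_equal(d$observed, 4L)

  # nodes missing from the state vector count as unchanged
  d <- assign_direction(h, c("r(A)" = 1L))
  expect_equal(d$observed, 1L)
  expect_equal(d$direction, 1L)
})

test_that("concordance equals the exhaustive enumeration oracle", {
  for (t in 0:10) {
    for (k in 0:t) {
      contra <- t - k
      expect_equal(concordance_pvalue(k, contra), oracle_binom_tail(k, t),
                   tolerance = 1e-12,
                   label = sprintf("conc(k=%d, t=%d)", k, t))
    }
  }
  # ambiguous nodes are excluded from the trials
  expect_equal(concordance_pvalue(4, 2, ambiguous = 3),
               concordance_pvalue(4, 2, ambiguous = 0))
})

test_that("concordance matches the independent binomial tail and closed forms", {
  cases <- expand.grid(k = 0:40, contra = c(0L, 1L, 3L, 10L))
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]; ct <- cases$contra[i]
    expect_equal(concordance_pvalue(k, ct),
                 stats::pbinom(k - 1, k + ct, 0.5, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # all-correct HYPs collapse to 0.5^k exactly
  for (k in 1:30) {
    expect_equal(concordance_pvalue(k, 0), 0.5^k, tolerance = 1e-14)
  }
  expect_equal(concordance_pvalue(0, 0), 1)
  # non-increasing in correct for fixed trials
  t <- 12
  pv <- vapply(0:t, function(k) concordance_pvalue(k, t - k), numeric(1))
  expect_true(all(diff(pv) < 0))
})

test_that("richness equals the exhaustive subset-enumeration oracle (N <= 12)", {
  grid <- expand.grid(N = c(8L, 10L, 12L), m = c(2L, 4L, 6L), n = c(3L, 5L))
  for (i in seq_len(nrow(grid))) {
    N <- grid$N[i]; m <- grid$m[i]; n <- grid$n[i]
    for (k in 0:min(n, m)) {
      expect_equal(richness_pvalue(k, n, N, m), oracle_hyper_tail(k, n, N, m),
                   tolerance = 1e-12,
                   label = sprintf("rich(k=%d,n=%d,N=%d,m=%d)", k, n, N, m))
    }
  }
  # the derived closed case: 2 of 3 drawn from 10 with 4 marked = 1/3
  expect_equal(richness_pvalue(2, 3, 10, 4), 1 / 3, tolerance = 1e-12)
})

test_that("richness matches the independent hypergeometric tail at scale", {
  cases <- data.frame(k = c(7, 76, 7, 4, 5),
                      n = c(27, 417, 16, 47, 33),
                      N = c(7594, 6644, 7500, 7594, 7594),
                      m = c(193, 330, 1126, 193, 193))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], expect_equal(
      richness_pvalue(k, n, N, m),
      stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE),
      tolerance = 1e-10))
  }
  expect_equal(richness_pvalue(0, 20, 100, 10), 1)
  expect_error(richness_pvalue(2, 30, 20, 5), "population size")
  # non-increasing in k
  pv <- vapply(0:10, function(k) richness_pvalue(k, 10, 100, 30), numeric(1))
  expect_true(all(diff(pv) < 0))
})

test_that("point probabilities of both distributions sum to one", {
  t <- 25
  binom_points <- vapply(0:t, function(j) {
    concordance_pvalue(j, t - j) - if (j < t) concordance_pvalue(j + 1, t - j - 1) else 0
  }, numeric(1))
  expect_equal(sum(binom_points), 1, tolerance = 1e-12)

  N <- 40; m <- 12; n <- 9
  hyper_points <- vapply(0:n, function(j) {
    richness_pvalue(j, n, N, m) -
      if (j < min(n, m)) richness_pvalue(j + 1, n, N, m) else 0
  }, numeric(1))
  expect_equal(sum(hyper_points), 1, tolerance = 1e-12)
})

test_that("score tables are complete, ordered, and internally consistent", {
  spec <- planted_spec(seed = 31)
  fx <- generate_fixture_graph(spec)
  de <- simulate_de_table(fx, spec)
  fit <- rcr(fx$edges, de, fx$mapping)
  sc <- fit$scores
  expect_equal(nrow(sc), length(fit$hyps))
  expect_true(all(sc$observed == sc$correct + sc$contra + sc$ambiguous))
  expect_true(all(sc$observed <= sc$possible))
  expect_true(all(sc$richness > 0 & sc$richness <= 1))
  expect_true(all(sc$concordance > 0 & sc$concordance <= 1))
  expect_true(!is.unsorted(sc$concordance))
  expect_named(sc, c("mechanism", "direction", "correct", "richness",
                     "concordance", "ambiguous", "contra", "possible",
                     "observed"))
})

test_that("relabelling nodes by a bijection leaves all scores identical", {
  fx <- fig_hyp_fixture()
  pop <- compute_population(fx$hyps, fx$states)
  sc <- score_hyps(fx$hyps, fx$states, pop)

  relabel <- function(x) chartr("ABCDEF", "QWERTY", x)
  graph2 <- fx$graph
  graph2$edges$target <- relabel(graph2$edges$target)
  graph2$nodes$node <- relabel(graph2$nodes$node)
  states2 <- stats::setNames(fx$states, relabel(names(fx$states)))
  hyps2 <- generate_hyps(graph2, names(states2))
  sc2 <- score_hyps(hyps2, states2, compute_population(hyps2, states2))
  expect_equal(sc[, -1], sc2[, -1])
})

test_that("global state negation flips directions and preserves p-values", {
  spec <- planted_spec(seed = 33, penetrance = 0.6, background = 0.1)
  fx <- generate_fixture_graph(spec)
  de <- simulate_de_table(fx, spec)
  fit <- rcr(fx$edges, de, fx$mapping)

  neg_states <- -fit$states
  sc_neg <- score_hyps(fit$hyps, neg_states,
                       compute_population(fit$hyps, neg_states))
  sc <- fit$scores
  key <- order(sc$mechanism); key_neg <- order(sc_neg$mechanism)
  expect_equal(sc_neg$direction[key_neg], -sc$direction[key])
  expect_equal(sc_neg$correct[key_neg], sc$correct[key])
  expect_equal(sc_neg$contra[key_neg], sc$contra[key])
  expect_equal(sc_neg$ambiguous[key_neg], sc$ambiguous[key])
  expect_equal(sc_neg$richness[key_neg], sc$richness[key])
  expect_equal(sc_neg$concordance[key_neg], sc$concordance[key])
})

test_that("the significance filter keeps only jointly significant HYPs", {
  sc <- data.frame(richness = c(0.05, 0.05, 0.2, 0.1),
                   concordance = c(0.09, 0.2, 0.05, 0.1))
  kept <- filter_significant(sc, 0.1)
  expect_equal(nrow(kept), 2L)  # row 4 kept: threshold is inclusive
  expect_equal(rownames(kept), c("1", "4"))
  expect_error(filter_significant(sc, 0), "alpha")
})

test_that("report formatting renders two-significant-figure p-values", {
  sc <- data.frame(mechanism = "x", direction = 1L, correct = 6L,
                   richness = 3.54e-6, concordance = 0.0625,
                   ambiguous = 0L, contra = 1L, possible = 27L,
                   observed = 7L)
  out <- format_scores(sc)
  expect_identical(out$concordance, "6.3E-02")
  expect_identical(out$richness, "3.5E-06")
})
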