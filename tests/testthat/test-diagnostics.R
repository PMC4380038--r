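tree_abc <- triad_tree(c("a", "b"), "c")

test_that("G statistic matches hand computation and conventions", {
  expect_equal(g_statistic(c(20, 20), c(20, 20)), 0)
  expect_equal(g_statistic(c(30, 10), c(20, 20)),
               2 * (30 * log(1.5) + 10 * log(0.5)), tolerance = 1e-12)
  # zero observed categories contribute nothing
  expect_equal(g_statistic(c(30, 10, 0), c(20, 19, 1)),
               2 * (30 * log(30 / 20) + 10 * log(10 / 19)), tolerance = 1e-12)
  expect_identical(g_statistic(c(1, 1), c(0, 2)), Inf)
  expect_error(g_statistic(c(1, 1), c(1, 2)), "totals")
})

test_that("G equals twice the saturated-vs-model log-likelihood gap", {
  m <- random_gtr_model(101, c(0.1, 0.3))
  cts <- pattern_counts(simulate_alignment(m, 2000, seed = 102), tree_abc)
  fit <- fit_gtr(cts, tree_abc, restarts = 0)
  n <- sum(cts)
  sel <- cts > 0
  lnl_sat <- sum(cts[sel] * log(cts[sel] / n))
  g <- g_statistic(cts, expected_pattern_counts(fit, n))
  expect_equal(g, 2 * (lnl_sat - fit$loglik), tolerance = 1e-8)
})

test_that("DLC check requires strict diagonal dominance per column", {
  expect_true(dlc_check(diag(4)))
  perm <- diag(4)[c(2, 1, 3, 4), ]
  expect_false(dlc_check(perm))
  set.seed(12)
  for (i in 1:6) {
    expect_true(dlc_check(transition_matrix(random_q(), 0.01)))
  }
  # exact tie fails
  P <- matrix(0.25, 4, 4)
  expect_false(dlc_check(P))
})

test_that("uniqueness screen accepts generic spectra, rejects the rest", {
  set.seed(13)
  for (i in 1:6) {
    Q <- random_q()
    P <- transition_matrix(Q, 0.3)
    ev <- eigen(P, only.values = TRUE)$values
    generic <- all(abs(Im(ev)) < 1e-9) && all(Re(ev) > 0) &&
      min(diff(sort(Re(ev)))) > 1e-5
    if (generic) expect_true(unique_mapping_check(P))
  }
  # JC transition matrix has a triple eigenvalue: conservatively rejected
  expect_false(unique_mapping_check(transition_matrix(jc_q(), 0.2)))
  # negative determinant: no real logarithm exists
  swap <- diag(4)[c(2, 1, 3, 4), ]
  expect_false(unique_mapping_check(swap))
})

test_that("identifiability screens pass for short generic edges", {
  set.seed(14)
  for (i in 1:10) {
    Q <- random_q()
    t <- stats::runif(1, 0.005, 0.05)
    P <- transition_matrix(Q, t)
    ev <- eigen(P, only.values = TRUE)$values
    generic <- all(abs(Im(ev)) < 1e-9 * max(Mod(ev))) &&
      min(diff(sort(Re(ev)))) > 1e-5
    expect_true(dlc_check(P))
    if (generic) expect_true(unique_mapping_check(P))
  }
})

test_that("clock LRT statistic, P-value, and input validation", {
  m <- random_gtr_model(111, c(0.1, 0.3), clock = TRUE)
  cts <- pattern_counts(simulate_alignment(m, 3000, seed = 112), tree_abc)
  free <- fit_gtr(cts, tree_abc, restarts = 0)
  clock <- fit_gtr(cts, tree_abc, clock = TRUE, restarts = 0)
  lrt <- clock_lrt(clock, free)
  expect_s3_class(lrt, "htest")
  expect_gte(unname(lrt$statistic), 0)
  expect_true(lrt$p.value >= 0 && lrt$p.value <= 1)
  expect_equal(lrt$p.value,
               pchisq(unname(lrt$statistic), 1, lower.tail = FALSE))

  # equal likelihoods give P = 1; the 95th percentile gives P = 0.05
  clock2 <- clock
  free2 <- free
  clock2$loglik <- free2$loglik
  expect_equal(clock_lrt(clock2, free2)$p.value, 1)
  clock3 <- clock
  clock3$loglik <- free$loglik - 3.841459 / 2
  expect_equal(clock_lrt(clock3, free)$p.value, 0.05, tolerance = 1e-6)

  expect_error(clock_lrt(free, clock), "clock-constrained")
  gen <- fit_general(cts, tree_abc, seed_model = free, restarts = 0)
  expect_error(clock_lrt(clock, gen), "same model family")
})

test_that("AIC follows from the stored degrees of freedom", {
  m <- random_gtr_model(121, c(0.1, 0.3))
  cts <- pattern_counts(simulate_alignment(m, 1000, seed = 122), tree_abc)
  fit <- fit_gtr(cts, tree_abc, restarts = 0)
  expect_equal(AIC(fit), 2 * 11 - 2 * fit$loglik, tolerance = 1e-10)
})

test_that("edge length ratios are reciprocal and exactly 1 under the clock", {
  m <- random_gtr_model(131, c(0.1, 0.3))
  cts <- pattern_counts(simulate_alignment(m, 3000, seed = 132), tree_abc)
  fit <- fit_gtr(cts, tree_abc, restarts = 0)
  r <- edge_length_ratio(fit, "a", "b")
  expect_equal(r * edge_length_ratio(fit, "b", "a"), 1, tolerance = 1e-12)
  clock <- fit_gtr(cts, tree_abc, clock = TRUE, restarts = 0)
  expect_equal(edge_length_ratio(clock, "a", "b"), 1)
  expect_error(edge_length_ratio(fit, "a", "z"), "unknown edge")
})

test_that("bootstrap P-values are roughly uniform under the null", {
  # data simulated from the fitted model itself: the goodness-of-fit
  # P-value should be close to uniform (scaled-down calibration check)
  m <- random_gtr_model(145, c(0.1, 0.25))
  base <- pattern_counts(simulate_alignment(m, 1000, seed = 146), tree_abc)
  fit0 <- fit_gtr(base, tree_abc, restarts = 0)
  ps <- vapply(1:20, function(i) {
    cts <- pattern_counts(simulate_alignment(fit0, 1000, seed = 500 + i),
                          tree_abc)
    f <- fit_gtr(cts, tree_abc, restarts = 0)
    parametric_bootstrap_pvalue(f, n_reps = 20, seed = 700 + i)$p_value
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("parametric bootstrap is seeded, bounded, and reproducible", {
  m <- random_gtr_model(141, c(0.1, 0.25))
  cts <- pattern_counts(simulate_alignment(m, 800, seed = 142), tree_abc)
  fit <- fit_gtr(cts, tree_abc, restarts = 0)
  g1 <- parametric_bootstrap_pvalue(fit, n_reps = 15, seed = 99)
  g2 <- parametric_bootstrap_pvalue(fit, n_reps = 15, seed = 99)
  expect_identical(g1$p_value, g2$p_value)
  expect_identical(g1$g_replicates, g2$g_replicates)
  # resolution is 1/n_reps
  expect_equal(g1$p_value * 15, round(g1$p_value * 15))
  expect_false(gof_rejected(structure(list(p_value = 0.5),
                                      class = "gof_test")))
  expect_true(gof_rejected(structure(list(p_value = 0.01),
                                     class = "gof_test")))
})
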