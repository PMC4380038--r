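tree_abc <- triad_tree(c("a", "b"), "c")

test_that("GTR fit recovers edge lengths from Jukes-Cantor data", {
  Q <- jc_q()
  truth <- c(a = 0.15, b = 0.25, c = 0.35)
  model <- structure(
    list(family = "GTR", clock = FALSE, tree = tree_abc,
         root_dist = rep(0.25, 4), Q = Q,
         edges = lapply(truth, function(t) edge_process(Q, t)),
         edge_ens = truth, gamma_shape = NULL, n_rate_bins = 1L, dof = 11L),
    class = "triad_model"
  )
  aln <- simulate_alignment(model, 1e5, seed = 21)
  fit <- fit_gtr(pattern_counts(aln, tree_abc), tree_abc)
  expect_lt(max(abs(fit$edge_ens - truth) / truth), 0.03)
})

test_that("clock constraint equalizes ingroup lengths and never gains lnL", {
  set.seed(31)
  m <- random_gtr_model(31, c(0.1, 0.3))
  cts <- pattern_counts(simulate_alignment(m, 5000, seed = 32), tree_abc)
  free <- fit_gtr(cts, tree_abc)
  clock <- fit_gtr(cts, tree_abc, clock = TRUE)
  expect_identical(unname(clock$edge_ens[1]), unname(clock$edge_ens[2]))
  expect_lte(clock$loglik, free$loglik + 1e-6)
  expect_equal(clock$dof, 10L)
  expect_equal(free$dof, 11L)
})

test_that("GTR+Gamma approaches GTR in the infinite-shape limit", {
  set.seed(41)
  m <- random_gtr_model(41, c(0.1, 0.4))
  cts <- pattern_counts(simulate_alignment(m, 10000, seed = 42), tree_abc)
  gtr <- fit_gtr(cts, tree_abc)
  # likelihood of the gamma model at the shape upper bound, same parameters
  par_gamma <- c(gtr$par, log(200))
  nll_gamma <- ensdist:::.gtr_negll_cpp(par_gamma, as.numeric(cts),
                                        FALSE, TRUE, 4L)
  expect_lt(abs(-nll_gamma - gtr$loglik), 0.1)
})

test_that("gamma shape is recovered within a factor of two", {
  set.seed(51)
  m <- random_gtr_model(51, c(0.15, 0.45))
  m$gamma_shape <- 0.5
  m$n_rate_bins <- 4L
  aln <- simulate_alignment(m, 1e5, seed = 52)
  cts <- pattern_counts(aln, tree_abc)
  fit <- fit_gtr_gamma(cts, tree_abc)
  expect_gt(fit$gamma_shape, 0.25)
  expect_lt(fit$gamma_shape, 1.0)
  # fitted shape beats nearby fixed shapes
  for (s in c(0.2, 1.5)) {
    par_s <- fit$par
    par_s[length(par_s)] <- log(s)
    expect_lte(ensdist:::.gtr_negll_cpp(fit$par, as.numeric(cts), FALSE,
                                        TRUE, 4L),
               ensdist:::.gtr_negll_cpp(par_s, as.numeric(cts), FALSE,
                                        TRUE, 4L) + 1e-6)
  }
})

test_that("general fit recovers a nonstationary truth", {
  m <- random_general_model(61, ens_range = c(0.1, 0.4), jsd_floor = 0.01)
  aln <- simulate_alignment(m, 5e4, seed = 62)
  cts <- pattern_counts(aln, tree_abc)
  fit <- fit_general(cts, tree_abc)
  expect_lt(max(abs(fit$edge_ens - m$edge_ens) / m$edge_ens), 0.12)
  expect_lt(max(abs(fit$root_dist - m$root_dist)), 0.03)
})

test_that("general clock fit satisfies the ENS equality exactly", {
  m <- random_general_model(71, ens_range = c(0.1, 0.3))
  cts <- pattern_counts(simulate_alignment(m, 3000, seed = 72), tree_abc)
  fit <- fit_general(cts, tree_abc, clock = TRUE)
  expect_lt(abs(fit$edge_ens[[1]] - fit$edge_ens[[2]]), 1e-8)
  expect_equal(fit$dof, 38L)
})

test_that("sequential fitting is monotone along nested chains", {
  m <- random_general_model(81, ens_range = c(0.1, 0.35), jsd_floor = 0.01)
  aln <- simulate_alignment(m, 4000, seed = 82)
  fits <- sequential_fit(aln, tree_abc, clock_suite = TRUE)
  expect_gte(fits$general$loglik, fits$gtr$loglik)
  expect_gte(fits$gtr$loglik, fits$gtr_clock$loglik)
  expect_gte(fits$gtr_gamma$loglik, fits$gtr_gamma_clock$loglik)
  expect_gte(fits$general$loglik, fits$general_clock$loglik)
  expect_gte(fits$general_clock$loglik, fits$gtr_clock$loglik)
  # optimum reported by optim matches the likelihood recomputed from the
  # stored model parameters
  for (f in fits) {
    expect_equal(f$loglik, log_likelihood(f, f$counts), tolerance = 1e-6)
  }
})
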