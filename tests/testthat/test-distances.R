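test_that("empirical_joint counts aligned base pairs", {
  J <- empirical_joint("AC", "CA")
  expect_equal(J["A", "C"], 0.5)
  expect_equal(J["C", "A"], 0.5)
  expect_equal(sum(J), 1)

  Jd <- empirical_joint("AACG", "AACG")
  expect_equal(unname(diag(Jd)), c(0.5, 0.25, 0.25, 0))
  expect_equal(sum(Jd != 0), 3)

  expect_error(empirical_joint("AC", "ACG"), "equal length")
  expect_error(empirical_joint("", ""), "non-empty")
})

test_that("paralinear distance equals t on calibrated Jukes-Cantor edges", {
  Q <- jc_q()
  for (t in c(0.1, 0.5, 1.2)) {
    J <- process_joint(rep(0.25, 4), transition_matrix(Q, t))
    expect_equal(paralinear_distance(J), t, tolerance = 1e-10)
  }
})

test_that("the J-form and P-form of the paralinear distance agree", {
  set.seed(9)
  for (i in 1:8) {
    Q <- random_q()
    pi <- stationary_distribution(Q)
    t <- stats::runif(1, 0.1, 1.5)
    P <- transition_matrix(Q, t)
    J <- process_joint(pi, P)
    pj <- paralinear_distance(J)
    pi_nu <- as.vector(pi %*% P)
    pform <- -log(det(diag(sqrt(pi)) %*% P %*% diag(1 / sqrt(pi_nu)))) / 4
    expect_equal(pj, pform, tolerance = 1e-10)
  }
})

test_that("paralinear edge cases: identity joint, zero marginal, saturation", {
  pi <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(paralinear_distance(diag(pi)), 0, tolerance = 1e-12)
  Jz <- diag(c(0.5, 0.3, 0.2, 0))
  expect_error(paralinear_distance(Jz), "singular")
  # a saturated joint (independent ends) has determinant 0
  Jsat <- outer(rep(0.25, 4), rep(0.25, 4))
  expect_error(paralinear_distance(Jsat), "saturated")
})

test_that("logdet distance and its relation to paralinear", {
  expect_equal(logdet_distance(0.25 * diag(4)), 4 * log(4), tolerance = 1e-12)
  # symmetric J with uniform marginals: d_para = (d_LogDet - 4 log 4) / 4
  Q <- jc_q()
  J <- process_joint(rep(0.25, 4), transition_matrix(Q, 0.4))
  expect_equal(paralinear_distance(J), (logdet_distance(J) - 4 * log(4)) / 4,
               tolerance = 1e-10)
  expect_error(logdet_distance(outer(rep(.25, 4), rep(.25, 4))), "saturated")
})

test_that("entropy and JSD match closed forms", {
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0)), log(2), tolerance = 1e-12)

  p <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(jsd(list(p, p)), 0, tolerance = 1e-12)
  expect_equal(jsd(list(c(1, 0, 0, 0), c(0, 1, 0, 0))), log(2),
               tolerance = 1e-12)
  expect_equal(jsd(list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))),
               log(3), tolerance = 1e-12)
  expect_error(jsd(list(p)), "at least two")
})

test_that("JSD between f(0) and f(t) increases with t for F81", {
  pi <- c(0.5, 0.2, 0.1, 0.2)
  Q <- rate_matrix_f81(pi, alpha = 1)
  f0 <- c(0.05, 0.45, 0.3, 0.2)
  ts <- seq(0, 5, length.out = 30)
  vals <- vapply(ts, function(t) {
    ft <- as.vector(f0 %*% transition_matrix(Q, t))
    jsd(list(f0, ft))
  }, 0)
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("gc_content and base composition", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_error(gc_content(""), "non-empty")
  expect_equal(base_composition("AACG"), c(A = .5, C = .25, G = .25, T = 0))
})

test_that("ens_path_distance sums edges through the root", {
  m <- random_general_model(91, ens_range = c(0.1, 0.3))
  expect_equal(ens_path_distance(m, "a", "a"), 0)
  expect_equal(ens_path_distance(m, "a", "b"),
               ens_path_distance(m, "b", "a"))
  expect_equal(ens_path_distance(m, "a", "b"),
               m$edge_ens[["a"]] + m$edge_ens[["b"]])
  expect_equal(ens_path_distance(m, "root", "c"), m$edge_ens[["c"]])
  expect_error(ens_path_distance(m, "a", "z"), "unknown node")
  # per-edge ENS equals the quadrature oracle with the root marginal
  e <- m$edges$c
  expect_lt(abs(m$edge_ens[["c"]] -
                  ens_quadrature(m$root_dist, e$Q, e$t)), 1e-6)
})

test_that("GTR path distances reduce to the stationary formula", {
  tr <- triad_tree(c("a", "b"), "c")
  m <- random_gtr_model(95, c(0.1, 0.4))
  cts <- pattern_counts(simulate_alignment(m, 20000, seed = 96), tr)
  fit <- fit_gtr(cts, tr)
  pi <- stationary_distribution(fit$Q)
  for (lv in tr$leaves) {
    e <- fit$edges[[lv]]
    expect_equal(fit$edge_ens[[lv]], ens_stationary(pi, e$Q, e$t),
                 tolerance = 1e-8)
    expect_equal(fit$edge_ens[[lv]], ens(pi, e$Q, e$t), tolerance = 1e-8)
  }
})
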