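test_that("make_rate_matrix builds valid generators", {
  Q <- jc_q()
  expect_equal(diag(Q), rep(-1, 4), ignore_attr = TRUE)
  expect_equal(rowSums(Q), rep(0, 4), ignore_attr = TRUE)

  Qf <- rate_matrix_f81(f81_pi, alpha = 1)
  expect_equal(rowSums(Qf), rep(0, 4), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(Qf["A", "C"], 0.2)

  set.seed(1)
  off <- stats::runif(12, 0.1, 2)
  Q3 <- make_rate_matrix(off)
  expect_equal(as.vector(t(Q3))[as.vector(t(row(Q3) != col(Q3)))], off)
  expect_equal(rowSums(Q3), rep(0, 4), ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(make_rate_matrix(c(-1, rep(1, 11))), "nonnegative")
  expect_error(make_rate_matrix(c(NaN, rep(1, 11))), "finite")
  expect_error(make_rate_matrix(rep(1, 11)), "length 12")
})

test_that("stationary_distribution solves pi Q = 0", {
  expect_equal(stationary_distribution(jc_q()), rep(0.25, 4),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(stationary_distribution(rate_matrix_f81(f81_pi)),
               unname(f81_pi), ignore_attr = TRUE, tolerance = 1e-10)

  set.seed(42)
  for (i in 1:10) {
    Q <- random_q(calibrated = FALSE)
    pi <- stationary_distribution(Q)
    expect_lt(max(abs(pi %*% Q)), 1e-10)
    # independent null-space oracle: overdetermined linear solve
    oracle <- qr.solve(rbind(t(Q), rep(1, 4)), c(rep(0, 4), 1))
    expect_equal(unname(pi), unname(oracle), tolerance = 1e-8)
  }

  # two closed communicating classes: no unique stationary distribution
  Qred <- matrix(0, 4, 4)
  Qred[1, 2] <- Qred[2, 1] <- Qred[3, 4] <- Qred[4, 3] <- 1
  diag(Qred) <- -1
  expect_error(stationary_distribution(Qred), "unique")
})

test_that("calibrate rescales to one substitution per unit time", {
  expect_equal(calibrate(jc_q()), jc_q(), tolerance = 1e-12)

  Qf <- rate_matrix_f81(f81_pi, alpha = 1)
  # total rate is sum(pi * (1 - pi)) = 0.66
  expect_equal(calibrate(Qf), Qf / 0.66, tolerance = 1e-12)

  set.seed(7)
  Q <- random_q(calibrated = FALSE)
  Qc <- calibrate(Q)
  pi <- stationary_distribution(Qc)
  expect_equal(-sum(pi * diag(Qc)), 1, tolerance = 1e-10)
  expect_equal(calibrate(Qc), Qc, tolerance = 1e-12)        # idempotent
  expect_equal(calibrate(3.7 * Q), Qc, tolerance = 1e-12)   # scale-free

  expect_error(calibrate(matrix(0, 4, 4), rep(0.25, 4)), "zero")
})

test_that("transition_matrix matches spectral forms", {
  Q <- jc_q()
  expect_equal(transition_matrix(Q, 0), diag(4), ignore_attr = TRUE,
               tolerance = 1e-14)
  for (t in c(0.1, 0.7, 2)) {
    P <- transition_matrix(Q, t)
    expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE,
                 tolerance = 1e-10)
    expect_equal(unname(diag(P)), rep(1 / 4 + 3 / 4 * exp(-4 * t / 3), 4),
                 tolerance = 1e-12)
  }
  set.seed(11)
  for (i in 1:8) {
    Q <- random_q()
    t <- stats::runif(1, 0.05, 3)
    expect_equal(unname(transition_matrix(Q, t)), eig_expm(Q * t),
                 tolerance = 1e-10)
  }
})

test_that("edge_process validates its fields", {
  expect_error(edge_process(jc_q(), -1), "t >= 0")
  e <- edge_process(jc_q(), 0.3)
  expect_s3_class(e, "edge_process")
  expect_equal(transition_matrix(e), transition_matrix(jc_q(), 0.3))
})
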