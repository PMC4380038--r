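#' Expected number of substitutions over an edge
#'
#' The expected number of substitutions per site accumulated over the
#' interval `[0, t]` by a (possibly nonstationary) Markov process with
#' generator `Q` and initial distribution `f0`:
#' `n(t) = -integral_0^t f(s) ds %*% diag(Q)` with `f(s) = f0 %*% exp(Qs)`.
#' Computed by exponentiating the 5x5 augmented matrix
#' `C = rbind(cbind(Q, -diag(Q)), 0)` and reading off the final column,
#' which is as robust as the matrix exponential itself.
#'
#' When `f0` equals the stationary distribution of `Q` this reduces to the
#' classical linear formula `-sum(pi * diag(Q)) * t` (see
#' [ens_stationary()]); for a calibrated `Q` it is then exactly `t`.
#'
#' @param f0 initial nucleotide distribution (row vector over A, C, G, T).
#' @param Q a 4x4 rate matrix, or an [edge_process()] (then `t` is taken
#'   from it).
#' @param t nonnegative duration.
#' @return nonnegative scalar, substitutions per site.
#' @examples
#' Q <- rate_matrix_f81(c(0.5, 0.2, 0.1, 0.2), alpha = 1)
#' ens(c(0.5, 0.2, 0.1, 0.2), Q, 1.5) # 0.99
#' ens(c(0.1, 0.3, 0.2, 0.4), Q, 1.5) # 1.09
#' @export
ens <- function(f0, Q, t = 1) {
  if (inherits(Q, "edge_process")) {
    t <- Q$t
    Q <- Q$Q
  }
  check_distribution(f0)
  check_rate_matrix(Q)
  stopifnot(is.numeric(t), length(t) == 1, t >= 0)
  if (t == 0) return(0)
  .ens_aug_cpp(f0, Q, t)
}

#' Stationary-process expected number of substitutions
#'
#' The classical formula `n(t) = -sum(pi * diag(Q)) * t`, valid when the
#' process starts at its stationary distribution (and, by iterated
#' expectation, under standard stationary rate-heterogeneous models).
#'
#' @param pi the stationary distribution of `Q`.
#' @param Q a 4x4 rate matrix.
#' @param t nonnegative duration.
#' @return nonnegative scalar, linear in `t`.
#' @export
ens_stationary <- function(pi, Q, t) {
  check_distribution(pi)
  check_rate_matrix(Q)
  -sum(pi * diag(Q)) * t
}

#' Quadrature oracle for the ENS integral
#'
#' Direct numerical integration of `-f(s) %*% diag(Q)` over `[0, t]` by
#' composite Simpson's rule, with `f` propagated stepwise through a single
#' per-step transition matrix. Intended as an independent cross-check of
#' [ens()]; it shares no code path with the augmented-matrix construction.
#'
#' @inheritParams ens
#' @param n_steps number of (even) quadrature steps, at least 100.
#' @return nonnegative scalar.
#' @export
ens_quadrature <- function(f0, Q, t, n_steps = 10000) {
  check_distribution(f0)
  check_rate_matrix(Q)
  stopifnot(n_steps >= 100, t >= 0)
  if (t == 0) return(0)
  n <- as.integer(n_steps)
  if (n %% 2L == 1L) n <- n + 1L
  h <- t / n
  Pstep <- .expm_cpp(Q * h)
  d <- diag(Q)
  f <- f0
  vals <- numeric(n + 1L)
  vals[1L] <- -sum(f * d)
  for (k in seq_len(n)) {
    f <- as.vector(f %*% Pstep)
    vals[k + 1L] <- -sum(f * d)
  }
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * vals) * h / 3
}

#' Closed-form ENS for the F81 model
#'
#' For the Felsenstein model `Q[i, j] = alpha * pi[j]` the state
#' distribution relaxes as `f_i(s) = pi_i + (f_i(0) - pi_i) * exp(-alpha s)`,
#' giving
#' `n(t) = alpha t sum_i pi_i (1 - pi_i) +
#'   (1 - exp(-alpha t)) sum_i (1 - pi_i) (f_i(0) - pi_i)`.
#' The second term is the nonstationarity correction; it vanishes for
#' uniform `pi` and for `f0 = pi`.
#'
#' @param pi stationary distribution of the F81 process.
#' @param alpha overall rate, > 0.
#' @param t nonnegative duration.
#' @param f0 initial distribution; defaults to `pi` (stationary case).
#' @return nonnegative scalar.
#' @export
f81_ens <- function(pi, alpha, t, f0 = pi) {
  check_distribution(pi)
  check_distribution(f0)
  stopifnot(alpha > 0, t >= 0)
  alpha * t * sum(pi * (1 - pi)) +
    (1 - exp(-alpha * t)) * sum((1 - pi) * (f0 - pi))
}
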