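# Shared fixtures and independent oracles.

jc_q <- function() make_rate_matrix(rep(1 / 3, 12))

f81_pi <- c(A = 0.5, C = 0.2, G = 0.1, T = 0.2)

# Independent matrix exponential by eigendecomposition (cross-check only;
# the package uses scaling-and-squaring).
eig_expm <- function(M) {
  e <- eigen(M)
  Re(e$vectors %*% diag(exp(e$values)) %*% solve(e$vectors))
}

# Random strictly-positive generator, optionally calibrated.
random_q <- function(calibrated = TRUE) {
  Q <- make_rate_matrix(exp(stats::rnorm(12, 0, 0.6)))
  if (calibrated) calibrate(Q) else Q
}

random_distribution <- function(alpha = 4) {
  g <- stats::rgamma(4, alpha)
  p <- g / sum(g)
  names(p) <- c("A", "C", "G", "T")
  p
}

# Brute-force triad pattern log likelihood: explicit sum over root states
# (and gamma bins), plain R loops, eigendecomposition exponentials.
oracle_loglik <- function(model, counts) {
  rates <- if (is.null(model$gamma_shape)) 1 else
    ensdist:::.gamma_bin_rates_cpp(model$gamma_shape, model$n_rate_bins)
  probs <- numeric(64)
  for (r in rates) {
    P <- lapply(model$edges, function(e) eig_expm(e$Q * (e$t * r)))
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      idx <- (i - 1) * 16 + (j - 1) * 4 + k
      s <- 0
      for (root in 1:4) {
        s <- s + model$root_dist[root] * P[[1]][root, i] *
          P[[2]][root, j] * P[[3]][root, k]
      }
      probs[idx] <- probs[idx] + s / length(rates)
    }
  }
  sum(counts[counts > 0] * log(probs[counts > 0]))
}
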