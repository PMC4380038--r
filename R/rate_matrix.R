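#' Build a rate matrix from its off-diagonal entries
#'
#' Constructs a 4x4 continuous-time Markov generator over the nucleotide
#' states A, C, G, T. The twelve off-diagonal rates are supplied row-major
#' (A->C, A->G, A->T, C->A, C->G, C->T, G->A, G->C, G->T, T->A, T->C, T->G)
#' and the diagonal is set so every row sums to zero.
#'
#' @param off_diagonals numeric vector of 12 nonnegative, finite rates,
#'   row-major in state order A, C, G, T.
#' @return a 4x4 numeric matrix with `dimnames` `list(NUC, NUC)`, rows
#'   summing to zero.
#' @examples
#' Q <- make_rate_matrix(rep(1 / 3, 12)) # Jukes-Cantor, diagonal -1
#' @export
make_rate_matrix <- function(off_diagonals) {
  if (length(off_diagonals) != 12 || !is.numeric(off_diagonals)) {
    stop("'off_diagonals' must be a numeric vector of length 12")
  }
  if (any(!is.finite(off_diagonals)) || any(off_diagonals < 0)) {
    stop("off-diagonal rates must be finite and nonnegative")
  }
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  idx <- 1L
  for (i in 1:4) {
    for (j in 1:4) {
      if (i != j) {
        Q[i, j] <- off_diagonals[idx]
        idx <- idx + 1L
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Felsenstein (F81) generator
#'
#' Generator with `Q[i, j] = alpha * pi[j]` for `i != j`, whose stationary
#' distribution is `pi`.
#'
#' @param pi probability vector over A, C, G, T.
#' @param alpha overall rate, > 0.
#' @return a 4x4 rate matrix.
#' @export
rate_matrix_f81 <- function(pi, alpha = 1) {
  check_distribution(pi)
  stopifnot(alpha > 0)
  off <- numeric(12)
  idx <- 1L
  for (i in 1:4) {
    for (j in 1:4) {
      if (i != j) {
        off[idx] <- alpha * pi[j]
        idx <- idx + 1L
      }
    }
  }
  make_rate_matrix(off)
}

#' GTR generator from exchangeabilities and frequencies
#'
#' Time-reversible generator `Q[i, j] = R[i, j] * pi[j]` for symmetric `R`.
#' Exchangeabilities are given in the order AC, AG, AT, CG, CT, GT.
#'
#' @param rates six nonnegative exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param pi stationary probability vector over A, C, G, T.
#' @param calibrated if `TRUE` (default) rescale so the stationary
#'   substitution rate per unit time is one.
#' @return a 4x4 rate matrix.
#' @export
rate_matrix_gtr <- function(rates, pi, calibrated = TRUE) {
  stopifnot(length(rates) == 6, all(rates >= 0))
  check_distribution(pi)
  R <- matrix(0, 4, 4)
  R[upper.tri(R)] <- rates[c(1, 2, 4, 3, 5, 6)] # column-major upper triangle
  R <- R + t(R)
  Q <- R * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(NUC, NUC)
  if (calibrated) Q <- calibrate(Q, pi) else Q
}

check_distribution <- function(p, tol = 1e-9) {
  if (length(p) != 4 || !is.numeric(p)) {
    stop("a nucleotide distribution must be a numeric vector of length 4")
  }
  if (any(p < -1e-12) || abs(sum(p) - 1) > tol) {
    stop("probabilities must be nonnegative and sum to 1")
  }
  invisible(p)
}

check_rate_matrix <- function(Q, tol = 1e-9) {
  if (!is.matrix(Q) || any(dim(Q) != 4)) stop("Q must be a 4x4 matrix")
  scale <- max(abs(Q), 1)
  off <- Q[row(Q) != col(Q)]
  if (any(off < -1e-12 * scale)) stop("off-diagonal rates must be nonnegative")
  if (any(abs(rowSums(Q)) > tol * scale)) stop("rows of Q must sum to zero")
  invisible(Q)
}

#' Stationary distribution of a generator
#'
#' Solves for the unique probability row vector `pi` with `pi %*% Q = 0`.
#'
#' @param Q a 4x4 rate matrix with an irreducible off-diagonal structure.
#' @return the stationary probability vector, named A, C, G, T.
#' @export
stationary_distribution <- function(Q) {
  check_rate_matrix(Q)
  # null space of t(Q) must be one-dimensional for uniqueness
  A <- t(Q)
  s <- svd(A)
  if (sum(s$d < 1e-10 * max(s$d, 1)) != 1L) {
    stop("Q has no unique stationary distribution (reducible or degenerate)")
  }
  v <- s$v[, 4]
  pi <- v / sum(v)
  if (any(pi < -1e-10)) {
    stop("Q has no unique stationary distribution (negative solution)")
  }
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  names(pi) <- NUC
  pi
}

#' Calibrate a rate matrix
#'
#' Rescales `Q` so that the expected number of substitutions per unit time at
#' the reference frequencies is one, i.e. `-sum(freq * diag(Q)) == 1`. By
#' default the reference is the stationary distribution of `Q` itself, making
#' edge durations directly interpretable as expected substitutions per site.
#'
#' @param Q a 4x4 rate matrix.
#' @param freq reference frequencies; defaults to `stationary_distribution(Q)`.
#' @return the rescaled rate matrix.
#' @export
calibrate <- function(Q, freq = NULL) {
  check_rate_matrix(Q)
  if (is.null(freq)) freq <- stationary_distribution(Q)
  check_distribution(freq)
  rate <- -sum(freq * diag(Q))
  if (rate <= 0) stop("total substitution rate is zero; cannot calibrate")
  Q / rate
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param Q a 4x4 rate matrix (or an [edge_process()]; then `t` is taken
#'   from it).
#' @param t nonnegative duration.
#' @return a 4x4 stochastic matrix.
#' @export
transition_matrix <- function(Q, t = 1) {
  if (inherits(Q, "edge_process")) {
    t <- Q$t
    Q <- Q$Q
  }
  check_rate_matrix(Q)
  stopifnot(is.numeric(t), length(t) == 1, t >= 0)
  P <- .expm_cpp(Q * t)
  dimnames(P) <- list(NUC, NUC)
  P
}

#' Edge process: a (Q, t) pair
#'
#' Bundles a generator with a duration. Only the product `Q * t` is
#' identifiable from data at the two ends of an edge; the pair is kept for
#' convenience of construction and reporting.
#'
#' @param Q a 4x4 rate matrix.
#' @param t nonnegative duration.
#' @return an object of class `edge_process` with elements `Q` and `t`.
#' @export
edge_process <- function(Q, t) {
  check_rate_matrix(Q)
  stopifnot(is.numeric(t), length(t) == 1, is.finite(t), t >= 0)
  structure(list(Q = Q, t = t), class = "edge_process")
}

#' @export
print.edge_process <- function(x, ...) {
  cat("Edge process: duration", format(x$t), "\n")
  print(round(x$Q, 4))
  invisible(x)
}
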