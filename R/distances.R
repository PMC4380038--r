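#' ENS distance between two nodes of a fitted triad
#'
#' The ENS distance between two nodes is the sum of per-edge ENS values
#' over the edges on the path between them. Edges of the general model use
#' the nonstationary integral with the fitted marginal at the edge's
#' ancestor as starting distribution; on the 3-edge star every edge starts
#' at the root, so the relevant marginal is the fitted root distribution.
#' GTR-family edges are stationary with calibrated rate matrices, so each
#' edge's ENS is its fitted duration.
#'
#' @param model a `triad_fit`.
#' @param a,b node names: any leaf, or `"root"` for the ingroup ancestor.
#' @return nonnegative scalar; 0 when `a == b`; symmetric in `(a, b)`.
#' @export
ens_path_distance <- function(model, a, b) {
  nodes <- c(model$tree$leaves, "root")
  if (!a %in% nodes) stop("unknown node: ", a)
  if (!b %in% nodes) stop("unknown node: ", b)
  if (a == b) return(0)
  path_ens <- function(x) if (x == "root") 0 else model$edge_ens[[x]]
  path_ens(a) + path_ens(b)
}

#' Empirical joint distribution of aligned bases
#'
#' Entry `(i, j)` is the proportion of alignment columns with base `i` in
#' the first sequence and base `j` in the second. Row sums give the first
#' sequence's composition, column sums the second's.
#'
#' @param seq_a,seq_b equal-length ACGT character strings.
#' @return a 4x4 matrix summing to 1.
#' @export
empirical_joint <- function(seq_a, seq_b) {
  xa <- match(strsplit(toupper(seq_a), "")[[1]], NUC)
  xb <- match(strsplit(toupper(seq_b), "")[[1]], NUC)
  if (length(xa) == 0) stop("sequences must be non-empty")
  if (length(xa) != length(xb)) stop("sequences must have equal length")
  if (anyNA(xa) || anyNA(xb)) stop("sequences must contain only A, C, G, T")
  J <- matrix(tabulate((xa - 1L) * 4L + xb, nbins = 16L) / length(xa),
              4, 4, byrow = TRUE, dimnames = list(NUC, NUC))
  J
}

#' Joint distribution implied by a process
#'
#' `J = diag(pi_mu) %*% P` for ancestor marginal `pi_mu` and transition
#' matrix `P`; the exact counterpart of [empirical_joint()].
#'
#' @param pi_mu ancestor marginal distribution.
#' @param P 4x4 transition matrix.
#' @return a 4x4 joint distribution matrix.
#' @export
process_joint <- function(pi_mu, P) {
  check_distribution(pi_mu)
  J <- diag(pi_mu) %*% P
  dimnames(J) <- list(NUC, NUC)
  J
}

#' Paralinear distance
#'
#' `d_para = -1/4 * log det( diag(pi_mu)^(-1/2) J diag(pi_nu)^(-1/2) )`,
#' where the marginals `pi_mu`, `pi_nu` are the row and column sums of the
#' joint distribution `J`. An approximation to the expected number of
#' substitutions computable purely from the joint distribution of states
#' at the two ends, without assuming stationarity.
#'
#' @param J a 4x4 joint distribution (see [empirical_joint()]), or a pair
#'   of sequences via `paralinear_distance(empirical_joint(a, b))`.
#' @param pseudocount optional Laplace pseudocount added to the underlying
#'   cell proportions before normalization (default off; raw frequencies
#'   are used).
#' @return nonnegative scalar. Errors on a zero marginal frequency
#'   (singularity) or a nonpositive determinant (saturation).
#' @export
paralinear_distance <- function(J, pseudocount = 0) {
  stopifnot(is.matrix(J), all(dim(J) == 4), all(J >= 0))
  if (pseudocount > 0) {
    J <- (J + pseudocount / 16) / (sum(J) + pseudocount)
  } else {
    J <- J / sum(J)
  }
  pm <- rowSums(J)
  pv <- colSums(J)
  if (any(pm <= 0) || any(pv <= 0)) {
    stop("zero marginal frequency: paralinear distance is singular")
  }
  M <- diag(1 / sqrt(pm)) %*% J %*% diag(1 / sqrt(pv))
  d <- det(M)
  if (d <= 0) stop("nonpositive determinant: paralinear distance saturated")
  -log(d) / 4
}

#' LogDet transformation
#'
#' `d_LogDet = -log det(J)`. Related to the paralinear distance but not an
#' estimator of edge lengths; provided for comparison.
#'
#' @param J a 4x4 joint distribution.
#' @return scalar; errors when `det(J) <= 0` (saturation).
#' @export
logdet_distance <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == 4))
  d <- det(J)
  if (d <= 0) stop("nonpositive determinant: LogDet saturated")
  -log(d)
}

#' Shannon entropy of a nucleotide distribution (natural log)
#'
#' @param p probability vector over A, C, G, T; `0 * log(0)` is 0.
#' @return entropy in nats, between 0 (point mass) and `log(4)` (uniform).
#' @export
shannon_entropy <- function(p) {
  check_distribution(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Equally weighted Jensen-Shannon divergence
#'
#' `JSD = H(mean(p_i)) - mean(H(p_i))` over two or more distributions on
#' the same state space, with `H` the Shannon entropy in nats. Zero iff
#' all distributions are equal; at most `log(n)`.
#'
#' @param distributions list of nucleotide distributions (n >= 2).
#' @return nonnegative scalar in nats.
#' @export
jsd <- function(distributions) {
  if (!is.list(distributions) || length(distributions) < 2) {
    stop("'distributions' must be a list of at least two distributions")
  }
  for (p in distributions) check_distribution(p)
  mix <- Reduce(`+`, distributions) / length(distributions)
  shannon_entropy(mix) -
    mean(vapply(distributions, shannon_entropy, 0))
}

#' G+C content of a sequence
#'
#' @param seq a non-empty ACGT character string.
#' @return fraction of G and C bases, in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  x <- strsplit(toupper(seq), "")[[1]]
  if (length(x) == 0) stop("sequence must be non-empty")
  if (!all(x %in% NUC)) stop("sequence must contain only A, C, G, T")
  mean(x %in% c("G", "C"))
}

#' Base composition of a sequence
#'
#' @param seq an ACGT character string.
#' @return probability vector over A, C, G, T.
#' @export
base_composition <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], NUC)
  if (length(x) == 0) stop("sequence must be non-empty")
  if (anyNA(x)) stop("sequence must contain only A, C, G, T")
  setNames(tabulate(x, 4) / length(x), NUC)
}
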