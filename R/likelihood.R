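#' Site-pattern probabilities under a fitted triad model
#'
#' Probability of each of the 64 ordered site patterns under the rooted
#' 3-edge star: `p(ijk) = sum_r root[r] * Pa[r,i] * Pb[r,j] * Pc[r,k]`,
#' averaged over the four discrete gamma rate bins for `GTR+G` models.
#'
#' @param model a `triad_fit` (or a compatible model parameter list from
#'   [random_general_model()]).
#' @return numeric vector of 64 probabilities summing to 1, named by
#'   pattern.
#' @export
triad_pattern_probs <- function(model) {
  root <- model$root_dist
  edges <- model$edges
  rates <- if (!is.null(model$gamma_shape)) {
    .gamma_bin_rates_cpp(model$gamma_shape, model$n_rate_bins)
  } else {
    1
  }
  probs <- numeric(64)
  for (r in rates) {
    P <- lapply(edges, function(e) .expm_cpp(e$Q * (e$t * r)))
    probs <- probs + .triad_probs_cpp(root, P[[1]], P[[2]], P[[3]]) /
      length(rates)
  }
  names(probs) <- pattern_labels()
  probs
}

#' Log likelihood of a triad model for site-pattern counts
#'
#' `sum(counts * log(p))` over patterns with positive counts. A pattern
#' with positive count but zero model probability is an explicit failure
#' state: the value is `-Inf` with attribute `failure = TRUE` (interior
#' optima with strictly positive rates never produce it).
#'
#' @param model a `triad_fit`.
#' @param counts site-pattern counts ([pattern_counts()]).
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(model, counts) {
  counts <- as_pattern_counts(counts)
  p <- triad_pattern_probs(model)
  sel <- counts > 0
  if (any(sel & p <= 0)) {
    return(structure(-Inf, failure = TRUE))
  }
  sum(counts[sel] * log(p[sel]))
}

#' Expected site-pattern counts under a fitted model
#'
#' @param model a `triad_fit`.
#' @param n alignment length; defaults to the length of the data the model
#'   was fitted to.
#' @return numeric vector of 64 expected counts.
#' @export
expected_pattern_counts <- function(model, n = NULL) {
  if (is.null(n)) n <- sum(model$counts)
  triad_pattern_probs(model) * n
}

#' @export
logLik.triad_fit <- function(object, ...) {
  structure(as.numeric(object$loglik), df = object$dof,
            nobs = sum(object$counts), class = "logLik")
}

#' @export
print.triad_fit <- function(x, ...) {
  fam <- paste0(x$family, if (x$clock) " (clock)" else "")
  cat("Triad fit:", fam, "\n")
  cat("  taxa: ((", x$tree$ingroup[1], ", ", x$tree$ingroup[2], "), ",
      x$tree$outgroup, ")\n", sep = "")
  cat("  log likelihood:", format(x$loglik, digits = 10),
      " df:", x$dof, "\n")
  cat("  root distribution:", paste(sprintf("%s=%.4f", NUC, x$root_dist),
                                    collapse = " "), "\n")
  cat("  edge ENS:", paste(sprintf("%s=%.4f", names(x$edge_ens), x$edge_ens),
                           collapse = " "), "\n")
  if (!is.null(x$gamma_shape)) {
    cat("  gamma shape:", format(x$gamma_shape, digits = 4), "\n")
  }
  invisible(x)
}
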