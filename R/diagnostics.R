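#' G statistic for site-pattern goodness of fit
#'
#' `G = 2 * sum(O * log(O / E))` over patterns with positive observed
#' count, comparing observed counts to model expectations against the
#' unrestricted multinomial alternative. Categories with `O == 0`
#' contribute nothing (the `x log x -> 0` convention).
#'
#' @param observed observed counts (any length, e.g. the 64 site
#'   patterns).
#' @param expected expected counts on the same categories, same total.
#' @return nonnegative scalar; `Inf` (failure state) if some category has
#'   positive observed count but zero expectation.
#' @export
g_statistic <- function(observed, expected) {
  observed <- as.numeric(observed)
  expected <- as.numeric(expected)
  stopifnot(length(observed) == length(expected), all(observed >= 0),
            all(expected >= 0))
  if (abs(sum(observed) - sum(expected)) > 1e-6 * max(sum(observed), 1)) {
    stop("observed and expected totals disagree")
  }
  sel <- observed > 0
  if (any(sel & expected == 0)) return(Inf)
  2 * sum(observed[sel] * log(observed[sel] / expected[sel]))
}

#' Parametric bootstrap P-value for the G statistic
#'
#' Simulates `n_reps` alignments of length `aln_length` under the null
#' hypothesis that the data were generated by the fitted model, refits the
#' model family to each (seeded through GTR, as in the original sequential
#' fit), and reports the proportion of replicate G statistics exceeding the
#' observed one. Replicates whose refit fails are excluded and counted.
#'
#' @param fit a `triad_fit` (carries the counts it was fitted to).
#' @param aln_length simulated alignment length; defaults to the fitted
#'   alignment's length.
#' @param n_reps number of bootstrap replicates (default 100, giving
#'   P-value resolution 0.01).
#' @param seed integer seed making the procedure reproducible.
#' @param restarts optimizer restarts used for the replicate refits.
#' @return an object of class `gof_test` with elements `p_value`,
#'   `g_observed`, `g_replicates`, `n_reps`, `n_excluded`.
#' @export
parametric_bootstrap_pvalue <- function(fit, aln_length = NULL, n_reps = 100,
                                        seed = NULL, restarts = 0) {
  stopifnot(inherits(fit, "triad_fit"), n_reps >= 1)
  if (is.null(aln_length)) aln_length <- sum(fit$counts)
  if (!is.null(seed)) set.seed(seed)
  g_obs <- g_statistic(fit$counts, expected_pattern_counts(fit, sum(fit$counts)))
  g_rep <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    aln <- simulate_alignment(fit, aln_length)
    cts <- pattern_counts(aln, fit$tree)
    refit <- tryCatch(
      .refit_family(cts, fit, restarts = restarts),
      error = function(e) NULL
    )
    if (!is.null(refit)) {
      g_rep[r] <- g_statistic(cts, expected_pattern_counts(refit, sum(cts)))
    }
  }
  ok <- !is.na(g_rep)
  structure(
    list(p_value = sum(g_rep[ok] > g_obs) / n_reps,
         g_observed = g_obs,
         g_replicates = g_rep,
         n_reps = n_reps,
         n_excluded = sum(!ok)),
    class = "gof_test"
  )
}

## Refit the family of `fit` to new counts, seeding through GTR as the
## sequential hierarchy prescribes.
.refit_family <- function(counts, fit, restarts = 0) {
  tree <- fit$tree
  gtr <- fit_gtr(counts, tree, clock = fit$clock, restarts = restarts)
  switch(fit$family,
    "GTR" = gtr,
    "GTR+G" = fit_gtr_gamma(counts, tree, seed_model = gtr,
                            clock = fit$clock, restarts = restarts),
    "General" = fit_general(counts, tree, seed_model = gtr,
                            clock = fit$clock, restarts = restarts),
    stop("unknown family: ", fit$family)
  )
}

#' Was the fit rejected by the goodness-of-fit screen?
#'
#' @param x a `gof_test`.
#' @param alpha rejection level (default 0.05).
#' @return logical.
#' @export
gof_rejected <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "gof_test"))
  x$p_value < alpha
}

#' @export
print.gof_test <- function(x, ...) {
  cat("Parametric bootstrap goodness of fit (G statistic)\n")
  cat("  G observed:", format(x$g_observed, digits = 6), "\n")
  cat("  replicates:", x$n_reps,
      if (x$n_excluded > 0) paste0("(", x$n_excluded, " excluded)") else "",
      "\n")
  cat("  P-value:", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Diagonal-largest-in-column check
#'
#' A transition matrix is Diagonal Largest in Column when every diagonal
#' entry strictly exceeds the other entries of its column. DLC is a
#' sufficient condition for identifiability of internal-node state
#' labeling; ties (within `tol`) fail, since the condition requires strict
#' inequality.
#'
#' @param P a 4x4 stochastic matrix.
#' @param tol tie tolerance (default 1e-12).
#' @return logical.
#' @export
dlc_check <- function(P, tol = 1e-12) {
  stopifnot(is.matrix(P), all(dim(P) == 4))
  for (j in 1:4) {
    others <- P[-j, j]
    if (any(P[j, j] <= others + tol)) return(FALSE)
  }
  TRUE
}

#' Conservative uniqueness check for the rate-matrix mapping
#'
#' A transition probability matrix can be consistent with zero, one,
#' several, or a continuum of rate matrices (non-uniqueness of the real
#' matrix logarithm). This check returns `TRUE` only when uniqueness is
#' guaranteed by a conservative spectral criterion: all eigenvalues of `P`
#' real, strictly positive, and distinct, in which case the principal
#' logarithm is the only real logarithm. Any other case — complex,
#' nonpositive, or (near-)repeated eigenvalues, including `det(P) <= 0` —
#' returns `FALSE` ("possibly nonunique; reject").
#'
#' @param P a 4x4 stochastic matrix.
#' @param tol relative tolerance for calling eigenvalues complex or
#'   repeated.
#' @return logical.
#' @export
unique_mapping_check <- function(P, tol = 1e-9) {
  stopifnot(is.matrix(P), all(dim(P) == 4))
  ev <- eigen(P, only.values = TRUE)$values
  scale <- max(Mod(ev), 1)
  if (any(abs(Im(ev)) > tol * scale)) return(FALSE)
  re <- sort(Re(ev))
  if (any(re <= tol * scale)) return(FALSE)
  if (any(diff(re) <= 1e-6 * scale)) return(FALSE)
  TRUE
}

#' Molecular-clock likelihood-ratio test
#'
#' Compares a clock-constrained fit (equal ingroup-edge ENS) against the
#' free fit of the same family on the same data. The statistic
#' `2 * (logLik_free - logLik_clock)` (floored at 0) is referred to a
#' chi-squared distribution with one degree of freedom.
#'
#' @param clock_fit,free_fit `triad_fit` objects of the same family fitted
#'   to the same counts, with `dof(free) - dof(clock) == 1`.
#' @return an `htest` with the statistic and P-value.
#' @export
clock_lrt <- function(clock_fit, free_fit) {
  stopifnot(inherits(clock_fit, "triad_fit"), inherits(free_fit, "triad_fit"))
  if (clock_fit$family != free_fit$family) {
    stop("clock and free fits must be of the same model family")
  }
  if (!clock_fit$clock || free_fit$clock) {
    stop("expected a clock-constrained fit and a free fit, in that order")
  }
  if (!identical(as.integer(clock_fit$counts), as.integer(free_fit$counts))) {
    stop("clock and free fits were not fitted to the same counts")
  }
  if (free_fit$dof - clock_fit$dof != 1L) {
    stop("degrees of freedom must differ by exactly one")
  }
  delta <- free_fit$loglik - clock_fit$loglik
  if (delta < -1e-6) {
    stop("free fit has lower log likelihood than the clock fit: ",
         "optimizer failure")
  }
  stat <- max(2 * delta, 0)
  structure(
    list(statistic = c(`2 log LR` = stat),
         parameter = c(df = 1),
         p.value = pchisq(stat, df = 1, lower.tail = FALSE),
         method = paste("Molecular clock likelihood-ratio test,",
                        clock_fit$family, "family"),
         data.name = paste(sum(free_fit$counts), "sites")),
    class = "htest"
  )
}

#' Ratio of two fitted edge lengths
#'
#' Ratio of the per-edge ENS values under the fit's own distance; used to
#' quantify lineage-specific rate differences (exactly 1 for a clock fit's
#' ingroup edges).
#'
#' @param fit a `triad_fit`.
#' @param edge_a,edge_b leaf names identifying the two edges.
#' @return positive scalar `ENS(edge_a) / ENS(edge_b)`.
#' @export
edge_length_ratio <- function(fit, edge_a, edge_b) {
  stopifnot(inherits(fit, "triad_fit"))
  for (e in c(edge_a, edge_b)) {
    if (!e %in% names(fit$edge_ens)) stop("unknown edge: ", e)
  }
  if (fit$edge_ens[[edge_b]] <= 0) stop("zero-length denominator edge")
  fit$edge_ens[[edge_a]] / fit$edge_ens[[edge_b]]
}

#' Identifiability diagnostics for a fitted triad model
#'
#' Applies [dlc_check()] and [unique_mapping_check()] to every fitted
#' edge's transition matrix.
#'
#' @param fit a `triad_fit`.
#' @return list with logical vectors `dlc` and `unique_mapping`, one entry
#'   per edge, and overall flags `dlc_all`, `unique_all`.
#' @export
identifiability_checks <- function(fit) {
  stopifnot(inherits(fit, "triad_fit"))
  P <- lapply(fit$edges, transition_matrix)
  dlc <- vapply(P, dlc_check, TRUE)
  uniq <- vapply(P, unique_mapping_check, TRUE)
  list(dlc = dlc, unique_mapping = uniq,
       dlc_all = all(dlc), unique_all = all(uniq))
}
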