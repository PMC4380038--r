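## Maximum-likelihood fitting of the triad model hierarchy.
##
## Models are fitted sequentially in order of increasing generality
## (GTR, then GTR+Gamma and the general nonstationary model), each seeded
## from the previous fit, so richer models are guaranteed at least the log
## likelihood of the models they nest. All positive parameters are
## optimised on the log scale with bounded quasi-Newton (L-BFGS-B) and a
## few randomly perturbed restarts.

.softmax4 <- function(b) {
  z <- c(0, b)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

.freq_logits <- function(p) log(p[2:4] / p[1])

.RATE_LOG_BOUNDS <- c(log(1e-6), log(200)) # calibrated relative rates
.EDGE_LOG_BOUNDS <- c(log(1e-8), log(50))  # edge durations / Qt entries
.SHAPE_LOG_BOUNDS <- c(log(0.01), log(200))
.LOGIT_BOUNDS <- c(-30, 30)
N_GAMMA_BINS <- 4L

as_pattern_counts <- function(x, tree = NULL) {
  if (inherits(x, "pattern_counts")) return(x)
  if (inherits(x, "triad_alignment") || (is.character(x) && length(x) == 3)) {
    return(pattern_counts(x, tree))
  }
  if (is.numeric(x) && length(x) == 64) {
    counts <- as.integer(round(x))
    names(counts) <- pattern_labels()
    return(structure(counts, class = "pattern_counts",
                     taxa = if (is.null(tree)) NULL else tree$leaves))
  }
  stop("cannot interpret 'counts' as triad site-pattern counts")
}

## Multistart bounded quasi-Newton: a fully converged run from the seeded
## start, plus `restarts` randomly perturbed short probes at loose
## tolerance; a probe that beats the seeded optimum is polished to full
## tolerance.
.fit_optim <- function(par0, fn, lower, upper, restarts = 3,
                       control = list()) {
  ctrl <- modifyList(list(maxit = 1000, factr = 1e7), control)
  probe_ctrl <- modifyList(ctrl, list(maxit = 80, factr = 1e9))
  par0 <- pmin(pmax(par0, lower), upper)
  run1 <- function(p, cl) {
    tryCatch(
      optim(p, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = cl),
      error = function(e) list(par = p, value = fn(p), convergence = 52,
                               message = conditionMessage(e))
    )
  }
  best <- run1(par0, ctrl)
  for (r in seq_len(restarts)) {
    p <- pmin(pmax(par0 + stats::rnorm(length(par0), 0, 0.5), lower), upper)
    cand <- run1(p, probe_ctrl)
    if (cand$value < best$value) {
      cand <- run1(cand$par, ctrl)
      if (cand$value < best$value) best <- cand
    }
  }
  if (!is.finite(best$value) || best$value >= 1e9) {
    stop("optimizer failed to find a finite-likelihood solution ",
         "(convergence code ", best$convergence, ")")
  }
  best
}

## Crude starting edge lengths from pairwise mismatch proportions with a
## Jukes-Cantor correction, decomposed onto the star.
.start_times <- function(counts) {
  a <- (seq_len(64) - 1L) %/% 16L
  b <- ((seq_len(64) - 1L) %/% 4L) %% 4L
  cc <- (seq_len(64) - 1L) %% 4L
  n <- sum(counts)
  pdist <- function(x, y) sum(counts[x != y]) / max(n, 1)
  jc <- function(p) {
    p <- min(p, 0.70)
    max(-3 / 4 * log(1 - 4 * p / 3), 1e-4)
  }
  dab <- jc(pdist(a, b))
  dac <- jc(pdist(a, cc))
  dbc <- jc(pdist(b, cc))
  t <- c((dab + dac - dbc) / 2, (dab + dbc - dac) / 2, (dac + dbc - dab) / 2)
  pmin(pmax(t, 5e-3), 20)
}

.empirical_freqs <- function(counts) {
  a <- (seq_len(64) - 1L) %/% 16L + 1L
  b <- ((seq_len(64) - 1L) %/% 4L) %% 4L + 1L
  cc <- (seq_len(64) - 1L) %% 4L + 1L
  f <- numeric(4)
  for (i in 1:4) {
    f[i] <- sum(counts[a == i]) + sum(counts[b == i]) + sum(counts[cc == i])
  }
  f <- f + 0.5 # regularize away from the boundary
  f / sum(f)
}

.gtr_par_layout <- function(clock, gamma) {
  n <- 8L + (if (clock) 2L else 3L) + (if (gamma) 1L else 0L)
  lower <- c(rep(.RATE_LOG_BOUNDS[1], 5), rep(.LOGIT_BOUNDS[1], 3),
             rep(.EDGE_LOG_BOUNDS[1], if (clock) 2 else 3),
             if (gamma) .SHAPE_LOG_BOUNDS[1])
  upper <- c(rep(.RATE_LOG_BOUNDS[2], 5), rep(.LOGIT_BOUNDS[2], 3),
             rep(.EDGE_LOG_BOUNDS[2], if (clock) 2 else 3),
             if (gamma) .SHAPE_LOG_BOUNDS[2])
  stopifnot(length(lower) == n)
  list(n = n, lower = lower, upper = upper)
}

.build_gtr_fit <- function(par, tree, counts, clock, gamma, opt = NULL) {
  rates <- exp(par[1:5])
  pi <- .softmax4(par[6:8])
  names(pi) <- NUC
  Q <- rate_matrix_gtr(c(rates, 1), pi, calibrated = TRUE)
  if (clock) {
    t_edges <- c(exp(par[9]), exp(par[9]), exp(par[10]))
    shape_par <- if (gamma) exp(par[11]) else NULL
  } else {
    t_edges <- exp(par[9:11])
    shape_par <- if (gamma) exp(par[12]) else NULL
  }
  names(t_edges) <- tree$leaves
  edges <- lapply(t_edges, function(t) edge_process(Q, t))
  fit <- structure(
    list(family = if (gamma) "GTR+G" else "GTR",
         clock = clock,
         tree = tree,
         root_dist = pi,
         Q = Q,
         rates = setNames(c(rates, 1), c("AC", "AG", "AT", "CG", "CT", "GT")),
         edges = edges,
         edge_ens = t_edges, # calibrated Q: ENS per edge equals its duration
         gamma_shape = shape_par,
         n_rate_bins = if (gamma) N_GAMMA_BINS else 1L,
         par = par,
         counts = counts,
         dof = (if (gamma) 12L else 11L) - (if (clock) 1L else 0L),
         optim = opt),
    class = "triad_fit"
  )
  fit$loglik <- log_likelihood(fit, counts)
  fit
}

#' Fit the GTR triad model by maximum likelihood
#'
#' Stationary time-reversible model with one calibrated rate matrix shared
#' by all three edges and the root distribution equal to its stationary
#' distribution. Free parameters: 5 relative exchangeabilities (GT fixed
#' at 1), 3 base frequencies, and 3 edge lengths (2 under the clock, where
#' the ingroup edges share one length).
#'
#' @param counts site-pattern counts from [pattern_counts()] (or a
#'   [triad_alignment()]).
#' @param tree a [triad_tree()].
#' @param clock constrain the two ingroup edges to equal length.
#' @param restarts number of randomly perturbed optimizer restarts after
#'   the seeded start.
#' @param control passed to [stats::optim()] (`L-BFGS-B`).
#' @return an object of class `triad_fit`.
#' @export
fit_gtr <- function(counts, tree, clock = FALSE, restarts = 3,
                    control = list()) {
  counts <- as_pattern_counts(counts, tree)
  if (sum(counts) == 0) stop("cannot fit a model to zero sites")
  lay <- .gtr_par_layout(clock, gamma = FALSE)
  f <- .empirical_freqs(counts)
  t0 <- .start_times(counts)
  par0 <- c(rep(0, 5), .freq_logits(f),
            if (clock) log(c(mean(t0[1:2]), t0[3])) else log(t0))
  cvec <- as.numeric(counts)
  fn <- function(p) .gtr_negll_cpp(p, cvec, clock, FALSE, N_GAMMA_BINS)
  opt <- .fit_optim(par0, fn, lay$lower, lay$upper, restarts, control)
  .build_gtr_fit(opt$par, tree, counts, clock, gamma = FALSE, opt = opt)
}

#' Fit the GTR+Gamma triad model
#'
#' As [fit_gtr()] with gamma-distributed rate heterogeneity across sites in
#' four equal-probability bins (represented by bin means), adding one shape
#' parameter shared across the tree. Initial parameter estimates are taken
#' from the seed GTR fit.
#'
#' @inheritParams fit_gtr
#' @param seed_model a `triad_fit` of family `"GTR"` fitted to the same
#'   counts; fitted internally when `NULL`.
#' @param shape_init starting value for the gamma shape.
#' @return an object of class `triad_fit`.
#' @export
fit_gtr_gamma <- function(counts, tree, seed_model = NULL, clock = FALSE,
                          restarts = 3, control = list(), shape_init = 2) {
  counts <- as_pattern_counts(counts, tree)
  if (is.null(seed_model)) {
    seed_model <- fit_gtr(counts, tree, clock = clock, restarts = restarts,
                          control = control)
  }
  stopifnot(inherits(seed_model, "triad_fit"),
            seed_model$family %in% c("GTR", "GTR+G"))
  lay <- .gtr_par_layout(clock, gamma = TRUE)
  seed_par <- seed_model$par
  if (seed_model$clock != clock) {
    t_seed <- seed_model$edge_ens
    base <- seed_par[1:8]
    seed_par <- c(base,
                  if (clock) log(c(mean(t_seed[1:2]), t_seed[3]))
                  else log(pmax(t_seed, 1e-8)))
    if (seed_model$family == "GTR+G") {
      seed_par <- c(seed_par, log(seed_model$gamma_shape))
    }
  }
  par0 <- if (seed_model$family == "GTR+G") seed_par
          else c(seed_par, log(shape_init))
  cvec <- as.numeric(counts)
  fn <- function(p) .gtr_negll_cpp(p, cvec, clock, TRUE, N_GAMMA_BINS)
  opt <- .fit_optim(par0, fn, lay$lower, lay$upper, restarts, control)
  .build_gtr_fit(opt$par, tree, counts, clock, gamma = TRUE, opt = opt)
}

.general_par_from_fit <- function(fit) {
  root <- fit$root_dist
  b <- .freq_logits(pmax(root, 1e-8))
  edge_par <- unlist(lapply(fit$edges, function(e) {
    M <- e$Q * e$t
    off <- as.vector(t(M))[as.vector(t(row(M) != col(M)))] # row-major

    log(pmax(off, 1e-6))
  }), use.names = FALSE)
  c(b, edge_par)
}

.build_general_fit <- function(par, tree, counts, clock, opt = NULL) {
  root <- .softmax4(par[1:3])
  names(root) <- NUC
  M <- list()
  for (e in 1:3) {
    off <- exp(par[3 + (e - 1) * 12 + 1:12])
    M[[e]] <- make_rate_matrix(off)
  }
  if (clock) {
    target <- .ens_aug_cpp(root, M[[1]], 1)
    s <- .ens_solve_scale_cpp(root, M[[2]], target)
    M[[2]] <- M[[2]] * s
  }
  names(M) <- tree$leaves
  edges <- lapply(M, function(m) edge_process(m, 1))
  edge_ens <- vapply(M, function(m) .ens_aug_cpp(root, m, 1), 0)
  fit <- structure(
    list(family = "General",
         clock = clock,
         tree = tree,
         root_dist = root,
         edges = edges,
         edge_ens = edge_ens,
         gamma_shape = NULL,
         n_rate_bins = 1L,
         par = par,
         counts = counts,
         dof = if (clock) 38L else 39L,
         optim = opt),
    class = "triad_fit"
  )
  fit$loglik <- log_likelihood(fit, counts)
  fit
}

#' Fit the general nonstationary triad model
#'
#' Places no constraint on the rate matrix of each edge or on the root
#' distribution, so the process may be nonstationary. The identifiable
#' per-edge quantity is the product `Q * t`; its 12 off-diagonal entries
#' are optimised directly for each edge, together with 3 free root
#' probabilities (39 parameters; 38 under the clock). Under the clock the
#' duration of the second ingroup edge is solved by monotone scalar
#' root-finding so the two ingroup edges have equal ENS.
#'
#' @inheritParams fit_gtr
#' @param seed_model a GTR-family `triad_fit` on the same counts used for
#'   initialization (fitted internally when `NULL`); seeding guarantees
#'   `logLik(general) >= logLik(seed)`.
#' @return an object of class `triad_fit`.
#' @export
fit_general <- function(counts, tree, seed_model = NULL, clock = FALSE,
                        restarts = 3, control = list()) {
  counts <- as_pattern_counts(counts, tree)
  if (is.null(seed_model)) {
    seed_model <- fit_gtr(counts, tree, clock = clock, restarts = restarts,
                          control = control)
  }
  stopifnot(inherits(seed_model, "triad_fit"))
  par0 <- .general_par_from_fit(seed_model)
  n <- 39L
  lower <- c(rep(.LOGIT_BOUNDS[1], 3), rep(.EDGE_LOG_BOUNDS[1], 36))
  upper <- c(rep(.LOGIT_BOUNDS[2], 3), rep(.EDGE_LOG_BOUNDS[2], 36))
  cvec <- as.numeric(counts)
  fn <- function(p) .general_negll_cpp(p, cvec, clock)
  opt <- .fit_optim(par0, fn, lower, upper, restarts, control)
  .build_general_fit(opt$par, tree, counts, clock, opt = opt)
}

#' Sequential nested fitting of the triad model hierarchy
#'
#' Fits models in order of increasing generality — GTR, then GTR+Gamma and
#' the general nonstationary model, each seeded from the GTR fit — so that
#' log likelihood is nondecreasing along each nested chain. With
#' `clock_suite = TRUE` the clock-constrained variant of every family is
#' fitted as well (free fits are guaranteed at least the clock fit's log
#' likelihood), ready for [clock_lrt()].
#'
#' @param aln a [triad_alignment()] or precomputed [pattern_counts()].
#' @param tree a [triad_tree()].
#' @param clock_suite also fit clock-constrained variants.
#' @param families subset of `c("GTR", "GTR+G", "General")`.
#' @inheritParams fit_gtr
#' @return named list of `triad_fit` objects (`gtr`, `gtr_gamma`,
#'   `general`, plus `*_clock` when requested).
#' @export
sequential_fit <- function(aln, tree, clock_suite = FALSE,
                           families = c("GTR", "GTR+G", "General"),
                           restarts = 3, control = list()) {
  counts <- as_pattern_counts(aln, tree)
  fits <- list()
  fits$gtr <- fit_gtr(counts, tree, restarts = restarts, control = control)
  if ("GTR+G" %in% families) {
    fits$gtr_gamma <- fit_gtr_gamma(counts, tree, seed_model = fits$gtr,
                                    restarts = restarts, control = control)
  }
  if ("General" %in% families) {
    fits$general <- fit_general(counts, tree, seed_model = fits$gtr,
                                restarts = restarts, control = control)
  }
  if (clock_suite) {
    fits$gtr_clock <- fit_gtr(counts, tree, clock = TRUE,
                              restarts = restarts, control = control)
    fits$gtr <- .ensure_free_dominates(fits$gtr, fits$gtr_clock, counts, tree,
                                       control)
    if ("GTR+G" %in% families) {
      fits$gtr_gamma_clock <- fit_gtr_gamma(counts, tree,
                                            seed_model = fits$gtr_clock,
                                            clock = TRUE, restarts = restarts,
                                            control = control)
      fits$gtr_gamma <- .ensure_free_dominates(fits$gtr_gamma,
                                               fits$gtr_gamma_clock,
                                               counts, tree, control)
    }
    if ("General" %in% families) {
      fits$general_clock <- fit_general(counts, tree,
                                        seed_model = fits$gtr_clock,
                                        clock = TRUE, restarts = restarts,
                                        control = control)
      fits$general <- .ensure_free_dominates(fits$general,
                                             fits$general_clock,
                                             counts, tree, control)
    }
  }
  fits
}

## Guarantee logLik(free) >= logLik(clock) by re-optimising the free model
## from the clock solution when the independent free fit came out lower
## (the clock solution is a feasible free-model point).
.ensure_free_dominates <- function(free_fit, clock_fit, counts, tree,
                                   control) {
  if (free_fit$loglik >= clock_fit$loglik - 1e-9) return(free_fit)
  cvec <- as.numeric(counts)
  if (free_fit$family == "General") {
    par0 <- .general_par_from_fit(clock_fit)
    lower <- c(rep(.LOGIT_BOUNDS[1], 3), rep(.EDGE_LOG_BOUNDS[1], 36))
    upper <- c(rep(.LOGIT_BOUNDS[2], 3), rep(.EDGE_LOG_BOUNDS[2], 36))
    fn <- function(p) .general_negll_cpp(p, cvec, FALSE)
    opt <- .fit_optim(par0, fn, lower, upper, restarts = 0, control = control)
    cand <- .build_general_fit(opt$par, tree, counts, FALSE, opt = opt)
  } else {
    gamma <- free_fit$family == "GTR+G"
    lay <- .gtr_par_layout(FALSE, gamma)
    cp <- clock_fit$par
    t_seed <- clock_fit$edge_ens
    par0 <- c(cp[1:8], log(pmax(t_seed, 1e-8)),
              if (gamma) log(clock_fit$gamma_shape))
    fn <- function(p) .gtr_negll_cpp(p, cvec, FALSE, gamma, N_GAMMA_BINS)
    opt <- .fit_optim(par0, fn, lay$lower, lay$upper, restarts = 0,
                      control = control)
    cand <- .build_gtr_fit(opt$par, tree, counts, FALSE, gamma, opt = opt)
  }
  if (cand$loglik > free_fit$loglik) cand else free_fit
}
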