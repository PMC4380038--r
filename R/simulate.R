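#' Simulate a triad alignment under a fitted or constructed model
#'
#' Sites are independent and identically distributed: for each site a root
#' state is drawn from the root distribution (and a rate bin for gamma
#' families), then evolved independently along each of the three edges by
#' sampling from the rows of the edge's transition matrix. End states are
#' sampled directly from transition probabilities; no waiting-time
#' simulation is needed since only end states enter an alignment.
#'
#' Draws use one stream for the root (and rate bins) and one per edge, all
#' derived from the master seed, so lengthening the alignment or reordering
#' edges does not perturb unrelated draws.
#'
#' @param model a `triad_fit` or a model parameter list with elements
#'   `root_dist`, `edges` (list of [edge_process()]), `tree`, and
#'   optionally `gamma_shape` / `n_rate_bins`.
#' @param n_sites number of alignment columns (>= 1).
#' @param seed optional integer; when supplied the result is reproducible.
#' @return a [triad_alignment()] with the model's leaf names.
#' @export
simulate_alignment <- function(model, n_sites, seed = NULL) {
  stopifnot(n_sites >= 1)
  n_sites <- as.integer(n_sites)
  if (!is.null(seed)) set.seed(as.integer(seed))
  streams <- floor(runif(4) * 2^31) # root stream + one per edge
  root <- model$root_dist
  edges <- model$edges
  leaves <- model$tree$leaves

  set.seed(streams[1])
  root_states <- sample.int(4, n_sites, replace = TRUE, prob = root)
  rates <- 1
  bin <- rep(1L, n_sites)
  if (!is.null(model$gamma_shape)) {
    rates <- .gamma_bin_rates_cpp(model$gamma_shape, model$n_rate_bins)
    bin <- sample.int(length(rates), n_sites, replace = TRUE)
  }

  seqs <- character(3)
  for (e in 1:3) {
    set.seed(streams[e + 1])
    P_by_rate <- lapply(rates, function(r) {
      .expm_cpp(edges[[e]]$Q * (edges[[e]]$t * r))
    })
    child <- integer(n_sites)
    for (b in seq_along(rates)) {
      for (s in 1:4) {
        sel <- which(bin == b & root_states == s)
        if (length(sel)) {
          child[sel] <- sample.int(4, length(sel), replace = TRUE,
                                   prob = P_by_rate[[b]][s, ])
        }
      }
    }
    seqs[e] <- paste(NUC[child], collapse = "")
  }
  names(seqs) <- leaves
  triad_alignment(seqs)
}

#' Random general nonstationary triad model
#'
#' Generates a model parameter set of the general-model shape for recovery
#' tests and synthetic corpora: a Dirichlet root distribution and, per
#' edge, a generator built from a random edge-specific target composition
#' (so the process is naturally nonstationary), scaled so the edge's ENS
#' falls in `ens_range`. Models are rejection-sampled until the JSD
#' between the root distribution and every leaf marginal reaches
#' `jsd_floor` (and stays below `jsd_max` when finite).
#'
#' @param seed integer seed.
#' @param ens_range interval for per-edge ENS (substitutions per site).
#' @param jsd_floor minimum JSD between root distribution and each leaf
#'   marginal (0 disables the constraint).
#' @param jsd_max optional upper bound on the same JSDs.
#' @param max_attempts rejection-sampling budget before erroring.
#' @param leaves leaf names (ingroup pair first).
#' @return a model list usable with [simulate_alignment()],
#'   [triad_pattern_probs()] and [log_likelihood()]; element `edge_ens`
#'   holds the realized per-edge ENS and `leaf_jsd` the root-vs-leaf JSDs.
#' @export
random_general_model <- function(seed, ens_range = c(0.05, 0.5),
                                 jsd_floor = 0, jsd_max = Inf,
                                 max_attempts = 500,
                                 leaves = c("a", "b", "c")) {
  stopifnot(length(ens_range) == 2, ens_range[1] > 0,
            ens_range[2] >= ens_range[1])
  set.seed(as.integer(seed))
  rdirichlet <- function(alpha) {
    g <- rgamma(length(alpha), alpha)
    g / sum(g)
  }
  root <- rdirichlet(rep(5, 4))
  names(root) <- NUC
  edges <- list()
  leaf_jsd <- numeric(3)
  edge_ens <- numeric(3)
  for (e in 1:3) {
    accepted <- FALSE
    for (attempt in seq_len(max_attempts)) {
      # edge-specific attractor composition; concentrated draws make strong
      # departures from the root composition reachable
      target_pi <- rdirichlet(rep(0.8, 4))
      target_pi <- pmax(target_pi, 1e-3)
      target_pi <- target_pi / sum(target_pi)
      off <- numeric(12)
      idx <- 1L
      for (i in 1:4) {
        for (j in 1:4) {
          if (i != j) {
            off[idx] <- target_pi[j] * exp(stats::rnorm(1, 0, 0.5))
            idx <- idx + 1L
          }
        }
      }
      M0 <- make_rate_matrix(off)
      tau <- runif(1, ens_range[1], ens_range[2])
      s <- .ens_solve_scale_cpp(root, M0, tau)
      M <- M0 * s
      leaf_marginal <- as.vector(root %*% .expm_cpp(M))
      j <- jsd(list(root, leaf_marginal))
      if (j >= jsd_floor && j <= jsd_max) {
        edges[[e]] <- edge_process(M, 1)
        edge_ens[e] <- .ens_aug_cpp(root, M, 1)
        leaf_jsd[e] <- j
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      stop("could not generate an edge satisfying the JSD constraints in ",
           max_attempts, " attempts")
    }
  }
  names(edges) <- leaves
  names(edge_ens) <- leaves
  names(leaf_jsd) <- leaves
  structure(
    list(family = "General", clock = FALSE,
         tree = triad_tree(leaves[1:2], leaves[3]),
         root_dist = root, edges = edges, edge_ens = edge_ens,
         leaf_jsd = leaf_jsd, gamma_shape = NULL, n_rate_bins = 1L,
         dof = 39L, seed = seed),
    class = "triad_model"
  )
}

#' Random calibrated GTR model
#'
#' Convenience generator for simulation studies: random exchangeabilities
#' and Dirichlet frequencies, calibrated rate matrix, and edge lengths
#' drawn from `ens_range`.
#'
#' @inheritParams random_general_model
#' @param clock force the two ingroup edges to equal length.
#' @return a model list of the GTR shape usable with
#'   [simulate_alignment()].
#' @export
random_gtr_model <- function(seed, ens_range = c(0.05, 0.5), clock = FALSE,
                             leaves = c("a", "b", "c")) {
  set.seed(as.integer(seed))
  rates <- c(exp(stats::rnorm(5, 0, 0.5)), 1)
  g <- rgamma(4, 8)
  pi <- g / sum(g)
  names(pi) <- NUC
  Q <- rate_matrix_gtr(rates, pi, calibrated = TRUE)
  t_edges <- runif(3, ens_range[1], ens_range[2])
  if (clock) t_edges[2] <- t_edges[1]
  names(t_edges) <- leaves
  structure(
    list(family = "GTR", clock = clock,
         tree = triad_tree(leaves[1:2], leaves[3]),
         root_dist = pi, Q = Q,
         rates = setNames(rates, c("AC", "AG", "AT", "CG", "CT", "GT")),
         edges = lapply(t_edges, function(t) edge_process(Q, t)),
         edge_ens = t_edges, gamma_shape = NULL, n_rate_bins = 1L,
         dof = 11L, seed = seed),
    class = "triad_model"
  )
}
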