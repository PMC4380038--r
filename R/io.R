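#' Read a triad alignment from FASTA
#'
#' Reads three named records, removes every alignment column containing a
#' gap or IUPAC ambiguity character (anything other than A, C, G, T), and
#' enforces a minimum post-filter length.
#'
#' @param path FASTA file with at least three records.
#' @param leaf_names taxa to extract (default: the first three records).
#' @param min_length minimum number of unambiguous, ungapped columns
#'   (default 500); set to 0 or `NULL` to disable.
#' @return a [triad_alignment()] with attribute `removed_columns`.
#' @export
read_triad_fasta <- function(path, leaf_names = NULL, min_length = 500) {
  recs <- Biostrings::readBStringSet(path)
  nms <- sub("\\s.*$", "", names(recs))
  names(recs) <- nms
  if (is.null(leaf_names)) leaf_names <- nms[seq_len(min(3, length(nms)))]
  missing <- setdiff(leaf_names, nms)
  if (length(missing)) {
    stop("FASTA is missing taxa: ", paste(missing, collapse = ", "))
  }
  seqs <- toupper(as.character(recs[leaf_names]))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("malformed alignment: unequal sequence lengths (",
         paste(lens, collapse = ", "), ")")
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  keep <- colSums(matrix(mat %in% NUC, nrow = 3)) == 3L
  removed <- sum(!keep)
  filtered <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  names(filtered) <- leaf_names
  if (!is.null(min_length) && min_length > 0 && sum(keep) < min_length) {
    stop("alignment rejected: only ", sum(keep),
         " unambiguous, ungapped sites (minimum ", min_length, ")")
  }
  aln <- triad_alignment(filtered)
  attr(aln, "removed_columns") <- removed
  aln
}

#' Write a triad alignment to FASTA
#'
#' @param aln a [triad_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_triad_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "triad_alignment"))
  x <- Biostrings::DNAStringSet(unclass(aln)[names(aln)])
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write model parameters as a JSON sidecar
#'
#' Serializes the generating parameters of a model (root distribution,
#' per-edge generator-times-duration matrices, gamma shape, realized edge
#' ENS) so simulated data can be paired with its truth for recovery tests.
#'
#' @param model a `triad_fit` or `triad_model`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    family = model$family,
    clock = isTRUE(model$clock),
    leaves = model$tree$leaves,
    ingroup = model$tree$ingroup,
    outgroup = model$tree$outgroup,
    root_dist = as.numeric(model$root_dist),
    edges = lapply(model$edges, function(e) {
      list(Qt = unname(e$Q * e$t))
    }),
    edge_ens = as.numeric(model$edge_ens),
    gamma_shape = model$gamma_shape
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model parameter sidecar written by [write_model_json()]
#'
#' @param path JSON file.
#' @return a `triad_model` list usable with [simulate_alignment()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(obj$gamma_shape) == 0) obj$gamma_shape <- NULL
  leaves <- obj$leaves
  edges <- lapply(obj$edges, function(e) {
    M <- matrix(unlist(e$Qt), 4, 4, dimnames = list(NUC, NUC))
    edge_process(M, 1)
  })
  names(edges) <- leaves
  root <- setNames(as.numeric(obj$root_dist), NUC)
  structure(
    list(family = obj$family, clock = isTRUE(obj$clock),
         tree = triad_tree(obj$ingroup, obj$outgroup),
         root_dist = root, edges = edges,
         edge_ens = setNames(as.numeric(obj$edge_ens), leaves),
         gamma_shape = obj$gamma_shape,
         n_rate_bins = if (is.null(obj$gamma_shape)) 1L else N_GAMMA_BINS,
         dof = NA_integer_),
    class = "triad_model"
  )
}

#' Run the full triad analysis pipeline over a batch of alignments
#'
#' For each alignment: sequential model fits, identifiability screens,
#' goodness of fit (optional parametric bootstrap), distances (per-edge
#' and ingroup-pair ENS under each family, paralinear, LogDet), sequence
#' compositions and JSD, and (optionally) the molecular-clock test.
#' Per-alignment failures are recorded in the `error` column and never
#' abort the batch.
#'
#' @param alignments list of [triad_alignment()] objects, or character
#'   paths to FASTA files.
#' @param tree a [triad_tree()] declaring the ingroup pair.
#' @param families model families to fit.
#' @param clock_test fit clock variants and run [clock_lrt()] per family.
#' @param bootstrap_reps parametric-bootstrap replicates for the
#'   goodness-of-fit P-value of the general model (0 disables the
#'   bootstrap).
#' @param seed master seed; per-alignment seeds are derived from it.
#' @param restarts optimizer restarts per fit.
#' @param min_length minimum alignment length for FASTA inputs.
#' @param out optional path; when given, the report is also written as
#'   tab-separated values.
#' @return a tibble with one row per alignment.
#' @export
run_pipeline <- function(alignments, tree,
                         families = c("GTR", "GTR+G", "General"),
                         clock_test = FALSE, bootstrap_reps = 0,
                         seed = 1, restarts = 3, min_length = 500,
                         out = NULL) {
  stopifnot(inherits(tree, "triad_tree"))
  if (!is.list(alignments)) alignments <- as.list(alignments)
  rows <- vector("list", length(alignments))
  ids <- names(alignments)
  if (is.null(ids)) ids <- paste0("aln", seq_along(alignments))
  for (i in seq_along(alignments)) {
    id <- ids[i]
    rows[[i]] <- tryCatch(
      .pipeline_row(alignments[[i]], id, tree, families, clock_test,
                    bootstrap_reps, seed = seed + i, restarts = restarts,
                    min_length = min_length),
      error = function(e) {
        tibble::tibble(id = id, error = conditionMessage(e))
      }
    )
  }
  report <- do.call(rbind, lapply(rows, function(r) {
    cols <- unique(unlist(lapply(rows, names)))
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA
    r[cols]
  }))
  if (!is.null(out)) {
    write.table(report, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

.pipeline_row <- function(aln, id, tree, families, clock_test,
                          bootstrap_reps, seed, restarts, min_length) {
  if (is.character(aln) && length(aln) == 1 && file.exists(aln)) {
    aln <- read_triad_fasta(aln, leaf_names = NULL, min_length = min_length)
  }
  if (!inherits(aln, "triad_alignment")) aln <- triad_alignment(aln)
  set.seed(seed)
  fits <- sequential_fit(aln, tree, clock_suite = clock_test,
                         families = families, restarts = restarts)
  n <- nchar(aln[[1]])
  ing <- tree$ingroup
  comp <- lapply(unclass(aln)[tree$leaves], base_composition)
  row <- tibble::tibble(
    id = id, n_sites = n,
    jsd_seqs = jsd(comp),
    gc_1 = gc_content(aln[[tree$leaves[1]]]),
    gc_2 = gc_content(aln[[tree$leaves[2]]]),
    gc_3 = gc_content(aln[[tree$leaves[3]]]),
    d_para = tryCatch(
      paralinear_distance(empirical_joint(aln[[ing[1]]], aln[[ing[2]]])),
      error = function(e) NA_real_),
    d_logdet = tryCatch(
      logdet_distance(empirical_joint(aln[[ing[1]]], aln[[ing[2]]])),
      error = function(e) NA_real_),
    error = NA_character_
  )
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    row[[paste0("lnL_", nm)]] <- fit$loglik
    row[[paste0("dof_", nm)]] <- fit$dof
    row[[paste0("aic_", nm)]] <- as.numeric(stats::AIC(logLik(fit)))
    row[[paste0("d_ingroup_", nm)]] <-
      ens_path_distance(fit, ing[1], ing[2])
    for (lv in tree$leaves) {
      row[[paste0("ens_", lv, "_", nm)]] <- unname(fit$edge_ens[[lv]])
    }
    chk <- identifiability_checks(fit)
    row[[paste0("dlc_", nm)]] <- chk$dlc_all
    row[[paste0("unique_", nm)]] <- chk$unique_all
    row[[paste0("g_stat_", nm)]] <-
      g_statistic(fit$counts, expected_pattern_counts(fit))
  }
  if (bootstrap_reps > 0 && "General" %in% families) {
    gof <- parametric_bootstrap_pvalue(fits$general, n_reps = bootstrap_reps,
                                       seed = seed, restarts = 0)
    row$gof_p_general <- gof$p_value
    row$gof_failed_reps <- gof$n_excluded
    # screening flag: reject the fit when P < 0.05 or an identifiability
    # screen fails; downstream summaries filter on it
    row$gof_reject_general <- gof_rejected(gof)
    row$screened_out <- gof_rejected(gof) ||
      !row[[paste0("dlc_", "general")]] || !row[[paste0("unique_", "general")]]
  }
  if (clock_test) {
    if ("General" %in% families) {
      row$clock_p_general <- clock_lrt(fits$general_clock,
                                       fits$general)$p.value
      row$rate_ratio_general <- edge_length_ratio(fits$general,
                                                  ing[1], ing[2])
    }
    row$clock_p_gtr <- clock_lrt(fits$gtr_clock, fits$gtr)$p.value
    row$rate_ratio_gtr <- edge_length_ratio(fits$gtr, ing[1], ing[2])
    if ("GTR+G" %in% families) {
      row$clock_p_gtr_gamma <- clock_lrt(fits$gtr_gamma_clock,
                                         fits$gtr_gamma)$p.value
    }
  }
  row
}
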