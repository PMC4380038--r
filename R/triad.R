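#' Rooted three-taxon tree with a declared ingroup pair
#'
#' The fitted process is rooted at the internal node joining the ingroup;
#' the two edges emanating from the original root are merged into a single
#' outgroup edge, since their parameters are not separately identifiable.
#' The fitted topology therefore has exactly three edges: one to each
#' ingroup taxon and one merged edge to the outgroup.
#'
#' @param ingroup character vector of the two ingroup leaf names.
#' @param outgroup single outgroup leaf name.
#' @return an object of class `triad_tree` with elements `ingroup`,
#'   `outgroup` and `leaves` (ingroup first).
#' @export
triad_tree <- function(ingroup, outgroup) {
  ingroup <- as.character(ingroup)
  outgroup <- as.character(outgroup)
  if (length(ingroup) != 2 || length(outgroup) != 1) {
    stop("a triad needs exactly two ingroup taxa and one outgroup taxon")
  }
  if (outgroup %in% ingroup || anyDuplicated(c(ingroup, outgroup))) {
    stop("ingroup and outgroup names must be three distinct taxa")
  }
  structure(
    list(ingroup = ingroup, outgroup = outgroup,
         leaves = c(ingroup, outgroup)),
    class = "triad_tree"
  )
}

#' Triad tree from a rooted newick string
#'
#' Reads a rooted 3-leaf newick topology of the form `((a,b),c);` and takes
#' the cherry as the ingroup pair.
#'
#' @param text newick string (or a file path when `file = TRUE`).
#' @param file logical; treat `text` as a path.
#' @return a [triad_tree()].
#' @export
triad_tree_from_newick <- function(text, file = FALSE) {
  tr <- if (file) ape::read.tree(text) else ape::read.tree(text = text)
  if (is.null(tr) || length(tr$tip.label) != 3) {
    stop("expected a rooted newick tree with exactly 3 leaves")
  }
  # the cherry: two tips sharing a parent that is not the root
  parents <- tr$edge[match(seq_len(3), tr$edge[, 2]), 1]
  tab <- table(parents)
  cherry_parent <- as.integer(names(tab)[tab == 2])
  if (length(cherry_parent) != 1) {
    stop("tree is not of the form ((a,b),c); cannot identify the ingroup")
  }
  ing <- tr$tip.label[which(parents == cherry_parent)]
  out <- setdiff(tr$tip.label, ing)
  triad_tree(ing, out)
}

#' @export
print.triad_tree <- function(x, ...) {
  cat("Triad: ((", x$ingroup[1], ", ", x$ingroup[2], "), ", x$outgroup,
      ")  [root at ingroup ancestor; outgroup edges merged]\n", sep = "")
  invisible(x)
}

#' Triad alignment
#'
#' Three equal-length nucleotide sequences (strictly A, C, G, T; gap and
#' ambiguity columns are removed upstream, see [read_triad_fasta()]).
#'
#' @param seqs named character vector of three sequences.
#' @return an object of class `triad_alignment` (a named character vector).
#' @export
triad_alignment <- function(seqs) {
  if (length(seqs) != 3 || is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("'seqs' must be three uniquely named sequences")
  }
  nms <- names(seqs)
  seqs <- toupper(vapply(seqs, as.character, ""))
  names(seqs) <- nms
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("sequences must have equal length (got ", paste(lens, collapse = ", "), ")")
  }
  structure(seqs, class = "triad_alignment")
}

#' @export
print.triad_alignment <- function(x, ...) {
  cat("Triad alignment:", nchar(x[[1]]), "sites\n")
  for (nm in names(x)) {
    s <- x[[nm]]
    cat(sprintf("  %-12s %s%s\n", nm, substr(s, 1, 50),
                if (nchar(s) > 50) "..." else ""))
  }
  invisible(x)
}

pattern_labels <- function() {
  g <- expand.grid(c = NUC, b = NUC, a = NUC, stringsAsFactors = FALSE)
  paste0(g$a, g$b, g$c)
}

#' Site-pattern counts of a triad alignment
#'
#' Tabulates the 64 ordered nucleotide triplets across alignment columns,
#' taxa ordered as in the tree (ingroup pair, then outgroup). Pattern index
#' is row-major in state order A, C, G, T.
#'
#' @param aln a [triad_alignment()].
#' @param tree a [triad_tree()] fixing the taxon order; by default the
#'   alignment's own order is used.
#' @return named integer vector of length 64 summing to the alignment
#'   length, class `pattern_counts`.
#' @export
pattern_counts <- function(aln, tree = NULL) {
  if (!inherits(aln, "triad_alignment")) aln <- triad_alignment(aln)
  ord <- if (is.null(tree)) names(aln) else tree$leaves
  if (!all(ord %in% names(aln))) {
    stop("alignment is missing taxa: ",
         paste(setdiff(ord, names(aln)), collapse = ", "))
  }
  n <- nchar(aln[[1]])
  codes <- lapply(unclass(aln)[ord], function(s) {
    v <- match(strsplit(s, "")[[1]], NUC)
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("non-ACGT character at alignment column ", bad)
    }
    v
  })
  counts <- integer(64)
  if (n > 0) {
    idx <- (codes[[1]] - 1L) * 16L + (codes[[2]] - 1L) * 4L + codes[[3]]
    tab <- tabulate(idx, nbins = 64L)
    counts <- as.integer(tab)
  }
  names(counts) <- pattern_labels()
  structure(counts, class = "pattern_counts", taxa = ord)
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat("Site-pattern counts over", sum(x), "sites; taxa:",
      paste(attr(x, "taxa"), collapse = ", "), "\n")
  nz <- x[x > 0]
  print(unclass(nz))
  invisible(x)
}
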