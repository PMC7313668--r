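# Isolate phylogeny from concatenated polymorphic positions. Heterozygous
# genotypes are IUPAC codes and distances use the average-state rule: each
# code is an equal-probability mixture over its bases and a column
# contributes the expected mismatch 1 - sum_b p1(b) p2(b). The tree is built
# with BioNJ (variance-weighted neighbor joining).

#' Per-isolate IUPAC strings over polymorphic positions
#'
#' Restricts an alignment to the union of per-isolate variant positions and
#' returns one string per isolate, one character per polymorphic column.
#'
#' @param aln An `iupac_alignment` (from [snp_alignment()]), or a named list
#'   of variant-call data.frames plus `ref` to build one.
#' @param ref Reference genome, required when `aln` is a records list.
#' @return Named character vector of equal-length IUPAC strings; attribute
#'   `n_columns` gives the column count.
#' @export
polymorphic_matrix <- function(aln, ref = NULL) {
  if (!inherits(aln, "iupac_alignment")) {
    if (is.null(ref)) stop("`ref` is required when passing raw records")
    aln <- snp_alignment(aln, ref)
  }
  out <- apply(aln$codes, 2, paste, collapse = "")
  if (!nrow(aln$codes)) out <- stats::setNames(rep("", length(aln$isolates)),
                                               aln$isolates)
  attr(out, "n_columns") <- nrow(aln$codes)
  out
}

#' Average-state distance between two IUPAC sequences
#'
#' Mean per-column expected mismatch under equal-probability resolution of
#' ambiguity codes: 'A' vs 'R' contributes 0.5, 'R' vs 'R' contributes 0.5,
#' identical plain bases contribute 0.
#'
#' @param s1,s2 IUPAC strings of equal length.
#' @return Distance per site in \[0, 1\].
#' @export
average_state_distance <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  if (length(a) != length(b)) stop("sequence length mismatch")
  if (!length(a)) return(0)
  mean(.iupac_mismatch[cbind(iupac_index(a), iupac_index(b))])
}

#' Average-state distance matrix of a cohort
#'
#' @param seqs Named character vector of IUPAC strings (equal length), e.g.
#'   from [polymorphic_matrix()].
#' @return A symmetric [stats::dist]-compatible matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs) {
  n <- length(seqs)
  labels <- names(seqs) %||% sprintf("seq%d", seq_len(n))
  cm <- .as_code_matrix(unname(seqs))$codes
  idx <- matrix(iupac_index(cm), nrow = nrow(cm))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- mean(.iupac_mismatch[cbind(idx[, i], idx[, j])])
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' BioNJ tree from a distance matrix
#'
#' Builds the neighbor-joining tree with the BioNJ agglomeration
#' (variance-weighted branch length estimates). Negative branch lengths, a
#' known NJ artifact on noisy distances, are clamped to zero with a message.
#'
#' @param d Symmetric distance matrix (or `dist`) with >= 3 labels.
#' @param method `"bionj"` (default) or `"nj"` for classic neighbor joining
#'   as a cross-check.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d, method = c("bionj", "nj")) {
  method <- match.arg(method)
  dm <- stats::as.dist(d)
  if (attr(dm, "Size") < 3L) stop("tree building requires >= 3 labels")
  tree <- if (method == "bionj") ape::bionj(dm) else ape::nj(dm)
  if (any(tree$edge.length < 0)) {
    message("clamping ", sum(tree$edge.length < 0),
            " negative branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Write a tree to newick
#'
#' @param tree An [ape::phylo].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path Newick file.
#' @return An [ape::phylo].
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
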