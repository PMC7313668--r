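#' Generate a random reference genome
#'
#' Produces a multi-scaffold reference with the requested per-scaffold
#' lengths and GC content. The sequence itself carries no biological signal;
#' it provides the coordinate space and reference bases that all downstream
#' window scans, variant simulation and alignment construction operate on,
#' in the way a small yeast assembly (a handful of scaffolds, a few Mb)
#' would.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param lengths Integer vector of scaffold lengths in bases; recycled to
#'   `n_scaffolds` if length 1.
#' @param gc Target GC fraction in (0, 1); bases are drawn i.i.d. with
#'   P(G) = P(C) = gc/2.
#' @param seed Integer seed; the genome is deterministic given it.
#' @return A `ref_genome` object: list with `scaffolds` (a named
#'   [Biostrings::DNAStringSet]) and `total_length`.
#' @examples
#' ref <- generate_reference(2, c(50000, 30000), gc = 0.4, seed = 1)
#' scaffold_lengths(ref)
#' @export
generate_reference <- function(n_scaffolds, lengths, gc = 0.4, seed = 1L) {
  stopifnot(is_count(n_scaffolds), n_scaffolds >= 1, gc > 0, gc < 1)
  if (length(lengths) == 1L) lengths <- rep(lengths, n_scaffolds)
  if (length(lengths) != n_scaffolds)
    stop("`lengths` must have length 1 or n_scaffolds")
  bad <- which(!is.finite(lengths) | lengths <= 0)
  if (length(bad))
    stop("non-positive length for scaffold ", bad[1L])
  lengths <- as.integer(lengths)
  set.seed(seed)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(n) {
    paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
  scaffolds <- Biostrings::DNAStringSet(seqs)
  names(scaffolds) <- sprintf("scf_%d", seq_len(n_scaffolds))
  structure(
    list(scaffolds = scaffolds, total_length = sum(as.numeric(lengths))),
    class = "ref_genome"
  )
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome:", length(x$scaffolds), "scaffold(s),",
      x$total_length, "bp total\n")
  invisible(x)
}

#' Scaffold lengths of a reference genome
#'
#' @param ref A `ref_genome`.
#' @return Named integer vector of scaffold lengths.
#' @export
scaffold_lengths <- function(ref) {
  stopifnot(inherits(ref, "ref_genome"))
  stats::setNames(Biostrings::width(ref$scaffolds), names(ref$scaffolds))
}

#' Reference base at given positions
#'
#' @param ref A `ref_genome`.
#' @param scaffold Scaffold names (recycled).
#' @param pos 1-based positions.
#' @return Character vector of bases.
#' @keywords internal
ref_base_at <- function(ref, scaffold, pos) {
  out <- character(length(pos))
  for (s in unique(scaffold)) {
    i <- scaffold == s
    out[i] <- substring(as.character(ref$scaffolds[[s]]), pos[i], pos[i])
  }
  out
}

#' Tile gene models along a reference
#'
#' Lays regularly spaced gene intervals over every scaffold, emulating the
#' dense gene spacing of a yeast genome (default: 1.5-kb genes separated by
#' 0.5-kb intergenic gaps, about 75% coding). Used by the fixture writer and
#' anywhere gene-level copy numbers are exercised.
#'
#' @param ref A `ref_genome`.
#' @param gene_length Gene span in bases.
#' @param intergenic Gap between consecutive genes in bases.
#' @return A [GenomicRanges::GRanges] of genes with `gene_id` metadata and
#'   alternating strand.
#' @export
tile_genes <- function(ref, gene_length = 1500L, intergenic = 500L) {
  stopifnot(gene_length > 0, intergenic >= 0)
  lens <- scaffold_lengths(ref)
  pitch <- gene_length + intergenic
  gr_list <- lapply(names(lens), function(s) {
    starts <- seq.int(1L, lens[[s]] - gene_length + 1L, by = pitch)
    if (!length(starts)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(s, IRanges::IRanges(starts, width = gene_length))
  })
  gr <- suppressWarnings(do.call(c, gr_list))
  GenomicRanges::strand(gr) <- rep_len(c("+", "-"), length(gr))
  gr$gene_id <- sprintf("gene_%05d", seq_along(gr))
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  gr
}

#' Write a reference genome to FASTA
#'
#' @param ref A `ref_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(ref$scaffolds, path)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A `ref_genome`.
#' @export
read_reference_fasta <- function(path) {
  scaffolds <- Biostrings::readDNAStringSet(path)
  names(scaffolds) <- sub("\\s.*$", "", names(scaffolds))
  structure(
    list(scaffolds = scaffolds,
         total_length = sum(as.numeric(Biostrings::width(scaffolds)))),
    class = "ref_genome"
  )
}

#' Write gene models to GFF3
#'
#' @param genes A [GenomicRanges::GRanges] with a `gene_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  g <- genes
  g$type <- "gene"
  g$ID <- g$gene_id
  rtracklayer::export(g, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `gene` features (all features if none are typed `gene`).
#'
#' @param path GFF3 file.
#' @return A [GenomicRanges::GRanges] with `gene_id` metadata.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  id <- gr$ID %||% gr$gene_id %||% sprintf("gene_%05d", seq_along(gr))
  mcols_keep <- S4Vectors::DataFrame(gene_id = as.character(id))
  S4Vectors::mcols(gr) <- mcols_keep
  if (anyDuplicated(gr$gene_id)) stop("duplicate gene ids in ", path)
  gr
}
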