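# Ploidy inference from the allele-balance distribution at heterozygous
# sites. A diploid's het sites sit at balance ~0.5; an allotriploid's sit at
# ~1/3 and ~2/3 because every het site has the minor allele on 1 of 3 (or 2
# of 3) copies.

#' Histogram of allele balance at heterozygous sites
#'
#' @param records Variant-call data.frame of heterozygous calls only.
#' @param bin_width Histogram bin width over \[0, 1\].
#' @return A `balance_histogram`: list with `bin_edges`, `counts`,
#'   `n_sites`, `empty`.
#' @export
balance_histogram <- function(records, bin_width = 0.01) {
  if (nrow(records) && !all(records$genotype == "het"))
    stop("balance_histogram expects heterozygous records only")
  edges <- seq(0, 1, by = bin_width)
  if (abs(edges[length(edges)] - 1) > 1e-12)
    stop("bin_width must evenly divide [0, 1]")
  if (!nrow(records)) {
    return(structure(list(bin_edges = edges,
                          counts = integer(length(edges) - 1L),
                          n_sites = 0L, empty = TRUE),
                     class = "balance_histogram"))
  }
  ab <- allele_balance(records)
  ab <- ab[!is.na(ab)]
  # right-open bins [e_i, e_{i+1}), with balance exactly 1 in the last bin
  idx <- pmin(findInterval(ab, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts,
                 n_sites = length(ab), empty = length(ab) == 0L),
            class = "balance_histogram")
}

#' @export
print.balance_histogram <- function(x, ...) {
  cat("balance_histogram:", x$n_sites, "het sites in",
      length(x$counts), "bins\n")
  invisible(x)
}

#' Modal bin center of a balance histogram
#'
#' @param hist A `balance_histogram`.
#' @param lower,upper Restrict the search to bins whose center lies in
#'   \[lower, upper\].
#' @return Center of the highest-count bin (first on ties).
#' @export
histogram_mode <- function(hist, lower = 0, upper = 1) {
  centers <- hist$bin_edges[-length(hist$bin_edges)] + diff(hist$bin_edges) / 2
  in_range <- centers >= lower & centers <= upper
  if (!any(in_range) || hist$n_sites == 0L)
    undefined_error("histogram mode undefined: no sites in range")
  cts <- hist$counts[in_range]
  centers[in_range][which.max(cts)]
}

#' Classify isolate ploidy from a balance histogram
#'
#' Measures the fraction of heterozygous sites whose allele balance falls in
#' the diploid band \[0.45, 0.55\] versus the triploid bands
#' \[0.28, 0.38\] and \[0.62, 0.72\], and calls the isolate diploid
#' (triploid) when the winning band's mass per unit band width exceeds
#' `margin` times the other's; otherwise ambiguous (width normalisation
#' keeps an uninformative uniform balance distribution ambiguous instead of
#' letting the wider triploid bands win by area). Band widths are set so binomial spread at 40x depth
#' does not bleed between bands; they are a reproducible surrogate for the
#' visual "centered ~0.5 / ~0.33 and 0.66" classification.
#'
#' @param hist A `balance_histogram`.
#' @param min_sites Minimum heterozygous sites for a confident call.
#' @param margin Dominance ratio required for a non-ambiguous label.
#' @param diploid_band,triploid_band_low,triploid_band_high Balance intervals
#'   (length-2 numeric vectors).
#' @return A `ploidy_call`: list with `label`
#'   (`"diploid"`/`"triploid"`/`"ambiguous"`), `mass_diploid`,
#'   `mass_triploid`, `modes` (detected peak centers) and `reason`.
#' @export
classify_ploidy <- function(hist, min_sites = 500L, margin = 1.5,
                            diploid_band = c(0.45, 0.55),
                            triploid_band_low = c(0.28, 0.38),
                            triploid_band_high = c(0.62, 0.72)) {
  stopifnot(inherits(hist, "balance_histogram"))
  centers <- hist$bin_edges[-length(hist$bin_edges)] +
    diff(hist$bin_edges) / 2
  band_mass <- function(b) {
    sum(hist$counts[centers >= b[1L] & centers <= b[2L]]) /
      max(hist$n_sites, 1L)
  }
  mass_di <- band_mass(diploid_band)
  mass_tri <- band_mass(triploid_band_low) + band_mass(triploid_band_high)
  # compare per unit band width: the triploid bands jointly cover twice the
  # balance range of the diploid band, so raw masses would call a uniform
  # (uninformative) balance distribution triploid instead of ambiguous
  width_ratio <- (diff(triploid_band_low) + diff(triploid_band_high)) /
    diff(diploid_band)
  dens_di <- mass_di
  dens_tri <- mass_tri / width_ratio
  call_out <- function(label, reason = NA_character_, modes = numeric(0)) {
    structure(list(label = label, mass_diploid = mass_di,
                   mass_triploid = mass_tri, modes = modes,
                   n_sites = hist$n_sites, reason = reason),
              class = "ploidy_call")
  }
  if (hist$n_sites < min_sites) {
    return(call_out("ambiguous",
                    sprintf("only %d het sites (minimum %d)",
                            hist$n_sites, min_sites)))
  }
  if (dens_di > margin * dens_tri) {
    call_out("diploid", modes = histogram_mode(hist, 0.40, 0.60))
  } else if (dens_tri > margin * dens_di) {
    call_out("triploid",
             modes = c(histogram_mode(hist, 0.23, 0.43),
                       histogram_mode(hist, 0.57, 0.77)))
  } else {
    call_out("ambiguous", "band masses within margin of each other")
  }
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("ploidy_call: %s (diploid band %.3f, triploid bands %.3f, %d sites)\n",
              x$label, x$mass_diploid, x$mass_triploid, x$n_sites))
  invisible(x)
}

#' Estimate subgenome divergence of an allotriploid
#'
#' In the allotriploid model the subgenome-distinguishing sites where the
#' diploid lineage carries the derived allele sit at balance 2/3, while the
#' haploid-derived half -- and the diploid subgenome's own het sites -- sit
#' at 1/3. Divergence mutations fall on either lineage with equal
#' probability, so twice the density of balance > 0.5 heterozygous sites
#' estimates the per-site divergence between the two subgenomes without
#' needing to know the diploid subgenome's het rate.
#'
#' @param records Heterozygous variant-call records of one triploid isolate.
#' @param genome_length Total callable genome length in bases.
#' @param split Balance threshold separating the 1/3 and 2/3 classes.
#' @return Estimated per-site subgenome divergence (e.g. 0.024 for 2.4%).
#' @export
estimate_subgenome_divergence <- function(records, genome_length,
                                          split = 0.5) {
  stopifnot(genome_length > 0)
  het <- records[records$genotype == "het", , drop = FALSE]
  ab <- allele_balance(het)
  2 * sum(ab > split, na.rm = TRUE) / genome_length
}
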