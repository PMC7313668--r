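# Shared fixture builders. Everything is generated in code; genome sizes are
# kept small so the default test run stays fast (larger-scale recovery runs
# live in the acceptance suite and scripts/acceptance.R).

small_ref <- function(lengths = c(100000L, 60000L), seed = 42L) {
  generate_reference(length(lengths), lengths, gc = 0.4, seed = seed)
}

# hand-built variant records, defaulting to clean high-quality het calls
make_records <- function(scaffold = "scf_1", pos, ref = "A", alt = "G",
                         genotype = "het", depth = 60L,
                         alt_depth = round(depth / 2), qual = 90) {
  n <- length(pos)
  data.frame(
    scaffold = rep_len(scaffold, n), pos = as.integer(pos),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    genotype = rep_len(genotype, n), depth = rep_len(as.integer(depth), n),
    alt_depth = rep_len(as.integer(alt_depth), n),
    qual = rep_len(qual, n), stringsAsFactors = FALSE
  )
}

quick_isolate <- function(ref, ploidy = 2L, het_rate = 7.1,
                          subgenome_divergence = if (ploidy == 3L) 0.024,
                          depth = 60, seed = 1L, ...) {
  sp <- isolate_spec(ploidy = ploidy, het_rate = het_rate,
                     subgenome_divergence = subgenome_divergence,
                     depth = depth, seed = seed,
                     id = sprintf("iso_s%d", seed), ...)
  simulate_isolate(ref, sp)
}

quick_calls <- function(ref, ..., depth_track = FALSE) {
  simulate_calls(quick_isolate(ref, ...), depth_track = depth_track)$records
}
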