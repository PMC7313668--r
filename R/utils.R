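# Shared internals: IUPAC state machinery, classed conditions, small helpers.

# Base-probability vectors for the nucleotide IUPAC alphabet. Each code is an
# equal-probability mixture over its compatible bases; expected mismatch
# between two codes is 1 - sum_b p1(b) * p2(b).
.iupac_bases <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

.iupac_codes <- names(.iupac_bases)

# 15 x 4 matrix of P(base | code)
.iupac_prob <- local({
  m <- matrix(0, length(.iupac_bases), 4,
              dimnames = list(names(.iupac_bases), c("A", "C", "G", "T")))
  for (code in names(.iupac_bases)) {
    b <- .iupac_bases[[code]]
    m[code, b] <- 1 / length(b)
  }
  m
})

# 15 x 15 expected-mismatch lookup between codes
.iupac_mismatch <- 1 - tcrossprod(.iupac_prob)

# het genotype -> ambiguity code, keyed by the sorted pair of bases
.het_code <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

iupac_het_code <- function(a, b) {
  key <- ifelse(a < b, paste0(a, b), paste0(b, a))
  code <- .het_code[key]
  if (anyNA(code)) stop("invalid base pair for IUPAC encoding")
  unname(code)
}

# map character vector of codes to integer indices into the IUPAC tables
iupac_index <- function(x) {
  idx <- match(x, .iupac_codes)
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unknown IUPAC code(s): ", paste(bad, collapse = ", "))
  }
  idx
}

# classed condition for quantities that are mathematically undefined on the
# given input (e.g. heterozygosity when LOH covers the whole genome)
undefined_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("hybridscan_undefined", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw a reproducible child seed; keeps values within 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483647L)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
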