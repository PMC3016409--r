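# Internal helpers: integer haplotype encoding and small utilities.
#
# A haplotype over n biallelic loci is stored as a non-negative integer in
# [0, 2^n): bit (i-1) is 1 iff the allele at locus i is allele "2" (the
# minor allele by convention).  n is capped well below 31 so that plain R
# integers suffice.

MAX_LOCI <- 25L

#' Convert haplotype integers to allele strings
#'
#' @param h integer vector of encoded haplotypes.
#' @param n_loci number of loci.
#' @return character vector of strings over \{"1","2"\}, e.g. `"12122"`.
#' @export
hap_to_str <- function(h, n_loci) {
  stopifnot(n_loci >= 1, n_loci <= MAX_LOCI)
  vapply(h, function(x) {
    bits <- bitwAnd(bitwShiftR(x, 0:(n_loci - 1L)), 1L)
    paste(ifelse(bits == 1L, "2", "1"), collapse = "")
  }, character(1))
}

#' Convert allele strings to haplotype integers
#'
#' @param s character vector of strings over \{"1","2"\}.
#' @return integer vector of encoded haplotypes.
#' @export
str_to_hap <- function(s) {
  vapply(s, function(x) {
    a <- strsplit(x, "")[[1]]
    if (!all(a %in% c("1", "2"))) {
      stop("haplotype string must contain only alleles '1' and '2': ", x)
    }
    sum(bitwShiftL(as.integer(a == "2"), seq_along(a) - 1L))
  }, integer(1), USE.NAMES = FALSE)
}

# Allele (0/1 minor-indicator) at a given 1-based locus of encoded haplotypes.
hap_bit <- function(h, locus) {
  bitwAnd(bitwShiftR(h, locus - 1L), 1L)
}

# Project encoded haplotypes onto a subset of loci (1-based, in given order).
hap_project <- function(h, loci) {
  out <- integer(length(h))
  for (k in seq_along(loci)) {
    out <- out + bitwShiftL(hap_bit(h, loci[k]), k - 1L)
  }
  out
}

# Canonical unordered pair: smaller haplotype first.
sort_pair <- function(h1, h2) {
  if (h2 < h1) c(h2, h1) else c(h1, h2)
}

# Genotype (count of allele 2, or NA) implied by a haplotype pair at each of
# n loci; used for consistency checks.
pair_genotype <- function(h1, h2, n_loci) {
  hap_bit(rep(h1, n_loci), seq_len(n_loci)) +
    hap_bit(rep(h2, n_loci), seq_len(n_loci))
}
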