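# Standard-genetic-code utilities shared by the classification and
# site-counting modules.  All codon arithmetic in the package funnels
# through translate_codon()/classify_effect() so the code table is applied
# in exactly one place.

BASES <- c("A", "C", "G", "T")

#' Sense codons of the standard genetic code
#'
#' The 61 stop-free codons, in lexicographic order.
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  all <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  all <- sort(all)
  all[!all %in% c("TAA", "TAG", "TGA")]
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

is_stop_codon <- function(codon) {
  toupper(codon) %in% c("TAA", "TAG", "TGA")
}

#' Classify a single-base codon change as synonymous or non-synonymous
#'
#' A change is synonymous when the encoded amino acid is unchanged under
#' the standard genetic code.  Changes that create a stop codon (nonsense)
#' are classified as non-synonymous; the reference codon itself must be a
#' sense codon (terminal stop codons are excluded upstream of this call).
#'
#' @param ref_codon Reference codon, 3 uppercase DNA letters (vectorised).
#' @param offset_in_codon Position of the change within the codon, 1-3.
#' @param alt_base Alternative base, one of A/C/G/T, different from the
#'   reference base at `offset_in_codon`.
#' @return Character vector, `"synonymous"` or `"nonsynonymous"`.
#' @examples
#' classify_effect("CCG", 2, "T")  # Pro -> Leu, nonsynonymous
#' classify_effect("CTG", 3, "A")  # Leu -> Leu, synonymous
#' @export
classify_effect <- function(ref_codon, offset_in_codon, alt_base) {
  ref_codon <- toupper(ref_codon)
  alt_base <- toupper(alt_base)
  if (any(is_stop_codon(ref_codon)))
    stop("classify_effect: reference codon is a stop codon")
  if (any(!offset_in_codon %in% 1:3))
    stop("classify_effect: offset_in_codon must be 1, 2 or 3")
  cur <- substr(ref_codon, offset_in_codon, offset_in_codon)
  if (any(cur == alt_base))
    stop("classify_effect: alt_base equals the reference base at the offset")
  alt_codon <- ref_codon
  substr(alt_codon, offset_in_codon, offset_in_codon) <- alt_base
  ifelse(translate_codon(alt_codon) == translate_codon(ref_codon),
         "synonymous", "nonsynonymous")
}

# Precomputed effect lookup keyed "CODON<offset><alt>", built lazily; used by
# the bulk classifier so per-variant work is a single named-vector lookup.
effect_lookup <- function() {
  if (!is.null(.domseln_cache$effect_lookup)) return(.domseln_cache$effect_lookup)
  keys <- character(0); vals <- character(0)
  for (cod in sense_codons()) {
    for (off in 1:3) {
      for (alt in setdiff(BASES, substr(cod, off, off))) {
        keys <- c(keys, paste0(cod, off, alt))
        vals <- c(vals, classify_effect(cod, off, alt))
      }
    }
  }
  .domseln_cache$effect_lookup <- stats::setNames(vals, keys)
  .domseln_cache$effect_lookup
}
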