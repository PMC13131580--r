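# Codon machinery: translation under the standard genetic code and
# single-nucleotide neighborhoods.

#' Translate codons under the standard genetic code
#'
#' @param codon character vector of 3-nucleotide strings (A/C/G/T).
#' @return character vector of one-letter amino acids; stop codons give `"*"`,
#'   codons containing an ambiguous base (e.g. N) are untranslatable and give
#'   `NA`.
#' @examples
#' translate_codon(c("ATG", "TGG", "TAG"))
#' @export
translate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  if (any(nchar(codon) != 3L)) stop("codons must have exactly 3 nucleotides")
  idx <- match(codon, .ab$codons)
  out <- rep(NA_character_, length(codon))
  out[!is.na(idx)] <- .ab$aa64[idx[!is.na(idx)]]
  out
}

#' Translate an in-frame nucleotide sequence
#'
#' @param nt_sequence nucleotide string, length divisible by 3.
#' @return amino-acid string; stop codons appear as `"*"`, untranslatable
#'   codons as `"X"`.
#' @export
translate_nt <- function(nt_sequence) {
  v <- nt_to_int(nt_sequence)
  if (length(v) %% 3L != 0L) stop("sequence length not divisible by 3")
  idx <- seq_codon_indices(v)
  aa <- ifelse(is.na(idx), "X", .ab$aa64[idx])
  paste(aa, collapse = "")
}

#' Amino acids reachable by a single nucleotide substitution
#'
#' Enumerates the 9 single-nucleotide neighbors of a codon and collects their
#' translations, excluding stop codons and the codon's own amino acid.  This
#' is the reachability filter applied to selection-factor records: only
#' targets a point mutation can produce are retained.
#'
#' @param codon a single 3-nucleotide string encoding an amino acid.
#' @return sorted character vector of reachable amino acids (possibly empty in
#'   principle, always 1-7 in practice).
#' @examples
#' single_nt_reachable_aas("TGG") # W -> {C, G, L, R, S}
#' @export
single_nt_reachable_aas <- function(codon) {
  codon <- toupper(as.character(codon))
  if (length(codon) != 1L || nchar(codon) != 3L) {
    stop("codon must be a single 3-nucleotide string")
  }
  idx <- match(codon, .ab$codons)
  if (is.na(idx)) stop("ambiguous or invalid codon: ", codon)
  if (.ab$aa64[idx] == "*") stop("stop codon has no source amino acid: ", codon)
  .ab$reachable_aas[[idx]]
}

#' The twenty standard amino acids
#'
#' @return character vector of one-letter codes, alphabetical.
#' @export
amino_acids <- function() .ab$aa_letters
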