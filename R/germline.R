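# Germline V-gene sets.
#
# A germline set is a data.frame with one row per allele:
#   name         allele identifier (e.g. "IGHV1-1*01")
#   family       V family (e.g. "IGHV1")
#   nt_sequence  nucleotide sequence, length divisible by 3, no stop codons
#   aa_sequence  translation of nt_sequence
#   site_labels  list-column of Chothia labels, one per amino-acid position,
#                strictly increasing in Chothia order
# On disk: FASTA with headers "name|family" plus a sidecar tab-delimited map
# of amino-acid position -> Chothia label.

#' Assemble and validate a germline V-gene set
#'
#' @param name,family character vectors, one entry per allele.
#' @param nt_sequence nucleotide sequences (A/C/G/T, length divisible by 3,
#'   stop-free).
#' @param site_labels list of character vectors of Chothia labels (one label
#'   per codon), or a single vector recycled to all alleles.
#' @return validated `data.frame` of class `germline_set`.
#' @export
germline_set <- function(name, family, nt_sequence, site_labels) {
  n <- length(name)
  family <- rep_len(family, n)
  stopifnot(length(nt_sequence) == n)
  if (!is.list(site_labels)) site_labels <- rep(list(site_labels), n)
  stopifnot(length(site_labels) == n)
  aa <- character(n)
  for (i in seq_len(n)) {
    if (nchar(nt_sequence[i]) %% 3L != 0L) {
      stop("germline ", name[i], ": length not divisible by 3")
    }
    aa[i] <- translate_nt(nt_sequence[i])
    if (grepl("\\*", aa[i], fixed = FALSE)) {
      stop("germline ", name[i], ": contains a stop codon")
    }
    if (grepl("X", aa[i], fixed = TRUE)) {
      stop("germline ", name[i], ": contains an ambiguous codon")
    }
    labs <- site_labels[[i]]
    if (length(labs) != nchar(aa[i])) {
      stop("germline ", name[i], ": ", length(labs),
           " site labels for ", nchar(aa[i]), " amino acids")
    }
    k <- chothia_key(labs)
    if (any(diff(k) <= 0)) {
      stop("germline ", name[i], ": site labels not strictly increasing")
    }
  }
  if (anyDuplicated(name)) stop("duplicate germline names")
  out <- data.frame(name = name, family = family,
                    nt_sequence = toupper(nt_sequence), aa_sequence = aa,
                    stringsAsFactors = FALSE)
  out$site_labels <- site_labels
  class(out) <- c("germline_set", "data.frame")
  out
}

#' Look up one germline allele
#'
#' @param germlines a `germline_set`.
#' @param name allele name.
#' @return single-row germline record (list) with fields `name`, `family`,
#'   `nt_sequence`, `aa_sequence`, `site_labels`.
#' @export
germline_gene <- function(germlines, name) {
  i <- match(name, germlines$name)
  if (is.na(i)) stop("unknown germline gene: ", name)
  list(name = germlines$name[i], family = germlines$family[i],
       nt_sequence = germlines$nt_sequence[i],
       aa_sequence = germlines$aa_sequence[i],
       site_labels = germlines$site_labels[[i]])
}

#' Germline codon and amino acid at a Chothia site
#'
#' @param germlines a `germline_set`.
#' @param name allele name.
#' @param site Chothia site label.
#' @return list with `codon`, `aa` and the 1-based codon `position`.
#' @export
germline_codon_at <- function(germlines, name, site) {
  g <- germline_gene(germlines, name)
  pos <- match(site, g$site_labels)
  if (is.na(pos)) stop("site ", site, " absent from germline ", name)
  codon <- substr(g$nt_sequence, 3L * pos - 2L, 3L * pos)
  list(codon = codon, aa = substr(g$aa_sequence, pos, pos), position = pos)
}

#' Write a germline set as FASTA plus a Chothia sidecar table
#'
#' Headers are `name|family`; the sidecar is tab-delimited with columns
#' `name`, `position` (1-based amino-acid position) and `site`.
#'
#' @param germlines a `germline_set`.
#' @param fasta_path,sites_path output paths.
#' @return invisibly, the two paths.
#' @export
write_germline_fasta <- function(germlines, fasta_path, sites_path) {
  seqs <- Biostrings::DNAStringSet(germlines$nt_sequence)
  names(seqs) <- paste(germlines$name, germlines$family, sep = "|")
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60L)
  sidecar <- do.call(rbind, lapply(seq_len(nrow(germlines)), function(i) {
    labs <- germlines$site_labels[[i]]
    data.frame(name = germlines$name[i], position = seq_along(labs),
               site = labs, stringsAsFactors = FALSE)
  }))
  utils::write.table(sidecar, sites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, sites_path))
}

#' Read a germline set written by [write_germline_fasta()]
#'
#' @param fasta_path,sites_path input paths.
#' @return a `germline_set`.
#' @export
read_germline_fasta <- function(fasta_path, sites_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  hdr <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(hdr) != 2L)) stop("FASTA headers must be 'name|family'")
  name <- vapply(hdr, `[`, "", 1L)
  family <- vapply(hdr, `[`, "", 2L)
  sidecar <- utils::read.delim(sites_path, colClasses = "character")
  labs <- lapply(name, function(nm) {
    s <- sidecar[sidecar$name == nm, ]
    if (nrow(s) == 0L) stop("no Chothia labels for germline ", nm)
    s$site[order(as.integer(s$position))]
  })
  germline_set(name, family, as.character(seqs), labs)
}
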