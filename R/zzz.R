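# Package-internal lookup tables, built once at load time.
#
# Bases are encoded internally as integers A=1, C=2, G=3, T=4; codons as
# 1..64 with index 16*(b1-1) + 4*(b2-1) + b3.  Amino acids use one-letter
# codes; the stop marker is "*".

.ab <- new.env(parent = emptyenv())

.ab_bases <- c("A", "C", "G", "T")

.onLoad <- function(libname, pkgname) {
  gc_tab <- Biostrings::GENETIC_CODE # standard code only (no mito variants)
  codons <- character(64)
  aa64 <- character(64)
  for (b1 in 1:4) for (b2 in 1:4) for (b3 in 1:4) {
    idx <- 16L * (b1 - 1L) + 4L * (b2 - 1L) + b3
    codons[idx] <- paste0(.ab_bases[b1], .ab_bases[b2], .ab_bases[b3])
    aa64[idx] <- unname(gc_tab[[codons[idx]]])
  }
  .ab$codons <- codons
  .ab$aa64 <- aa64
  .ab$aa_letters <- sort(unique(aa64[aa64 != "*"]))
  # aa code: 1..20 amino acids (alphabetical), 21 = stop
  .ab$aa_code <- c(stats::setNames(seq_along(.ab$aa_letters), .ab$aa_letters),
                   "*" = 21L)
  .ab$aa64_int <- unname(.ab$aa_code[aa64])

  # Single-nucleotide neighbors of each codon: 9 per codon (3 positions x 3
  # alternative bases).  neighbor_idx[i, ] are codon indices, neighbor_pos /
  # neighbor_base record which position changed and to what.
  nb_idx <- matrix(0L, 64, 9)
  nb_pos <- matrix(0L, 64, 9)
  nb_base <- matrix(0L, 64, 9)
  for (idx in 1:64) {
    b <- codon_index_to_bases(idx)
    k <- 0L
    for (p in 1:3) for (nb in (1:4)[-b[p]]) {
      k <- k + 1L
      bb <- b
      bb[p] <- nb
      nb_idx[idx, k] <- bases_to_codon_index(bb)
      nb_pos[idx, k] <- p
      nb_base[idx, k] <- nb
    }
  }
  .ab$neighbor_idx <- nb_idx
  .ab$neighbor_pos <- nb_pos
  .ab$neighbor_base <- nb_base

  # reachable_aas[[idx]]: amino acids encoded by single-nt neighbors of codon
  # idx, excluding stops and the codon's own translation.
  .ab$reachable_aas <- lapply(1:64, function(idx) {
    aas <- aa64[nb_idx[idx, ]]
    sort(unique(aas[aas != "*" & aas != aa64[idx]]))
  })

  invisible(NULL)
}

codon_index_to_bases <- function(idx) {
  i <- idx - 1L
  c(i %/% 16L + 1L, (i %/% 4L) %% 4L + 1L, i %% 4L + 1L)
}

bases_to_codon_index <- function(b) {
  16L * (b[1] - 1L) + 4L * (b[2] - 1L) + b[3]
}

# Encode a nucleotide string as integers (A=1,C=2,G=3,T=4, N and anything
# else = NA), and back.
nt_to_int <- function(seq) {
  m <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], .ab_bases)
  m
}

int_to_nt <- function(v) {
  paste(.ab_bases[v], collapse = "")
}

# Codon indices for an integer-encoded sequence (length divisible by 3).
# Positions with NA bases yield NA codons.
seq_codon_indices <- function(v) {
  n <- length(v) %/% 3L
  b1 <- v[seq(1L, by = 3L, length.out = n)]
  b2 <- v[seq(2L, by = 3L, length.out = n)]
  b3 <- v[seq(3L, by = 3L, length.out = n)]
  16L * (b1 - 1L) + 4L * (b2 - 1L) + b3
}

# Derive a reproducible 31-bit sub-seed from a base seed and a text tag.
derive_seed <- function(seed, tag) {
  h <- as.integer(seed %% 2147483647L)
  for (ch in utf8ToInt(tag)) {
    h <- as.integer((as.double(h) * 31 + ch) %% 2147483647)
  }
  if (h <= 0L) h <- h + 2147483646L
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a
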