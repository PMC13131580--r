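# Parent-child pair (PCP) tables and selection-factor tables.
#
# A PCP is one edge of a clonal-family tree.  Tables are plain data.frames:
#   pcp_id, family_id, depth (integer >= 2; 2 = edge out of the clonal
#   family's most recent common ancestor), is_leaf_child (logical), v_gene,
#   frame_class ("productive" | "out_of_frame"), parent_nt, child_nt.
# Selection-factor records carry one natural-log selection factor per
# (pcp_id, site, parent_aa, target_aa).

.pcp_cols <- c("pcp_id", "family_id", "depth", "is_leaf_child", "v_gene",
               "frame_class", "parent_nt", "child_nt")
.sf_cols <- c("pcp_id", "site", "parent_aa", "target_aa", "log_f")

#' Validate a PCP table
#'
#' Checks column presence, equal parent/child lengths, length divisible by 3,
#' depth >= 2, known frame classes and A/C/G/T/N alphabets.  Problems are
#' reported with row numbers.
#'
#' @param pcps data.frame of PCPs.
#' @return `pcps`, invisibly, with canonical column types.
#' @export
validate_pcp_table <- function(pcps) {
  miss <- setdiff(.pcp_cols, names(pcps))
  if (length(miss)) stop("PCP table missing column(s): ", paste(miss, collapse = ", "))
  pcps$depth <- as.integer(pcps$depth)
  pcps$is_leaf_child <- as.logical(pcps$is_leaf_child)
  bad <- function(cond, what) {
    if (any(cond)) {
      stop("PCP table row(s) ", paste(utils::head(which(cond), 10L), collapse = ", "),
           ": ", what)
    }
  }
  bad(is.na(pcps$depth) | pcps$depth < 2L, "depth must be an integer >= 2")
  bad(is.na(pcps$is_leaf_child), "is_leaf_child must be TRUE/FALSE")
  bad(!pcps$frame_class %in% c("productive", "out_of_frame"),
      "unknown frame_class")
  bad(nchar(pcps$parent_nt) != nchar(pcps$child_nt),
      "parent and child sequences differ in length")
  bad(nchar(pcps$parent_nt) %% 3L != 0L, "sequence length not divisible by 3")
  bad(grepl("[^ACGTN]", pcps$parent_nt) | grepl("[^ACGTN]", pcps$child_nt),
      "sequences may contain only A/C/G/T/N")
  invisible(pcps)
}

#' Read / write PCP tables
#'
#' Tab-delimited with header columns `pcp_id`, `family_id`, `depth`,
#' `is_leaf_child`, `v_gene`, `frame_class`, `parent_nt`, `child_nt`.
#' Reading validates every row and reports offending row numbers; writing
#' then reading is lossless.
#'
#' @param path file path.
#' @return `read_pcp_table()`: validated data.frame (possibly 0 rows).
#' @export
read_pcp_table <- function(path) {
  pcps <- utils::read.delim(path, colClasses = "character")
  miss <- setdiff(.pcp_cols, names(pcps))
  if (length(miss)) stop("PCP file missing column(s): ", paste(miss, collapse = ", "))
  pcps$depth <- as.integer(pcps$depth)
  pcps$is_leaf_child <- pcps$is_leaf_child %in% c("TRUE", "true", "1")
  pcps$parent_nt <- toupper(pcps$parent_nt)
  pcps$child_nt <- toupper(pcps$child_nt)
  validate_pcp_table(pcps)
  pcps
}

#' @param pcps validated PCP data.frame.
#' @rdname read_pcp_table
#' @export
write_pcp_table <- function(pcps, path) {
  validate_pcp_table(pcps)
  utils::write.table(pcps[, .pcp_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a selection-factor table
#'
#' @param sf data.frame with columns `pcp_id`, `site`, `parent_aa`,
#'   `target_aa`, `log_f`.
#' @return `sf`, invisibly.
#' @export
validate_selection_factors <- function(sf) {
  miss <- setdiff(.sf_cols, names(sf))
  if (length(miss)) stop("selection-factor table missing column(s): ",
                         paste(miss, collapse = ", "))
  sf$log_f <- as.numeric(sf$log_f)
  if (any(!is.finite(sf$log_f))) stop("log_f must be finite")
  if (any(sf$parent_aa == sf$target_aa)) {
    stop("parent_aa must differ from target_aa")
  }
  chothia_parse(sf$site) # label syntax check
  invisible(sf)
}

#' Read / write selection-factor tables
#'
#' Tab-delimited with columns `pcp_id`, `site`, `parent_aa`, `target_aa`,
#' `log_f` (natural log).
#'
#' @param path file path.
#' @return `read_selection_factors()`: validated data.frame.
#' @export
read_selection_factors <- function(path) {
  sf <- utils::read.delim(path, colClasses = c(pcp_id = "character",
                                               site = "character"))
  validate_selection_factors(sf)
  sf$log_f <- as.numeric(sf$log_f)
  sf
}

#' @param sf validated selection-factor data.frame.
#' @rdname read_selection_factors
#' @export
write_selection_factors <- function(sf, path) {
  validate_selection_factors(sf)
  utils::write.table(sf[, .sf_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Does a PCP's parent codon match germline at a site?
#'
#' Implements the germline-codon filter in its strict, nucleotide-identity
#' reading: the parent codon at the site must be nucleotide-identical to the
#' assigned germline V gene's codon there.  A synonymous parent codon (same
#' amino acid, different nucleotides) does NOT match: nucleotide identity
#' guarantees that both the amino-acid state and the local mutational context
#' are germline.
#'
#' @param pcp a single PCP (one-row data.frame or list with `parent_nt`,
#'   `v_gene`).
#' @param germlines a `germline_set` containing the PCP's V gene.
#' @param site Chothia site label; must be present in the gene's labels.
#' @return logical scalar.
#' @export
parent_matches_germline <- function(pcp, germlines, site) {
  g <- germline_codon_at(germlines, pcp$v_gene[[1]], site)
  parent_codon <- substr(pcp$parent_nt[[1]], 3L * g$position - 2L,
                         3L * g$position)
  identical(parent_codon, g$codon)
}
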