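# Entrenchment detection from per-sequence selection factors.
#
# The statistic is the median natural-log selection factor per (grouping,
# site, parent amino acid, target amino acid), computed from records that
# pass three filters: the PCP is a root edge (depth 2, parent = most recent
# common ancestor of its clonal family), the parent codon at the site is
# nucleotide-identical to germline, and the target amino acid is reachable
# from the parent codon by a single nucleotide substitution.  A site is
# entrenched for the unordered pair (A, B) when BOTH reciprocal medians lie
# strictly below the threshold (default -1, i.e. both substitutions occur at
# less than 100*exp(-1) ~ 37% of the neutral rate).

#' Apply the inference filters to selection-factor records
#'
#' Joins records to their PCPs and germlines and retains only records where
#' (i) the PCP has depth 2, (ii) the parent codon at the site is
#' nucleotide-identical to the germline codon ([parent_matches_germline()]'s
#' strict reading), and (iii) the target amino acid is reachable from the
#' parent codon by a single nucleotide substitution.
#'
#' @param pcps PCP table.
#' @param sf_records selection-factor table; every `pcp_id` must exist in
#'   `pcps` (dangling ids are an error listing the offenders).
#' @param germlines a `germline_set` covering the PCPs' V genes.
#' @return the retained records with join columns `v_gene` and `family`
#'   added.
#' @export
filter_inference_records <- function(pcps, sf_records, germlines) {
  validate_selection_factors(sf_records)
  i <- match(sf_records$pcp_id, pcps$pcp_id)
  if (any(is.na(i))) {
    stop("selection-factor records reference unknown pcp_id(s): ",
         paste(utils::head(unique(sf_records$pcp_id[is.na(i)]), 10L),
               collapse = ", "))
  }
  sf <- sf_records
  sf$v_gene <- pcps$v_gene[i]
  sf$depth <- pcps$depth[i]
  sf$parent_nt <- pcps$parent_nt[i]
  gi <- match(sf$v_gene, germlines$name)
  if (any(is.na(gi))) {
    stop("PCPs reference unknown germline gene(s): ",
         paste(unique(sf$v_gene[is.na(gi)]), collapse = ", "))
  }
  sf$family <- germlines$family[gi]

  keep <- sf$depth == 2L
  # site -> codon position per gene (all records; NA where site absent)
  pos <- rep(NA_integer_, nrow(sf))
  for (g in unique(sf$v_gene)) {
    labs <- germlines$site_labels[[match(g, germlines$name)]]
    sel <- sf$v_gene == g
    pos[sel] <- match(sf$site[sel], labs)
  }
  keep <- keep & !is.na(pos)
  parent_codon <- substr(sf$parent_nt, 3L * pos - 2L, 3L * pos)
  germ_codon <- rep(NA_character_, nrow(sf))
  for (g in unique(sf$v_gene)) {
    sel <- sf$v_gene == g & !is.na(pos)
    germ_codon[sel] <- substring(germlines$nt_sequence[match(g, germlines$name)],
                                 3L * pos[sel] - 2L, 3L * pos[sel])
  }
  keep <- keep & !is.na(germ_codon) & parent_codon == germ_codon
  cidx <- match(parent_codon, .ab$codons)
  reach <- rep(FALSE, nrow(sf))
  ok <- !is.na(cidx) & keep
  reach[ok] <- mapply(function(ci, t) t %in% .ab$reachable_aas[[ci]],
                      cidx[ok], sf$target_aa[ok])
  out <- sf[keep & reach,
            c(.sf_cols, "v_gene", "family"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate selection factors into per-combination medians
#'
#' One cell per (group, site, parent_aa, target_aa) with at least `min_obs`
#' observations; the median is the standard midpoint-of-two for even counts.
#'
#' @param records filtered selection-factor records.
#' @param grouping grouping label per record (character vector, recycled), or
#'   a function of the records data.frame returning one.
#' @param min_obs minimum observations per combination (default 10).
#' @return data.frame with columns `grouping`, `site`, `parent_aa`,
#'   `target_aa`, `median_log_f`, `n_obs`.
#' @export
aggregate_medians <- function(records, grouping, min_obs = 10L) {
  if (is.function(grouping)) grouping <- grouping(records)
  grouping <- rep_len(as.character(grouping), nrow(records))
  if (nrow(records) == 0L) {
    return(data.frame(grouping = character(0), site = character(0),
                      parent_aa = character(0), target_aa = character(0),
                      median_log_f = numeric(0), n_obs = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(grouping, records$site, records$parent_aa, records$target_aa,
               sep = "\r")
  sp <- split(records$log_f, key)
  n <- lengths(sp)
  med <- vapply(sp, stats::median, 0)
  parts <- strsplit(names(sp), "\r", fixed = TRUE)
  out <- data.frame(grouping = vapply(parts, `[`, "", 1L),
                    site = vapply(parts, `[`, "", 2L),
                    parent_aa = vapply(parts, `[`, "", 3L),
                    target_aa = vapply(parts, `[`, "", 4L),
                    median_log_f = unname(med), n_obs = unname(n),
                    stringsAsFactors = FALSE)
  out <- out[out$n_obs >= min_obs, , drop = FALSE]
  out <- out[order(out$grouping, chothia_key(out$site), out$parent_aa,
                   out$target_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair up reciprocal median cells
#'
#' One result per unordered amino-acid pair per (grouping prefix, site) where
#' both directed medians exist.  For between-group pairings the two
#' directions may come from different grouping labels; `pair_key` controls
#' which part of the grouping must agree (default: the whole label minus the
#' parent amino acid, see [within_family_analysis()]).  Cells whose reverse
#' direction is missing are dropped with a message.
#'
#' @param cells output of [aggregate_medians()].
#' @param pair_key character vector (recycled): cells may pair only within
#'   equal `pair_key`; defaults to a single shared key.
#' @param quiet suppress the unpaired-cell message?
#' @return data.frame with one row per reciprocal pair: `grouping`, `site`,
#'   `aa_a`, `aa_b` (alphabetical), `median_a_to_b`, `median_b_to_a`,
#'   `n_a_to_b`, `n_b_to_a`, `entrenched` (NA until classified).
#' @export
build_reciprocal_pairs <- function(cells, pair_key = NULL, quiet = FALSE) {
  if (is.null(pair_key)) pair_key <- rep("", nrow(cells))
  pair_key <- rep_len(as.character(pair_key), nrow(cells))
  empty <- data.frame(grouping = character(0), site = character(0),
                      aa_a = character(0), aa_b = character(0),
                      median_a_to_b = numeric(0), median_b_to_a = numeric(0),
                      n_a_to_b = integer(0), n_b_to_a = integer(0),
                      entrenched = logical(0), stringsAsFactors = FALSE)
  if (nrow(cells) == 0L) return(empty)
  fwd_key <- paste(pair_key, cells$site, cells$parent_aa, cells$target_aa,
                   sep = "\r")
  rev_key <- paste(pair_key, cells$site, cells$target_aa, cells$parent_aa,
                   sep = "\r")
  j <- match(rev_key, fwd_key)
  unpaired <- is.na(j)
  if (any(unpaired) && !quiet) {
    message(sum(unpaired), " directed median cell(s) lack the reciprocal ",
            "direction and were excluded from pairing")
  }
  keep <- !unpaired & cells$parent_aa < cells$target_aa # one row per pair
  if (!any(keep)) return(empty)
  a <- cells[keep, , drop = FALSE]
  b <- cells[j[keep], , drop = FALSE]
  out <- data.frame(grouping = paste(a$grouping, b$grouping, sep = "|"),
                    site = a$site, aa_a = a$parent_aa, aa_b = a$target_aa,
                    median_a_to_b = a$median_log_f,
                    median_b_to_a = b$median_log_f,
                    n_a_to_b = a$n_obs, n_b_to_a = b$n_obs,
                    entrenched = NA, stringsAsFactors = FALSE)
  out <- out[order(chothia_key(out$site), out$aa_a, out$aa_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify reciprocal pairs as entrenched
#'
#' A pair is entrenched iff BOTH reciprocal medians are strictly below the
#' threshold.  The default threshold -1 corresponds to both substitutions
#' being less than `100 * exp(-1)` (about 37) percent as likely as under
#' neutral evolution.
#'
#' @param pairs output of [build_reciprocal_pairs()].
#' @param threshold natural-log threshold (default -1).
#' @return `pairs` with the `entrenched` flag set.
#' @export
classify_entrenched <- function(pairs, threshold = -1.0) {
  pairs$entrenched <- pairs$median_a_to_b < threshold &
    pairs$median_b_to_a < threshold
  pairs
}

#' Within-family entrenchment analysis
#'
#' Full chain for one V family: filter records, aggregate medians per
#' (family, germline amino acid at site) group -- pooling all V genes in the
#' family that share the same amino acid at the site -- pair up reciprocal
#' directions, classify.
#'
#' @param pcps,sf_records,germlines as in [filter_inference_records()].
#' @param family V-family label present in `germlines$family`.
#' @param min_obs minimum observations per combination (default 10).
#' @param threshold entrenchment threshold (default -1).
#' @return classified pair table (see [build_reciprocal_pairs()]).
#' @export
within_family_analysis <- function(pcps, sf_records, germlines, family,
                                   min_obs = 10L, threshold = -1.0) {
  if (!family %in% germlines$family) stop("unknown family: ", family)
  rec <- filter_inference_records(pcps, sf_records, germlines)
  rec <- rec[rec$family == family, , drop = FALSE]
  # after the germline-codon filter, parent_aa IS the gene's germline amino
  # acid at the site, so (family, parent_aa) defines the germline-state group
  cells <- aggregate_medians(rec, paste(family, rec$parent_aa, sep = ":"),
                             min_obs = min_obs)
  pairs <- build_reciprocal_pairs(cells, quiet = TRUE)
  classify_entrenched(pairs, threshold)
}

#' Between-family entrenchment analysis
#'
#' Considers unordered pairs (A, B) at sites where the two families differ in
#' germline identity: A occurs as a germline amino acid at the site in
#' `family_x` but not in `family_y`, and B in `family_y` but not in
#' `family_x` (amino acids germline in both families at the site are
#' within-family comparisons and are excluded).  Direction A->B is aggregated
#' over `family_x` genes carrying A; B->A over `family_y` genes carrying B.
#'
#' @inheritParams within_family_analysis
#' @param family_x,family_y the two V families.
#' @return classified pair table; `grouping` records the two family:amino
#'   acid groups.
#' @export
between_family_analysis <- function(pcps, sf_records, germlines,
                                    family_x, family_y,
                                    min_obs = 10L, threshold = -1.0) {
  for (f in c(family_x, family_y)) {
    if (!f %in% germlines$family) stop("unknown family: ", f)
  }
  rec <- filter_inference_records(pcps, sf_records, germlines)
  rec <- rec[rec$family %in% c(family_x, family_y), , drop = FALSE]
  cells <- aggregate_medians(rec, paste(rec$family, rec$parent_aa, sep = ":"),
                             min_obs = min_obs)
  if (nrow(cells) == 0L) {
    return(classify_entrenched(build_reciprocal_pairs(cells), threshold))
  }
  cell_fam <- sub(":.*$", "", cells$grouping)
  # germline amino-acid sets per (family, site)
  germ_aa <- germline_site_aas(germlines)
  aa_set <- function(fam, site) {
    germ_aa$aa[germ_aa$family == fam & germ_aa$site == site]
  }
  ok <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    own <- cell_fam[i]
    other <- if (own == family_x) family_y else family_x
    a <- cells$parent_aa[i]; b <- cells$target_aa[i]
    ok[i] <- a %in% aa_set(own, cells$site[i]) &&
      !a %in% aa_set(other, cells$site[i]) &&
      b %in% aa_set(other, cells$site[i]) &&
      !b %in% aa_set(own, cells$site[i])
  }
  cells <- cells[ok, , drop = FALSE]
  pairs <- build_reciprocal_pairs(cells, pair_key = rep("", nrow(cells)),
                                  quiet = TRUE)
  classify_entrenched(pairs, threshold)
}

# Long table of germline amino acids: one row per (family, gene, site, aa).
germline_site_aas <- function(germlines) {
  parts <- lapply(seq_len(nrow(germlines)), function(i) {
    labs <- germlines$site_labels[[i]]
    data.frame(family = germlines$family[i], gene = germlines$name[i],
               site = labs,
               aa = strsplit(germlines$aa_sequence[i], "")[[1]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Shannon entropy of germline amino acids at a site
#'
#' Entropy (natural log) of the amino-acid distribution across a family's
#' reference alleles at one site, one count per allele.
#'
#' @param germlines a `germline_set`.
#' @param family V-family label.
#' @param site Chothia site label; at least one allele must cover it.
#' @return entropy in nats (0 when all alleles agree).
#' @examples
#' # two amino acids at 50/50 give log(2)
#' @export
site_entropy <- function(germlines, family, site) {
  tab <- germline_site_aas(germlines)
  aa <- tab$aa[tab$family == family & tab$site == site]
  if (!length(aa)) stop("no allele of ", family, " covers site ", site)
  p <- table(aa) / length(aa)
  -sum(p * log(p))
}
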