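# Validation of the within-family grouping.
#
# Family-level aggregation pools V genes that share a germline amino acid at
# a site.  To check that pooling is justified, per-V-gene medians are
# computed with the same filters, and their consistency within substitution
# identity (site, parent amino acid, target amino acid) is quantified with a
# one-way random-effects intraclass correlation coefficient and with the
# fraction of individual gene medians that independently cross the
# entrenchment threshold.

#' Per-V-gene median selection factors
#'
#' @param records selection-factor records that already passed
#'   [filter_inference_records()] (they carry `v_gene`).
#' @param min_obs minimum observations per (gene, site, parent_aa,
#'   target_aa) combination (default 3).
#' @return data.frame with columns `v_gene`, `site`, `parent_aa`,
#'   `target_aa`, `median_log_f`, `n_obs`.
#' @export
per_gene_medians <- function(records, min_obs = 3L) {
  out <- aggregate_medians(records, records$v_gene, min_obs = min_obs)
  names(out)[names(out) == "grouping"] <- "v_gene"
  out
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' Partitions variance into between-group and within-group components:
#' `ICC(1) = (MSB - MSW) / (MSB + (n0 - 1) * MSW)` with the unbalanced-design
#' group-size correction `n0 = (N - sum(n_i^2) / N) / (k - 1)`.  Here groups
#' are substitution identities and the replicated values are per-V-gene
#' medians, so ICC near 1 means gene identity contributes almost no
#' variance.  Negative values are reported as computed (within-group
#' dominance), never clamped.
#'
#' @param values numeric vector.
#' @param groups group label per value; at least 2 groups and at least 2
#'   total within-group degrees of freedom are required.
#' @return ICC(1), a number in (-Inf, 1].
#' @examples
#' icc_oneway(c(0, 0, 1, 1), c("a", "a", "b", "b")) # 1
#' icc_oneway(c(0, 1, 0, 1), c("a", "a", "b", "b")) # -1
#' @export
icc_oneway <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  sp <- split(values, groups)
  k <- length(sp)
  if (k < 2L) stop("need at least 2 groups")
  ni <- lengths(sp)
  N <- sum(ni)
  if (N - k < 2L) stop("need at least 2 within-group degrees of freedom")
  gm <- mean(values)
  mi <- vapply(sp, mean, 0)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum(vapply(sp, function(v) sum((v - mean(v))^2), 0))
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  if (msb == 0 && msw == 0) stop("all values identical: ICC undefined")
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

#' Threshold agreement of per-gene medians at entrenched combinations
#'
#' Restricts gene-level medians to the directed substitutions that belong to
#' family-level entrenched pairs and reports the fraction that independently
#' fall below the threshold.
#'
#' @param gene_medians output of [per_gene_medians()].
#' @param entrenched_pairs classified pair table (only rows with
#'   `entrenched == TRUE` are used).
#' @param threshold entrenchment threshold (default -1).
#' @return fraction in `[0, 1]`; an empty eligible set is an error.
#' @export
threshold_agreement <- function(gene_medians, entrenched_pairs,
                                threshold = -1.0) {
  ep <- entrenched_pairs[isTRUE_v(entrenched_pairs$entrenched), , drop = FALSE]
  dir_key <- c(paste(ep$site, ep$aa_a, ep$aa_b, sep = "\r"),
               paste(ep$site, ep$aa_b, ep$aa_a, sep = "\r"))
  gk <- paste(gene_medians$site, gene_medians$parent_aa,
              gene_medians$target_aa, sep = "\r")
  eligible <- gene_medians[gk %in% dir_key, , drop = FALSE]
  if (nrow(eligible) == 0L) {
    stop("no gene medians at family-level entrenched combinations")
  }
  mean(eligible$median_log_f < threshold)
}

isTRUE_v <- function(x) !is.na(x) & x
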