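# Observed-vs-expected mutation-rate validation.
#
# Selection factors predict how much a substitution's probability is shifted
# relative to neutral, so for small per-site mutation probabilities the
# observed/expected rate ratio should approximate the selection factor.  Two
# complementary baselines are implemented:
#   Approach 1: out-of-frame sequences as empirical neutral baseline, with
#     synonymous-mutation branch lengths as exposure on both sides.
#   Approach 2: expected counts from the neutral mutation model itself, with
#     total-mutation branch lengths scaled by alpha (default 1.6, i.e.
#     observed mutations are ~1/1.6 = 0.63 of the neutral expectation once
#     purifying selection has removed its share); branch lengths then cancel
#     in the ratio so counts are compared directly.
# Counts condition on the parent retaining the germline amino acid at the
# site (amino-acid identity at the codon, deliberately weaker than the
# nucleotide-identity filter used for selection-factor aggregation, because
# the PCP set is defined by the parent's amino-acid state).  Both pseudocount
# smoothing (0.5) and the minimum-baseline filters act exactly as stated:
# smoothing on the counts entering the ratio, filters on raw counts.

# ---- per-PCP branch lengths ------------------------------------------------

#' Synonymous-mutation branch length of a PCP
#'
#' Number of nucleotide differences lying in codons whose amino acid is
#' unchanged between parent and child, divided by sequence length.  Synonymy
#' is classified at codon level: all differences in a codon count iff the
#' codon's amino acid is unchanged (per-nucleotide attribution is ill-defined
#' for multi-hit codons).
#'
#' @param pcp one PCP (one-row data.frame or list with `parent_nt`,
#'   `child_nt`); ambiguous bases are an error.
#' @return branch length, a fraction >= 0.
#' @examples
#' synonymous_branch_length(list(parent_nt = "ATGAAA", child_nt = "ATGAAG"))
#' @export
synonymous_branch_length <- function(pcp) {
  p <- nt_to_int(pcp$parent_nt[[1]])
  c <- nt_to_int(pcp$child_nt[[1]])
  if (anyNA(p) || anyNA(c)) stop("ambiguous base in PCP sequences")
  if (length(p) != length(c)) stop("parent/child length mismatch")
  d <- p != c
  pa <- .ab$aa64_int[seq_codon_indices(p)]
  ca <- .ab$aa64_int[seq_codon_indices(c)]
  syn_codon <- pa == ca
  sum(d & rep(syn_codon, each = 3L)) / length(p)
}

#' Scaled total-mutation branch length of a PCP
#'
#' Total nucleotide mutation frequency multiplied by `alpha`; `alpha = 1`
#' recovers the raw frequency.
#'
#' @inheritParams synonymous_branch_length
#' @param alpha scaling factor correcting the observed frequency back to the
#'   neutral scale (default 1.6).
#' @return branch length >= 0.
#' @export
scaled_branch_length <- function(pcp, alpha = 1.6) {
  p <- nt_to_int(pcp$parent_nt[[1]])
  c <- nt_to_int(pcp$child_nt[[1]])
  if (length(p) != length(c)) stop("parent/child length mismatch")
  sum(p != c, na.rm = TRUE) / length(p) * alpha
}

# ---- internal vectorized per-gene machinery --------------------------------

# Integer sequence matrix (n x nt) for equal-length sequences.
seq_matrix <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(integer(0), 0, 0))
  width <- nchar(seqs[1])
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                    .ab_bases),
              nrow = n, ncol = width, byrow = TRUE)
  m
}

# Amino-acid integer matrix (n x L) from a base matrix.
aa_matrix <- function(m) {
  n <- nrow(m); L <- ncol(m) %/% 3L
  idx <- 16L * (m[, seq(1L, by = 3L, length.out = L), drop = FALSE] - 1L) +
    4L * (m[, seq(2L, by = 3L, length.out = L), drop = FALSE] - 1L) +
    m[, seq(3L, by = 3L, length.out = L), drop = FALSE]
  matrix(.ab$aa64_int[idx], n, L)
}

# Drop PCPs containing ambiguous bases; message when any are removed.
drop_ambiguous <- function(pcps, quiet = TRUE) {
  hasN <- grepl("N", pcps$parent_nt, fixed = TRUE) |
    grepl("N", pcps$child_nt, fixed = TRUE)
  if (any(hasN) && !quiet) {
    message("removed ", sum(hasN), " PCP(s) with ambiguous nucleotides")
  }
  pcps[!hasN, , drop = FALSE]
}

# ---- substitution counting -------------------------------------------------

#' Count amino-acid substitutions per (family, site, A, B)
#'
#' For each V family, site, germline amino acid A and target amino acid B,
#' counts the PCPs where the parent has germline amino acid A at the site
#' (amino-acid identity at the codon) and the child amino acid is B, and sums
#' the branch lengths of ALL PCPs whose parent has A there (the exposure).
#' Stop-codon outcomes are excluded as targets.  Rows are emitted for every
#' target reachable from a germline codon by a single nucleotide change
#' (count 0 if unobserved) plus any additionally observed substitution.
#' Productive counting excludes PCPs whose child is a leaf (mutations are
#' then known to have survived further selection); out-of-frame counting
#' keeps every PCP.  PCPs containing N are removed before counting.
#'
#' @param pcps PCP table.
#' @param germlines a `germline_set`.
#' @param dataset_role `"productive"` (exclude leaf children) or
#'   `"out_of_frame"` (include all PCPs).
#' @param branch_length `"synonymous"` (rate denominators, Approach 1) or
#'   `"scaled"` (Approach 2 bookkeeping).
#' @param alpha scaling for `branch_length = "scaled"`.
#' @return data.frame with columns `family`, `site`, `parent_aa`,
#'   `target_aa`, `count`, `exposure`.
#' @export
count_substitutions <- function(pcps, germlines,
                                dataset_role = c("productive", "out_of_frame"),
                                branch_length = c("synonymous", "scaled"),
                                alpha = 1.6) {
  dataset_role <- match.arg(dataset_role)
  branch_length <- match.arg(branch_length)
  pcps <- drop_ambiguous(pcps)
  if (dataset_role == "productive") {
    pcps <- pcps[!pcps$is_leaf_child, , drop = FALSE]
  }
  acc <- new.env(parent = emptyenv()) # key family\rsite\rA\rB -> count
  expo <- new.env(parent = emptyenv()) # key family\rsite\rA -> exposure
  add <- function(env, key, x) {
    assign(key, (if (exists(key, envir = env)) get(key, envir = env) else 0) + x,
           envir = env)
  }
  for (g in unique(pcps$v_gene)) {
    gi <- match(g, germlines$name)
    if (is.na(gi)) stop("unknown germline gene: ", g)
    fam <- germlines$family[gi]
    labs <- germlines$site_labels[[gi]]
    sub <- pcps[pcps$v_gene == g, , drop = FALSE]
    gaa <- .ab$aa64_int[seq_codon_indices(nt_to_int(germlines$nt_sequence[gi]))]
    gcod <- seq_codon_indices(nt_to_int(germlines$nt_sequence[gi]))
    L <- length(gaa)
    # reachable-target grid rows (zero counts)
    for (j in seq_len(L)) {
      for (b in .ab$reachable_aas[[gcod[j]]]) {
        add(acc, paste(fam, labs[j], .ab$aa_letters[gaa[j]], b, sep = "\r"), 0)
      }
    }
    if (nrow(sub) == 0L) {
      for (j in seq_len(L)) {
        add(expo, paste(fam, labs[j], .ab$aa_letters[gaa[j]], sep = "\r"), 0)
      }
      next
    }
    P <- seq_matrix(sub$parent_nt)
    C <- seq_matrix(sub$child_nt)
    Pa <- aa_matrix(P)
    Ca <- aa_matrix(C)
    D <- P != C
    ntdiff_codon <- D[, seq(1L, by = 3L, length.out = L), drop = FALSE] +
      D[, seq(2L, by = 3L, length.out = L), drop = FALSE] +
      D[, seq(3L, by = 3L, length.out = L), drop = FALSE]
    if (branch_length == "synonymous") {
      bl <- rowSums(ntdiff_codon * (Pa == Ca)) / ncol(P)
    } else {
      bl <- rowSums(D) / ncol(P) * alpha
    }
    retains <- Pa == matrix(gaa, nrow(P), L, byrow = TRUE)
    for (j in seq_len(L)) {
      keyA <- paste(fam, labs[j], .ab$aa_letters[gaa[j]], sep = "\r")
      rj <- retains[, j]
      add(expo, keyA, sum(bl[rj]))
      hit <- rj & Ca[, j] != Pa[, j] & Ca[, j] != 21L
      if (any(hit)) {
        tb <- table(Ca[hit, j])
        for (t in names(tb)) {
          add(acc, paste(fam, labs[j], .ab$aa_letters[gaa[j]],
                         .ab$aa_letters[as.integer(t)], sep = "\r"),
              as.numeric(tb[[t]]))
        }
      }
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(family = vapply(parts, `[`, "", 1L),
                    site = vapply(parts, `[`, "", 2L),
                    parent_aa = vapply(parts, `[`, "", 3L),
                    target_aa = vapply(parts, `[`, "", 4L),
                    count = vapply(keys, function(k) get(k, envir = acc), 0),
                    stringsAsFactors = FALSE)
  ek <- paste(out$family, out$site, out$parent_aa, sep = "\r")
  out$exposure <- vapply(ek, function(k) {
    if (exists(k, envir = expo)) get(k, envir = expo) else 0
  }, 0)
  out <- out[order(out$family, chothia_key(out$site), out$parent_aa,
                   out$target_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Substitution rate from a count record
#'
#' @param counts data.frame with `count` and `exposure` columns.
#' @return `counts` with a `rate = count / exposure` column; rows with zero
#'   exposure are excluded with a message.
#' @export
rate_from_counts <- function(counts) {
  zero <- counts$exposure == 0
  if (any(zero)) {
    message("excluded ", sum(zero), " substitution(s) with zero exposure")
    counts <- counts[!zero, , drop = FALSE]
  }
  counts$rate <- counts$count / counts$exposure
  counts
}

# ---- Approach 1: out-of-frame baseline -------------------------------------

#' Approach-1 rate ratios (out-of-frame neutral baseline)
#'
#' `log_ratio = log[((obs + ps)/obs_exposure) / ((oof + ps)/oof_exposure)]`
#' with pseudocount `ps` added to both counts; `passed_filter` requires at
#' least `min_baseline` RAW out-of-frame mutations.  Substitutions with zero
#' exposure on either side are excluded.
#'
#' @param productive_counts,oof_counts outputs of [count_substitutions()]
#'   with synonymous branch lengths.
#' @param pseudocount smoothing constant (default 0.5).
#' @param min_baseline minimum raw out-of-frame count (default 5).
#' @return rate-ratio records: `family`, `site`, `parent_aa`, `target_aa`,
#'   `observed`, `expected`, `log_ratio`, `passed_filter`, `approach`.
#' @export
approach1_ratios <- function(productive_counts, oof_counts,
                             pseudocount = 0.5, min_baseline = 5) {
  key <- function(d) paste(d$family, d$site, d$parent_aa, d$target_aa,
                           sep = "\r")
  j <- match(key(productive_counts), key(oof_counts))
  ok <- !is.na(j)
  p <- productive_counts[ok, , drop = FALSE]
  o <- oof_counts[j[ok], , drop = FALSE]
  keep <- p$exposure > 0 & o$exposure > 0
  if (any(!keep)) {
    message("excluded ", sum(!keep), " substitution(s) with zero exposure")
  }
  p <- p[keep, , drop = FALSE]; o <- o[keep, , drop = FALSE]
  out <- data.frame(family = p$family, site = p$site,
                    parent_aa = p$parent_aa, target_aa = p$target_aa,
                    observed = p$count, expected = o$count,
                    log_ratio = log(((p$count + pseudocount) / p$exposure) /
                                      ((o$count + pseudocount) / o$exposure)),
                    passed_filter = o$count >= min_baseline,
                    approach = 1L, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# ---- Approach 2: neutral-model expected counts -----------------------------

# Pentamer cache: for a codon with one flanking base on each side (4^5 =
# 1024 states), the codon-level neutral rate, the distribution of
# single-nucleotide outcomes over amino-acid targets (rho, a 1024 x 21
# matrix whose rows sum to 1 across synonymous, nonsynonymous and stop
# outcomes), and the synonymous fraction.  Filled lazily per unique state;
# lookups are then plain vector indexing.
pentamer_tables <- function(neutral) {
  env <- new.env(parent = emptyenv())
  env$lam <- rep(NA_real_, 1024L)
  env$syn <- rep(NA_real_, 1024L)
  env$rho <- matrix(NA_real_, 1024L, 21L)
  env$ensure <- function(pids) {
    for (pid in unique(pids[is.na(env$lam[pids])])) {
      b <- integer(5)
      x <- pid - 1L
      for (i in 5:1) { b[i] <- x %% 4L + 1L; x <- x %/% 4L }
      cod <- b[2:4]
      ctx_idx <- c(16L * (b[1] - 1L) + 4L * (b[2] - 1L) + b[3],
                   16L * (b[2] - 1L) + 4L * (b[3] - 1L) + b[4],
                   16L * (b[3] - 1L) + 4L * (b[4] - 1L) + b[5])
      lam <- neutral$rate64[ctx_idx]
      lam_tot <- sum(lam)
      a0 <- .ab$aa64_int[bases_to_codon_index(cod)]
      rho <- numeric(21)
      for (p in 1:3) for (nb in (1:4)[-cod[p]]) {
        cc <- cod; cc[p] <- nb
        a1 <- .ab$aa64_int[bases_to_codon_index(cc)]
        rho[a1] <- rho[a1] + lam[p] / lam_tot * neutral$probs64[ctx_idx[p], nb]
      }
      env$lam[pid] <- lam_tot
      env$syn[pid] <- rho[a0]
      env$rho[pid, ] <- rho
    }
    invisible(NULL)
  }
  env
}

# pentamer ids (1..1024) for every codon of each row of a base matrix,
# sequence ends padded with A.
pentamer_ids <- function(m) {
  n <- nrow(m); L <- ncol(m) %/% 3L
  prev <- cbind(1L, m[, seq(3L, by = 3L, length.out = L - 1L), drop = FALSE])
  nxt <- cbind(m[, seq(4L, by = 3L, length.out = L - 1L), drop = FALSE], 1L)
  b1 <- m[, seq(1L, by = 3L, length.out = L), drop = FALSE]
  b2 <- m[, seq(2L, by = 3L, length.out = L), drop = FALSE]
  b3 <- m[, seq(3L, by = 3L, length.out = L), drop = FALSE]
  (prev - 1L) * 256L + (b1 - 1L) * 64L + (b2 - 1L) * 16L + (b3 - 1L) * 4L +
    nxt
}

#' Neutral-model expected substitution counts
#'
#' For every PCP whose parent has germline amino acid A at a site, the
#' probability that the site mutates is `p_mut = 1 - exp(-lambda * t)` with
#' `lambda` the sum of the three per-nucleotide neutral rates of the parent
#' codon and `t` the scaled total-mutation branch length; the conditional
#' amino-acid outcome distribution sums the per-base substitution
#' probabilities over the parent codon's single-nucleotide neighbors
#' (synonymous and stop outcomes complete the normalization but are not
#' emitted).  Expected counts sum `p_mut * P(B|A)` over the same leaf-free,
#' N-free productive PCP set used for observed counting.
#'
#' @param pcps productive PCP table.
#' @param neutral a `neutral_model`.
#' @param germlines a `germline_set`.
#' @param alpha branch-length scaling (default 1.6).
#' @return data.frame `family`, `site`, `parent_aa`, `target_aa`,
#'   `expected` (real-valued).
#' @export
expected_counts <- function(pcps, neutral, germlines, alpha = 1.6) {
  pcps <- drop_ambiguous(pcps)
  pcps <- pcps[!pcps$is_leaf_child, , drop = FALSE]
  pent <- pentamer_tables(neutral)
  acc <- new.env(parent = emptyenv())
  add <- function(key, x) {
    assign(key, (if (exists(key, envir = acc)) get(key, envir = acc) else 0) + x,
           envir = acc)
  }
  for (g in unique(pcps$v_gene)) {
    gi <- match(g, germlines$name)
    if (is.na(gi)) stop("unknown germline gene: ", g)
    fam <- germlines$family[gi]
    labs <- germlines$site_labels[[gi]]
    sub <- pcps[pcps$v_gene == g, , drop = FALSE]
    if (nrow(sub) == 0L) next
    gaa <- .ab$aa64_int[seq_codon_indices(nt_to_int(germlines$nt_sequence[gi]))]
    L <- length(gaa)
    P <- seq_matrix(sub$parent_nt)
    C <- seq_matrix(sub$child_nt)
    Pa <- aa_matrix(P)
    t_i <- rowSums(P != C) / ncol(P) * alpha
    pid <- pentamer_ids(P)
    pent$ensure(as.integer(unique(as.vector(pid))))
    retains <- Pa == matrix(gaa, nrow(P), L, byrow = TRUE)
    for (j in seq_len(L)) {
      rj <- which(retains[, j])
      if (!length(rj)) next
      pj <- pid[rj, j]
      pm <- 1 - exp(-pent$lam[pj] * t_i[rj]) # per-PCP site mutation prob
      pm_by_pid <- rowsum(pm, pj)            # grouped by pentamer state
      pids <- as.integer(rownames(pm_by_pid))
      rho_acc <- colSums(pm_by_pid[, 1L] * pent$rho[pids, , drop = FALSE])
      A <- .ab$aa_letters[gaa[j]]
      for (b in which(rho_acc > 0)) {
        if (b == 21L || b == gaa[j]) next
        add(paste(fam, labs[j], A, .ab$aa_letters[b], sep = "\r"), rho_acc[b])
      }
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(family = vapply(parts, `[`, "", 1L),
                    site = vapply(parts, `[`, "", 2L),
                    parent_aa = vapply(parts, `[`, "", 3L),
                    target_aa = vapply(parts, `[`, "", 4L),
                    expected = vapply(keys, function(k) get(k, envir = acc), 0),
                    stringsAsFactors = FALSE)
  out <- out[order(out$family, chothia_key(out$site), out$parent_aa,
                   out$target_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Approach-2 rate ratios (neutral-model expected counts)
#'
#' Branch lengths cancel in the ratio, so counts are compared directly:
#' `log_ratio = log((obs + ps)/(exp + ps))`; `passed_filter` requires raw
#' expected >= `min_expected`.
#'
#' @param observed_counts [count_substitutions()] output on the productive
#'   data (leaf-excluded).
#' @param expected [expected_counts()] output on the same PCP set.
#' @param pseudocount smoothing constant (default 0.5).
#' @param min_expected minimum raw expected count (default 5).
#' @return rate-ratio records as in [approach1_ratios()] with `approach = 2`.
#' @export
approach2_ratios <- function(observed_counts, expected,
                             pseudocount = 0.5, min_expected = 5) {
  key <- function(d) paste(d$family, d$site, d$parent_aa, d$target_aa,
                           sep = "\r")
  j <- match(key(observed_counts), key(expected))
  ok <- !is.na(j)
  p <- observed_counts[ok, , drop = FALSE]
  e <- expected[j[ok], , drop = FALSE]
  out <- data.frame(family = p$family, site = p$site,
                    parent_aa = p$parent_aa, target_aa = p$target_aa,
                    observed = p$count, expected = e$expected,
                    log_ratio = log((p$count + pseudocount) /
                                      (e$expected + pseudocount)),
                    passed_filter = e$expected >= min_expected,
                    approach = 2L, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Estimate the branch-length scaling alpha from data
#'
#' Mirrors the published derivation of alpha (observed mutation frequencies
#' regressed against selection-corrected branch lengths) using synonymous
#' mutations as the anchor: for each PCP the neutral model gives the ratio of
#' total to synonymous mutation rate on the parent sequence, so the
#' synonymous count predicts the neutral total; alpha is the summed neutral
#' prediction over the summed observed total.  Under neutral evolution alpha
#' is 1; purifying selection (including stop-codon removal) pushes it above
#' 1.
#'
#' @param pcps productive PCP table (all rows are used).
#' @param neutral a `neutral_model`.
#' @param germlines a `germline_set`.
#' @return estimated alpha (> 0).
#' @export
estimate_alpha <- function(pcps, neutral, germlines) {
  pcps <- drop_ambiguous(pcps)
  pent <- pentamer_tables(neutral)
  num <- 0; den <- 0
  for (g in unique(pcps$v_gene)) {
    sub <- pcps[pcps$v_gene == g, , drop = FALSE]
    if (nrow(sub) == 0L) next
    P <- seq_matrix(sub$parent_nt)
    C <- seq_matrix(sub$child_nt)
    Pa <- aa_matrix(P)
    Ca <- aa_matrix(C)
    L <- ncol(Pa)
    D <- P != C
    ntdiff_codon <- D[, seq(1L, by = 3L, length.out = L), drop = FALSE] +
      D[, seq(2L, by = 3L, length.out = L), drop = FALSE] +
      D[, seq(3L, by = 3L, length.out = L), drop = FALSE]
    syn_i <- rowSums(ntdiff_codon * (Pa == Ca))
    tot_i <- rowSums(D)
    # neutral total and synonymous rates per parent sequence
    pid <- pentamer_ids(P)
    pent$ensure(as.integer(unique(as.vector(pid))))
    lam_mat <- matrix(pent$lam[pid], nrow(P), L)
    syn_mat <- matrix(pent$syn[pid], nrow(P), L)
    lam_tot <- rowSums(lam_mat)
    lam_syn <- rowSums(lam_mat * syn_mat)
    R_i <- lam_tot / lam_syn
    num <- num + sum(syn_i * R_i)
    den <- den + sum(tot_i)
  }
  if (den == 0) stop("no observed mutations: cannot estimate alpha")
  num / den
}

# ---- comparison to selection factors ---------------------------------------

#' Deming (orthogonal, lambda = 1) regression
#'
#' Fits the line minimizing summed squared perpendicular distances, the
#' appropriate comparison when both variables carry error.  Swapping x and y
#' inverts the slope.
#'
#' @param x,y numeric vectors (>= 3 points).
#' @return list with `slope` and `intercept`.
#' @export
deming_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 points")
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0 || sxx == 0 || syy == 0) {
    stop("degenerate variance: Deming fit undefined")
  }
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Compare rate ratios with median selection factors
#'
#' Joins rate-ratio records with median cells on (family, site, parent_aa,
#' target_aa) and summarizes the agreement with the Pearson correlation and a
#' Deming (lambda = 1) orthogonal regression of log ratio on median log
#' selection factor.
#'
#' @param ratio_records output of [approach1_ratios()] or
#'   [approach2_ratios()]; only rows with `passed_filter` are used.
#' @param cells [aggregate_medians()] output whose grouping labels are
#'   `family:parent_aa` (as produced by [within_family_analysis()]'s
#'   aggregation), or any data.frame with a `family` column plus `site`,
#'   `parent_aa`, `target_aa`, `median_log_f`.
#' @return list with `pearson_r`, `deming_slope`, `deming_intercept`, `n`
#'   and the joined data.frame `points`.
#' @export
compare_to_selection <- function(ratio_records, cells) {
  if (!"family" %in% names(cells)) {
    cells$family <- sub(":.*$", "", cells$grouping)
  }
  rr <- ratio_records[ratio_records$passed_filter, , drop = FALSE]
  key <- function(d) paste(d$family, d$site, d$parent_aa, d$target_aa,
                           sep = "\r")
  j <- match(key(rr), key(cells))
  ok <- !is.na(j)
  pts <- data.frame(rr[ok, , drop = FALSE],
                    median_log_f = cells$median_log_f[j[ok]],
                    stringsAsFactors = FALSE)
  if (nrow(pts) < 3L) stop("fewer than 3 joined points")
  fit <- deming_fit(pts$median_log_f, pts$log_ratio)
  list(pearson_r = stats::cor(pts$median_log_f, pts$log_ratio),
       deming_slope = fit$slope, deming_intercept = fit$intercept,
       n = nrow(pts), points = pts)
}

#' Reciprocal-pair agreement between rate ratios and entrenchment calls
#'
#' For each entrenched pair, looks up the filtered rate ratios of both
#' directions within the pair's family and reports whether both fall below
#' each threshold; pairs missing a filtered ratio in either direction are
#' flagged `insufficient_data`.
#'
#' @param ratio_records rate-ratio records.
#' @param entrenched_results classified pair table (rows with
#'   `entrenched == TRUE` are summarized); `grouping` must start with
#'   `family:`.
#' @param thresholds numeric thresholds (default -0.5 and -1).
#' @return per-pair data.frame with the two log ratios, an
#'   `insufficient_data` flag and one `both_below_<t>` indicator per
#'   threshold.
#' @export
reciprocal_pair_summary <- function(ratio_records, entrenched_results,
                                    thresholds = c(-0.5, -1.0)) {
  ep <- entrenched_results[isTRUE_v(entrenched_results$entrenched), ,
                           drop = FALSE]
  rr <- ratio_records[ratio_records$passed_filter, , drop = FALSE]
  rk <- paste(rr$family, rr$site, rr$parent_aa, rr$target_aa, sep = "\r")
  n <- nrow(ep)
  fam <- sub(":.*$", "", ep$grouping)
  r_ab <- rep(NA_real_, n); r_ba <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    i1 <- match(paste(fam[i], ep$site[i], ep$aa_a[i], ep$aa_b[i], sep = "\r"), rk)
    i2 <- match(paste(fam[i], ep$site[i], ep$aa_b[i], ep$aa_a[i], sep = "\r"), rk)
    if (!is.na(i1)) r_ab[i] <- rr$log_ratio[i1]
    if (!is.na(i2)) r_ba[i] <- rr$log_ratio[i2]
  }
  out <- data.frame(family = fam, site = ep$site, aa_a = ep$aa_a,
                    aa_b = ep$aa_b, log_ratio_a_to_b = r_ab,
                    log_ratio_b_to_a = r_ba,
                    insufficient_data = is.na(r_ab) | is.na(r_ba),
                    stringsAsFactors = FALSE)
  for (t in thresholds) {
    out[[sprintf("both_below_%g", t)]] <-
      ifelse(out$insufficient_data, NA, r_ab < t & r_ba < t)
  }
  out
}
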