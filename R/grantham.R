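# Grantham physicochemical distances and the stratified permutation test.
#
# Grantham's distance combines composition (c), polarity (p) and molecular
# volume (v) differences:
#   D = 50.723 * sqrt(1.833 (dc)^2 + 0.1018 (dp)^2 + 0.000399 (dv)^2)
# with the constant scaling the mean over all pairs to 100; rounding to
# integers reproduces the published 20 x 20 matrix.

.grantham_props <- data.frame(
  aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
         "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
  c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
        0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
  p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
        6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
  v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
        136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
  stringsAsFactors = FALSE)

.grantham_matrix_cache <- new.env(parent = emptyenv())

#' The Grantham distance matrix
#'
#' @return 20 x 20 integer-valued symmetric matrix (one-letter codes),
#'   computed from the published composition/polarity/volume properties and
#'   constants.
#' @export
grantham_matrix <- function() {
  if (!is.null(.grantham_matrix_cache$m)) return(.grantham_matrix_cache$m)
  p <- .grantham_props
  n <- nrow(p)
  m <- matrix(0, n, n, dimnames = list(p$aa, p$aa))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    m[i, j] <- round(50.723 * sqrt(1.833 * (p$c[i] - p$c[j])^2 +
                                     0.1018 * (p$p[i] - p$p[j])^2 +
                                     0.000399 * (p$v[i] - p$v[j])^2))
  }
  .grantham_matrix_cache$m <- m
  m
}

#' Grantham distance between amino acids
#'
#' @param aa1,aa2 one-letter amino-acid codes (vectors recycled).
#' @return numeric distances (>= 0, symmetric, 0 iff identical); non-standard
#'   residues are an error.
#' @examples
#' grantham_distance("L", "I") # 5
#' grantham_distance("S", "T") # 58
#' @export
grantham_distance <- function(aa1, aa2) {
  m <- grantham_matrix()
  n <- max(length(aa1), length(aa2))
  aa1 <- rep_len(toupper(aa1), n)
  aa2 <- rep_len(toupper(aa2), n)
  i <- match(aa1, rownames(m)); j <- match(aa2, colnames(m))
  if (anyNA(i) || anyNA(j)) {
    stop("non-standard residue(s): ",
         paste(unique(c(aa1[is.na(i)], aa2[is.na(j)])), collapse = ", "))
  }
  m[cbind(i, j)]
}

#' Stratified permutation test of entrenched-vs-other Grantham distances
#'
#' The statistic is the mean, over strata containing both labels, of
#' (mean distance of entrenched pairs - mean distance of non-entrenched
#' pairs); single-label strata are excluded from both observed and permuted
#' statistics (their difference is undefined) with a message.  Labels are
#' shuffled independently within each stratum.  The one-sided p-value is the
#' plain proportion of permuted statistics greater than or equal to the
#' observed one (no +1 correction).  With `exact = TRUE` all distinct
#' label assignments are enumerated instead of sampled.
#'
#' @param inputs data.frame with columns `stratum`, `distance` (>= 0) and
#'   `entrenched` (logical).
#' @param n_perm number of Monte Carlo permutations (default 10000).
#' @param seed integer seed for the Monte Carlo draw.
#' @param exact enumerate all label assignments exhaustively (error if more
#'   than `max_exact`).
#' @param max_exact enumeration budget (default 1e6 assignments).
#' @return list with `observed`, `p`, `n_perm` (or number of enumerated
#'   assignments) and `n_strata` (eligible strata).
#' @export
stratified_permutation_test <- function(inputs, n_perm = 10000L, seed = 1L,
                                        exact = FALSE, max_exact = 1e6) {
  stopifnot(all(c("stratum", "distance", "entrenched") %in% names(inputs)))
  sp <- split(inputs[, c("distance", "entrenched")],
              as.character(inputs$stratum))
  both <- vapply(sp, function(d) any(d$entrenched) && any(!d$entrenched),
                 NA)
  if (!any(both)) stop("no stratum contains both labels")
  if (any(!both)) {
    message(sum(!both), " single-label stratum/strata excluded")
  }
  sp <- sp[both]
  stat_of <- function(labels_list) {
    diffs <- vapply(seq_along(sp), function(s) {
      d <- sp[[s]]$distance
      lab <- labels_list[[s]]
      mean(d[lab]) - mean(d[!lab])
    }, 0)
    mean(diffs)
  }
  obs_labels <- lapply(sp, `[[`, "entrenched")
  observed <- stat_of(obs_labels)
  if (exact) {
    combos <- lapply(sp, function(d) {
      k <- sum(d$entrenched)
      utils::combn(length(d$entrenched), k, simplify = FALSE)
    })
    total <- prod(vapply(combos, length, 0))
    if (total > max_exact) {
      stop("exact enumeration too large (", total, " assignments)")
    }
    grid <- expand.grid(lapply(combos, seq_along))
    perm_stats <- vapply(seq_len(nrow(grid)), function(r) {
      labs <- lapply(seq_along(sp), function(s) {
        v <- rep(FALSE, nrow(sp[[s]]))
        v[combos[[s]][[grid[r, s]]]] <- TRUE
        v
      })
      stat_of(labs)
    }, 0)
    n_used <- length(perm_stats)
  } else {
    set.seed(derive_seed(seed, "grantham_perm"))
    perm_stats <- vapply(seq_len(n_perm), function(b) {
      labs <- lapply(sp, function(d) sample(d$entrenched))
      stat_of(labs)
    }, 0)
    n_used <- n_perm
  }
  list(observed = observed,
       p = mean(perm_stats >= observed),
       n_perm = n_used,
       n_strata = length(sp))
}
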