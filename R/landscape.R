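# Planted amino-acid selection landscapes.
#
# A landscape assigns a natural-log selection factor to every directed
# substitution (site, parent amino acid -> target amino acid), optionally
# with per-gene overrides.  It is the ground truth the synthetic repertoire
# evolves under and the oracle that downstream aggregation is checked
# against.  Values <= 0 mean purifying selection; a substitution is accepted
# during simulation with probability min(1, exp(log_f)), so for deleterious
# changes the realized observed/expected rate ratio converges to exp(log_f).

#' Construct a selection landscape
#'
#' Base values for every directed substitution are drawn i.i.d. from
#' `Uniform(base_range[1], base_range[2])` (default purifying-only, away from
#' the -1 entrenchment threshold), or set to 0 with `base = "zero"` for a
#' fully neutral landscape.  Designated entrenched site/amino-acid pairs are
#' planted with `planted_log_f` in both directions; both must lie below -1.
#'
#' @param sites character vector of Chothia site labels the landscape covers.
#' @param base `"uniform"` or `"zero"`.
#' @param base_range length-2 numeric, bounds of the base draw.
#' @param entrenched_pairs `NULL` or data.frame with columns `site`, `aa_a`,
#'   `aa_b` (one planted reciprocal pair per row).
#' @param planted_log_f value planted in both directions of each entrenched
#'   pair; must be < -1.
#' @param gene_overrides `NULL` or data.frame with columns `gene`, `site`,
#'   `parent_aa`, `target_aa`, `log_f` replacing individual values for
#'   individual genes (used to plant outlier genes).
#' @param seed integer seed for the base draw.
#' @return object of class `selection_landscape`.
#' @export
make_selection_landscape <- function(sites,
                                     base = c("uniform", "zero"),
                                     base_range = c(-0.9, 0),
                                     entrenched_pairs = NULL,
                                     planted_log_f = -1.5,
                                     gene_overrides = NULL,
                                     seed = 1L) {
  base <- match.arg(base)
  sites <- as.character(sites)
  aa <- .ab$aa_letters
  arr <- array(0, dim = c(length(sites), 20L, 20L),
               dimnames = list(sites, aa, aa))
  if (base == "uniform") {
    stopifnot(length(base_range) == 2L, base_range[1] <= base_range[2])
    set.seed(derive_seed(seed, "landscape_base"))
    arr[] <- stats::runif(length(arr), base_range[1], base_range[2])
  }
  for (s in seq_along(sites)) arr[s, , ][cbind(1:20, 1:20)] <- 0
  if (!is.null(entrenched_pairs) && nrow(entrenched_pairs)) {
    if (planted_log_f >= -1) {
      stop("planted entrenched pairs must have log_f < -1 in both directions")
    }
    for (i in seq_len(nrow(entrenched_pairs))) {
      e <- entrenched_pairs[i, ]
      if (!e$site %in% sites) stop("entrenched site ", e$site, " not in sites")
      arr[e$site, e$aa_a, e$aa_b] <- planted_log_f
      arr[e$site, e$aa_b, e$aa_a] <- planted_log_f
    }
    entrenched_pairs <- data.frame(site = as.character(entrenched_pairs$site),
                                   aa_a = entrenched_pairs$aa_a,
                                   aa_b = entrenched_pairs$aa_b,
                                   stringsAsFactors = FALSE)
  }
  gene_arrs <- list()
  if (!is.null(gene_overrides) && nrow(gene_overrides)) {
    for (g in unique(gene_overrides$gene)) {
      ga <- arr
      ov <- gene_overrides[gene_overrides$gene == g, ]
      for (i in seq_len(nrow(ov))) {
        ga[ov$site[i], ov$parent_aa[i], ov$target_aa[i]] <- ov$log_f[i]
      }
      gene_arrs[[g]] <- ga
    }
  }
  structure(list(sites = sites, arr = arr, gene_arrs = gene_arrs,
                 entrenched_spec = entrenched_pairs,
                 planted_log_f = if (is.null(entrenched_pairs)) NULL else planted_log_f),
            class = "selection_landscape")
}

# Landscape array for one gene (base array unless the gene has overrides).
landscape_array <- function(landscape, gene = NULL) {
  if (!is.null(gene) && !is.null(landscape$gene_arrs[[gene]])) {
    landscape$gene_arrs[[gene]]
  } else {
    landscape$arr
  }
}

#' Query a selection landscape
#'
#' @param landscape a `selection_landscape`.
#' @param site,parent_aa,target_aa vectors (recycled to common length).
#' @param gene optional single gene name whose overrides apply.
#' @return numeric vector of natural-log selection factors.
#' @export
landscape_log_f <- function(landscape, site, parent_aa, target_aa,
                            gene = NULL) {
  arr <- landscape_array(landscape, gene)
  n <- max(length(site), length(parent_aa), length(target_aa))
  site <- rep_len(as.character(site), n)
  parent_aa <- rep_len(parent_aa, n)
  target_aa <- rep_len(target_aa, n)
  si <- match(site, landscape$sites)
  if (any(is.na(si))) stop("site(s) outside the landscape: ",
                           paste(unique(site[is.na(si)]), collapse = ", "))
  arr[cbind(si, match(parent_aa, .ab$aa_letters),
            match(target_aa, .ab$aa_letters))]
}

#' @export
print.selection_landscape <- function(x, ...) {
  cat(sprintf("Selection landscape over %d sites", length(x$sites)))
  if (!is.null(x$entrenched_spec)) {
    cat(sprintf("; %d planted entrenched pair(s) at log_f = %.3g",
                nrow(x$entrenched_spec), x$planted_log_f))
  }
  if (length(x$gene_arrs)) {
    cat(sprintf("; gene overrides for %s",
                paste(names(x$gene_arrs), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}
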