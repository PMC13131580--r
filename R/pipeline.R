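# End-to-end pipeline orchestration.
#
# A run executes six stages -- simulate, detect, validate-grouping,
# validate-rates, structure-rsa, grantham-test -- each reading its inputs
# from the run directory and writing tab-delimited outputs there, so any
# stage can be re-run from cached intermediates.  A manifest JSON records
# the configuration, seed and per-stage row counts (no timestamps: runs
# with the same seed are byte-identical).

#' Pipeline run configuration
#'
#' Every analysis constant is surfaced as a named key with its standard
#' default: entrenchment threshold -1, minimum 10 observations per
#' family-level combination, 3 per gene-level combination, pseudocount 0.5,
#' minimum baseline/expected count 5, branch-length scaling alpha 1.6, and
#' 10000 permutations.  All defaults are overridable.
#'
#' @param seed integer seed (mandatory); every stage derives its randomness
#'   from it.
#' @param out_dir output directory for tables and the manifest.
#' @param inputs optional list of pre-existing input paths (`germline_fasta`,
#'   `germline_sites`, `pcp_productive`, `pcp_out_of_frame`,
#'   `selection_factors`); when given, the simulate stage only validates and
#'   copies them into the run.
#' @param n_families,genes_per_family,length_codons germline-set shape.
#' @param divergence_within,divergence_between divergence targets.
#' @param n_diversity_sites germline-diverse sites available for pairing.
#' @param n_planted planted entrenched pairs (at `planted_log_f` both ways).
#' @param planted_log_f planted log selection factor (< -1).
#' @param base_range non-planted directed log selection factors are drawn
#'   from this uniform range (purifying-only by default).
#' @param oracle_noise_sd selection-factor oracle noise.
#' @param n_families_per_gene,mean_children,max_depth,mutations_per_branch
#'   clonal-family simulation shape.
#' @param neutral_kind `"uniform"` or `"context_3mer"`.
#' @param entrench_threshold,min_obs,per_gene_min_obs,pseudocount,
#'   min_baseline,min_expected,alpha,n_perm analysis constants.
#' @param n_complexes synthetic complexes for the accessibility stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed,
                       out_dir = "abentrench_run",
                       inputs = NULL,
                       n_families = 2L,
                       genes_per_family = 5L,
                       length_codons = 100L,
                       divergence_within = 0.10,
                       divergence_between = 0.30,
                       n_diversity_sites = 20L,
                       n_planted = 3L,
                       planted_log_f = -1.5,
                       base_range = c(-0.9, 0),
                       oracle_noise_sd = 0.25,
                       n_families_per_gene = 24L,
                       mean_children = 2,
                       max_depth = 4L,
                       mutations_per_branch = 4,
                       neutral_kind = "uniform",
                       entrench_threshold = -1.0,
                       min_obs = 10L,
                       per_gene_min_obs = 3L,
                       pseudocount = 0.5,
                       min_baseline = 5,
                       min_expected = 5,
                       alpha = 1.6,
                       n_perm = 10000L,
                       n_complexes = 3L) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  if (!is.null(inputs)) {
    missing_paths <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing_paths)) {
      stop("missing input path(s): ", paste(missing_paths, collapse = ", "))
    }
  }
  structure(cfg, class = "run_config")
}

.pipeline_stages <- c("simulate", "detect", "validate_grouping",
                      "validate_rates", "structure_rsa", "grantham_test")

run_path <- function(cfg, name) file.path(cfg$out_dir, name)

read_run_table <- function(cfg, name, character_cols = "site") {
  path <- run_path(cfg, name)
  if (!file.exists(path)) {
    stop("cached intermediate ", name, " not found; run earlier stages first")
  }
  cc <- stats::setNames(rep("character", length(character_cols)), character_cols)
  utils::read.delim(path, colClasses = cc)
}

write_run_table <- function(d, cfg, name) {
  utils::write.table(d, run_path(cfg, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nrow(d)
}

stage_simulate <- function(cfg) {
  div_sites <- as.character(seq(5L, by = 4L, length.out = cfg$n_diversity_sites))
  if (chothia_key(div_sites[length(div_sites)]) > cfg$length_codons) {
    stop("too many diversity sites for the sequence length")
  }
  if (!is.null(cfg$inputs)) {
    germlines <- read_germline_fasta(cfg$inputs$germline_fasta,
                                     cfg$inputs$germline_sites)
    prod <- read_pcp_table(cfg$inputs$pcp_productive)
    oof <- read_pcp_table(cfg$inputs$pcp_out_of_frame)
    sf <- read_selection_factors(cfg$inputs$selection_factors)
    landscape <- NULL
  } else {
    germlines <- make_germline_set(cfg$n_families, cfg$genes_per_family,
                                   cfg$length_codons, cfg$divergence_within,
                                   cfg$divergence_between, div_sites,
                                   seed = cfg$seed)
    dp <- attr(germlines, "diversity_pairs")
    planted <- dp[seq_len(min(cfg$n_planted, nrow(dp))), , drop = FALSE]
    landscape <- make_selection_landscape(
      sites = as.character(seq_len(cfg$length_codons)),
      base_range = cfg$base_range, entrenched_pairs = planted,
      planted_log_f = cfg$planted_log_f, seed = cfg$seed)
    neutral <- make_neutral_model(cfg$neutral_kind, seed = cfg$seed)
    sim <- simulate_repertoire(germlines, neutral, landscape,
                               simulation_config(
                                 n_families_per_gene = cfg$n_families_per_gene,
                                 mean_children = cfg$mean_children,
                                 max_depth = cfg$max_depth,
                                 mutations_per_branch = cfg$mutations_per_branch,
                                 oracle_noise_sd = cfg$oracle_noise_sd,
                                 seed = cfg$seed))
    prod <- sim$productive
    oof <- sim$out_of_frame
    sf <- sim$selection_factors
    utils::write.table(planted, run_path(cfg, "planted_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_germline_fasta(germlines, run_path(cfg, "germlines.fasta"),
                       run_path(cfg, "germline_sites.tsv"))
  n1 <- write_run_table(prod, cfg, "pcp_productive.tsv")
  n2 <- write_run_table(oof, cfg, "pcp_out_of_frame.tsv")
  n3 <- write_run_table(sf, cfg, "selection_factors.tsv")
  c(productive_pcps = n1, out_of_frame_pcps = n2, selection_factors = n3)
}

stage_inputs <- function(cfg) {
  for (f in c("germlines.fasta", "germline_sites.tsv", "pcp_productive.tsv",
              "pcp_out_of_frame.tsv", "selection_factors.tsv")) {
    if (!file.exists(run_path(cfg, f))) {
      stop("cached intermediate ", f, " not found; run the simulate stage first")
    }
  }
  list(germlines = read_germline_fasta(run_path(cfg, "germlines.fasta"),
                                       run_path(cfg, "germline_sites.tsv")),
       prod = read_pcp_table(run_path(cfg, "pcp_productive.tsv")),
       oof = read_pcp_table(run_path(cfg, "pcp_out_of_frame.tsv")),
       sf = read_selection_factors(run_path(cfg, "selection_factors.tsv")))
}

stage_detect <- function(cfg) {
  x <- stage_inputs(cfg)
  fams <- unique(x$germlines$family)
  within <- do.call(rbind, lapply(fams, function(f) {
    within_family_analysis(x$prod, x$sf, x$germlines, f,
                           min_obs = cfg$min_obs,
                           threshold = cfg$entrench_threshold)
  }))
  n1 <- write_run_table(within, cfg, "entrenchment_within.tsv")
  n2 <- 0L
  if (length(fams) >= 2L) {
    between <- between_family_analysis(x$prod, x$sf, x$germlines,
                                       fams[1], fams[2],
                                       min_obs = cfg$min_obs,
                                       threshold = cfg$entrench_threshold)
    n2 <- write_run_table(between, cfg, "entrenchment_between.tsv")
  }
  c(within_pairs = n1, between_pairs = n2)
}

stage_validate_grouping <- function(cfg) {
  x <- stage_inputs(cfg)
  rec <- filter_inference_records(x$prod, x$sf, x$germlines)
  gm <- per_gene_medians(rec, min_obs = cfg$per_gene_min_obs)
  n1 <- write_run_table(gm, cfg, "gene_medians.tsv")
  within <- read_run_table(cfg, "entrenchment_within.tsv")
  fams <- unique(x$germlines$family)
  rows <- lapply(fams, function(f) {
    genes <- x$germlines$name[x$germlines$family == f]
    gmf <- gm[gm$v_gene %in% genes, , drop = FALSE]
    icc <- tryCatch(
      icc_oneway(gmf$median_log_f,
                 paste(gmf$site, gmf$parent_aa, gmf$target_aa)),
      error = function(e) NA_real_)
    epf <- within[startsWith(within$grouping, paste0(f, ":")), , drop = FALSE]
    agree <- tryCatch(
      threshold_agreement(gmf, epf, threshold = cfg$entrench_threshold),
      error = function(e) NA_real_)
    data.frame(family = f, icc = icc, threshold_agreement = agree,
               n_gene_medians = nrow(gmf), stringsAsFactors = FALSE)
  })
  n2 <- write_run_table(do.call(rbind, rows), cfg, "grouping_validation.tsv")
  c(gene_medians = n1, families = n2)
}

stage_validate_rates <- function(cfg) {
  x <- stage_inputs(cfg)
  neutral <- make_neutral_model(cfg$neutral_kind, seed = cfg$seed)
  prod_syn <- count_substitutions(x$prod, x$germlines, "productive",
                                  "synonymous")
  oof_syn <- count_substitutions(x$oof, x$germlines, "out_of_frame",
                                 "synonymous")
  a1 <- approach1_ratios(prod_syn, oof_syn, pseudocount = cfg$pseudocount,
                         min_baseline = cfg$min_baseline)
  exp2 <- expected_counts(x$prod, neutral, x$germlines, alpha = cfg$alpha)
  a2 <- approach2_ratios(prod_syn, exp2, pseudocount = cfg$pseudocount,
                         min_expected = cfg$min_expected)
  n1 <- write_run_table(a1, cfg, "rate_ratios_approach1.tsv")
  n2 <- write_run_table(a2, cfg, "rate_ratios_approach2.tsv")
  rec <- filter_inference_records(x$prod, x$sf, x$germlines)
  cells <- aggregate_medians(rec, paste(rec$family, rec$parent_aa, sep = ":"),
                             min_obs = cfg$min_obs)
  cmp <- lapply(list(a1, a2), function(a) {
    tryCatch(compare_to_selection(a, cells)[c("pearson_r", "deming_slope",
                                              "deming_intercept", "n")],
             error = function(e) list(pearson_r = NA_real_,
                                      deming_slope = NA_real_,
                                      deming_intercept = NA_real_, n = 0L))
  })
  summary <- data.frame(approach = c(1L, 2L),
                        pearson_r = vapply(cmp, `[[`, 0, "pearson_r"),
                        deming_slope = vapply(cmp, `[[`, 0, "deming_slope"),
                        deming_intercept = vapply(cmp, `[[`, 0,
                                                  "deming_intercept"),
                        n = vapply(cmp, function(z) as.numeric(z$n), 0))
  n3 <- write_run_table(summary, cfg, "rate_selection_agreement.tsv")
  c(approach1 = n1, approach2 = n2, comparisons = n3)
}

stage_structure_rsa <- function(cfg) {
  parts <- lapply(seq_len(cfg$n_complexes), function(i) {
    cx <- simulate_complex(derive_seed(cfg$seed, paste0("complex", i)))
    d <- delta_rsa_decomposition(cx)
    d$structure_id <- cx$structure_id[1]
    d
  })
  write_run_table(do.call(rbind, parts), cfg, "delta_rsa.tsv")
}

stage_grantham_test <- function(cfg) {
  within <- read_run_table(cfg, "entrenchment_within.tsv")
  if (nrow(within) == 0L) return(c(pairs = 0L))
  fam <- sub(":.*$", "", within$grouping)
  gin <- data.frame(stratum = paste(fam, within$site, sep = ":"),
                    aa_pair = paste0(within$aa_a, within$aa_b),
                    distance = grantham_distance(within$aa_a, within$aa_b),
                    entrenched = within$entrenched,
                    stringsAsFactors = FALSE)
  res <- tryCatch(
    suppressMessages(stratified_permutation_test(gin, n_perm = cfg$n_perm,
                                                 seed = cfg$seed)),
    error = function(e) list(observed = NA_real_, p = NA_real_,
                             n_perm = 0L, n_strata = 0L))
  out <- data.frame(observed = res$observed, p = res$p, n_perm = res$n_perm,
                    n_strata = res$n_strata)
  write_run_table(gin, cfg, "grantham_inputs.tsv")
  c(pairs = write_run_table(out, cfg, "grantham_test.tsv"))
}

#' Run the analysis pipeline
#'
#' @param config a [run_config()].
#' @param stages stages to run (default: all six, in order); later stages
#'   read the cached outputs of earlier ones from the run directory.
#' @return the manifest list, invisibly; also written as `manifest.json` in
#'   the run directory.
#' @export
run_pipeline <- function(config, stages = .pipeline_stages) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  for (st in .pipeline_stages) {
    if (!st %in% stages) next
    fn <- switch(st,
                 simulate = stage_simulate,
                 detect = stage_detect,
                 validate_grouping = stage_validate_grouping,
                 validate_rates = stage_validate_rates,
                 structure_rsa = stage_structure_rsa,
                 grantham_test = stage_grantham_test)
    counts[[st]] <- tryCatch(as.list(fn(config)),
                             error = function(e) {
                               stop("stage '", st, "' failed: ",
                                    conditionMessage(e), call. = FALSE)
                             })
  }
  cfg_plain <- unclass(config)
  cfg_plain$inputs <- if (is.null(config$inputs)) NULL else
    lapply(config$inputs, as.character)
  manifest <- list(
    package = "abentrench",
    version = as.character(utils::packageVersion("abentrench")),
    seed = config$seed,
    config = cfg_plain,
    stages = .pipeline_stages,
    stages_run = stages,
    row_counts = counts)
  jsonlite::write_json(manifest, run_path(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
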