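test_that("per-gene medians honor the 3-observation minimum", {
  rec <- rbind(make_sf(paste0("a", 1:3), "4", "K", "E", c(-1, -2, -3)),
               make_sf(paste0("b", 1:2), "4", "K", "E", c(0, 0)))
  rec$v_gene <- c(rep("g1", 3), rep("g2", 2))
  gm <- per_gene_medians(rec)
  expect_identical(nrow(gm), 1L) # 2 observations dropped
  expect_identical(gm$v_gene, "g1")
  expect_identical(gm$median_log_f, -2)
  # constant values give that constant
  rec2 <- make_sf(paste0("c", 1:5), "2", "A", "V", rep(-0.7, 5))
  rec2$v_gene <- "g3"
  expect_identical(per_gene_medians(rec2)$median_log_f, -0.7)
  # a family with a single gene: gene-level equals family-level medians
  fam <- aggregate_medians(rec2, "FAM", min_obs = 3)
  expect_identical(per_gene_medians(rec2)$median_log_f, fam$median_log_f)
})

test_that("ICC(1) reproduces hand-computed and oracle values", {
  expect_identical(icc_oneway(c(0, 0, 1, 1), c("a", "a", "b", "b")), 1)
  # MSB = 0, MSW = 0.5, n0 = 2 -> (0 - 0.5)/(0 + 0.5) = -1 exactly
  expect_identical(icc_oneway(c(0, 1, 0, 1), c("a", "a", "b", "b")), -1)
  expect_error(icc_oneway(rep(1, 6), rep(c("a", "b"), 3)), "identical")
  expect_error(icc_oneway(1:5, rep("a", 5)), "2 groups")

  # brute-force one-way ANOVA decomposition as independent oracle
  set.seed(101)
  for (r in 1:100) {
    k <- sample(3:7, 1)
    ni <- sample(2:6, k, replace = TRUE)
    groups <- rep(paste0("g", seq_len(k)), ni)
    vals <- rnorm(sum(ni)) + rep(rnorm(k, sd = 1.5), ni)
    a <- anova(stats::aov(vals ~ factor(groups)))
    msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
    N <- sum(ni)
    n0 <- (N - sum(ni^2) / N) / (k - 1)
    expect_equal(icc_oneway(vals, groups),
                 (msb - msw) / (msb + (n0 - 1) * msw), tolerance = 1e-10)
  }
})

test_that("ICC is location/scale invariant and approaches 1 as noise vanishes", {
  set.seed(7)
  groups <- rep(paste0("s", 1:8), each = 4)
  mu <- rep(rnorm(8, sd = 1), each = 4)
  vals <- mu + rnorm(32, sd = 0.3)
  base <- icc_oneway(vals, groups)
  expect_equal(icc_oneway(vals + 5.3, groups), base, tolerance = 1e-12)
  expect_equal(icc_oneway(vals * 2.7, groups), base, tolerance = 1e-12)
  expect_lte(base, 1)
  noisier <- icc_oneway(mu + rnorm(32, sd = 3), groups)
  cleaner <- icc_oneway(mu + rnorm(32, sd = 0.01), groups)
  expect_gt(cleaner, 0.999)
  expect_gt(cleaner, noisier)
})

test_that("threshold agreement counts gene medians below the cutoff", {
  ep <- data.frame(grouping = "F:K|F:E", site = "4", aa_a = "E", aa_b = "K",
                   median_a_to_b = -1.4, median_b_to_a = -1.5,
                   n_a_to_b = 20L, n_b_to_a = 20L, entrenched = TRUE,
                   stringsAsFactors = FALSE)
  gm <- data.frame(v_gene = paste0("g", 1:4), site = "4",
                   parent_aa = "K", target_aa = "E",
                   median_log_f = c(-1.2, -1.7, -2.1, -0.3), n_obs = 5L,
                   stringsAsFactors = FALSE)
  expect_identical(threshold_agreement(gm, ep), 0.75)
  gm$median_log_f <- rep(-2, 4)
  expect_identical(threshold_agreement(gm, ep), 1)
  ep$entrenched <- FALSE
  expect_error(threshold_agreement(gm, ep), "no gene medians")
})

test_that("a planted outlier gene lowers agreement to the expected fraction", {
  # one family, 10 genes, one diversity site; gene 10 has positive selection
  # in both directions at the planted site
  g <- make_germline_set(1, 10, 60, 0.1, 0.3, diversity_sites = "7",
                         diversity_variants = 2, seed = 31)
  dp <- attr(g, "diversity_pairs")
  ov <- data.frame(gene = g$name[10], site = dp$site,
                   parent_aa = c(dp$aa_a, dp$aa_b),
                   target_aa = c(dp$aa_b, dp$aa_a), log_f = 0.5)
  # outlier gene must carry a diversity state so it contributes medians
  lan <- make_selection_landscape(as.character(1:60),
                                  entrenched_pairs = dp,
                                  planted_log_f = -1.5,
                                  gene_overrides = ov, seed = 31)
  sim <- simulate_repertoire(g, make_neutral_model("uniform"), lan,
                             simulation_config(n_families_per_gene = 4,
                                               n_oof_families_per_gene = 0,
                                               mean_children = 2,
                                               max_depth = 3,
                                               mutations_per_branch = 3,
                                               oracle_noise_sd = 0,
                                               seed = 32))
  rec <- filter_inference_records(sim$productive, sim$selection_factors, g)
  res <- within_family_analysis(sim$productive, sim$selection_factors, g,
                                "IGHV1")
  expect_true(any(res$entrenched))
  gm <- per_gene_medians(rec)
  agree <- threshold_agreement(gm, res)
  # 1 outlier gene of 10 -> 2 of 20 directed gene medians above threshold
  expect_equal(agree, 0.9, tolerance = 1e-12)
})
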