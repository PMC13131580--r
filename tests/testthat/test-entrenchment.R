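test_that("inference filters enforce depth-2, germline-codon and reachability", {
  g <- tiny_germlines()
  germ <- g$nt_sequence[1] # ATGGCATGGAAA
  pcps <- rbind(
    make_pcp("p1", "IGHV8-1*01", germ, germ),                       # depth 2
    make_pcp("p2", "IGHV8-1*01", germ, germ, depth = 3L),           # depth 3
    make_pcp("p3", "IGHV8-1*01", "ATGGCATGGAAG", "ATGGCATGGAAG"))   # syn codon
  sf <- rbind(
    make_sf("p1", "4", "K", "E", -0.2),  # passes all filters (AAA->GAA)
    make_sf("p1", "4", "K", "W", -0.2),  # W needs >1 nt from AAA -> removed
    make_sf("p2", "4", "K", "E", -0.2),  # depth 3 -> removed
    make_sf("p3", "4", "K", "E", -0.2))  # parent codon not germline -> removed
  out <- filter_inference_records(pcps, sf, g)
  expect_identical(nrow(out), 1L)
  expect_identical(out$pcp_id, "p1")
  expect_identical(out$family, "IGHV8")
  # retained record is unchanged
  expect_identical(out$log_f, -0.2)
  # dangling pcp_id is an error naming the offender
  expect_error(filter_inference_records(pcps, make_sf("zz", "4", "K", "E", 0),
                                        g), "zz")
})

test_that("median aggregation uses midpoints and the minimum-observation rule", {
  rec <- make_sf(paste0("p", 1:19), "4", "K", "E",
                 c(rep(-1.2, 5), rep(-0.8, 5), rep(0.3, 9)))
  rec$grp <- c(rep("a", 10), rep("b", 9))
  cells <- aggregate_medians(rec, rec$grp, min_obs = 10)
  # 9 observations -> no cell; even count -> midpoint median
  expect_identical(nrow(cells), 1L)
  expect_identical(cells$grouping, "a")
  expect_identical(cells$median_log_f, -1.0)
  expect_identical(cells$n_obs, 10L)
  # 10 identical values -> that value
  rec2 <- make_sf(paste0("q", 1:10), "2", "A", "V", rep(-0.44, 10))
  c2 <- aggregate_medians(rec2, "g", min_obs = 10)
  expect_identical(c2$median_log_f, -0.44)
  expect_identical(nrow(aggregate_medians(rec2[0, ], character(0))), 0L)
})

test_that("reciprocal pairing keeps only two-sided combinations", {
  cells <- data.frame(
    grouping = c("F:W", "F:G", "F:A", "F:A", "F:D", "F:D", "F:C", "F:C"),
    site = c("50", "50", "7", "7", "7", "7", "7", "7"),
    parent_aa = c("W", "G", "A", "A", "D", "D", "C", "C"),
    target_aa = c("G", "W", "D", "C", "A", "C", "A", "D"),
    median_log_f = seq(-0.8, by = -0.1, length.out = 8),
    n_obs = 11:18, stringsAsFactors = FALSE)
  pairs <- build_reciprocal_pairs(cells, quiet = TRUE)
  # W<->G at 50; three mutually available amino acids give 3 pairs at 7
  expect_identical(nrow(pairs), 4L)
  expect_identical(sum(pairs$site == "7"), 3L)
  w <- pairs[pairs$site == "50", ]
  expect_identical(w$aa_a, "G"); expect_identical(w$aa_b, "W")
  expect_identical(w$median_a_to_b, cells$median_log_f[2]) # G->W cell
  expect_identical(w$median_b_to_a, cells$median_log_f[1]) # W->G cell
  # one-sided cell: excluded, with a log line
  one <- cells[1, ]
  expect_message(out <- build_reciprocal_pairs(one), "lack the reciprocal")
  expect_identical(nrow(out), 0L)
})

test_that("entrenchment classification is strict, symmetric, monotone", {
  mk <- function(a, b) data.frame(grouping = "g", site = "1", aa_a = "A",
                                  aa_b = "G", median_a_to_b = a,
                                  median_b_to_a = b, n_a_to_b = 10L,
                                  n_b_to_a = 10L, entrenched = NA)
  expect_true(classify_entrenched(mk(-1.5, -2.0))$entrenched)
  expect_false(classify_entrenched(mk(-1.5, 0.3))$entrenched) # directional
  expect_false(classify_entrenched(mk(-1.0, -1.2))$entrenched) # strict <
  # swapping directions never changes the flag
  set.seed(9)
  for (i in 1:20) {
    a <- runif(1, -2, 0.5); b <- runif(1, -2, 0.5)
    expect_identical(classify_entrenched(mk(a, b))$entrenched,
                     classify_entrenched(mk(b, a))$entrenched)
  }
  # lowering the threshold never adds entrenched pairs
  pairs <- do.call(rbind, lapply(1:30, function(i) mk(runif(1, -2, 0),
                                                      runif(1, -2, 0))))
  for (th in c(-0.5, -1, -1.5)) {
    hi <- classify_entrenched(pairs, th)$entrenched
    lo <- classify_entrenched(pairs, th - 0.4)$entrenched
    expect_true(all(!lo | hi))
  }
})

test_that("with a noiseless oracle the pipeline medians equal the landscape exactly", {
  g <- fixture_germlines()
  lan <- fixture_landscape()
  sim <- simulate_repertoire(g, make_neutral_model("uniform"), lan,
                             simulation_config(n_families_per_gene = 6,
                                               n_oof_families_per_gene = 0,
                                               mean_children = 2, max_depth = 3,
                                               mutations_per_branch = 4,
                                               oracle_noise_sd = 0, seed = 21))
  rec <- filter_inference_records(sim$productive, sim$selection_factors, g)
  cells <- aggregate_medians(rec, paste(rec$family, rec$parent_aa, sep = ":"),
                             min_obs = 5)
  truth <- landscape_log_f(lan, cells$site, cells$parent_aa, cells$target_aa)
  expect_equal(cells$median_log_f, truth, tolerance = 1e-12)
})

test_that("within-family analysis flags planted pairs and nothing else", {
  g <- fixture_germlines()
  sim <- fixture_recovery_sim()
  res <- rbind(
    within_family_analysis(sim$productive, sim$selection_factors, g, "IGHV1"),
    within_family_analysis(sim$productive, sim$selection_factors, g, "IGHV2"))
  planted <- fixture_planted()
  pk <- paste(planted$site, pmin(planted$aa_a, planted$aa_b),
              pmax(planted$aa_a, planted$aa_b))
  fk <- paste(res$site, res$aa_a, res$aa_b)[res$entrenched]
  expect_setequal(unique(fk), pk)
  expect_error(within_family_analysis(sim$productive, sim$selection_factors,
                                      g, "IGHV9"), "unknown family")
  # a site where all genes share one amino acid yields no pairs
  expect_false("2" %in% res$site)
})

test_that("between-family pairs require differing germline identity", {
  g <- tiny_germlines()
  # records at site 2 (A in both families, V only in IGHV9) and site 4
  # (K only in IGHV8, E only in IGHV9)
  pcps <- rbind(
    do.call(rbind, lapply(1:12, function(i) {
      make_pcp(paste0("x", i), "IGHV8-1*01", g$nt_sequence[1],
               g$nt_sequence[1], family_id = paste0("f", i))
    })),
    do.call(rbind, lapply(1:12, function(i) {
      make_pcp(paste0("y", i), "IGHV9-2*01", g$nt_sequence[4],
               g$nt_sequence[4], family_id = paste0("h", i))
    })))
  sf <- rbind(
    make_sf(paste0("x", 1:12), "4", "K", "E", -1.7), # IGHV8 direction
    make_sf(paste0("y", 1:12), "4", "E", "K", -1.6), # IGHV9 direction
    make_sf(paste0("x", 1:12), "2", "A", "V", -1.9), # A germline in BOTH
    make_sf(paste0("y", 1:12), "2", "V", "A", -1.9))
  out <- between_family_analysis(pcps, sf, g, "IGHV8", "IGHV9")
  expect_identical(out$site, "4") # site 2's (A,V) excluded: A is shared
  expect_true(out$entrenched)
  expect_identical(sort(c(out$aa_a, out$aa_b)), c("E", "K"))
  # identical families -> empty output
  out2 <- between_family_analysis(pcps, sf, g, "IGHV8", "IGHV8")
  expect_identical(nrow(out2), 0L)
})

test_that("site entropy counts alleles with natural logs", {
  g <- tiny_germlines()
  expect_identical(site_entropy(g, "IGHV8", "1"), 0) # all M
  expect_equal(site_entropy(g, "IGHV9", "2"), log(2)) # A/V at 50:50
  expect_error(site_entropy(g, "IGHV8", "99"), "covers")
  # counts (3,1) -> 0.5623 nats
  g2 <- germline_set(paste0("g", 1:4), "F",
                     c("GCA", "GCA", "GCA", "GTA"), "1")
  expect_equal(site_entropy(g2, "F", "1"),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(round(site_entropy(g2, "F", "1"), 4), 0.5623)
})
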