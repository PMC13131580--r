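test_that("branch lengths classify synonymy at codon level", {
  expect_identical(synonymous_branch_length(
    list(parent_nt = "ATGAAA", child_nt = "ATGAAA")), 0)
  # AAA -> AAG, both Lys: one synonymous difference over 6 nucleotides
  expect_equal(synonymous_branch_length(
    list(parent_nt = "ATGAAA", child_nt = "ATGAAG")), 1 / 6)
  # AAA -> GAA is Lys -> Glu: nonsynonymous, contributes nothing
  expect_identical(synonymous_branch_length(
    list(parent_nt = "ATGAAA", child_nt = "ATGGAA")), 0)
  expect_error(synonymous_branch_length(
    list(parent_nt = "ATGANA", child_nt = "ATGAAA")), "ambiguous")

  expect_identical(scaled_branch_length(
    list(parent_nt = "ATGAAA", child_nt = "ATGAAA")), 0)
  # 8 differences over 320 nt at alpha 1.6 -> 0.04
  parent <- strrep("ACGT", 80)
  child <- parent
  for (i in seq(1, by = 40, length.out = 8)) {
    substr(child, i, i) <- if (substr(parent, i, i) == "A") "C" else "A"
  }
  pcp2 <- list(parent_nt = parent, child_nt = child)
  expect_equal(scaled_branch_length(pcp2), 8 / 320 * 1.6)
  expect_equal(scaled_branch_length(pcp2), 0.04)
  expect_equal(scaled_branch_length(pcp2, alpha = 1),
               scaled_branch_length(pcp2) / 1.6)
})

test_that("substitution counting follows the leaf and germline-A rules", {
  g <- tiny_germlines()
  germ <- g$nt_sequence[1]          # ATG GCA TGG AAA -> M A W K
  mut <- "ATGGCATGGGAA"             # K -> E at site 4
  syn <- "ATGGCATGGAAG"             # synonymous K codon
  away <- "ATGGAATGGAAA"            # site 2 A -> E (parent no longer germline A)
  pcps <- rbind(
    make_pcp("e1", "IGHV8-1*01", germ, mut),                      # internal
    make_pcp("e2", "IGHV8-1*01", germ, mut, is_leaf_child = TRUE),# leaf
    make_pcp("e3", "IGHV8-1*01", syn, mut, depth = 3L),           # syn parent: counts (aa identity)
    make_pcp("e4", "IGHV8-1*01", away, away, depth = 3L),         # parent != germline at 2
    make_pcp("e5", "IGHV8-1*01", germ, "ATGGCATGAAAA", depth = 3L)) # W->stop: excluded
  prod <- count_substitutions(pcps, g, "productive")
  k4 <- prod[prod$site == "4" & prod$target_aa == "E", ]
  expect_identical(k4$count, 2) # e1 + e3; leaf e2 excluded
  expect_identical(k4$parent_aa, "K")
  oof <- count_substitutions(pcps, g, "out_of_frame")
  expect_identical(oof[oof$site == "4" & oof$target_aa == "E", "count"], 3)
  # stop outcomes are never targets
  expect_false(any(prod$target_aa == "*"))
  # parent without germline A contributes neither count nor exposure at site 2
  a2 <- prod[prod$site == "2" & prod$parent_aa == "A", ][1, ]
  e_others <- sum(vapply(list("e1", "e3", "e5"), function(id) {
    synonymous_branch_length(pcps[pcps$pcp_id == id, ])
  }, 0))
  expect_equal(a2$exposure, e_others)
  # PCPs containing N are removed before counting
  pcpN <- make_pcp("n1", "IGHV8-1*01", germ, "ATGGCATGGGAN")
  expect_identical(
    count_substitutions(rbind(pcps, pcpN), g, "productive")[
      prod$site == "4" & prod$target_aa == "E", "count"], 2)
})

test_that("rates scale with exposure and zero exposure is excluded", {
  d <- data.frame(count = c(6, 0, 2), exposure = c(3, 5, 0))
  expect_message(r <- rate_from_counts(d), "zero exposure")
  expect_equal(r$rate, c(2, 0))
  d2 <- d[1:2, ]
  expect_equal(rate_from_counts(d2)$rate * 2,
               rate_from_counts(transform(d2, exposure = exposure / 2))$rate)
})

test_that("Approach-1 ratios apply smoothing and the baseline filter as stated", {
  mk <- function(count, exposure) {
    data.frame(family = "F", site = "10", parent_aa = "K", target_aa = "E",
               count = count, exposure = exposure, stringsAsFactors = FALSE)
  }
  # obs 4/exposure 1 vs baseline 9/exposure 1 -> log(4.5/9.5)
  r <- approach1_ratios(mk(4, 1), mk(9, 1))
  expect_equal(r$log_ratio, log(4.5 / 9.5))
  expect_equal(round(r$log_ratio, 3), -0.747)
  expect_true(r$passed_filter)
  # raw baseline 4 fails the >=5 filter (smoothing does not rescue it)
  expect_false(approach1_ratios(mk(10, 1), mk(4, 1))$passed_filter)
  # identical data on both sides -> ratio 0
  expect_equal(approach1_ratios(mk(7, 2.5), mk(7, 2.5))$log_ratio, 0)
  # exposures enter the ratio
  r2 <- approach1_ratios(mk(4, 2), mk(9, 3))
  expect_equal(r2$log_ratio, log((4.5 / 2) / (9.5 / 3)))
})

test_that("expected counts integrate the neutral model over codon neighborhoods", {
  neu <- make_neutral_model("uniform")
  pent <- abentrench:::pentamer_tables(neu)
  pent$ensure(1:1024)
  # outcome distributions are normalized over amino acid, synonymous and
  # stop outcomes for every pentamer state
  expect_equal(unname(rowSums(pent$rho)), rep(1, 1024))
  expect_equal(unname(pent$lam), rep(3, 1024)) # uniform rates sum over codon

  g <- tiny_germlines()
  germ <- g$nt_sequence[1]
  # identical parent/child: t = 0 -> p_mut = 0 -> all expected counts 0
  e0 <- expected_counts(make_pcp("z", "IGHV8-1*01", germ, germ), neu, g)
  expect_true(all(e0$expected == 0))
  # one PCP with known mutation count: p_mut = 1 - exp(-lambda * t)
  mut <- "ATGGCATGGGAA"
  e1 <- expected_counts(make_pcp("z", "IGHV8-1*01", germ, mut), neu, g,
                        alpha = 1.6)
  t_i <- 1 / 12 * 1.6
  p_mut <- 1 - exp(-3 * t_i)
  # site 4 AAA: neighbors at 9 x 1/9; E reachable via GAA only
  expect_equal(e1[e1$site == "4" & e1$target_aa == "E", "expected"],
               p_mut * 1 / 9)
})

test_that("Approach-2 ratios smooth counts and filter on raw expected", {
  mk_o <- function(count) data.frame(family = "F", site = "1",
                                     parent_aa = "K", target_aa = "E",
                                     count = count, exposure = 1,
                                     stringsAsFactors = FALSE)
  mk_e <- function(expected) data.frame(family = "F", site = "1",
                                        parent_aa = "K", target_aa = "E",
                                        expected = expected,
                                        stringsAsFactors = FALSE)
  expect_equal(approach2_ratios(mk_o(10), mk_e(10))$log_ratio, 0)
  r <- approach2_ratios(mk_o(4), mk_e(9))
  expect_equal(r$log_ratio, log(4.5 / 9.5))
  expect_false(approach2_ratios(mk_o(10), mk_e(4.9))$passed_filter)
  expect_true(approach2_ratios(mk_o(10), mk_e(5.0))$passed_filter)
  # pseudocount influence vanishes as counts grow
  small <- abs(approach2_ratios(mk_o(4), mk_e(9))$log_ratio - log(4 / 9))
  large <- abs(approach2_ratios(mk_o(400), mk_e(900))$log_ratio - log(4 / 9))
  expect_lt(large, small / 50)
})

test_that("Deming regression matches a brute-force perpendicular minimizer", {
  f <- deming_fit(1:10, 2 * (1:10) + 1)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1)
  set.seed(19)
  for (i in 1:5) {
    x <- rnorm(10); y <- 0.8 * x + rnorm(10, sd = 0.5)
    f <- deming_fit(x, y)
    # swapping axes inverts the slope (lambda = 1 symmetry)
    expect_equal(deming_fit(y, x)$slope, 1 / f$slope, tolerance = 1e-9)
    perp <- function(par) sum((y - par[1] * x - par[2])^2 / (1 + par[1]^2))
    o <- stats::optim(c(1, 0), perp, control = list(reltol = 1e-15))
    expect_equal(f$slope, o$par[1], tolerance = 1e-6)
    expect_equal(f$intercept, o$par[2], tolerance = 1e-6)
  }
  expect_error(deming_fit(rep(1, 5), rnorm(5)), "degenerate")
  expect_error(deming_fit(1:2, 2:3), "3 points")
})

test_that("comparison to selection factors joins correctly and detects exact lines", {
  cells <- data.frame(grouping = paste0("F:", LETTERS[1:5]),
                      site = as.character(1:5), parent_aa = "K",
                      target_aa = "E", median_log_f = c(-2, -1, 0, -0.5, -1.5),
                      n_obs = 20L, stringsAsFactors = FALSE)
  cells$family <- "F"
  rr <- data.frame(family = "F", site = as.character(1:5), parent_aa = "K",
                   target_aa = "E", observed = 5, expected = 10,
                   log_ratio = cells$median_log_f, passed_filter = TRUE,
                   approach = 2L, stringsAsFactors = FALSE)
  s <- compare_to_selection(rr, cells)
  expect_equal(s$pearson_r, 1)
  expect_equal(s$deming_slope, 1)
  expect_equal(s$deming_intercept, 0, tolerance = 1e-12)
  expect_identical(s$n, 5L)
})

test_that("reciprocal-pair summaries report threshold and data-sufficiency status", {
  ep <- data.frame(grouping = c("F:A|F:G", "F:C|F:W"), site = c("1", "2"),
                   aa_a = c("A", "C"), aa_b = c("G", "W"),
                   median_a_to_b = -1.5, median_b_to_a = -1.5,
                   n_a_to_b = 10L, n_b_to_a = 10L, entrenched = TRUE,
                   stringsAsFactors = FALSE)
  rr <- data.frame(family = "F", site = c("1", "1", "2"),
                   parent_aa = c("A", "G", "C"), target_aa = c("G", "A", "W"),
                   observed = 5, expected = 10,
                   log_ratio = c(-0.8, -0.6, -1.2), passed_filter = TRUE,
                   approach = 2L, stringsAsFactors = FALSE)
  out <- reciprocal_pair_summary(rr, ep)
  r1 <- out[out$site == "1", ]
  expect_false(r1$insufficient_data)
  expect_true(r1$`both_below_-0.5`)
  expect_false(r1$`both_below_-1`)
  # the W direction for site 2 is missing -> insufficient data
  r2 <- out[out$site == "2", ]
  expect_true(r2$insufficient_data)
  expect_true(is.na(r2$`both_below_-1`))
  # (-1.2, -1.5) passes both thresholds
  rr2 <- rbind(rr, data.frame(family = "F", site = "2", parent_aa = "W",
                              target_aa = "C", observed = 5, expected = 10,
                              log_ratio = -1.5, passed_filter = TRUE,
                              approach = 2L))
  out2 <- reciprocal_pair_summary(rr2, ep)
  expect_true(all(out2$`both_below_-1`[out2$site == "2"]))
})
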