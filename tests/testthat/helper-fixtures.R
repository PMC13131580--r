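# Shared fixtures, generated in code and cached for the session.

.fx <- new.env(parent = emptyenv())

# default study-condition germline set: 2 families x 5 genes, 100 codons,
# 20 diversity sites (every third three-variant)
fixture_germlines <- function() {
  if (is.null(.fx$germlines)) {
    .fx$germlines <- make_germline_set(
      2, 5, 100, 0.1, 0.3,
      diversity_sites = as.character(seq(5, by = 4, length.out = 20)),
      seed = 1)
  }
  .fx$germlines
}

fixture_landscape <- function() {
  g <- fixture_germlines()
  if (is.null(.fx$landscape)) {
    dp <- attr(g, "diversity_pairs")
    .fx$landscape <- make_selection_landscape(
      as.character(1:100), base_range = c(-0.9, 0),
      entrenched_pairs = dp[1:3, ], planted_log_f = -1.5, seed = 1)
  }
  .fx$landscape
}

fixture_planted <- function() {
  attr(fixture_germlines(), "diversity_pairs")[1:3, ]
}

# one recovery-scale simulation (noise 0.25, >= 30 obs per combination)
fixture_recovery_sim <- function(seed = 11) {
  key <- paste0("sim", seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- simulate_repertoire(
      fixture_germlines(), make_neutral_model("uniform"), fixture_landscape(),
      simulation_config(n_families_per_gene = 24, n_oof_families_per_gene = 0,
                        mean_children = 2, max_depth = 4,
                        mutations_per_branch = 4, oracle_noise_sd = 0.25,
                        seed = seed))
  }
  .fx[[key]]
}

# a tiny hand-built germline set: 2 families x 2 genes, 4 codons
# site 2 has A (fam1 both genes, fam2 gene1) and V (fam2 gene2);
# site 3 differs between families: K (fam1) vs E (fam2), single-nt reachable
tiny_germlines <- function() {
  germline_set(
    name = c("IGHV8-1*01", "IGHV8-2*01", "IGHV9-1*01", "IGHV9-2*01"),
    family = c("IGHV8", "IGHV8", "IGHV9", "IGHV9"),
    nt_sequence = c("ATGGCATGGAAA",   # M A W K
                    "ATGGCATGGAAA",   # M A W K
                    "ATGGCATGGGAA",   # M A W E
                    "ATGGTATGGGAA"),  # M V W E
    site_labels = c("1", "2", "3", "4"))
}

# minimal PCP row builder
make_pcp <- function(pcp_id, v_gene, parent_nt, child_nt, depth = 2L,
                     is_leaf_child = FALSE, frame_class = "productive",
                     family_id = "fam1") {
  data.frame(pcp_id = pcp_id, family_id = family_id, depth = depth,
             is_leaf_child = is_leaf_child, v_gene = v_gene,
             frame_class = frame_class, parent_nt = parent_nt,
             child_nt = child_nt, stringsAsFactors = FALSE)
}

make_sf <- function(pcp_id, site, parent_aa, target_aa, log_f) {
  data.frame(pcp_id = pcp_id, site = as.character(site),
             parent_aa = parent_aa, target_aa = target_aa, log_f = log_f,
             stringsAsFactors = FALSE)
}
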