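test_that("Shrake-Rupley SASA matches closed forms and is rigid-motion invariant", {
  # isolated atom: exactly the probe-expanded sphere area
  one <- data.frame(element = "C", x = 0, y = 0, z = 0)
  expect_equal(sasa_atoms(one), 4 * pi * (1.70 + 1.4)^2)
  expect_error(sasa_atoms(data.frame(element = "Xx", x = 0, y = 0, z = 0)),
               "unknown element")

  # atom enclosed in a dense shell: fully occluded
  shell <- abentrench:::sphere_points(240) * 2.0
  encl <- rbind(one, data.frame(element = "C", x = shell[, 1],
                                y = shell[, 2], z = shell[, 3]))
  expect_equal(sasa_atoms(encl)[1], 0)

  # two far-apart residues: per-residue SASA equals each computed alone
  res1 <- data.frame(element = c("N", "C", "C"), x = c(0, 1.4, 2.4),
                     y = 0, z = 0)
  res2 <- transform(res1, x = x + 100)
  both <- rbind(res1, res2)
  expect_equal(sasa_atoms(both, canonicalize = FALSE),
               c(sasa_atoms(res1, canonicalize = FALSE),
                 sasa_atoms(res2, canonicalize = FALSE)),
               tolerance = 1e-12)

  # rigid rotation + translation leaves areas unchanged
  set.seed(5)
  pts <- matrix(rnorm(45), 15, 3) * 3.5
  at <- data.frame(element = sample(c("C", "N", "O", "S"), 15, TRUE),
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  s0 <- sasa_atoms(at)
  th <- c(0.31, 1.2, 2.8)
  Rz <- matrix(c(cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1]), 0,
                 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), sin(th[2]),
                 0, -sin(th[2]), cos(th[2])), 3, 3)
  pr <- pts %*% Rz %*% Rx
  at2 <- data.frame(element = at$element, x = pr[, 1] + 7.3,
                    y = pr[, 2] - 2.2, z = pr[, 3] + 0.5)
  expect_equal(sasa_atoms(at2), s0, tolerance = 1e-6)
})

test_that("RSA normalizes by Wilke maxima without clamping", {
  expect_identical(rsa(0, "A"), 0)
  expect_equal(rsa(wilke_max_asa()[["W"]], "W"), 1)
  expect_gt(rsa(300, "G"), 1) # not clamped
  expect_error(rsa(10, "Z"), "unknown residue")
  # central residue of an extended tripeptide: moderately exposed
  bb <- build_peptide_backbone(rep(-139, 3), rep(135, 3))
  at <- data.frame(structure_id = "t", chain_id = "X", chain_role = "heavy",
                   resno = attr(bb, "resno"), aa = "G",
                   atom_name = rep(c("N", "CA", "C"), 3),
                   element = rep(c("N", "C", "C"), 3),
                   x = bb[, 1], y = bb[, 2], z = bb[, 3],
                   chothia = NA_character_, stringsAsFactors = FALSE)
  rs <- residue_sasa(at)
  central <- rsa(rs$sasa[2], rs$aa[2])
  expect_gt(central, 0.5)
  expect_lt(central, 1.3)
})

test_that("partner-removal RSA effects telescope exactly and are non-negative", {
  for (s in c(3, 8)) {
    cx <- simulate_complex(s)
    d <- delta_rsa_decomposition(cx)
    expect_gte(min(d$d_antigen), -1e-9)
    expect_gte(min(d$d_light), -1e-9)
    expect_gte(min(d$d_cdr3), -1e-9)
    expect_gte(min(d$rsa_full), 0)
    # telescoping: effects sum to RSA4 - RSA1, recomputed independently
    xyz <- abentrench:::canonical_frame(as.matrix(cx[, c("x", "y", "z")]))
    cx2 <- cx; cx2$x <- xyz[, 1]; cx2$y <- xyz[, 2]; cx2$z <- xyz[, 3]
    r1 <- residue_sasa(cx2, canonicalize = FALSE)
    r1 <- r1[r1$chain_role == "heavy", ]
    r4 <- residue_sasa(cx2[cx2$chain_role == "heavy" &
                             !chothia_in_range(ifelse(is.na(cx2$chothia), "1",
                                                      cx2$chothia),
                                               c("95", "102")), ],
                       canonicalize = FALSE)
    ix <- match(d$chothia, r1$chothia)
    ix4 <- match(d$chothia, r4$chothia)
    lhs <- d$d_antigen + d$d_light + d$d_cdr3
    rhs <- rsa(r4$sasa[ix4], r4$aa[ix4]) - rsa(r1$sasa[ix], r1$aa[ix])
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  # an antigen packed against one heavy residue buries mostly that residue
  bb <- build_peptide_backbone(rep(-120, 12), rep(130, 12))
  heavy <- data.frame(structure_id = "x", chain_id = "H",
                      chain_role = "heavy", resno = attr(bb, "resno"),
                      aa = "A", atom_name = rep(c("N", "CA", "C"), 12),
                      element = rep(c("N", "C", "C"), 12),
                      x = bb[, 1], y = bb[, 2], z = bb[, 3],
                      chothia = as.character(rep(91:102, each = 3)),
                      stringsAsFactors = FALSE)
  anchor <- as.numeric(heavy[heavy$resno == 3 & heavy$atom_name == "CA",
                             c("x", "y", "z")])
  ag <- data.frame(structure_id = "x", chain_id = "A",
                   chain_role = "antigen", resno = 1L, aa = "G",
                   atom_name = c("N", "CA", "C"), element = c("N", "C", "C"),
                   x = anchor[1] + c(2.8, 3.6, 3.2),
                   y = anchor[2] + c(0, 1, -1), z = anchor[3],
                   chothia = NA_character_, stringsAsFactors = FALSE)
  lt <- transform(ag, chain_id = "L", chain_role = "light", x = x + 200)
  cx <- rbind(heavy, lt, ag)
  d <- delta_rsa_decomposition(cx)
  expect_gt(d$d_antigen[d$chothia == "93"], 0.02)
  far <- d$d_antigen[!d$chothia %in% c("92", "93", "94")]
  expect_lt(max(far), d$d_antigen[d$chothia == "93"] / 2)
})

test_that("backbone dihedrals recover ideal geometry with correct conventions", {
  n <- 8
  bb <- build_peptide_backbone(rep(-57, n), rep(-47, n))
  at <- data.frame(structure_id = "h", chain_id = "H", chain_role = "heavy",
                   resno = attr(bb, "resno"), aa = "A",
                   atom_name = rep(c("N", "CA", "C"), n),
                   element = rep(c("N", "C", "C"), n),
                   x = bb[, 1], y = bb[, 2], z = bb[, 3],
                   chothia = NA_character_, stringsAsFactors = FALSE)
  dh <- backbone_dihedrals(at, "H")
  expect_true(is.na(dh$phi[1]))   # first residue: no preceding C
  expect_true(is.na(dh$psi[n]))   # last residue: no following N
  expect_equal(dh$phi[-1], rep(-57, n - 1), tolerance = 5 / 57)
  expect_equal(dh$psi[-n], rep(-47, n - 1), tolerance = 5 / 47)
  expect_true(all(dh$phi[-1] > -180 & dh$phi[-1] <= 180))
  # mirroring the coordinates negates both angles
  at2 <- at; at2$x <- -at2$x
  dh2 <- backbone_dihedrals(at2, "H")
  expect_equal(dh2$phi[-1], -dh$phi[-1], tolerance = 1e-9)
  expect_equal(dh2$psi[-n], -dh$psi[-n], tolerance = 1e-9)
  # a residue missing a backbone atom gets NA angles
  at3 <- at[!(at$resno == 4 & at$atom_name == "CA"), ]
  dh3 <- backbone_dihedrals(at3, "H")
  expect_true(is.na(dh3$phi[4]) && is.na(dh3$psi[4]))
  expect_error(backbone_dihedrals(at, "Q"), "unknown chain")
})

test_that("dihedrals agree with an independent torsion implementation", {
  cx <- simulate_complex(17)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  roles <- withr::local_tempfile(); cho <- withr::local_tempfile()
  write_complex_pdb(cx, pdb, roles, cho)
  ours <- backbone_dihedrals(read_complex_pdb(pdb, roles, cho), "H")
  ref <- bio3d::torsion.pdb(bio3d::read.pdb(pdb))$tbl
  hrows <- grep("\\.H\\.", rownames(ref))
  ref_phi <- ref[hrows, "phi"]; ref_psi <- ref[hrows, "psi"]
  ok_phi <- !is.na(ours$phi) & !is.na(ref_phi)
  ok_psi <- !is.na(ours$psi) & !is.na(ref_psi)
  expect_gt(sum(ok_phi), 10)
  expect_equal(ours$phi[ok_phi], unname(ref_phi[ok_phi]), tolerance = 0.01)
  expect_equal(ours$psi[ok_psi], unname(ref_psi[ok_psi]), tolerance = 0.01)
})

test_that("structure filtering applies every inclusion criterion with reasons", {
  meta <- data.frame(
    structure_id = paste0("s", 1:7),
    species = c("human", "mouse", "human", "human", "human", "human", NA),
    has_heavy = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    has_light = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    has_antigen = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    is_vhh = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    annotations_consistent = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  out <- filter_complexes(meta)
  expect_identical(out$retained, "s1")
  reasons <- setNames(out$rejected$reason, out$rejected$structure_id)
  expect_identical(reasons[["s2"]], "non_human")
  expect_identical(reasons[["s3"]], "missing_light_chain")
  expect_identical(reasons[["s4"]], "missing_antigen_chain")
  expect_identical(reasons[["s5"]], "missing_heavy_chain")
  expect_identical(reasons[["s6"]], "heavy_chain_only")
  expect_identical(reasons[["s7"]], "unannotated")
  meta2 <- meta[1, ]; meta2$annotations_consistent <- FALSE
  expect_identical(filter_complexes(meta2)$rejected$reason,
                   "inconsistent_vj_annotations")
})
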