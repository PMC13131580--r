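# Solvent accessibility and backbone geometry of antibody-antigen complexes.
#
# A complex is a plain data.frame of atoms:
#   structure_id, chain_id, chain_role ("heavy" | "light" | "antigen"),
#   resno (integer residue index within the chain), aa (one-letter),
#   atom_name, element, x, y, z (Angstrom), chothia (site label for heavy
#   chain residues, NA otherwise)
# SASA uses the Shrake-Rupley algorithm (default 960 sphere points, probe
# 1.4 A) with a fixed published van der Waals radii set.  Sphere point
# directions are expressed in a PCA-canonical molecular frame, so results
# are invariant under rigid rotation and translation to machine precision.
# RSA divides residue SASA by the residue's theoretical maximum accessible
# area (Wilke reference values); values may exceed 1 for unusually exposed
# conformations and are not clamped.

# van der Waals radii (Angstrom), NACCESS-flavored set
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# Theoretical maximum accessible surface areas (Angstrom^2) per residue
# (Tien et al. / Wilke theoretical values), one-letter codes.
.wilke_max_asa <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  E = 223.0, Q = 225.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

#' Wilke maximum accessible surface areas
#'
#' @return named numeric vector (Angstrom^2), one-letter amino-acid codes.
#' @export
wilke_max_asa <- function() .wilke_max_asa

# Deterministic unit sphere points (golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Canonical (PCA) frame of a coordinate matrix: rotates coordinates so the
# principal axes align with the coordinate axes, with a deterministic sign
# convention, making downstream quadrature rigid-motion invariant.
canonical_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  if (nrow(xyz) < 3L) return(xc)
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  V <- ev$vectors
  for (k in 1:2) {
    # orient each axis by the sign of the third moment of the projections
    # (rotation-equivariant, unlike any component-based convention)
    pk <- xc %*% V[, k]
    s3 <- sum(pk^3)
    if (abs(s3) < 1e-8) s3 <- sum(pk^5) # fallback for near-symmetric clouds
    if (s3 < 0) V[, k] <- -V[, k]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2]) # right-handed
  xc %*% V
}

#' Shrake-Rupley solvent-accessible surface area per atom
#'
#' @param atoms data.frame with `element`, `x`, `y`, `z` columns.
#' @param probe_radius probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere quadrature points per atom (default 960).
#' @param canonicalize rotate into the PCA-canonical molecular frame first
#'   (set `FALSE` when coordinates are already in a shared fixed frame, as
#'   in the multi-scenario decomposition).
#' @return numeric vector of per-atom SASA (Angstrom^2).
#' @export
sasa_atoms <- function(atoms, probe_radius = 1.4, n_points = 960L,
                       canonicalize = TRUE) {
  n <- nrow(atoms)
  if (n == 0L) return(numeric(0))
  r <- .vdw_radii[toupper(atoms$element)]
  if (anyNA(r)) {
    stop("unknown element(s): ",
         paste(unique(atoms$element[is.na(r)]), collapse = ", "))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (canonicalize) xyz <- canonical_frame(xyz)
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  pts <- sphere_points(n_points)
  R <- unname(r) + probe_radius
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R + R[i])^2 & seq_len(n) != i)
    if (!length(nb)) {
      out[i] <- 4 * pi * R[i]^2
      next
    }
    sp <- pts * R[i]
    sp[, 1] <- sp[, 1] + xyz[i, 1]
    sp[, 2] <- sp[, 2] + xyz[i, 2]
    sp[, 3] <- sp[, 3] + xyz[i, 3]
    buried <- rep(FALSE, n_points)
    for (k in nb) {
      if (all(buried)) break
      free <- which(!buried)
      dd <- (sp[free, 1] - xyz[k, 1])^2 + (sp[free, 2] - xyz[k, 2])^2 +
        (sp[free, 3] - xyz[k, 3])^2
      buried[free[dd < R[k]^2]] <- TRUE
    }
    out[i] <- 4 * pi * R[i]^2 * sum(!buried) / n_points
  }
  out
}

#' Per-residue SASA of a complex
#'
#' @param atoms atoms data.frame (see [sasa_atoms()]; must also carry
#'   `chain_id`, `resno`, `aa`, and `chothia`).
#' @param probe_radius,n_points,canonicalize as in [sasa_atoms()].
#' @return data.frame with one row per (chain_id, resno): `chain_id`,
#'   `chain_role`, `resno`, `aa`, `chothia`, `sasa`.
#' @export
residue_sasa <- function(atoms, probe_radius = 1.4, n_points = 960L,
                         canonicalize = TRUE) {
  a <- sasa_atoms(atoms, probe_radius, n_points, canonicalize)
  key <- paste(atoms$chain_id, atoms$resno, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(chain_id = atoms$chain_id[first],
                    chain_role = atoms$chain_role[first],
                    resno = atoms$resno[first],
                    aa = atoms$aa[first],
                    chothia = atoms$chothia[first],
                    stringsAsFactors = FALSE)
  sums <- rowsum(a, key)
  out$sasa <- sums[match(key[first], rownames(sums)), 1L]
  out
}

#' Relative solvent accessibility
#'
#' @param sasa per-residue SASA values (Angstrom^2).
#' @param aa one-letter amino-acid codes (recycled).
#' @return `sasa / wilke_max_asa()[aa]`; unknown residue types are an error.
#' @export
rsa <- function(sasa, aa) {
  mx <- .wilke_max_asa[aa]
  if (anyNA(mx)) {
    stop("unknown residue type(s): ", paste(unique(aa[is.na(mx)]), collapse = ", "))
  }
  unname(sasa / mx)
}

#' Partner-removal RSA decomposition of a complex
#'
#' Computes per-heavy-chain-residue RSA in four scenarios -- (1) heavy +
#' light + antigen, (2) heavy + light, (3) heavy alone, (4) heavy with the
#' CDR3 removal window excised (FR4 retained) -- and the three effects:
#' antigen `RSA2 - RSA1`, light chain `RSA3 - RSA2`, CDR3 `RSA4 - RSA3`.
#' The effects telescope: their sum equals `RSA4 - RSA1` exactly, and each
#' is non-negative up to numerical tolerance because removing atoms cannot
#' shrink the exposure of the rest.
#'
#' @param atoms complex atoms data.frame (heavy residues must carry Chothia
#'   labels; waters/heteroatoms are assumed already excluded).
#' @param cdr_def a [cdr_definition()].
#' @param probe_radius,n_points as in [sasa_atoms()].
#' @return data.frame per heavy residue: `chothia`, `aa`, `rsa_full`,
#'   `d_antigen`, `d_light`, `d_cdr3`.
#' @export
delta_rsa_decomposition <- function(atoms, cdr_def = cdr_definition(),
                                    probe_radius = 1.4, n_points = 960L) {
  roles <- unique(atoms$chain_role)
  for (need in c("heavy", "light", "antigen")) {
    if (!need %in% roles) stop("complex lacks a ", need, " chain")
  }
  heavy <- atoms$chain_role == "heavy"
  if (any(is.na(atoms$chothia[heavy]))) {
    stop("heavy-chain residues must all carry Chothia labels")
  }
  in_cdr3win <- heavy & chothia_in_range(ifelse(heavy, atoms$chothia, "1"),
                                         cdr_def$cdr3_removal_range)
  # one shared canonical frame from the full complex, so all four scenarios
  # use identical quadrature directions and the effects telescope exactly
  xyz <- canonical_frame(as.matrix(atoms[, c("x", "y", "z")]))
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  scen <- list(s1 = rep(TRUE, nrow(atoms)),
               s2 = atoms$chain_role != "antigen",
               s3 = heavy,
               s4 = heavy & !in_cdr3win)
  res_rsa <- function(sel) {
    rs <- residue_sasa(atoms[sel, , drop = FALSE], probe_radius, n_points,
                       canonicalize = FALSE)
    rs <- rs[rs$chain_role == "heavy", , drop = FALSE]
    stats::setNames(rsa(rs$sasa, rs$aa), rs$chothia)
  }
  r1 <- res_rsa(scen$s1); r2 <- res_rsa(scen$s2)
  r3 <- res_rsa(scen$s3); r4 <- res_rsa(scen$s4)
  sites <- names(r4) # heavy residues outside the removal window
  out <- data.frame(chothia = sites,
                    aa = atoms$aa[heavy][match(sites, atoms$chothia[heavy])],
                    rsa_full = unname(r1[sites]),
                    d_antigen = unname(r2[sites] - r1[sites]),
                    d_light = unname(r3[sites] - r2[sites]),
                    d_cdr3 = unname(r4[sites] - r3[sites]),
                    stringsAsFactors = FALSE)
  out[order(chothia_key(out$chothia)), , drop = FALSE]
}

#' Backbone dihedral angles
#'
#' Computes phi and psi (degrees, in (-180, 180]) for one chain from its N,
#' CA and C atoms.  Phi is undefined for the first residue, psi for the
#' last; residues missing a backbone atom get NA for the affected angles.
#'
#' @param atoms complex atoms data.frame.
#' @param chain chain_id to analyze.
#' @return data.frame per residue: `resno`, `aa`, `chothia`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(atoms, chain) {
  a <- atoms[atoms$chain_id == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("unknown chain: ", chain)
  resnos <- sort(unique(a$resno))
  coord <- function(resno, name) {
    i <- which(a$resno == resno & a$atom_name == name)
    if (length(i) != 1L) return(c(NA_real_, NA_real_, NA_real_))
    c(a$x[i], a$y[i], a$z[i])
  }
  n <- length(resnos)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  N <- t(vapply(resnos, coord, numeric(3), name = "N"))
  CA <- t(vapply(resnos, coord, numeric(3), name = "CA"))
  CC <- t(vapply(resnos, coord, numeric(3), name = "C"))
  for (i in seq_len(n)) {
    if (i > 1L) phi[i] <- dihedral4(CC[i - 1L, ], N[i, ], CA[i, ], CC[i, ])
    if (i < n) psi[i] <- dihedral4(N[i, ], CA[i, ], CC[i, ], N[i + 1L, ])
  }
  first <- match(resnos, a$resno)
  data.frame(resno = resnos, aa = a$aa[first], chothia = a$chothia[first],
             phi = phi, psi = psi, stringsAsFactors = FALSE)
}

# Dihedral angle (degrees) of four points, IUPAC sign convention.
dihedral4 <- function(p1, p2, p3, p4) {
  if (anyNA(c(p1, p2, p3, p4))) return(NA_real_)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Filter complex structures on annotation metadata
#'
#' Retains only structures meeting all criteria of the accessibility
#' analysis: human antibodies with complete heavy, light and antigen chains,
#' not heavy-chain-only (VHH/nanobody), and with V/J annotations consistent
#' across entries when a structure contains multiple antibodies.
#'
#' @param meta data.frame with columns `structure_id`, `species`,
#'   `has_heavy`, `has_light`, `has_antigen`, `is_vhh`,
#'   `annotations_consistent` (logical; `NA` anywhere rejects the structure
#'   as unannotated).
#' @return list with `retained` (structure ids) and `rejected` (data.frame
#'   `structure_id`, `reason`).
#' @export
filter_complexes <- function(meta) {
  req <- c("structure_id", "species", "has_heavy", "has_light", "has_antigen",
           "is_vhh", "annotations_consistent")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(meta))
  unannotated <- is.na(meta$species) | is.na(meta$has_heavy) |
    is.na(meta$has_light) | is.na(meta$has_antigen) | is.na(meta$is_vhh) |
    is.na(meta$annotations_consistent)
  reason[unannotated] <- "unannotated"
  set <- function(cond, why) {
    reason[is.na(reason) & cond] <<- why
  }
  set(meta$species != "human", "non_human")
  set(!meta$has_heavy, "missing_heavy_chain")
  set(meta$is_vhh, "heavy_chain_only")
  set(!meta$has_light, "missing_light_chain")
  set(!meta$has_antigen, "missing_antigen_chain")
  set(!meta$annotations_consistent, "inconsistent_vj_annotations")
  list(retained = meta$structure_id[is.na(reason)],
       rejected = data.frame(structure_id = meta$structure_id[!is.na(reason)],
                             reason = reason[!is.na(reason)],
                             stringsAsFactors = FALSE))
}

#' Read an annotated complex from a PDB file
#'
#' Chain roles and heavy-chain Chothia labels come from sidecar
#' tab-delimited files: `roles_path` with columns `chain_id`, `role`;
#' `chothia_path` with columns `chain_id`, `resno`, `chothia`.  Waters and
#' heteroatoms are excluded; hydrogens are kept if present.
#'
#' @param pdb_path PDB file.
#' @param roles_path,chothia_path sidecar annotation files.
#' @param structure_id identifier stored on the atoms (default: file name).
#' @return complex atoms data.frame.
#' @export
read_complex_pdb <- function(pdb_path, roles_path, chothia_path,
                             structure_id = basename(pdb_path)) {
  pdb <- bio3d::read.pdb(pdb_path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  roles <- utils::read.delim(roles_path, colClasses = "character")
  role <- roles$role[match(at$chain, roles$chain_id)]
  if (anyNA(role)) {
    stop("chains without a role annotation: ",
         paste(unique(at$chain[is.na(role)]), collapse = ", "))
  }
  cho <- utils::read.delim(chothia_path, colClasses = "character")
  chothia <- cho$chothia[match(paste(at$chain, at$resno),
                               paste(cho$chain_id, cho$resno))]
  aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
           GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  data.frame(structure_id = structure_id, chain_id = at$chain,
             chain_role = role, resno = as.integer(at$resno),
             aa = unname(aa3[at$resid]), atom_name = at$elety,
             element = toupper(substr(at$elety, 1L, 1L)),
             x = at$x, y = at$y, z = at$z, chothia = chothia,
             stringsAsFactors = FALSE)
}
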