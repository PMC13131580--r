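# Synthetic antibody-antigen complexes.
#
# Chains are built as N-CA-C backbones from internal coordinates (standard
# bond lengths/angles, caller-supplied phi/psi, trans omega), then placed so
# that light chain and antigen pack against chosen heavy-chain residues.
# The geometry is idealized, not energy-minimized: it exercises the
# accessibility and dihedral machinery, not protein physics.

.bb_geom <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                 a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7)

# Place point D given A, B, C, bond |C-D|, angle B-C-D and torsion A-B-C-D
# (degrees): the standard internal-to-Cartesian (NeRF) step.
place_atom <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  d <- bond * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  nrm <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  m2 <- c(nrm[2] * bc[3] - nrm[3] * bc[2], nrm[3] * bc[1] - nrm[1] * bc[3],
          nrm[1] * bc[2] - nrm[2] * bc[1])
  C + cbind(bc, m2, nrm) %*% d
}

#' Build an N-CA-C peptide backbone from phi/psi angles
#'
#' @param phi,psi dihedral vectors in degrees, one per residue (`phi[1]` and
#'   `psi[n]` are unused); omega is fixed trans (180).
#' @return matrix of 3n rows (N, CA, C per residue) with columns x, y, z and
#'   a `resno` attribute.
#' @export
build_peptide_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2L)
  g <- .bb_geom
  xyz <- matrix(NA_real_, 3L * n, 3L)
  rownames(xyz) <- rep(c("N", "CA", "C"), n)
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  xyz[3, ] <- xyz[2, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in 2:n) {
    r0 <- 3L * (i - 2L)
    r1 <- 3L * (i - 1L)
    xyz[r1 + 1L, ] <- place_atom(xyz[r0 + 1L, ], xyz[r0 + 2L, ], xyz[r0 + 3L, ],
                                 g$b_c_n, g$a_ca_c_n, psi[i - 1L])
    xyz[r1 + 2L, ] <- place_atom(xyz[r0 + 2L, ], xyz[r0 + 3L, ], xyz[r1 + 1L, ],
                                 g$b_n_ca, g$a_c_n_ca, 180)
    xyz[r1 + 3L, ] <- place_atom(xyz[r0 + 3L, ], xyz[r1 + 1L, ], xyz[r1 + 2L, ],
                                 g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  attr(xyz, "resno") <- rep(seq_len(n), each = 3L)
  xyz
}

chain_atoms <- function(xyz, chain_id, chain_role, aa, chothia,
                        structure_id) {
  resno <- attr(xyz, "resno")
  data.frame(structure_id = structure_id, chain_id = chain_id,
             chain_role = chain_role, resno = resno,
             aa = aa[resno], atom_name = rep(c("N", "CA", "C"), max(resno)),
             element = rep(c("N", "C", "C"), max(resno)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             chothia = if (is.null(chothia)) NA_character_ else chothia[resno],
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic antibody-antigen complex
#'
#' Builds heavy, light and antigen chains as random-coil backbones; the
#' light chain and antigen are translated to pack against randomly chosen
#' heavy-chain residues so partner burial is present.  Heavy-chain residues
#' carry consecutive Chothia labels starting at `first_label`, which places
#' the CDR3 removal window (95-102) inside the chain at the default sizes.
#'
#' @param seed integer seed.
#' @param n_heavy,n_light,n_antigen residues per chain.
#' @param first_label first heavy-chain Chothia number (default 88).
#' @param contact_distance packing distance (Angstrom) between partner
#'   centroid and its heavy anchor residue.
#' @param structure_id identifier stored on the atoms.
#' @return complex atoms data.frame (see [residue_sasa()]).
#' @export
simulate_complex <- function(seed, n_heavy = 26L, n_light = 16L,
                             n_antigen = 12L, first_label = 88L,
                             contact_distance = 4.5,
                             structure_id = sprintf("synth%04d", seed)) {
  set.seed(derive_seed(seed, "complex"))
  coil <- function(n) {
    list(phi = stats::runif(n, -150, -50), psi = stats::runif(n, -60, 160))
  }
  rand_aa <- function(n) sample(.ab$aa_letters, n, replace = TRUE)
  h <- coil(n_heavy)
  hx <- build_peptide_backbone(h$phi, h$psi)
  heavy <- chain_atoms(hx, "H", "heavy", rand_aa(n_heavy),
                       as.character(seq(first_label, length.out = n_heavy)),
                       structure_id)
  pack <- function(xyz, anchor_xyz, dist) {
    ctr <- colMeans(xyz)
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    target <- anchor_xyz + dir * dist
    sweep(xyz, 2, ctr - target)
  }
  l <- coil(n_light)
  lx <- build_peptide_backbone(l$phi, l$psi)
  anchor_l <- as.numeric(hx[3L * (sample.int(n_heavy, 1L) - 1L) + 2L, ])
  lx2 <- pack(unclass(lx[, , drop = FALSE]), anchor_l, contact_distance)
  attr(lx2, "resno") <- attr(lx, "resno")
  light <- chain_atoms(lx2, "L", "light", rand_aa(n_light), NULL, structure_id)
  a <- coil(n_antigen)
  ax <- build_peptide_backbone(a$phi, a$psi)
  anchor_a <- as.numeric(hx[3L * (sample.int(n_heavy, 1L) - 1L) + 2L, ])
  ax2 <- pack(unclass(ax[, , drop = FALSE]), anchor_a, contact_distance)
  attr(ax2, "resno") <- attr(ax, "resno")
  antigen <- chain_atoms(ax2, "A", "antigen", rand_aa(n_antigen), NULL,
                         structure_id)
  rbind(heavy, light, antigen)
}

#' Write an annotated complex as PDB plus sidecar tables
#'
#' Counterpart of [read_complex_pdb()].
#'
#' @param atoms complex atoms data.frame.
#' @param pdb_path,roles_path,chothia_path output paths.
#' @return invisibly, the three paths.
#' @export
write_complex_pdb <- function(atoms, pdb_path, roles_path, chothia_path) {
  aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = pdb_path, xyz = xyz,
                   resno = atoms$resno, chain = atoms$chain_id,
                   resid = unname(aa1to3[atoms$aa]), elety = atoms$atom_name,
                   eleno = seq_len(nrow(atoms)))
  roles <- unique(atoms[, c("chain_id", "chain_role")])
  names(roles) <- c("chain_id", "role")
  utils::write.table(roles, roles_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hv <- atoms[atoms$chain_role == "heavy" & !is.na(atoms$chothia), ,
              drop = FALSE]
  cho <- unique(data.frame(chain_id = hv$chain_id, resno = hv$resno,
                           chothia = hv$chothia, stringsAsFactors = FALSE))
  utils::write.table(cho, chothia_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pdb_path, roles_path, chothia_path))
}
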