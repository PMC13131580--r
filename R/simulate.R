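# Synthetic repertoire generation.
#
# The generator emulates the statistical structure the analysis assumes:
# germline V-gene sets with controlled within- and between-family amino-acid
# divergence, clonal families as rooted trees whose root is the germline
# sequence (so depth-2 PCP parents match germline), a context-dependent
# neutral nucleotide mutation process, and selection by acceptance-rejection:
# every proposed nonsynonymous change in a productive lineage is accepted
# with probability min(1, exp(log_f)), so the realized observed/expected rate
# ratio for a deleterious substitution converges to exp(log_f) -- exactly the
# relationship the rate-ratio validation assumes.  Out-of-frame lineages
# accept every proposal (neutral with respect to amino-acid changes).

#' Generate a germline V-gene set with controlled divergence
#'
#' Builds `n_families` families of `genes_per_family` alleles from a common
#' stop-free base sequence.  Family consensus sequences and individual genes
#' are diversified by nonsynonymous single-nucleotide codon changes at
#' disjoint positions, so realized within-family pairwise amino-acid
#' divergence stays at or below `divergence_within` (+0.05 tolerance) and
#' between-family divergence lands near `divergence_between` (within 0.1).
#' Designated `diversity_sites` are given two germline amino acids per family
#' (alternating across genes), each reachable from the other's codon by a
#' single nucleotide change -- the site/amino-acid pairs available for
#' entrenchment planting; they are recorded in the `"diversity_pairs"`
#' attribute.
#'
#' @param n_families number of V families.
#' @param genes_per_family alleles per family.
#' @param length_codons sequence length in codons; Chothia labels are
#'   `"1" ... "<length_codons>"`.
#' @param divergence_within,divergence_between target amino-acid divergence
#'   fractions, `0 < divergence_within < divergence_between < 1`.
#' @param diversity_sites character vector of Chothia labels (plain numbers
#'   within the sequence) to make germline-diverse.
#' @param diversity_variants number of germline amino acids (2 or 3) per
#'   diversity site, recycled; default makes every third site three-variant
#'   so family-site strata contain several amino-acid pairs.
#' @param seed integer seed; the same seed reproduces the set byte-for-byte.
#' @param family_names names for the families (default IGHV1, IGHV2, ...).
#' @return a `germline_set` with attribute `diversity_pairs` (data.frame
#'   `site`, `aa_a`, `aa_b`).
#' @export
make_germline_set <- function(n_families, genes_per_family, length_codons,
                              divergence_within, divergence_between,
                              diversity_sites = character(), seed = 1L,
                              diversity_variants = 2L +
                                (seq_along(diversity_sites) %% 3L == 0L),
                              family_names = paste0("IGHV", seq_len(n_families))) {
  stopifnot(n_families >= 1, genes_per_family >= 1, length_codons >= 3)
  if (!(divergence_within > 0 && divergence_within < divergence_between &&
        divergence_between < 1)) {
    stop("need 0 < divergence_within < divergence_between < 1")
  }
  L <- as.integer(length_codons)
  labels <- as.character(seq_len(L))
  div_pos <- integer(0)
  if (length(diversity_sites)) {
    div_pos <- match(as.character(diversity_sites), labels)
    if (any(is.na(div_pos))) stop("diversity_sites outside the sequence")
  }
  n_div <- length(div_pos)

  # Diversity sites carry two or three germline amino acids per family,
  # assigned to balanced gene subsets chosen greedily so the extra within-
  # and cross-family differences spread evenly across gene pairs.  The
  # per-gene mutation budget is then chosen so the within-family bound
  # still holds, and the family-consensus budget so between-family
  # divergence centres on its target.
  G <- as.integer(genes_per_family)
  R <- n_families * G # all gene rows, r = (family-1)*G + gene
  n_variants <- rep_len(as.integer(diversity_variants), n_div)
  if (n_div > 0L && any(!n_variants %in% 2:3)) {
    stop("diversity_variants must be 2 or 3")
  }
  if (G < 3L) n_variants <- pmin(n_variants, G)
  state_mask <- matrix(0L, R, max(n_div, 1L))[, seq_len(n_div), drop = FALSE]
  D_within_max <- 0L
  D_cross_mean <- 0
  if (n_div > 0L && G >= 2L) {
    # all assignments of states 0..V-1 to G genes with near-equal counts
    arrangements <- function(V) {
      sizes <- rep(G %/% V, V)
      extra <- G %% V
      if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      out <- list(rep(0L, G))
      for (st in seq_len(V - 1L)) {
        nxt <- list()
        for (a in out) {
          free <- which(a == 0L)
          for (S in utils::combn(free, sizes[st + 1L], simplify = FALSE)) {
            b <- a
            b[S] <- st
            nxt[[length(nxt) + 1L]] <- b
          }
        }
        out <- nxt
      }
      unique(out)
    }
    arr_by_V <- lapply(2:3, arrangements)
    pr <- utils::combn(R, 2L)
    fam_of <- (seq_len(R) - 1L) %/% G + 1L
    within_pair <- fam_of[pr[1, ]] == fam_of[pr[2, ]]
    D_all <- integer(ncol(pr))
    for (s in seq_len(n_div)) {
      cands <- arr_by_V[[n_variants[s] - 1L]]
      col <- rep(0L, R)
      for (f in seq_len(n_families)) {
        rows_f <- (f - 1L) * G + seq_len(G)
        best <- NULL; best_score <- Inf
        for (a in cands) {
          cand <- col
          cand[rows_f] <- a
          d <- as.integer(cand[pr[1, ]] != cand[pr[2, ]])
          # only count pairs whose both rows are already decided this site
          decided <- pr[1, ] <= max(rows_f) & pr[2, ] <= max(rows_f)
          Dn <- D_all + d * decided
          v_or_0 <- function(x) if (length(x) > 1L) stats::var(x) else 0
          score <- max(Dn[within_pair]) * 1e6 +
            v_or_0(Dn[within_pair]) * 1e3 + v_or_0(Dn[!within_pair])
          if (score < best_score) { best_score <- score; best <- cand }
        }
        col <- best
      }
      state_mask[, s] <- col
      D_all <- D_all + as.integer(col[pr[1, ]] != col[pr[2, ]])
    }
    D_within_max <- max(D_all[within_pair])
    D_cross_mean <- if (any(!within_pair)) mean(D_all[!within_pair]) else 0
  }
  if (D_within_max > (divergence_within + 0.05) * L) {
    stop("infeasible divergence targets: too many diversity sites for ",
         "the within-family divergence budget")
  }
  m_gene <- round(divergence_within * L / 2)
  m_eff <- max(0L, min(m_gene,
                       floor(((divergence_within + 0.05) * L - D_within_max) / 2)))
  k_fam <- round(max(divergence_between * L - 2 * m_eff - D_cross_mean, 0) / 2)
  pool <- setdiff(seq_len(L), div_pos)
  if (n_families * k_fam > length(pool) ||
      genes_per_family * m_eff > length(pool) - n_families * k_fam) {
    stop("infeasible divergence targets for sequence length ", L)
  }

  set.seed(derive_seed(seed, "germline_set"))
  non_stop <- which(.ab$aa64 != "*")
  base <- sample(non_stop, L, replace = TRUE)

  # one nonsynonymous, non-stop single-nt neighbor of a codon
  nonsyn_neighbor <- function(idx) {
    nb <- .ab$neighbor_idx[idx, ]
    ok <- .ab$aa64_int[nb] != 21L & .ab$aa64_int[nb] != .ab$aa64_int[idx]
    cand <- nb[ok]
    if (!length(cand)) stop("codon with no nonsynonymous neighbor") # unreachable
    cand[sample.int(length(cand), 1L)]
  }

  fam_pos_all <- if (k_fam > 0) sample(pool, n_families * k_fam) else integer(0)
  fam_pos <- if (k_fam > 0)
    split(fam_pos_all, rep(seq_len(n_families), each = k_fam)) else list()
  pool2 <- setdiff(pool, fam_pos_all)

  # alternative codons at diversity sites: alt1 is a nonsynonymous single-nt
  # neighbor of the base codon; alt2 (three-variant sites) encodes a third
  # amino acid, preferring a change at the same nucleotide position so the
  # two alternatives are also single-nt reachable from each other
  div_alt <- matrix(NA_integer_, 2L, max(n_div, 1L))[, seq_len(n_div),
                                                     drop = FALSE]
  for (k in seq_len(n_div)) {
    idx <- base[div_pos[k]]
    div_alt[1L, k] <- nonsyn_neighbor(idx)
    if (n_variants[k] == 3L) {
      nb <- .ab$neighbor_idx[idx, ]
      pos_of <- .ab$neighbor_pos[idx, ]
      alt1 <- div_alt[1L, k]
      alt1_pos <- pos_of[match(alt1, nb)]
      banned <- c(21L, .ab$aa64_int[idx], .ab$aa64_int[alt1])
      ok <- !(.ab$aa64_int[nb] %in% banned)
      cand <- nb[ok & pos_of == alt1_pos]
      if (!length(cand)) cand <- nb[ok]
      if (length(cand)) {
        div_alt[2L, k] <- cand[sample.int(length(cand), 1L)]
      } else {
        n_variants[k] <- 2L # codon cannot host a third amino acid
      }
    }
  }

  name <- character(0); family <- character(0); nt <- character(0)
  for (f in seq_len(n_families)) {
    cons <- base
    for (p in if (k_fam > 0) fam_pos[[f]] else integer(0)) {
      cons[p] <- nonsyn_neighbor(cons[p])
    }
    gene_pos_all <- if (m_eff > 0) sample(pool2, genes_per_family * m_eff) else integer(0)
    gene_pos <- if (m_eff > 0)
      split(gene_pos_all, rep(seq_len(genes_per_family), each = m_eff)) else list()
    for (g in seq_len(genes_per_family)) {
      gene <- cons
      for (p in if (m_eff > 0) gene_pos[[g]] else integer(0)) {
        gene[p] <- nonsyn_neighbor(gene[p])
      }
      if (n_div && genes_per_family >= 2L) {
        st <- state_mask[(f - 1L) * G + g, ]
        for (v in 1:2) {
          take <- which(st == v)
          take <- take[!is.na(div_alt[v, take])]
          gene[div_pos[take]] <- div_alt[v, take]
        }
      }
      codons <- .ab$codons[gene]
      name <- c(name, sprintf("%s-%d*01", family_names[f], g))
      family <- c(family, family_names[f])
      nt <- c(nt, paste(codons, collapse = ""))
    }
  }
  out <- germline_set(name, family, nt, labels)
  attr(out, "diversity_pairs") <- data.frame(
    site = labels[div_pos],
    aa_a = .ab$aa64[base[div_pos]],
    aa_b = .ab$aa64[div_alt[1L, ]],
    aa_c = ifelse(is.na(div_alt[2L, ]), NA_character_, .ab$aa64[div_alt[2L, ]]),
    stringsAsFactors = FALSE)
  out
}

#' Simulation configuration
#'
#' @param n_families_per_gene clonal families per gene in the productive
#'   dataset.
#' @param n_oof_families_per_gene clonal families per gene in the
#'   out-of-frame dataset (default: same).
#' @param mean_children mean number of children per internal tree node
#'   (Poisson; the root always has at least one child so every family has
#'   depth-2 PCPs).
#' @param max_depth number of tree levels including the root (max PCP depth).
#' @param mutations_per_branch Poisson mean of proposed single-nucleotide
#'   events per edge; events are applied sequentially, so multi-hit codons
#'   arise naturally.
#' @param oracle_noise_sd additive Gaussian noise (sd, natural-log scale) on
#'   the emitted selection factors; 0 makes the oracle exact.
#' @param emit_selection_factors emit the depth-2 selection-factor table?
#' @param seed integer seed (mandatory).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_families_per_gene,
                              n_oof_families_per_gene = n_families_per_gene,
                              mean_children = 2,
                              max_depth = 4L,
                              mutations_per_branch = 4,
                              oracle_noise_sd = 0,
                              emit_selection_factors = TRUE,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_families_per_gene >= 1, n_oof_families_per_gene >= 0,
            mean_children > 0, max_depth >= 2, mutations_per_branch > 0,
            oracle_noise_sd >= 0)
  structure(list(n_families_per_gene = as.integer(n_families_per_gene),
                 n_oof_families_per_gene = as.integer(n_oof_families_per_gene),
                 mean_children = mean_children,
                 max_depth = as.integer(max_depth),
                 mutations_per_branch = mutations_per_branch,
                 oracle_noise_sd = oracle_noise_sd,
                 emit_selection_factors = isTRUE(emit_selection_factors),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Simulate one clonal family; returns per-edge vectors.
# seq vectors are integer-encoded; landscape array lan3 is [L,20,20] in the
# gene's site order (NULL for out-of-frame lineages).
sim_family <- function(root, cfg, neutral, lan3, productive) {
  n <- length(root)
  L <- n %/% 3L
  aa_int <- .ab$aa64_int
  uniform <- neutral$kind == "uniform"
  rate64 <- neutral$rate64
  probs64 <- neutral$probs64
  mu <- cfg$mutations_per_branch
  parent_chr <- character(0); child_chr <- character(0)
  depth <- integer(0); leaf <- logical(0)
  ascii <- c(65L, 67L, 71L, 84L)

  to_chr <- function(v) intToUtf8(ascii[v])

  mutate_edge <- function(seq) {
    K <- stats::rpois(1L, mu)
    if (K == 0L) return(seq)
    if (uniform) {
      pos <- sample.int(n, K, replace = TRUE)
      alt <- sample.int(3L, K, replace = TRUE)
    } else {
      pos <- integer(K); alt <- integer(K)
    }
    u <- stats::runif(K)
    for (e in seq_len(K)) {
      if (uniform) {
        p <- pos[e]
        cur <- seq[p]
        nb <- if (alt[e] >= cur) alt[e] + 1L else alt[e]
      } else {
        ctx <- seq_context_indices(seq)
        w <- rate64[ctx]
        p <- sample.int(n, 1L, prob = w)
        cur <- seq[p]
        nb <- sample.int(4L, 1L, prob = probs64[ctx[p], ])
      }
      cp <- (p - 1L) %/% 3L            # 0-based codon
      s0 <- 3L * cp + 1L
      w3 <- c(16L, 4L, 1L)[p - s0 + 1L]
      old_idx <- 16L * (seq[s0] - 1L) + 4L * (seq[s0 + 1L] - 1L) + seq[s0 + 2L]
      new_idx <- old_idx + (nb - cur) * w3
      a0 <- aa_int[old_idx]; a1 <- aa_int[new_idx]
      accept <- TRUE
      if (a1 != a0 && productive) {
        if (a1 == 21L) {
          accept <- FALSE            # stop codon: never productive
        } else if (a0 != 21L) {
          lf <- lan3[cp + 1L + (a0 - 1L) * L + (a1 - 1L) * L * 20L]
          if (lf < 0) accept <- u[e] < exp(lf)
        }
      }
      if (accept) seq[p] <- nb
    }
    seq
  }

  recurse <- function(seq, seq_chr, level) {
    if (level >= cfg$max_depth) return(0L)
    k <- stats::rpois(1L, cfg$mean_children)
    if (level == 1L) k <- max(1L, k)
    for (ch in seq_len(k)) {
      child <- mutate_edge(seq)
      child_chr_1 <- to_chr(child)
      i <- length(depth) + 1L
      parent_chr[i] <<- seq_chr
      child_chr[i] <<- child_chr_1
      depth[i] <<- level + 1L
      leaf[i] <<- TRUE # provisional; fixed below
      nchild <- recurse(child, child_chr_1, level + 1L)
      leaf[i] <<- nchild == 0L
    }
    k
  }

  recurse(root, to_chr(root), 1L)
  list(parent = parent_chr, child = child_chr, depth = depth, leaf = leaf)
}

#' Simulate productive and out-of-frame clonal-family repertoires
#'
#' Each clonal family is a rooted tree whose root is the gene's germline
#' sequence; every edge is emitted as a PCP with its depth (2 = root edge)
#' and leaf flag.  Productive lineages evolve under the landscape by
#' acceptance-rejection (stop codons always rejected); out-of-frame lineages
#' accept every nucleotide proposal.  For every productive depth-2 PCP the
#' oracle emits the landscape's log selection factor (plus optional Gaussian
#' noise) for every site and single-nucleotide-reachable target.
#'
#' @param germlines a `germline_set`.
#' @param neutral a `neutral_model`.
#' @param landscape a `selection_landscape` covering the germline site
#'   labels.
#' @param config a `simulation_config`.
#' @return list with elements `productive`, `out_of_frame` (PCP tables),
#'   `selection_factors` (oracle table, `NULL` if not emitted) and `config`.
#' @export
simulate_repertoire <- function(germlines, neutral, landscape, config) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(neutral, "neutral_model"),
            inherits(landscape, "selection_landscape"))
  set.seed(derive_seed(config$seed, "repertoire"))

  res <- list(productive = list(), out_of_frame = list())
  sf_parts <- list()

  for (gi in seq_len(nrow(germlines))) {
    gene <- germlines$name[gi]
    labs <- germlines$site_labels[[gi]]
    si <- match(labs, landscape$sites)
    if (any(is.na(si))) {
      stop("landscape does not cover all sites of gene ", gene)
    }
    lan3 <- landscape_array(landscape, gene)[si, , , drop = FALSE]
    root <- nt_to_int(germlines$nt_sequence[gi])
    L <- length(root) %/% 3L

    # oracle grid: one row per (site, reachable target) of the germline
    grid <- NULL
    if (config$emit_selection_factors) {
      cidx <- seq_codon_indices(root)
      gs <- list(site = character(0), paa = character(0), taa = character(0))
      for (j in seq_len(L)) {
        tg <- .ab$reachable_aas[[cidx[j]]]
        if (length(tg)) {
          gs$site <- c(gs$site, rep(labs[j], length(tg)))
          gs$paa <- c(gs$paa, rep(.ab$aa64[cidx[j]], length(tg)))
          gs$taa <- c(gs$taa, tg)
        }
      }
      true_lf <- landscape_log_f(landscape, gs$site, gs$paa, gs$taa, gene = gene)
      grid <- data.frame(site = gs$site, parent_aa = gs$paa,
                         target_aa = gs$taa, true_lf = true_lf,
                         stringsAsFactors = FALSE)
    }

    for (role in c("productive", "out_of_frame")) {
      nfam <- if (role == "productive") config$n_families_per_gene else
        config$n_oof_families_per_gene
      if (nfam == 0L) next
      productive <- role == "productive"
      for (f in seq_len(nfam)) {
        fam <- sim_family(root, config, neutral,
                          if (productive) lan3 else NULL, productive)
        ne <- length(fam$depth)
        fam_id <- sprintf("%s:%s:%d", gene, role, f)
        ids <- sprintf("%s:e%d", fam_id, seq_len(ne))
        res[[role]][[length(res[[role]]) + 1L]] <- list(
          pcp_id = ids, family_id = rep(fam_id, ne), depth = fam$depth,
          is_leaf_child = fam$leaf, v_gene = rep(gene, ne),
          frame_class = rep(role, ne),
          parent_nt = fam$parent, child_nt = fam$child)
        if (productive && !is.null(grid)) {
          d2 <- ids[fam$depth == 2L]
          G <- nrow(grid)
          lf <- rep(grid$true_lf, times = length(d2))
          if (config$oracle_noise_sd > 0) {
            lf <- lf + stats::rnorm(length(lf), 0, config$oracle_noise_sd)
          }
          sf_parts[[length(sf_parts) + 1L]] <- list(
            pcp_id = rep(d2, each = G),
            site = rep(grid$site, times = length(d2)),
            parent_aa = rep(grid$parent_aa, times = length(d2)),
            target_aa = rep(grid$target_aa, times = length(d2)),
            log_f = lf)
        }
      }
    }
  }

  bind <- function(parts, cols) {
    out <- lapply(cols, function(cl) {
      unlist(lapply(parts, `[[`, cl), use.names = FALSE)
    })
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  pcp_cols <- c("pcp_id", "family_id", "depth", "is_leaf_child", "v_gene",
                "frame_class", "parent_nt", "child_nt")
  empty_pcp <- data.frame(pcp_id = character(0), family_id = character(0),
                          depth = integer(0), is_leaf_child = logical(0),
                          v_gene = character(0), frame_class = character(0),
                          parent_nt = character(0), child_nt = character(0),
                          stringsAsFactors = FALSE)
  sf <- NULL
  if (config$emit_selection_factors) {
    sf <- bind(sf_parts, c("pcp_id", "site", "parent_aa", "target_aa", "log_f"))
  }
  list(productive = if (length(res$productive))
         bind(res$productive, pcp_cols) else empty_pcp,
       out_of_frame = if (length(res$out_of_frame))
         bind(res$out_of_frame, pcp_cols) else empty_pcp,
       selection_factors = sf,
       config = config)
}
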