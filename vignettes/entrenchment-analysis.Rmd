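---
title: "Detecting entrenched germline amino acids in antibody V genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting entrenched germline amino acids in antibody V genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abentrench)
```

## The question and the statistic

Human immunoglobulin heavy-chain variable (IGHV) genes are a family of
roughly fifty paralogs that differ at up to ~40% of amino-acid positions.
When two V genes carry different germline amino acids at a homologous
Chothia-numbered site, the difference may be neutral, or each residue may be
*entrenched*: held in place by epistatic constraints, so that substituting
toward the other gene's state is deleterious in both backgrounds.

Affinity maturation gives a direct window on this. B-cell clonal families
evolve rapidly under selection for antigen binding, and a selection model
fitted to repertoire data can assign each possible amino-acid substitution in
each sequence a *selection factor* `f`: the multiplicative shift of the
substitution's probability relative to the neutral mutation process, analyzed
throughout on the natural-log scale. `abentrench` consumes tables of such
per-sequence log selection factors together with the clonal-family
parent-child pairs (PCPs) they were computed on, and asks, for every site
`j` and unordered amino-acid pair (A, B):

> median log f_j(A→B) < −1  **and**  median log f_j(B→A) < −1 ?

A pair meeting both conditions is classified entrenched: each substitution
runs at less than `100·exp(−1)` ≈ 37% of its neutral rate. The threshold is
a tunable parameter (`threshold`, default −1, strict inequality); the
cutoff deliberately targets strong bidirectional purifying selection since
entrenchment strength is continuous.

Three filters precede aggregation, each with a rationale:

* **Root edges only** (`depth == 2`): the parent is the most recent common
  ancestor of its clonal family, where selection factors are not yet shifted
  by accumulated somatic mutations.
* **Germline-codon parents**: the parent codon at the site must be
  *nucleotide-identical* to the assigned germline codon. We read the
  requirement that the parent amino acid be "encoded by a germline codon"
  in its strictest sense — identity at the nucleotide level — because it
  guarantees both the amino-acid state and the local mutational context
  match germline. A synonymous codon variant is therefore excluded. The
  weaker amino-acid-identity reading is used for mutation *counting* (see
  below), where the set of informative PCPs is defined by the parent's
  amino-acid state, not its context.
* **Single-nucleotide reachability**: the target amino acid must be
  reachable from the parent codon by one nucleotide substitution;
  multi-nucleotide substitutions are too rare to support stable estimates.

Medians are taken per (grouping, site, parent, target) with at least
`min_obs = 10` observations, using the ordinary midpoint rule for even
counts. Within a family, the grouping pools all V genes sharing the same
germline amino acid at the site. Between families, only sites where the two
families *differ* in germline identity are compared: an amino acid that is
germline in both families at a site is a within-family comparison and is
excluded from the between-family list.

## Validating the grouping: ICC and threshold agreement

Pooling V genes that share a germline amino acid assumes the local selection
landscape is similar across those genes. Two checks quantify this. First,
per-gene medians (minimum 3 observations per gene-level combination) are
decomposed with a one-way random-effects model into between-group
(substitution identity) and within-group (V-gene identity) variance,
summarized as

ICC(1) = (MSB − MSW) / (MSB + (n₀ − 1)·MSW),

with the standard unbalanced-design correction
n₀ = (N − Σnᵢ²/N)/(k − 1). Negative values are reported as computed — they
indicate within-group dominance and are informative — and the estimator is
checked in the tests against an independent ANOVA decomposition. Second,
*threshold agreement* is the fraction of individual gene medians at
family-level entrenched combinations that independently fall below the
threshold.

## Validating the selection factors: rate ratios

When per-site mutation probabilities are small, the ratio of observed to
neutrally expected substitution rates approximates the selection factor.
Counts are accumulated per (V family, site, germline amino acid A, target
B) over PCPs whose parent retains germline A at the site (amino-acid
identity at the codon). Productive counting excludes PCPs whose child is a
leaf — mutations on internal edges have demonstrably survived further
rounds of selection — while out-of-frame counting keeps every PCP, because
those data are the scarce limiting resource. PCPs containing ambiguous
nucleotides are removed before counting. Synonymy is classified at codon
level (all nucleotide differences in a codon count as synonymous iff the
codon's amino acid is unchanged), since per-nucleotide attribution is
ill-defined for multi-hit codons. Codon changes that create stop codons are
excluded as targets.

**Approach 1** uses out-of-frame (non-productive) sequences — frameshifted
rearrangements that evolve neutrally with respect to amino-acid changes —
as an empirical neutral baseline. Rates divide counts by per-PCP branch
lengths measured as the frequency of synonymous nucleotide mutations, a
quantity under comparable selective pressure in both datasets, so residual
bias approximately cancels in the ratio. The log rate ratio uses 0.5
pseudocounts on both counts, and a substitution passes filtering only with
at least 5 *raw* out-of-frame mutations.

**Approach 2** replaces the empirical baseline with expected counts from
the neutral mutation model itself. Per PCP, branch length is the total
nucleotide mutation frequency scaled by `alpha` (default 1.6 — observed
mutations are ~1/1.6 ≈ 63% as likely as neutral expectation once purifying
selection has removed its share); the per-site mutation probability is
`1 − exp(−λ·t)` with `λ` the summed per-nucleotide context-dependent rates
of the parent codon, and the conditional outcome distribution sums the
per-base substitution probabilities over the codon's single-nucleotide
neighbors (synonymous and stop outcomes complete the normalization).
Because observed and expected counts share the same trees, branch lengths
approximately cancel and counts are compared directly, with the same
pseudocount and an expected-count ≥ 5 filter.

For synthetic data the package also provides `estimate_alpha()`, which
mirrors the way `alpha` is derived in practice (a regression of observed
mutation frequencies against selection-corrected branch lengths) using
synonymous mutations as the neutral anchor: the neutral model supplies each
parent sequence's total-to-synonymous rate ratio, so the synonymous count
predicts the neutral total and `alpha` is the summed prediction over the
summed observed total. The estimator inherits a small downward bias from
codon-level synonymy classification at high per-branch mutation density
(multi-hit codons swallow synonymous changes); at the simulation densities
used here the bias is below 0.05 on the log scale.

Agreement between rate ratios and median log selection factors is
summarized by the Pearson correlation and a Deming (orthogonal, error-variance
ratio 1) regression, appropriate because both variables carry error; the
closed-form estimator is cross-checked in the tests against a brute-force
perpendicular-distance minimizer.

## Structural characterization

Entrenched sites are interpreted structurally through four quantities:

* **SASA** by the Shrake–Rupley method: 960 deterministic golden-spiral
  sphere points per atom, probe radius 1.4 Å, NACCESS-flavored van der
  Waals radii (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å). Sphere
  directions are expressed in a PCA-canonical molecular frame with a
  third-moment sign convention, making results invariant under rigid
  rotation and translation to machine precision — a property the tests
  verify at 1e-6 relative tolerance. Waters and heteroatoms are excluded.
* **RSA** divides residue SASA by the Wilke theoretical maximum for the
  residue type. Values above 1 (possible for unusually exposed
  conformations) are reported unclamped; figures should clip at 1.
* **Partner-removal decomposition**: SASA is computed in four scenarios —
  full complex, antibody only, heavy chain only, and heavy chain with the
  CDR3 removal window (Chothia 95–102, one position beyond the CDR-H3
  boundaries on each side) excised. FR4 (103–113) is retained in the last
  scenario: although J-gene-encoded, it is a conserved framework segment,
  not part of the somatically diversified junction. Differences between
  consecutive scenarios give the antigen, light-chain and CDR3 burial
  effects. All four scenarios share one canonical frame, so the three
  effects telescope *exactly* to RSA₄ − RSA₁ and are individually
  non-negative up to numerical tolerance (removing atoms cannot shrink the
  remaining exposure).
* **Backbone dihedrals** (φ, ψ) from N/Cα/C coordinates, in degrees on
  (−180, 180], with φ undefined at the first residue and ψ at the last;
  the sign convention is checked against an independent torsion
  implementation.

Physicochemical contrast between entrenched and non-entrenched pairs uses
Grantham distances, computed from the published composition/polarity/volume
properties with constants 1.833, 0.1018, 0.000399 and scale 50.723, rounded
to integers (spot-checked: Leu–Ile 5, Ser–Thr 58, Arg–Leu 102). Because
different sites carry different amino-acid repertoires, the test is a
stratified permutation: labels are shuffled independently within each
(family, site) stratum, the statistic is the across-strata mean of
(mean entrenched distance − mean non-entrenched distance), and the
one-sided p-value is the plain proportion of permuted statistics at or
above the observed one, with no +1 correction. Strata containing a single
label class are excluded from both observed and permuted statistics, with a
message. For very small problems `exact = TRUE` enumerates every distinct
labeling, which is what the exhaustive three-labeling example in the tests
uses.

## The synthetic repertoire generator

Because the analysis is defined against external repertoire datasets and a
trained selection model, the package carries a generator that reproduces the
statistical structure the analysis assumes, so every stage is testable
end-to-end from code alone.

* `make_germline_set()` builds V families from a shared stop-free base
  sequence. Family consensus and per-gene changes are nonsynonymous
  single-nucleotide codon substitutions at disjoint positions, giving
  controlled within-family (≤ target + 0.05) and between-family (target
  ± 0.1) amino-acid divergence. Designated diversity sites carry two or
  three germline amino acids per family — every third site three-variant by
  default, mimicking the multi-residue repertoires of real diverse sites
  and giving the Grantham strata more than one pair — assigned to gene
  subsets chosen greedily so the diversity load is near-uniform across
  gene pairs and the realized divergence is close to deterministic. Each
  alternative is single-nucleotide reachable from the base codon (and the
  two alternatives from each other where the codon allows it).
* `simulate_repertoire()` grows each clonal family as a rooted tree whose
  root is the germline sequence; child counts are Poisson (the root is
  forced to have at least one child so depth-2 PCPs always exist), and each
  edge receives a Poisson number of proposed single-nucleotide events
  applied sequentially, so multi-hit codons arise naturally. Positions and
  replacement bases follow the neutral model (`uniform`, or `context_3mer`
  with reproducible per-3-mer rate multipliers normalized to mean 1).
  Productive lineages accept a proposed nonsynonymous change with
  probability min(1, exp(log f)) — chosen precisely because it makes the
  realized observed/expected rate ratio converge to exp(log f) for
  deleterious changes, the relationship the rate-ratio validation assumes —
  and always reject stop codons; synonymous changes are always accepted.
  Out-of-frame lineages accept everything, emulating neutrality with
  respect to amino-acid changes on the same V region without modelling the
  frameshifted junction explicitly.
* The **selection-factor oracle** emits, for every productive depth-2 PCP,
  site and single-nucleotide-reachable target, the landscape's true log
  selection factor plus optional Gaussian noise (`oracle_noise_sd`), which
  stress-tests the robustness of median aggregation.
* `make_selection_landscape()` draws non-planted directed values i.i.d.
  from Uniform(−0.9, 0). The purifying-only default reflects the regime
  the rate-ratio validation operates in (germline-encoded framework sites
  under predominantly purifying selection) and keeps non-planted pairs
  clearly separated from the −1 threshold, so recovery tests measure
  detection of the planted signal rather than threshold-grazing noise.
  Planted entrenched pairs get a constant log f (default −1.5) in both
  directions; per-gene overrides support planting outlier genes.
* `simulate_complex()` builds idealized antibody-antigen complexes:
  N–Cα–C backbones from internal coordinates (standard bond geometry,
  random-coil φ/ψ, trans ω) with light chain and antigen translated to
  pack against randomly chosen heavy residues. The geometry exercises the
  accessibility and dihedral machinery; it makes no claim to protein
  physics.

What passing tests on these data do and do not show: they demonstrate that
the statistics are implemented correctly and recover planted truth under
the generator's assumptions (independent sites, context-dependent but
time-homogeneous mutation, selection acting per proposed change). Real
repertoires add alignment and annotation error, per-individual repertoire
structure, indels, selection-model misspecification and phylogenetic
uncertainty, none of which the generator emulates; conclusions about real
data rest on the upstream models, not on these tests.

## Study-condition defaults and problem sizes

The default synthetic study conditions (`run_config()`) are: 2 families × 5
genes of 100 codons; within/between divergence targets 0.10/0.30; 20
diversity sites; 3 planted entrenched pairs at log f −1.5; oracle noise
sd 0.25; 24 clonal families per gene (about 50 depth-2 PCPs per gene, so
every candidate direction clears 30 observations); Poisson(2) children to
depth 4 and Poisson(4) proposed events per edge (~2% per-branch nucleotide
divergence). Under these conditions the detector recovers all planted
pairs with no false discoveries across seeds, family-level ICC is ≈ 0.97
and threshold agreement ≈ 100% — the tests and the acceptance script
recompute these rather than quoting them.

Rate-ratio analyses need far more events, since they count realized
substitutions at specific sites: those runs use 2 families × 4 genes of 60
codons, 2 500 productive and 700 out-of-frame families per gene (~650 000
and ~180 000 PCPs), sized so that planted substitutions accumulate ≥ 50
baseline counts and Monte-Carlo error is small against the comparison
bands. The agreement summary (Pearson, Deming) is computed over
substitutions with expected counts ≥ 50; below that the per-substitution
ratio noise (sd ≈ 1/√count) dominates and attenuates any correlation — the
same stability rationale as the published ≥ 5 filter, applied at the scale
of these larger synthetic counts.

Numerical details worth knowing: medians use the midpoint rule; the
entrenchment inequality is strict, so a median exactly at the threshold is
not entrenched; rate ratios are undefined (and dropped, with a message)
when an exposure is zero; Deming fits error out on degenerate variance;
the permutation p can be exactly 0 or 1 by construction; and all
randomness everywhere derives from explicit integer seeds, so every table
the pipeline writes — including the run manifest — is byte-identical across
runs with the same configuration.

## Known limitations

* The selection-factor oracle is a planted landscape, not a trained model;
  interface compatibility, not predictive accuracy, is what is tested.
* `estimate_alpha()`'s synonymous anchor is biased low by a few percent at
  high per-branch mutation density (codon-level synonymy classification);
  real-data work should prefer an externally calibrated `alpha`.
* Approach-2 expected counts consider single-nucleotide neighbors only;
  multi-hit corrections are out of scope, so substitutions requiring two
  nucleotide changes are systematically unexpected (and are excluded by
  the expected-count filter).
* The Shrake–Rupley quadrature is exact only in the limit of many sphere
  points; comparisons should stay within a fixed point count (default 960,
  worst-case area error well under 1%).
* Chothia numbering is taken as given on input; assigning it from sequence
  is an annotation tool's job.
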