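Package: abentrench
Title: Entrenchment Analysis of Antibody Germline V Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects reciprocally disfavored (entrenched) germline amino-acid
    substitutions across immunoglobulin heavy-chain variable (IGHV) genes from
    per-sequence natural-log selection factors, and validates those signals
    end-to-end. Provides parent-child pair (PCP) and selection-factor table
    handling with Chothia site numbering, reciprocal median selection-factor
    aggregation within and between V-gene families, one-way random-effects
    intraclass correlation and threshold-agreement checks of the within-family
    grouping, observed-versus-expected mutation-rate-ratio validation against an
    out-of-frame neutral baseline and against a context-dependent neutral
    mutation model (with Deming orthogonal regression comparison), per-residue
    solvent-accessibility decomposition of antibody-antigen complexes
    (Shrake-Rupley SASA, Wilke-normalized RSA, partner-removal effects),
    backbone dihedrals, Grantham-distance stratified permutation testing, and a
    seeded synthetic-repertoire generator (clonal families evolving under a
    context-dependent neutral mutation process with a planted amino-acid
    selection landscape) so the whole pipeline is testable without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
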