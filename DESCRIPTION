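Package: codsig
Title: Derivation and Application of a Core Diffuse-Type Gastric Cancer
    Expression Signature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a cluster-derived gene-signature workflow for
    diffuse-type gastric cancer: variance filtering and unsupervised
    hierarchical clustering of bulk expression profiles into normal-like,
    intestinal-like and core diffuse-type groups; differential-expression
    screening with a Venn partition that isolates the core diffuse-type (COD)
    signature; two-subtype classification of independent cohorts; Kaplan-Meier,
    log-rank and Cox proportional-hazards prognostic analysis including a
    chemotherapy-by-subtype interaction model; tumor-mutation-burden and
    per-gene mutation-frequency contrasts; and a synthetic cohort generator
    with known latent structure so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
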