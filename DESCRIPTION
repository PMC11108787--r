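Package: lctau
Title: Locus Coeruleus Integrity, Tau Spread and Transcriptomic Similarity
Version: 0.1.0
Authors@R: person("lctau", "maintainers", email = "lctau@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline linking neuromelanin-sensitive MRI measures
    of locus coeruleus (LC) integrity to longitudinal tau-PET accumulation,
    cognition, ex vivo tangle staging and shared gene-expression profiles.
    Provides LC intensity quantification from dedicated MRI slabs, voxel-wise
    general linear models with Monte-Carlo cluster-extent correction,
    Johnson-Neyman moderation and nonparametric bootstrap mediation, exact
    binomial spatial staging of tangle pathology, partial Spearman
    correlations, an Allen-atlas-style imaging-transcriptomics aggregation
    with top-fraction gene intersections, and a synthetic-data generator that
    plants every effect the downstream stages are expected to recover.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
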