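Package: SigPolytope
Title: Convex-Polytope Geometry of Paired Multi-Omic Signatures
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Represents paired multi-omic regulatory circuitries (a signature
    side and an interaction side) as 18-dimensional latent vectors built from
    phenotype correlations, tumor-versus-normal shifts, four survival
    endpoints, microenvironment scores and immune classes; embeds all
    circuitries jointly by principal component analysis; expands each side
    into an axis-aligned convex polytope; and derives geometric descriptors
    (barycenter distance, convex-hull volumes, volume asymmetry, anisotropy)
    together with distance regimes, nine volume classes, four joint geometric
    phenotypes and a concordance summary. Includes Shannon-entropy
    heterogeneity analysis, baseline discordance benchmarking, axis-ablation
    robustness checks, a stratified permutation null model with the
    bias-corrected empirical p-value estimator, a synthetic-atlas generator
    with controllable concordance structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'SigPolytope-package.R'
    'circuitry-table.R'
    'cli.R'
    'embedding.R'
    'encoding.R'
    'hull3d.R'
    'mesh.R'
    'params.R'
    'permutation.R'
    'pipeline.R'
    'polytope.R'
    'regimes.R'
    'simulate.R'
    'stats.R'
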