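Package: fibroprog
Title: Cross-Model Transcriptional Programs in Genetic Liver Fibrosis Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts a common transcriptional program across multiple
    knockout mouse models of liver fibrosis. Provides per-gene two-group
    linear models with empirical-Bayes moderated t-statistics and
    Benjamini-Hochberg false discovery rates; parametric gene-set enrichment
    (per-sample set activation scores followed by sample-level inference);
    cross-model Venn partitioning, asymmetric similarity-ratio matrices and
    hierarchical clustering; and integration of differential expression into
    a constraint-based metabolic model by exact binary gene-state matching
    (MADE-style), with flux balance and flux variability analysis and
    hypergeometric subsystem enrichment. A synthetic-data generator emulates
    multi-study knockout-versus-wild-type designs with planted effects so the
    whole pipeline can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
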