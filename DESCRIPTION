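Package: mdikit
Title: Microbial Dysbiosis Index Scoring for Gut Microbiota Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes a microbial dysbiosis index (MDI) for 16S gut
    microbiota profiles: a percentage quadratic dissimilarity between a
    subject's multi-level taxonomic profile (phylum, family, genus) and
    the median profile of age- and gender-matched healthy controls, with
    mild/moderate/high dysbiosis classification. Includes the taxonomic
    preprocessing the score requires (rank collapse, relative-abundance
    conversion, prevalence/abundance filtering, cumulative sum scaling,
    rarefaction), alpha/beta diversity and PERMANOVA wrappers, a
    taxa-index correlation battery with Benjamini-Hochberg FDR, a
    faecal-ileal correlation network builder, and a Dirichlet-multinomial
    synthetic cohort generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
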