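Package: teclass
Title: Feature-Based Classification of mRNA Translation Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Encodes open reading frames as named feature vectors (codon
    usage frequencies, start-codon context, composition-transition-
    distribution protein descriptors, network-neighborhood Gene Ontology
    enrichment scores and auxiliary mRNA properties), ranks features by
    maximum-relevance minimum-redundancy mutual information, classifies
    high versus low translation rate with a cosine-distance nearest-
    neighbor rule under jackknife (leave-one-out) cross-validation, picks
    the optimal feature subset by incremental feature selection, and
    reports point-biserial feature-class correlations. Ships a
    deterministic synthetic-data generator with planted signal so the
    whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
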