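Package: caseolap
Title: Text-Cube Scoring of Protein-Disease Associations in the Biomedical Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds disease-specific document cells from MeSH descriptor
    annotations of MEDLINE/PubMed records, counts protein name mentions with a
    curated synonym dictionary, and scores every protein-cell pair by the
    CaseOLAP composite of integrity, popularity and distinctiveness. Downstream
    stages derive per-cell score cutoffs and attribution classes, rank top
    proteins, quantify cross-domain overlaps, regress and cluster score
    vectors, and validate ranked proteins against expression data via
    Kolmogorov-Smirnov differential ranking, exact hypergeometric enrichment
    and tissue-of-maximal-expression assignment. Synthetic corpus and
    expression generators with planted ground truth make every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    stringi,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
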