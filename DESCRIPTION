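Package: cernet
Title: Dysregulated miRNA-Mediated lncRNA-mRNA ceRNA Networks and
    Random-Forest lncRNA Biomarker Selection
Version: 0.1.0
Authors@R: person("cernet", "maintainers", email = "cernet@example.org",
    role = c("aut", "cre"))
Description: Builds dysregulated miRNA-mediated lncRNA-mRNA competing
    endogenous RNA (ceRNA) networks from paired two-group expression
    profiles of three RNA classes and a table of validated miRNA-target
    interactions. Provides moderated-t differential expression, Pearson
    correlation filtering of candidate lncRNA-mRNA crosstalk, a shared
    negatively correlated miRNA mediation filter, random-forest out-of-bag
    feature selection of lncRNA biomarker panels, leave-one-out
    cross-validated ROC/AUC evaluation, hypergeometric over-representation
    with enrichment-map style term clustering, a synthetic data generator
    with planted ground truth, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
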