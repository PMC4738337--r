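Package: crossdex
Title: Cross-Species Transcriptome Subtyping and Agreement of Differential
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumour subgroup discovery from log2 expression matrices and
    cross-species matching of the discovered entities. Implements
    background and relative-IQR gene filtering, three unsupervised
    subgrouping routes (average-linkage hierarchical clustering on
    Pearson distance, consensus clustering with PAC-based model
    selection, Kullback-Leibler non-negative matrix factorization with
    cophenetic model selection), per-gene Welch tests with
    Benjamini-Hochberg adjustment and fold-change filtering, group
    signature construction, AGDEX-style agreement of differential
    expression over one-to-one orthologs with permutation inference,
    centroid correlation against reference progenitor profiles, and a
    two-species synthetic data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
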