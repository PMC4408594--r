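Package: protofam
Title: Hierarchical Protein Family Clustering from Pairwise Sequence Similarity
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bottom-up agglomerative clustering of proteins from all-vs-all
    BLAST E-values into a binary merge forest, with ProtoLevel (percentage of
    merge steps completed) and LifeTime (persistence of a cluster along the
    merge trajectory) coordinates. Families are extracted as the disjoint
    clusters alive at a chosen ProtoLevel cut. Annotation quality is scored
    against keyword tables (Pfam-style domain assignments) with a Jaccard
    correspondence score and specificity (purity), and keywords are
    transferred to unannotated members of sufficiently pure families
    (guilt-by-association annotation gain). Species representation of
    families is tested against an exact multinomial occupancy null computed
    by inclusion-exclusion. A synthetic-data generator with planted family
    structure makes the whole pipeline testable without sequence downloads,
    and a command-line entry point exposes every step as a subcommand.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
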