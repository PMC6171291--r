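Package: exclutax
Title: Exclusivity-Based Delimitation of Bacterial Taxa from Genome
    Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Delimits bacterial taxa by the exclusivity criterion: a group
    is exclusive when all of its members are more closely related to each
    other than to any genome outside the group, with relatedness measured
    as the average of per-gene patristic distances across the core genome.
    Provides readers for gene trees, presence/absence matrices, pairwise
    protein hit tables and ANI/AF tables; reconstruction of clusters of
    orthologous genes from filtered reciprocal-best-hit graphs by Markov
    clustering; UPGMA and gene-content (Jaccard) trees; Robinson-Foulds
    comparison with an analytic null for random trees; Fitch parsimony
    gain/loss mapping of the pan-genome; exclusivity scoring, enumeration
    and subsampling analyses; and species assignment as the largest
    exclusive groups meeting a joint ANI/AF threshold under single- or
    complete-linkage. A synthetic-data generator produces clock-like
    species trees, transfer-discordant gene trees, gain/loss gene content
    and ANI/AF tables for testing every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
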