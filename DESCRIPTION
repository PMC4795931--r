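Package: themenet
Title: Gene-Set Enrichment, PPI Confidence and Composite Molecular
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for list-centric systems-biology analysis: unifies
    chemical compounds by InChIKey skeleton and filters bioactivities by
    binding-assay criteria, classifies protein-protein interactions into
    high-confidence and direct-physical subsets from multi-source evidence,
    computes degree and betweenness centrality with hub/bottleneck calls on
    the largest network component, derives orthologues by mutual best hits
    and converts gene lists across species, performs Fisher's exact theme
    enrichment with Bonferroni/Holm/Benjamini-Hochberg correction, renders
    heatmap-ready binary gene-by-theme matrices ordered by UPGMA clustering,
    and assembles composite typed interaction networks (PPI, miRNA-target,
    protein-compound, TF-target) around a query gene list. Includes a
    deterministic synthetic-fixture generator and an end-to-end workflow
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
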