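Package: phylospat
Title: Spatial Phylogenetic Diversity, Endemism and Multi-Taxon Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-based spatial phylogenetics for one or several co-registered
    taxonomic groups. Aggregates point occurrence records to an equal-area
    grid, computes per-cell taxon richness, weighted endemism, phylogenetic
    diversity and endemism, and their relative (equal-branch-length
    comparison tree) variants, tests them against a fixed-margin
    randomization null, classifies cells of significant phylogenetic
    endemism into neo-, paleo-, mixed- and super-endemism (CANAPE), clusters
    cells by phylogenetic (phylo-jaccard) beta diversity, and compares
    diversity surfaces across taxonomic groups via 0-1 standardization,
    mean-all and mean-concordant summary maps and fuzzy neighborhood map
    comparison. Includes seeded generators for synthetic trees, spatially
    clustered species ranges and injected endemism scenarios so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    phangorn
Config/testthat/edition: 3
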