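Package: introdepth
Title: Gene-Tree Discordance, Node-Depth Introgression Tests, and LTR
    Insertion-Age Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-phylogenomic toolkit for separating introgression
    from incomplete lineage sorting among three lineages and an outgroup.
    Provides a multispecies-coalescent gene-tree simulator with an optional
    post-speciation introgression pulse, sliding-window alignment masking,
    triplet gene-tree classification with internode certainty, a node-depth
    (T1/T2) test that assigns the species branching order to the deeper set
    of gene trees, and insertion-age dating of long terminal repeat
    retrotransposons from terminal-repeat divergence (T = K / 2 mu). All
    stages are driven either by user data or by the built-in synthetic-data
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
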