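Package: longamp
Title: Near Full-Length 16S rRNA Amplicons from Dual Molecular Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, reconstruction and analysis of near full-length
    (>1300 nt) 16S rRNA gene amplicon libraries built with 10-nt random
    molecular tags on both amplicon ends. Provides a ground-truthed paired-end
    library simulator (tag collisions, PCR substitution errors, chimeras,
    tagmentation fragments mixed with full-length amplicons), per-tag-bin
    greedy overlap-layout-consensus assembly with completeness filtering,
    open-reference OTU clustering at a configurable identity threshold with
    IUPAC-aware pooling rules, alpha-diversity statistics (rarefaction,
    one-tailed Mann-Whitney group comparison, rank abundance, taxon-level
    composition), and strain-level haplotype analysis of a focal OTU
    contrasting full-length against V4 sub-region resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
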