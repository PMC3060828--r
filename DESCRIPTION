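Package: swarmprimer
Type: Package
Title: Particle Swarm Design of Conserved Overlapping Primer Tilings for
    Circular Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs complete sets of mutually overlapping PCR primer pairs
    that tile an entire circular genome (such as a mitochondrial genome),
    restricting primers to regions conserved across a multiple sequence
    alignment of closely related species. Candidate primer pairs are scored
    against standard design constraints (nearest-neighbor melting
    temperature, GC content, product length, secondary structure,
    specificity, terminal composition) and optimized one amplicon at a time
    with particle swarm optimization; a sliding window walks the circle so
    that consecutive amplicons overlap, supporting reliable end-to-end
    sequencing by primer walking. Includes a synthetic generator of closely
    related circular genome families for testing, tabular/BED/JSON output
    writers, and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
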