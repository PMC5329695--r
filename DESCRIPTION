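Package: pseudoprimer
Title: In-Silico Auditing of 16S rRNA PCR Primers Against Central
    Pseudoknot Base Pairing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates degenerate PCR primers for functional cloning of
    bacterial 16S rRNA genes. Anchors arbitrary 16S templates onto
    Escherichia coli numbering by pairwise semi-global alignment, profiles
    per-position nucleotide composition and primer coverage at the gene
    termini, audits primer footprints against base-paired variable sites of
    the central pseudoknot (helix h2, positions 17-19 paired with 918-916),
    classifies 19-916 base pairs by an experimentally derived functionality
    rule table, predicts primer-templated substitution artifacts in
    amplicons, and tabulates clone libraries by taxon origin and base-pair
    pattern. Includes a deterministic synthetic 16S-like template and clone
    generator so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
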