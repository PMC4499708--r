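Package: phytofam
Title: Evolutionary Analysis of Plant Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for studying the expansion of plant gene
    families, developed around the phytocyanin (plant blue copper protein)
    family. It types protein architectures from signal-peptide, domain,
    AGP-like-region and GPI-anchor annotations; estimates pairwise Ka and
    Ks by Nei-Gojobori counting with Jukes-Cantor correction; dates
    duplication events with a synonymous molecular clock (T = Ks/2*lambda)
    and classifies their mechanism as tandem, segmental or
    retrotransposition from gene order, collinear anchor chains and intron
    loss; builds neighbor-joining trees with bootstrap support; reconciles
    gene trees against a labelled species tree to count duplications,
    losses and ancestral copy numbers; infers retrogene donor genes from
    conserved-intron presence; and summarises tissue expression and qPCR
    relative expression (2^-ddCt). A seeded simulator generates
    ground-truthed gene families, codon pairs, genome layouts and Ct
    tables so every step is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
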