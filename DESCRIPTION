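Package: slocus
Title: S-Locus Genotype Dynamics and Hemizygosity Analysis for the Loss of
    Distyly in Primula
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying intraspecific transitions from distyly to
    homostyly at the hemizygous Primula S-locus supergene. Implements a
    deterministic genotype-frequency recursion (Crosby's model) with
    viability selection on homozygous homostyles, a read-depth classifier
    for S-locus copy number, loss-of-function and structural screens on the
    style-length gene CYP^T (premature stop codons, frameshift indels,
    zero-coverage deletions, discordant read pairs), missing-data-aware
    nucleotide diversity at 0-fold and 4-fold degenerate sites, and
    chi-squared goodness-of-fit of observed S-locus genotype frequencies to
    model expectations. A synthetic-data module generates gene models,
    allele sequences, cohorts, depth tracks and genotype matrices with
    known ground truth so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
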