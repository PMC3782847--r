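Package: pyroimmune
Title: Comparative Immune Transcriptome Analysis from Pyrosequencing Read Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of insect immune transcriptomes
    sequenced as single pyrosequencing read libraries per condition:
    hierarchical read triage against mitochondrial, ribosomal and nuclear
    gene references; expression quantification by reads per site per million
    (RPSM) with trimmed-mean-of-M-values (TMM) between-library normalization;
    induction coefficients with control-anchored contingency tests and
    regulation categories; immune gene class summaries and cross-species
    homologue mapping; discovery of novel transcription units from unmapped
    reads with translated homology screening; physicochemical screening of
    antimicrobial peptide candidates; Poisson-corrected neighbor-joining
    phylogenies with bootstrap support; and median lethal time (LT50)
    estimation from daily survival counts. A synthetic-data generator
    produces every input the pipeline consumes, with truth labels for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
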