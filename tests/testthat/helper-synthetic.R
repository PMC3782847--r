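# Shared synthetic fixtures, built in code at test time.

# A small two-library triage world: catalog, genome, reference sets and
# paired infected/naive read libraries with truth labels.
make_triage_world <- function(n_genes = 30, n_reads = 400, seed = 7,
                              mix = c(mito = 0.05, rrna = 0.25, gene = 0.50, unannotated = 0.20),
                              n_hidden = 3) {
  catalog <- sim_gene_catalog(n_genes = n_genes, seed = seed)
  genome <- sim_genome(catalog, n_hidden = n_hidden, seed = seed + 1)
  seg_seq <- function(type) {
    s <- genome$segments[genome$segments$type == type, ][1, ]
    stats::setNames(substring(genome$sequence, s$start, s$end), type)
  }
  cds <- stats::setNames(catalog$cds_sequence, catalog$gene_id)
  references <- list(
    mito = seg_seq("mito"), rrna = seg_seq("rrna"),
    cds = cds, gene = cds, transcript = cds
  )
  reads_inf <- sim_read_library(genome,
    mix = mix, n_reads = n_reads,
    condition = "infected", seed = seed + 2
  )
  reads_nai <- sim_read_library(genome,
    mix = mix, n_reads = n_reads,
    condition = "naive", seed = seed + 3
  )
  list(
    catalog = catalog, genome = genome, references = references,
    reads = dplyr::bind_rows(reads_inf, reads_nai)
  )
}

# Truth stage implied by a read's source under an exact matcher whose
# cds/gene/transcript databases are all the catalog CDS set.
truth_stage <- function(truth_source) {
  ifelse(grepl("^gene:", truth_source), "cds",
    ifelse(truth_source == "unannotated", "unidentified", truth_source)
  )
}

# A count table with chosen per-gene RPSM-scale structure for quantification
# tests (deterministic, no RNG).
make_count_table <- function(reads_infected, reads_naive, lengths = NULL) {
  n <- length(reads_infected)
  tibble::tibble(
    gene_id = sprintf("G%03d", seq_len(n)),
    reads_infected = reads_infected,
    reads_naive = reads_naive,
    transcript_length = lengths %||% rep(1000L, n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
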