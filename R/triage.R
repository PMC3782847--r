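#' Hierarchical read triage
#'
#' Classifies each read by querying it against reference sets in the fixed
#' cascade order mitochondrial genome, then ribosomal RNA, then CDS, then
#' gene, then transcript sequences; the first stage with a hit stops the
#' cascade, and reads hitting nothing are `unidentified`. This mirrors the
#' read-accounting workflow used for single-library 454 transcriptome
#' surveys, where organellar and ribosomal reads are removed before per-gene
#' counting.
#'
#' @param reads Tibble with columns `read_id`, `sequence` and optionally
#'   `condition` (carried through).
#' @param references Named list with elements `mito`, `rrna`, `cds`, `gene`,
#'   `transcript`; each a named character vector or `XStringSet`. All five
#'   must be present (configuration error otherwise).
#' @param matcher A matcher function as returned by [kmer_matcher()].
#'
#' @return Tibble with `read_id`, `condition`, `stage` (one of `mito`,
#'   `rrna`, `cds`, `gene`, `transcript`, `unidentified`), `target_id`
#'   (present iff stage is cds/gene/transcript) and `score`.
#' @export
#' @seealso [count_reads_per_gene()], [summarize_library()]
classify_reads <- function(reads, references, matcher = kmer_matcher()) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  if (nrow(reads) == 0) {
    abort("`reads` must be non-empty.", class = "pyroimmune_parameter_error")
  }
  if (anyDuplicated(reads$read_id)) {
    abort("read ids must be unique.", class = "pyroimmune_parameter_error")
  }
  stages <- c("mito", "rrna", "cds", "gene", "transcript")
  missing <- setdiff(stages, names(references))
  if (length(missing) > 0) {
    abort(paste0("Missing reference set(s): ", paste(missing, collapse = ", ")),
      class = "pyroimmune_configuration_error"
    )
  }

  condition <- if ("condition" %in% names(reads)) reads$condition else NA_character_
  out <- tibble(
    read_id = reads$read_id,
    condition = condition,
    stage = "unidentified",
    target_id = NA_character_,
    score = NA_real_
  )
  remaining <- setNames(reads$sequence, reads$read_id)
  for (st in stages) {
    if (length(remaining) == 0) break
    refs <- as_reference_set(references[[st]], name = st)
    hits <- matcher(remaining, refs)
    if (nrow(hits) > 0) {
      i <- match(hits$query_id, out$read_id)
      out$stage[i] <- st
      out$score[i] <- hits$score
      if (st %in% c("cds", "gene", "transcript")) {
        out$target_id[i] <- hits$target_id
      }
      remaining <- remaining[!names(remaining) %in% hits$query_id]
    }
  }
  out
}

#' Count assigned reads per gene
#'
#' Tallies, per gene and condition, the reads assigned at the CDS, gene or
#' transcript stage of the triage cascade. Each read counts towards exactly
#' one gene. Genes listed in `genes` but hit by no read are retained with
#' count 0.
#'
#' @param assignments Output of [classify_reads()].
#' @param genes Optional character vector of gene ids to retain with zeros.
#' @return Tibble with `gene_id`, `reads_infected`, `reads_naive` (a missing
#'   condition yields a zero column).
#' @export
count_reads_per_gene <- function(assignments, genes = NULL) {
  assigned <- filter(assignments, .data$stage %in% c("cds", "gene", "transcript"))
  counts <- assigned |>
    mutate(condition = ifelse(is.na(.data$condition), "infected", .data$condition)) |>
    count(.data$target_id, .data$condition) |>
    tidyr::pivot_wider(
      names_from = "condition", values_from = "n",
      names_prefix = "reads_", values_fill = 0
    ) |>
    rename(gene_id = "target_id")
  for (col in c("reads_infected", "reads_naive")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  if (!is.null(genes)) {
    counts <- tibble(gene_id = genes) |>
      left_join(counts, by = "gene_id") |>
      mutate(across(c("reads_infected", "reads_naive"), ~ tidyr::replace_na(.x, 0L)))
  }
  select(counts, "gene_id", "reads_infected", "reads_naive")
}

#' Summarize a triaged read library
#'
#' Produces the per-library read accounting: totals, organellar and ribosomal
#' read counts, remaining ("other") reads, reads assigned to genes, distinct
#' genes hit, unidentified reads and read-length statistics. The conservation
#' identities `mito + rrna + other = total` and
#' `assigned + unidentified = other` hold by construction.
#'
#' @param assignments Output of [classify_reads()].
#' @param reads The read tibble passed to [classify_reads()].
#' @return One-row tibble per condition present in the library.
#' @export
summarize_library <- function(assignments, reads) {
  joined <- assignments |>
    left_join(select(reads, "read_id", "sequence"), by = "read_id") |>
    mutate(
      condition = ifelse(is.na(.data$condition), "all", .data$condition),
      length = nchar(.data$sequence)
    )
  joined |>
    group_by(.data$condition) |>
    summarise(
      total_reads = n(),
      mito_reads = sum(.data$stage == "mito"),
      rrna_reads = sum(.data$stage == "rrna"),
      other_reads = sum(!.data$stage %in% c("mito", "rrna")),
      assigned_reads = sum(.data$stage %in% c("cds", "gene", "transcript")),
      genes_hit = dplyr::n_distinct(.data$target_id[!is.na(.data$target_id)]),
      unidentified_reads = sum(.data$stage == "unidentified"),
      min_length = min(.data$length),
      max_length = max(.data$length),
      mean_length = mean(.data$length),
      .groups = "drop"
    )
}

#' Read-accounting identities from library totals
#'
#' Given per-library totals (total reads, mitochondrial reads, rRNA reads and
#' reads assigned to genes), computes the derived accounting columns: reads
#' remaining after organellar/ribosomal removal (`other_reads`, presumed
#' nuclear mRNA) and reads hitting no annotated gene (`unidentified_reads`).
#'
#' @param totals Tibble with columns `total_reads`, `mito_reads`,
#'   `rrna_reads` and (optionally) `assigned_reads`.
#' @return The input with `other_reads` (and, when `assigned_reads` is
#'   present, `unidentified_reads`) added.
#' @export
#' @examples
#' read_accounting(tibble::tibble(
#'   total_reads = 109106, mito_reads = 5557,
#'   rrna_reads = 25991, assigned_reads = 55358
#' ))
read_accounting <- function(totals) {
  stopifnot(is.data.frame(totals))
  need <- c("total_reads", "mito_reads", "rrna_reads")
  if (!all(need %in% names(totals))) {
    abort("`totals` needs total_reads, mito_reads, rrna_reads columns.",
      class = "pyroimmune_parameter_error"
    )
  }
  out <- mutate(totals,
    other_reads = .data$total_reads - .data$mito_reads - .data$rrna_reads
  )
  if ("assigned_reads" %in% names(totals)) {
    out <- mutate(out, unidentified_reads = .data$other_reads - .data$assigned_reads)
  }
  out
}
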