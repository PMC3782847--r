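#' Build contigs from unidentified reads by reference-guided assembly
#'
#' Places each unidentified read at its best genome position (same matcher
#' contract as the triage cascade), merges overlapping or touching placements
#' into maximal intervals and calls a per-column majority consensus (ties are
#' broken towards the reference base). Unmappable reads are reported, not
#' fatal.
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `condition`.
#' @param genome A `pyro_genome` or a single (optionally named) genome string.
#' @param matcher Matcher function from [kmer_matcher()].
#' @return Tibble of contigs (`contig_id`, `start`, `end`, `consensus`,
#'   `n_reads_infected`, `n_reads_naive`, `mean_depth`) with attributes
#'   `mapped_fraction` (mapped / total reads) and `placements` (per-read
#'   placement table).
#' @export
build_contigs <- function(reads, genome, matcher = kmer_matcher()) {
  genome_seq <- if (inherits(genome, "pyro_genome")) genome$sequence else unname(genome)[1]
  if (is.null(genome_seq) || nchar(genome_seq) == 0) {
    abort("`genome` must be non-empty.", class = "pyroimmune_parameter_error")
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  empty <- tibble(
    contig_id = character(), start = integer(), end = integer(),
    consensus = character(), n_reads_infected = integer(),
    n_reads_naive = integer(), mean_depth = numeric()
  )
  if (nrow(reads) == 0) {
    attr(empty, "mapped_fraction") <- NA_real_
    attr(empty, "placements") <- tibble()
    return(empty)
  }
  hits <- matcher(
    setNames(reads$sequence, reads$read_id),
    c(genome = genome_seq)
  )
  placements <- hits |>
    left_join(
      select(reads, query_id = "read_id", dplyr::any_of("condition")),
      by = "query_id"
    )
  if (!"condition" %in% names(placements)) placements$condition <- "infected"
  mapped_fraction <- nrow(placements) / nrow(reads)
  if (nrow(placements) == 0) {
    attr(empty, "mapped_fraction") <- mapped_fraction
    attr(empty, "placements") <- placements
    return(empty)
  }

  ir <- IRanges::IRanges(start = placements$target_start, end = placements$target_end)
  merged <- IRanges::reduce(ir)
  idx <- IRanges::findOverlaps(ir, merged, select = "first")
  placements$contig_index <- idx

  contigs <- purrr::map_dfr(seq_along(merged), function(ci) {
    cs <- IRanges::start(merged)[ci]
    ce <- IRanges::end(merged)[ci]
    width <- ce - cs + 1L
    sub <- placements[placements$contig_index == ci, ]
    rows <- match(sub$query_id, reads$read_id)
    votes <- matrix(0L, nrow = 4, ncol = width, dimnames = list(DNA_BASES, NULL))
    for (k in seq_len(nrow(sub))) {
      seq_chars <- strsplit(reads$sequence[rows[k]], "")[[1]]
      # the matcher reports ungapped placements; a span clipped at the
      # reference start drops the query prefix, otherwise the suffix
      span <- sub$target_start[k]:sub$target_end[k]
      offset <- span - cs + 1L
      qchars <- if (sub$target_start[k] == 1L && length(span) < length(seq_chars)) {
        utils::tail(seq_chars, length(span))
      } else {
        utils::head(seq_chars, length(span))
      }
      base_idx <- match(qchars, DNA_BASES)
      ok <- !is.na(base_idx)
      votes[cbind(base_idx[ok], offset[ok])] <- votes[cbind(base_idx[ok], offset[ok])] + 1L
    }
    ref_chars <- strsplit(substring(genome_seq, cs, ce), "")[[1]]
    consensus <- vapply(seq_len(width), function(col) {
      v <- votes[, col]
      top <- which(v == max(v))
      if (max(v) == 0) {
        return(ref_chars[col])
      }
      cand <- DNA_BASES[top]
      if (ref_chars[col] %in% cand) ref_chars[col] else cand[1]
    }, character(1))
    tibble(
      contig_id = NA_character_,
      start = cs, end = ce,
      consensus = paste(consensus, collapse = ""),
      n_reads_infected = sum(sub$condition == "infected"),
      n_reads_naive = sum(sub$condition == "naive"),
      mean_depth = sum(sub$target_end - sub$target_start + 1) / width
    )
  }) |>
    arrange(.data$start) |>
    mutate(contig_id = sprintf("CTG%04d", row_number()))

  attr(contigs, "mapped_fraction") <- mapped_fraction
  attr(contigs, "placements") <- placements
  contigs
}

#' Extend a contig interval with flanking genome sequence
#'
#' Adds `flank` bp of upstream and downstream genomic sequence to a contig
#' interval, clipped to the genome bounds, and extracts the query sequence
#' used for translated homology screening. Contigs assembled from short
#' transcript fragments often cover untranslated regions only, so the flanks
#' recover nearby coding sequence.
#'
#' @param contigs Contig tibble from [build_contigs()] (needs `start`, `end`).
#' @param genome A `pyro_genome` or genome string.
#' @param flank Flank size in bp (default 250); 0 is the identity.
#' @return The contig tibble with `query_start`, `query_end`, `query_sequence`
#'   columns added.
#' @export
extend_contig <- function(contigs, genome, flank = 250) {
  check_scalar_number(flank, "flank", min = 0, integerish = TRUE)
  genome_seq <- if (inherits(genome, "pyro_genome")) genome$sequence else unname(genome)[1]
  glen <- nchar(genome_seq)
  if (any(contigs$start < 1) || any(contigs$end > glen)) {
    abort("Contig intervals must lie within the genome.",
      class = "pyroimmune_parameter_error"
    )
  }
  contigs |>
    mutate(
      query_start = pmax(1L, .data$start - as.integer(flank)),
      query_end = pmin(glen, .data$end + as.integer(flank)),
      query_sequence = substring(genome_seq, .data$query_start, .data$query_end)
    )
}

#' Translated homology screen of a query sequence
#'
#' Translates the query in all six frames and locally aligns each frame
#' against each database protein (BLOSUM62, affine gaps, Smith-Waterman as
#' implemented by [Biostrings::pairwiseAlignment]). The e-value follows the
#' Karlin-Altschul form `E = K * m * n * exp(-lambda * S)` with the standard
#' gapped BLOSUM62 constants (`lambda` = 0.267, `K` = 0.041), `m` the query
#' translation length and `n` the database residue count. The best hit is
#' retained iff its e-value is at most `e_threshold`; filtering is a pure
#' post-condition of the search.
#'
#' @param query Nucleotide query sequence (>= 3 nt for any hit).
#' @param proteins Named character vector (or `AAStringSet`) of database
#'   proteins; must be non-empty.
#' @param e_threshold E-value cutoff (default 1e-5).
#' @param lambda,k_const Karlin-Altschul constants.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return One-row tibble (`protein_id`, `frame`, `score`, `evalue`) for the
#'   best hit passing the threshold, or a zero-row tibble.
#' @export
screen_homology <- function(query, proteins, e_threshold = 1e-5,
                            lambda = 0.267, k_const = 0.041,
                            gap_opening = 11, gap_extension = 1) {
  proteins <- if (inherits(proteins, "XStringSet")) {
    setNames(as.character(proteins), names(proteins))
  } else {
    proteins
  }
  if (length(proteins) == 0) {
    abort("`proteins` must be non-empty.", class = "pyroimmune_configuration_error")
  }
  none <- tibble(
    protein_id = character(), frame = integer(),
    score = numeric(), evalue = numeric()
  )
  if (nchar(query) < 3) {
    return(none)
  }
  frames <- six_frame_translation(query)
  m <- nchar(query) %/% 3
  n_db <- sum(nchar(proteins))
  best <- NULL
  for (f in seq_along(frames)) {
    aa <- frames[[f]]
    if (nchar(aa) < 1) next
    for (p in seq_along(proteins)) {
      s <- Biostrings::score(Biostrings::pairwiseAlignment(
        Biostrings::AAString(aa), Biostrings::AAString(proteins[[p]]),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = gap_opening, gapExtension = gap_extension
      ))
      if (is.null(best) || s > best$score ||
        (s == best$score && names(proteins)[p] < best$protein_id)) {
        best <- list(
          protein_id = names(proteins)[p],
          frame = as.integer(names(frames)[f]), score = s
        )
      }
    }
  }
  if (is.null(best)) {
    return(none)
  }
  evalue <- k_const * m * n_db * exp(-lambda * best$score)
  if (evalue > e_threshold) {
    return(none)
  }
  tibble(
    protein_id = best$protein_id, frame = best$frame,
    score = best$score, evalue = evalue
  )
}

# frames named +1 +2 +3 -1 -2 -3; stop codons become '*'
six_frame_translation <- function(query) {
  query <- toupper(query)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
  tr <- function(s, off) {
    len <- nchar(s) - off + 1
    len <- 3 * (len %/% 3)
    if (len < 3) {
      return("")
    }
    as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(substr(s, off, off + len - 1)),
      if.fuzzy.codon = "solve", no.init.codon = TRUE
    )))
  }
  out <- c(
    tr(query, 1), tr(query, 2), tr(query, 3),
    tr(rc, 1), tr(rc, 2), tr(rc, 3)
  )
  names(out) <- c("1", "2", "3", "-1", "-2", "-3")
  out
}

#' Discover and test putative genes from unidentified reads
#'
#' End-to-end novel-gene workflow: assemble unidentified reads into contigs
#' on the genome, extend each contig with flanking sequence, screen the
#' queries by translated homology against a protein database, and test the
#' induction of each putative gene with the same control-anchored
#' contingency test as annotated genes. Because unannotated units have no
#' transcript length, the induction coefficient uses depth-normalized read
#' counts (`reads / library size`) instead of TMM values.
#'
#' @param reads Unidentified reads tibble (`read_id`, `sequence`,
#'   `condition`).
#' @param genome A `pyro_genome` or genome string.
#' @param proteins Protein database (named character vector or `AAStringSet`).
#' @param control_counts Pooled endogenous-control counts
#'   `c(infected = , naive = )` (e.g. `pool_controls()$pooled`).
#' @param library_sizes Named vector `c(infected = , naive = )` of reads
#'   assigned to nuclear genes, used for depth normalization.
#' @param flank Flank size for [extend_contig()].
#' @param e_threshold Passed to [screen_homology()].
#' @param alpha Significance level.
#' @param matcher Matcher for read placement.
#' @return Tibble of putative genes (`putative_id`, contig interval, best
#'   hit, per-condition reads, `ic`, `p_value`, `test_used`, `significant`,
#'   `stars`, `category`) with the contig table as attribute `contigs`.
#' @export
discover_novel_genes <- function(reads, genome, proteins, control_counts,
                                 library_sizes, flank = 250, e_threshold = 1e-5,
                                 alpha = 0.05, matcher = kmer_matcher()) {
  contigs <- build_contigs(reads, genome, matcher = matcher)
  if (nrow(contigs) == 0) {
    out <- tibble()
    attr(out, "contigs") <- contigs
    return(out)
  }
  queries <- extend_contig(contigs, genome, flank = flank)
  hits <- purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    hit <- screen_homology(queries$query_sequence[i], proteins,
      e_threshold = e_threshold
    )
    if (nrow(hit) == 0) {
      return(tibble())
    }
    dplyr::bind_cols(queries[i, ], hit)
  })
  if (nrow(hits) == 0) {
    out <- tibble()
    attr(out, "contigs") <- contigs
    return(out)
  }
  out <- hits |>
    mutate(putative_id = sprintf("PG%05d", row_number())) |>
    test_putative_genes(control_counts, library_sizes, alpha = alpha)
  attr(out, "contigs") <- contigs
  out
}

#' Induction testing of putative genes
#'
#' Applies the control-anchored contingency test to putative-gene read
#' counts. The induction coefficient is the depth-normalized read ratio
#' `(reads_inf / size_inf) / (reads_naive / size_naive)`, with the usual
#' `Inf` (infected-only) and `NA` (no reads) conventions.
#'
#' @param putatives Tibble with `n_reads_infected`, `n_reads_naive` columns.
#' @param control_counts Pooled control counts `c(infected = , naive = )`.
#' @param library_sizes Named library sizes `c(infected = , naive = )`.
#' @param alpha Significance level.
#' @return `putatives` with `ic`, `p_value`, `test_used`, `significant`,
#'   `stars`, `category` added.
#' @export
test_putative_genes <- function(putatives, control_counts, library_sizes,
                                alpha = 0.05) {
  stopifnot(all(c("n_reads_infected", "n_reads_naive") %in% names(putatives)))
  if (!all(c("infected", "naive") %in% names(library_sizes))) {
    abort("`library_sizes` must be named c(infected = , naive = ).",
      class = "pyroimmune_parameter_error"
    )
  }
  norm_inf <- putatives$n_reads_infected / library_sizes[["infected"]]
  norm_nai <- putatives$n_reads_naive / library_sizes[["naive"]]
  ic <- induction_coefficient(norm_inf, norm_nai)
  tests <- purrr::map(seq_len(nrow(putatives)), function(i) {
    gene_induction_test(
      c(putatives$n_reads_infected[i], putatives$n_reads_naive[i]),
      control_counts
    )
  })
  calls <- classify_regulation(ic, purrr::map_dbl(tests, "p_value"), alpha = alpha)
  putatives |>
    mutate(
      ic = ic,
      p_value = calls$p_value,
      test_used = purrr::map_chr(tests, "test_used"),
      significant = calls$significant,
      stars = calls$stars,
      category = calls$category
    )
}
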