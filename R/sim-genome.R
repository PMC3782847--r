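#' Simulate a genome with annotated and hidden segments
#'
#' Builds a single genome sequence holding, in order: a mitochondrial segment,
#' a ribosomal RNA segment, every catalog CDS separated by random spacers, a
#' set of "hidden gene" segments (unannotated transcription units, each a
#' clean open reading frame with short untranscribed flanks) and one plain
#' unannotated filler segment with no coding content. Segment coordinates are
#' returned 1-based inclusive in a sidecar table.
#'
#' @param catalog Gene catalog from [sim_gene_catalog()].
#' @param mito_length,rrna_length Lengths (bp) of the organellar and rRNA
#'   segments.
#' @param n_hidden Number of hidden (unannotated) genes to plant.
#' @param hidden_codons Length-2 integer range of hidden ORF codon counts.
#' @param hidden_flank Untranslated bp kept on each side of a hidden ORF
#'   inside its transcribed segment.
#' @param spacer Random spacer bp between consecutive gene segments.
#' @param filler_length Length of the non-coding unannotated segment.
#' @param seed Integer seed.
#'
#' @return A list of class `pyro_genome` with elements `sequence` (character
#'   scalar), `segments` (tibble: `segment_id`, `type`, `feature_id`, `start`,
#'   `end`) and `hidden` (tibble: `hidden_id`, `orf_start`, `orf_end`,
#'   `protein`).
#' @export
sim_genome <- function(catalog,
                       mito_length = 2000,
                       rrna_length = 2000,
                       n_hidden = 5,
                       hidden_codons = c(60, 120),
                       hidden_flank = 150,
                       spacer = 150,
                       filler_length = 3000,
                       seed = 1) {
  check_scalar_number(mito_length, "mito_length", min = 200, integerish = TRUE)
  check_scalar_number(rrna_length, "rrna_length", min = 200, integerish = TRUE)
  check_scalar_number(n_hidden, "n_hidden", min = 0, integerish = TRUE)
  check_seed(seed)

  withr::with_seed(seed, {
    pieces <- character(0)
    seg <- list()
    pos <- 0L
    add <- function(sequence, type, feature_id) {
      pieces[[length(pieces) + 1]] <<- sequence
      w <- nchar(sequence)
      seg[[length(seg) + 1]] <<- tibble(
        segment_id = sprintf("SEG%03d", length(seg) + 1),
        type = type, feature_id = feature_id,
        start = pos + 1L, end = pos + w
      )
      pos <<- pos + w
    }

    add(random_dna(mito_length), "mito", "mito")
    add(random_dna(rrna_length), "rrna", "rrna")
    for (i in seq_len(nrow(catalog))) {
      add(random_dna(spacer), "spacer", NA_character_)
      add(catalog$cds_sequence[i], "gene", catalog$gene_id[i])
    }

    codons <- sense_codons()
    hidden <- vector("list", n_hidden)
    for (h in seq_len(n_hidden)) {
      add(random_dna(spacer), "spacer", NA_character_)
      nc <- sample(seq(hidden_codons[1], hidden_codons[2]), 1)
      orf <- paste0(
        "ATG", paste(sample(codons, nc - 1, replace = TRUE), collapse = ""), "TAA"
      )
      segment <- paste0(random_dna(hidden_flank), orf, random_dna(hidden_flank))
      id <- sprintf("HG%02d", h)
      add(segment, "unannotated", id)
      orf_start <- pos - nchar(segment) + hidden_flank + 1L
      protein <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(orf, 1, nchar(orf) - 3))
      ))
      hidden[[h]] <- tibble(
        hidden_id = id, orf_start = orf_start,
        orf_end = orf_start + nchar(orf) - 1L, protein = protein
      )
    }
    add(random_dna(spacer), "spacer", NA_character_)
    add(random_dna(filler_length), "unannotated", "filler")

    structure(
      list(
        sequence = paste(pieces, collapse = ""),
        segments = bind_rows(seg),
        hidden = if (n_hidden > 0) bind_rows(hidden) else tibble(
          hidden_id = character(), orf_start = integer(),
          orf_end = integer(), protein = character()
        )
      ),
      class = "pyro_genome"
    )
  })
}

#' Simulate a pyrosequencing read library
#'
#' Draws error-free reads (exact genome substrings, forward strand) from the
#' segments of a simulated genome. Each read's source category is drawn from
#' `mix`; within a category the source segment is drawn according to optional
#' weights and the read start uniformly inside the segment. An optional
#' uniform substitution rate adds sequencing noise.
#'
#' @param genome A `pyro_genome` from [sim_genome()].
#' @param mix Named fractions for `mito`, `rrna`, `gene`, `unannotated`;
#'   must sum to 1.
#' @param n_reads Number of reads.
#' @param read_length Read length (bp); must not exceed the shortest segment
#'   of any category with positive mix.
#' @param condition Library condition label, `"infected"` or `"naive"`.
#' @param gene_weights Optional named weights over catalog gene ids.
#' @param unannotated_weights Optional named weights over unannotated
#'   feature ids (hidden gene ids and `"filler"`).
#' @param substitution_rate Per-base substitution probability (default 0).
#' @param seed Integer seed.
#'
#' @return Tibble with `read_id`, `sequence`, `truth_source` (`"mito"`,
#'   `"rrna"`, `"gene:<id>"` or `"unannotated"`), `truth_feature` (segment
#'   feature id) and `condition`.
#' @export
sim_read_library <- function(genome,
                             mix = c(mito = 0.05, rrna = 0.25, gene = 0.50, unannotated = 0.20),
                             n_reads = 10000,
                             read_length = 100,
                             condition = c("infected", "naive"),
                             gene_weights = NULL,
                             unannotated_weights = NULL,
                             substitution_rate = 0,
                             seed = 1) {
  stopifnot(inherits(genome, "pyro_genome"))
  condition <- match.arg(condition)
  check_scalar_number(n_reads, "n_reads", min = 1, integerish = TRUE)
  check_scalar_number(read_length, "read_length", min = 10, integerish = TRUE)
  check_scalar_number(substitution_rate, "substitution_rate", min = 0, max = 1)
  check_seed(seed)
  wanted <- c("mito", "rrna", "gene", "unannotated")
  if (!all(wanted %in% names(mix)) || any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    abort("`mix` must be named mito/rrna/gene/unannotated fractions summing to 1.",
      class = "pyroimmune_parameter_error"
    )
  }
  mix <- mix[wanted]
  segs <- filter(genome$segments, .data$type %in% wanted)
  for (ty in wanted[mix > 0]) {
    len <- filter(segs, .data$type == ty)
    if (nrow(len) == 0) {
      abort(sprintf("Genome has no %s segment but mix[%s] > 0.", ty, ty),
        class = "pyroimmune_parameter_error"
      )
    }
    if (read_length > min(len$end - len$start + 1)) {
      abort(sprintf("read_length exceeds the shortest %s segment.", ty),
        class = "pyroimmune_parameter_error"
      )
    }
  }

  withr::with_seed(seed, {
    category <- sample(wanted, n_reads, replace = TRUE, prob = mix)
    pick_segment <- function(ty, k, weights = NULL) {
      pool <- filter(segs, .data$type == ty)
      prob <- NULL
      if (!is.null(weights)) {
        prob <- unname(weights[pool$feature_id])
        prob[is.na(prob)] <- 0
        if (sum(prob) <= 0) prob <- NULL
      }
      pool[sample.int(nrow(pool), k, replace = TRUE, prob = prob), ]
    }
    rows <- vector("list", 4)
    names(rows) <- wanted
    idx <- split(seq_len(n_reads), factor(category, levels = wanted))
    out_start <- integer(n_reads)
    out_feature <- character(n_reads)
    out_type <- character(n_reads)
    for (ty in wanted) {
      k <- length(idx[[ty]])
      if (k == 0) next
      weights <- switch(ty,
        gene = gene_weights,
        unannotated = unannotated_weights,
        NULL
      )
      chosen <- pick_segment(ty, k, weights)
      starts <- chosen$start +
        floor(runif(k) * (chosen$end - chosen$start + 2 - read_length))
      out_start[idx[[ty]]] <- as.integer(starts)
      out_feature[idx[[ty]]] <- chosen$feature_id
      out_type[idx[[ty]]] <- ty
    }
    sequences <- substring(genome$sequence, out_start, out_start + read_length - 1)
    if (substitution_rate > 0) {
      sequences <- vapply(sequences, function(s) {
        chars <- strsplit(s, "")[[1]]
        hit <- runif(length(chars)) < substitution_rate
        if (any(hit)) {
          chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(DNA_BASES, b), 1),
            character(1)
          )
        }
        paste(chars, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    tibble(
      read_id = sprintf("%s_r%06d", condition, seq_len(n_reads)),
      sequence = sequences,
      truth_source = ifelse(out_type == "gene", paste0("gene:", out_feature), out_type),
      truth_feature = out_feature,
      condition = condition
    )
  })
}
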