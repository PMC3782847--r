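#' Resolve many-to-many homologue tables to one-to-one pairs
#'
#' Cross-species gene families with multiple copies in either species are
#' resolved to one-to-one homologue pairs by translated-alignment score:
#' for each ambiguous family the candidate pair with the highest local
#' protein alignment score between the translated CDS sequences is chosen,
#' with ties broken by longer alignment and then lexicographically smallest
#' id pair. Unambiguous rows pass through unchanged. Ids absent from either
#' catalog are listed in a rejects report rather than failing.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b` (possibly
#'   many-to-many).
#' @param catalog_a,catalog_b Gene catalogs holding `gene_id` and
#'   `cds_sequence` for each species.
#' @param matcher Translated-search function `f(cds_a, cds_b)` returning
#'   `list(score = , aln_length = )`; defaults to a local BLOSUM62 alignment
#'   of the translated sequences.
#' @return List with `map` (tibble `gene_a`, `gene_b`, `provenance`,
#'   `score`; injective both ways) and `rejects` (tibble of unresolvable
#'   rows with a reason).
#' @export
resolve_homologues <- function(pairs, catalog_a, catalog_b,
                               matcher = translated_matcher()) {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  if (nrow(pairs) == 0) {
    return(list(
      map = tibble(
        gene_a = character(), gene_b = character(),
        provenance = character(), score = numeric()
      ),
      rejects = tibble(gene_a = character(), gene_b = character(), reason = character())
    ))
  }
  known_a <- pairs$gene_a %in% catalog_a$gene_id
  known_b <- pairs$gene_b %in% catalog_b$gene_id
  rejects <- pairs[!(known_a & known_b), c("gene_a", "gene_b")]
  rejects$reason <- ifelse(!known_a[!(known_a & known_b)],
    "gene_a not in catalog", "gene_b not in catalog"
  )
  pairs <- pairs[known_a & known_b, ]

  ambiguous <- pairs$gene_a %in% pairs$gene_a[duplicated(pairs$gene_a)] |
    pairs$gene_b %in% pairs$gene_b[duplicated(pairs$gene_b)]
  clear <- pairs[!ambiguous, ] |>
    mutate(provenance = "table", score = NA_real_)

  amb <- pairs[ambiguous, ]
  resolved <- tibble(
    gene_a = character(), gene_b = character(),
    provenance = character(), score = numeric()
  )
  if (nrow(amb) > 0) {
    seq_a <- setNames(catalog_a$cds_sequence, catalog_a$gene_id)
    seq_b <- setNames(catalog_b$cds_sequence, catalog_b$gene_id)
    scored <- purrr::map_dfr(seq_len(nrow(amb)), function(i) {
      hit <- matcher(seq_a[[amb$gene_a[i]]], seq_b[[amb$gene_b[i]]])
      tibble(
        gene_a = amb$gene_a[i], gene_b = amb$gene_b[i],
        score = hit$score, aln_length = hit$aln_length
      )
    }) |>
      arrange(desc(.data$score), desc(.data$aln_length), .data$gene_a, .data$gene_b)
    used_a <- character(0)
    used_b <- character(0)
    for (i in seq_len(nrow(scored))) {
      if (scored$gene_a[i] %in% used_a || scored$gene_b[i] %in% used_b) next
      resolved <- bind_rows(resolved, tibble(
        gene_a = scored$gene_a[i], gene_b = scored$gene_b[i],
        provenance = "best_translated_hit", score = scored$score[i]
      ))
      used_a <- c(used_a, scored$gene_a[i])
      used_b <- c(used_b, scored$gene_b[i])
    }
  }
  list(map = bind_rows(clear, resolved), rejects = rejects)
}

#' Translated local-alignment scorer
#'
#' Returns a function scoring two CDS sequences by local alignment of their
#' translations (BLOSUM62, affine gaps).
#'
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Function `f(cds_a, cds_b)` -> `list(score, aln_length)`.
#' @export
translated_matcher <- function(gap_opening = 11, gap_extension = 1) {
  function(cds_a, cds_b) {
    pa <- translate_cds(cds_a)
    pb <- translate_cds(cds_b)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pa), Biostrings::AAString(pb),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension
    )
    list(score = Biostrings::score(aln), aln_length = Biostrings::nchar(aln))
  }
}

translate_cds <- function(cds) {
  len <- 3 * (nchar(cds) %/% 3)
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(substr(toupper(cds), 1, len)),
    if.fuzzy.codon = "solve"
  )))
  sub("\\*$", "", aa)
}

#' Annotate a catalog with immune classes from a reference list
#'
#' Marks each gene with its immune functional class (recognition, signaling,
#' effector) and effector subtype according to a curated reference list;
#' genes absent from the list get class `"none"`.
#'
#' @param catalog Gene catalog tibble with `gene_id`.
#' @param reference_list Tibble with `gene_id`, `class` and optionally
#'   `subtype`; class tokens other than recognition/signaling/effector are an
#'   input error.
#' @return The catalog with `immune_class` and `effector_subtype` replaced by
#'   the reference annotations.
#' @export
assign_immune_class <- function(catalog, reference_list) {
  stopifnot(is.data.frame(reference_list))
  if (nrow(reference_list) > 0) {
    bad <- setdiff(unique(reference_list$class), c("recognition", "signaling", "effector"))
    if (length(bad) > 0) {
      abort(paste0("Unknown immune class token(s): ", paste(bad, collapse = ", ")),
        class = "pyroimmune_input_error"
      )
    }
  }
  if (!"subtype" %in% names(reference_list)) reference_list$subtype <- NA_character_
  catalog |>
    select(-dplyr::any_of(c("immune_class", "effector_subtype"))) |>
    left_join(
      select(reference_list, "gene_id",
        immune_class = "class", effector_subtype = "subtype"
      ),
      by = "gene_id"
    ) |>
    mutate(immune_class = ifelse(is.na(.data$immune_class), "none", .data$immune_class))
}

#' Effector-panel summary
#'
#' Builds the per-species effector summary: effector-class genes expressed in
#' the infected library (at least `min_reads` assigned reads), sorted in
#' stable descending order of infected TMM, each with its regulation category
#' and significance stars, and with homologous genes linked across species
#' through a resolved one-to-one map.
#'
#' @param records Tested expression tibble (from [test_induction()]) joined
#'   with `immune_class` / `effector_subtype` columns; may contain one or two
#'   species distinguished by a `species` column (single-species input gets
#'   `species = "A"`).
#' @param map Optional resolved homologue map (tibble `gene_a`, `gene_b`)
#'   linking species `"A"` ids to species `"B"` ids.
#' @param min_reads Expression threshold on infected reads (default 1).
#' @return Tibble sorted by species then descending infected TMM with a
#'   `homologue` column where a cross-species partner exists.
#' @export
effector_summary <- function(records, map = NULL, min_reads = 1) {
  if (!"species" %in% names(records)) records$species <- "A"
  out <- records |>
    filter(.data$immune_class == "effector", .data$reads_infected >= min_reads) |>
    arrange(.data$species, desc(.data$tmm_infected), .data$gene_id) |>
    select(dplyr::any_of(c(
      "species", "gene_id", "effector_subtype", "reads_infected", "tmm_infected",
      "reads_naive", "tmm_naive", "ic", "p_value", "significant", "stars", "category"
    )))
  out$homologue <- NA_character_
  if (!is.null(map) && nrow(map) > 0) {
    i_a <- match(out$gene_id, map$gene_a)
    i_b <- match(out$gene_id, map$gene_b)
    out$homologue <- dplyr::coalesce(map$gene_b[i_a], map$gene_a[i_b])
  }
  out
}

#' Venn counts of expressed genes across two species
#'
#' Counts genes expressed only in species A, shared (via resolved homologue
#' pairs) and only in species B. When catalogs with `homologue_id` columns
#' are supplied, extra expressed copies of the same homology family are
#' reported separately as duplicates.
#'
#' @param expressed_a,expressed_b Character vectors of expressed gene ids.
#' @param map Resolved one-to-one homologue map (`gene_a`, `gene_b`).
#' @param catalog_a,catalog_b Optional catalogs for duplicate accounting.
#' @return Tibble with `only_a`, `shared`, `only_b`, `duplicates_a`,
#'   `duplicates_b`.
#' @export
venn_counts <- function(expressed_a, expressed_b, map,
                        catalog_a = NULL, catalog_b = NULL) {
  expressed_a <- unique(expressed_a)
  expressed_b <- unique(expressed_b)
  shared_pairs <- map[map$gene_a %in% expressed_a & map$gene_b %in% expressed_b, ]
  shared <- nrow(shared_pairs)
  dup <- function(expressed, catalog) {
    if (is.null(catalog) || !"homologue_id" %in% names(catalog)) {
      return(0L)
    }
    fam <- catalog$homologue_id[match(expressed, catalog$gene_id)]
    fam <- fam[!is.na(fam)]
    sum(duplicated(fam))
  }
  tibble(
    only_a = length(setdiff(expressed_a, shared_pairs$gene_a)),
    shared = shared,
    only_b = length(setdiff(expressed_b, shared_pairs$gene_b)),
    duplicates_a = dup(expressed_a, catalog_a),
    duplicates_b = dup(expressed_b, catalog_b)
  )
}
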