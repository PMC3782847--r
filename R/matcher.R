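# Built-in homology matcher for read triage and genome mapping.
#
# The matcher contract: a function f(sequences, refs) where `sequences` is a
# named character vector of queries and `refs` a named character vector of
# reference sequences, returning a tibble with one row per query that hit:
# query_id, target_id, score, target_start, target_end. Determinism and the
# tie-break (highest score, then longest span, then lexicographically
# smallest target_id, then leftmost position) are part of the contract.

#' Built-in exact/near-exact read matcher
#'
#' Returns a matcher function implementing exact full-length substring
#' matching (fast path, via `Biostrings::matchPDict`) with a k-mer seeded
#' ungapped-extension fallback for reads carrying substitutions. A query is
#' a hit when its best ungapped placement reaches at least `min_identity`
#' identity over at least `min_coverage` of the query length. The score is
#' the number of matching bases.
#'
#' @param k Seed k-mer length for the inexact fallback.
#' @param min_identity Minimum identity over the aligned span.
#' @param min_coverage Minimum aligned fraction of the query.
#' @return A matcher function `f(sequences, refs)`; see Details.
#' @export
kmer_matcher <- function(k = 16, min_identity = 0.95, min_coverage = 0.9) {
  check_scalar_number(k, "k", min = 4, integerish = TRUE)
  check_scalar_number(min_identity, "min_identity", min = 0, max = 1)
  check_scalar_number(min_coverage, "min_coverage", min = 0, max = 1)
  force(k)

  function(sequences, refs) {
    refs <- as_reference_set(refs)
    if (length(sequences) == 0) {
      return(tibble(
        query_id = character(), target_id = character(), score = numeric(),
        target_start = integer(), target_end = integer()
      ))
    }
    if (is.null(names(sequences))) names(sequences) <- paste0("q", seq_along(sequences))
    sequences <- toupper(sequences)
    ref_order <- order(names(refs))
    refs <- refs[ref_order] # lexicographic target tie-break for free
    ref_set <- Biostrings::DNAStringSet(refs)

    hits <- vector("list", 0)
    # fast path: exact full-length matches, grouped by read width
    widths <- nchar(sequences)
    for (w in sort(unique(widths))) {
      grp <- which(widths == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(sequences[grp]))
      for (ri in seq_along(ref_set)) {
        if (w > nchar(refs[ri])) next
        m <- Biostrings::matchPDict(pd, ref_set[[ri]])
        starts <- Biostrings::startIndex(m)
        found <- which(lengths(starts) > 0)
        if (length(found) == 0) next
        first <- vapply(starts[found], min, integer(1))
        hits[[length(hits) + 1]] <- tibble(
          query_id = names(sequences)[grp[found]],
          target_id = names(refs)[ri],
          score = as.numeric(w),
          target_start = first,
          target_end = first + w - 1L,
          .rank = ri
        )
      }
    }
    res <- if (length(hits) > 0) bind_rows(hits) else tibble(
      query_id = character(), target_id = character(), score = numeric(),
      target_start = integer(), target_end = integer(), .rank = integer()
    )
    # keep the best hit per query: widest score, then span, then target rank,
    # then leftmost position
    if (nrow(res) > 0) {
      res <- res |>
        mutate(span = .data$target_end - .data$target_start + 1L) |>
        arrange(
          .data$query_id, desc(.data$score), desc(.data$span),
          .data$.rank, .data$target_start
        ) |>
        group_by(.data$query_id) |>
        slice(1) |>
        ungroup()
    }

    unmatched <- setdiff(names(sequences), res$query_id)
    if (length(unmatched) > 0 && min_identity < 1) {
      fb <- seed_extend_batch(
        sequences[unmatched], refs, ref_set, k, min_identity, min_coverage
      )
      res <- bind_rows(res, fb)
    }
    res |>
      select("query_id", "target_id", "score", "target_start", "target_end") |>
      arrange(.data$query_id)
  }
}

# Ungapped seed-and-extend for the queries that had no exact hit. All seed
# k-mers of all queries are searched at once (one PDict pass per reference);
# candidate placements are then extended and scored in R. Returns the best
# placement per query meeting the identity/coverage thresholds.
seed_extend_batch <- function(queries, refs, ref_set, k, min_identity, min_coverage) {
  empty <- tibble(
    query_id = character(), target_id = character(), score = numeric(),
    target_start = integer(), target_end = integer(), .rank = integer(),
    span = integer()
  )
  qlens <- nchar(queries)
  usable <- qlens >= k
  queries <- queries[usable]
  qlens <- qlens[usable]
  if (length(queries) == 0) {
    return(empty)
  }
  seed_tab <- purrr::map_dfr(seq_along(queries), function(i) {
    offs <- unique(c(seq(1, qlens[i] - k + 1, by = k), qlens[i] - k + 1))
    kmers_i <- substring(queries[[i]], offs, offs + k - 1)
    tibble(qi = i, off = offs, kmer = kmers_i)
  })
  kmers <- unique(seed_tab$kmer)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  cand <- vector("list", 0)
  for (ri in seq_along(ref_set)) {
    if (k > nchar(refs[ri])) next
    m <- Biostrings::matchPDict(pd, ref_set[[ri]])
    starts <- Biostrings::startIndex(m)
    found <- which(lengths(starts) > 0)
    if (length(found) == 0) next
    hit_tab <- tibble(
      kmer = rep(kmers[found], lengths(starts[found])),
      pos = unlist(starts[found])
    )
    joined <- dplyr::inner_join(seed_tab, hit_tab, by = "kmer",
      relationship = "many-to-many"
    )
    if (nrow(joined) == 0) next
    joined$aln_start <- joined$pos - joined$off + 1L
    joined <- dplyr::distinct(joined, .data$qi, .data$aln_start)
    joined$ri <- ri
    cand[[length(cand) + 1]] <- joined
  }
  if (length(cand) == 0) {
    return(empty)
  }
  cand <- bind_rows(cand)

  best <- vector("list", length(queries))
  for (row in seq_len(nrow(cand))) {
    qi <- cand$qi[row]
    ri <- cand$ri[row]
    aln_start <- cand$aln_start[row]
    qlen <- qlens[qi]
    rlen <- nchar(refs[ri])
    r_from <- max(1L, aln_start)
    r_to <- min(rlen, aln_start + qlen - 1L)
    span <- r_to - r_from + 1L
    if (span < min_coverage * qlen) next
    q_from <- r_from - aln_start + 1L
    qsub <- substr(queries[[qi]], q_from, q_from + span - 1L)
    rsub <- substr(refs[[ri]], r_from, r_to)
    matches <- span - hamming_distance(qsub, rsub)
    if (matches / span < min_identity) next
    cur <- best[[qi]]
    if (is.null(cur) ||
      matches > cur$score ||
      (matches == cur$score && span > cur$span) ||
      (matches == cur$score && span == cur$span && ri < cur$rank)) {
      best[[qi]] <- list(
        score = as.numeric(matches), span = span, rank = ri,
        start = r_from, end = r_to
      )
    }
  }
  hits <- which(!vapply(best, is.null, logical(1)))
  if (length(hits) == 0) {
    return(empty)
  }
  purrr::map_dfr(hits, function(qi) {
    b <- best[[qi]]
    tibble(
      query_id = names(queries)[qi], target_id = names(refs)[b$rank],
      score = b$score, target_start = b$start, target_end = b$end,
      .rank = b$rank, span = b$span
    )
  })
}

hamming_distance <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}
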