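#' Reads per site per million reads (RPSM)
#'
#' Length- and depth-normalized expression for single-library count data:
#' `RPSM = (reads / total_reads / transcript_length) * 1e6`. The total is the
#' number of reads assigned to nuclear genes in the library, not the raw read
#' count, so grossly different organellar/ribosomal fractions between
#' libraries do not distort the per-million scaling.
#'
#' @param reads Non-negative read count(s) for the gene.
#' @param total_reads Library total (> 0).
#' @param transcript_length Transcript length in bp (> 0).
#' @return Numeric RPSM value(s); linear in `reads`.
#' @export
#' @examples
#' rpsm(10, 1e6, 1000) # 0.01
rpsm <- function(reads, total_reads, transcript_length) {
  if (any(total_reads <= 0)) {
    abort("`total_reads` must be positive.", class = "pyroimmune_parameter_error")
  }
  if (any(transcript_length <= 0)) {
    abort("`transcript_length` must be positive.", class = "pyroimmune_parameter_error")
  }
  if (any(reads < 0)) {
    abort("`reads` must be non-negative.", class = "pyroimmune_parameter_error")
  }
  reads / total_reads / transcript_length * 1e6
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Estimates between-library scaling factors from per-gene RPSM values by the
#' trimmed mean of M values: genes with a zero in either library are removed;
#' per-gene log2 ratios `M = log2(rpsm_inf / rpsm_naive)` (naive library as
#' reference) and log2 abundances `A` are computed; genes in the top/bottom
#' `trim_m` fraction by M or `trim_a` fraction by A are trimmed; the factor is
#' the weighted mean of the remaining M values with inverse asymptotic
#' binomial variance weights, exponentiated. Factors are scaled so their
#' product is 1.
#'
#' @param counts Tibble with `gene_id`, `reads_infected`, `reads_naive`,
#'   `transcript_length`.
#' @param totals Optional named vector `c(infected = , naive = )` of library
#'   totals; defaults to the column sums of `counts`.
#' @param trim_m,trim_a Trim fractions for M (default 0.30) and A (default
#'   0.05), each applied to both tails.
#' @return Tibble with `condition` and `tmm_factor`; the attribute
#'   `relative_factor` holds the infected/naive ratio of the factors.
#' @export
tmm_factors <- function(counts, totals = NULL, trim_m = 0.30, trim_a = 0.05) {
  need <- c("gene_id", "reads_infected", "reads_naive", "transcript_length")
  stopifnot(is.data.frame(counts), all(need %in% names(counts)))
  check_scalar_number(trim_m, "trim_m", min = 0, max = 0.49)
  check_scalar_number(trim_a, "trim_a", min = 0, max = 0.49)
  totals <- resolve_totals(counts, totals)

  y_inf <- counts$reads_infected
  y_nai <- counts$reads_naive
  r_inf <- rpsm(y_inf, totals[["infected"]], counts$transcript_length)
  r_nai <- rpsm(y_nai, totals[["naive"]], counts$transcript_length)
  use <- which(r_inf > 0 & r_nai > 0)
  if (length(use) < 2) {
    abort("TMM estimation needs at least 2 genes expressed in both libraries.",
      class = "pyroimmune_estimation_error"
    )
  }
  m <- log2(r_inf[use] / r_nai[use])
  a <- 0.5 * log2(r_inf[use] * r_nai[use])
  n <- length(use)
  keep_m <- rank_keep(m, trim_m)
  keep_a <- rank_keep(a, trim_a)
  keep <- keep_m & keep_a
  if (!any(keep)) keep <- rep(TRUE, n) # degenerate trim: fall back to untrimmed
  # asymptotic variance of M for count data (delta method, binomial sampling)
  w <- 1 / ((totals[["infected"]] - y_inf[use]) / (totals[["infected"]] * pmax(y_inf[use], 1)) +
    (totals[["naive"]] - y_nai[use]) / (totals[["naive"]] * pmax(y_nai[use], 1)))
  f <- 2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  out <- tibble(
    condition = c("infected", "naive"),
    tmm_factor = c(sqrt(f), 1 / sqrt(f))
  )
  attr(out, "relative_factor") <- f
  out
}

# keep the central part after trimming floor(n*trim) observations off each end
rank_keep <- function(x, trim) {
  n <- length(x)
  lo <- floor(n * trim)
  r <- rank(x, ties.method = "first")
  r > lo & r <= n - lo
}

resolve_totals <- function(counts, totals) {
  if (is.null(totals)) {
    totals <- c(
      infected = sum(counts$reads_infected),
      naive = sum(counts$reads_naive)
    )
  }
  if (!all(c("infected", "naive") %in% names(totals))) {
    abort("`totals` must be named c(infected = , naive = ).",
      class = "pyroimmune_parameter_error"
    )
  }
  if (any(totals <= 0)) {
    abort("library totals must be positive.", class = "pyroimmune_parameter_error")
  }
  totals
}

#' TMM-normalized expression values
#'
#' Computes per-gene, per-condition normalized expression: RPSM divided by
#' that condition's TMM scaling factor.
#'
#' @inheritParams tmm_factors
#' @return The `counts` tibble with `rpsm_infected`, `rpsm_naive`,
#'   `tmm_infected`, `tmm_naive` columns added.
#' @export
normalized_expression <- function(counts, totals = NULL, trim_m = 0.30, trim_a = 0.05) {
  totals <- resolve_totals(counts, totals)
  fac <- tmm_factors(counts, totals = totals, trim_m = trim_m, trim_a = trim_a)
  s <- setNames(fac$tmm_factor, fac$condition)
  counts |>
    mutate(
      rpsm_infected = rpsm(.data$reads_infected, totals[["infected"]], .data$transcript_length),
      rpsm_naive = rpsm(.data$reads_naive, totals[["naive"]], .data$transcript_length),
      tmm_infected = .data$rpsm_infected / s[["infected"]],
      tmm_naive = .data$rpsm_naive / s[["naive"]]
    )
}

#' Induction coefficient
#'
#' Ratio of normalized expression in the infected over the naive library,
#' `IC = TMM_infected / TMM_naive`. Expression observed only in the infected
#' library returns `Inf` (the distinguished "Infinity" value); a gene silent
#' in both libraries returns `NA` (undefined).
#'
#' @param tmm_infected,tmm_naive Non-negative normalized expression values.
#' @return Numeric vector of induction coefficients.
#' @export
#' @examples
#' induction_coefficient(23.719, 3.673) # ~6.457
#' induction_coefficient(2.445, 0) # Inf
induction_coefficient <- function(tmm_infected, tmm_naive) {
  if (any(tmm_infected < 0, na.rm = TRUE) || any(tmm_naive < 0, na.rm = TRUE)) {
    abort("TMM values must be non-negative.", class = "pyroimmune_parameter_error")
  }
  dplyr::case_when(
    tmm_infected == 0 & tmm_naive == 0 ~ NA_real_,
    tmm_naive == 0 ~ Inf,
    TRUE ~ tmm_infected / tmm_naive
  )
}

#' Quantify expression for a paired count table
#'
#' Convenience wrapper chaining [rpsm()], [tmm_factors()],
#' [normalized_expression()] and [induction_coefficient()] into one
#' expression table.
#'
#' @inheritParams tmm_factors
#' @return Tibble with raw counts, RPSM, TMM values and `ic` per gene.
#' @export
quantify_expression <- function(counts, totals = NULL, trim_m = 0.30, trim_a = 0.05) {
  normalized_expression(counts, totals = totals, trim_m = trim_m, trim_a = trim_a) |>
    mutate(ic = induction_coefficient(.data$tmm_infected, .data$tmm_naive))
}
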