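#' Pool endogenous control genes
#'
#' Sums the per-condition read counts of the endogenous control genes
#' (housekeeping genes assumed expression-stable across conditions, e.g.
#' ribosomal protein RpL32 and GAPDH) and checks their homogeneity across
#' conditions by Fisher's exact test on the controls-by-condition table.
#' With a single control gene, pooling is the identity and the homogeneity
#' p-value is 1 by convention.
#'
#' @param counts Count tibble with `gene_id`, `reads_infected`, `reads_naive`.
#' @param control_ids Character vector of control gene ids (>= 1 must be
#'   present in `counts`).
#' @return A list of class `pyro_controls`: `control_ids`,
#'   `pooled` (named vector infected/naive) and `homogeneity_p`.
#' @export
pool_controls <- function(counts, control_ids) {
  rows <- filter(counts, .data$gene_id %in% control_ids)
  if (nrow(rows) == 0) {
    abort("None of the control ids are present in the count table.",
      class = "pyroimmune_configuration_error"
    )
  }
  pooled <- c(
    infected = sum(rows$reads_infected),
    naive = sum(rows$reads_naive)
  )
  homogeneity_p <- if (nrow(rows) < 2) {
    1
  } else {
    m <- as.matrix(rows[, c("reads_infected", "reads_naive")])
    tryCatch(
      fisher.test(m)$p.value,
      error = function(e) chisq.test(m, correct = FALSE)$p.value
    )
  }
  structure(
    list(
      control_ids = rows$gene_id,
      pooled = pooled,
      homogeneity_p = homogeneity_p
    ),
    class = "pyro_controls"
  )
}

#' Control-anchored induction test for one gene
#'
#' Tests whether a gene's infected/naive read counts deviate from the pooled
#' endogenous-control proportions, on the 2x2 table
#' `[gene_infected, gene_naive; control_infected, control_naive]`.
#' When the minimum over the four cells is five or more, Pearson's chi-square
#' test (1 df, no continuity correction) is used; otherwise the two-sided
#' Fisher's exact test (probability-mass method, as in [stats::fisher.test]).
#' A gene with zero reads in both conditions returns p = 1 with a
#' `"no-signal"` flag.
#'
#' @param gene_counts Length-2 vector `c(infected, naive)` for the gene.
#' @param control_counts Length-2 vector `c(infected, naive)` of pooled
#'   control counts; both must be positive.
#' @return List with `p_value` and `test_used` (`"chi-square"`, `"fisher"` or
#'   `"no-signal"`).
#' @export
gene_induction_test <- function(gene_counts, control_counts) {
  if (length(gene_counts) != 2 || length(control_counts) != 2 ||
    any(gene_counts < 0) || any(is.na(gene_counts))) {
    abort("Counts must be two non-negative integers per group.",
      class = "pyroimmune_parameter_error"
    )
  }
  if (any(control_counts <= 0)) {
    abort("Pooled control counts must both be positive.",
      class = "pyroimmune_parameter_error"
    )
  }
  if (sum(gene_counts) == 0) {
    return(list(p_value = 1, test_used = "no-signal"))
  }
  tab <- rbind(as.numeric(gene_counts), as.numeric(control_counts))
  if (min(tab) >= 5) {
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    list(p_value = p, test_used = "chi-square")
  } else {
    list(p_value = fisher.test(tab)$p.value, test_used = "fisher")
  }
}

#' Regulation category from induction coefficient and p-value
#'
#' Assigns the standard regulation categories: `infected_only` (IC infinite,
#' expression seen only after infection), `up_strong` (IC > 2), `up_weak`
#' (1 < IC <= 2), `unchanged` (IC = 1), `down_weak` (0.5 <= IC < 1),
#' `down_strong` (IC < 0.5) and `undefined` (IC undefined). Boundary
#' convention: IC exactly 2 is `up_weak`, exactly 0.5 is `down_weak`,
#' exactly 1 is `unchanged`. Significance is `p_value < alpha`.
#'
#' @param ic Induction coefficient(s); `Inf` and `NA` allowed.
#' @param p_value P-value(s) from [gene_induction_test()].
#' @param alpha Significance level in (0, 1).
#' @return Tibble with `ic`, `p_value`, `significant`, `stars`, `category`.
#' @export
classify_regulation <- function(ic, p_value = NA_real_, alpha = 0.05) {
  check_scalar_number(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  category <- dplyr::case_when(
    is.na(ic) ~ "undefined",
    is.infinite(ic) ~ "infected_only",
    ic > 2 ~ "up_strong",
    ic > 1 ~ "up_weak",
    ic == 1 ~ "unchanged",
    ic >= 0.5 ~ "down_weak",
    TRUE ~ "down_strong"
  )
  tibble(
    ic = ic,
    p_value = p_value,
    significant = !is.na(p_value) & p_value < alpha,
    stars = significance_stars(p_value),
    category = factor(category, levels = c(
      "infected_only", "up_strong", "up_weak", "unchanged",
      "down_weak", "down_strong", "undefined"
    ))
  )
}

#' Test induction for every gene in an expression table
#'
#' Applies the control-anchored contingency test gene-wise and attaches
#' regulation categories. Control genes themselves are kept in the output but
#' flagged and not tested. Raw p-values are reported by default; optional
#' Benjamini-Hochberg adjustment is available.
#'
#' @param expression Expression tibble from [quantify_expression()] (needs
#'   `gene_id`, `reads_infected`, `reads_naive`, `ic`).
#' @param control_ids Endogenous control gene ids.
#' @param alpha Significance level.
#' @param adjust If `TRUE`, Benjamini-Hochberg-adjust the p-values before
#'   calling significance.
#' @return The expression tibble with `p_value`, `test_used`, `significant`,
#'   `stars`, `category` and `is_control` columns.
#' @export
test_induction <- function(expression, control_ids, alpha = 0.05, adjust = FALSE) {
  controls <- pool_controls(expression, control_ids)
  is_ctrl <- expression$gene_id %in% controls$control_ids
  tests <- purrr::map(seq_len(nrow(expression)), function(i) {
    if (is_ctrl[i]) {
      return(list(p_value = NA_real_, test_used = "control"))
    }
    gene_induction_test(
      c(expression$reads_infected[i], expression$reads_naive[i]),
      controls$pooled
    )
  })
  p <- purrr::map_dbl(tests, "p_value")
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  calls <- classify_regulation(expression$ic, p, alpha = alpha)
  expression |>
    mutate(
      p_value = p,
      test_used = purrr::map_chr(tests, "test_used"),
      significant = calls$significant,
      stars = calls$stars,
      category = calls$category,
      is_control = is_ctrl
    )
}
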