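#' Simulate a paired infected/naive count experiment
#'
#' Draws per-gene read counts for one infected and one naive library from a
#' negative-binomial model. Each gene has a baseline relative abundance
#' (gamma-distributed, endogenous controls boosted towards the highly
#' expressed housekeeping range); the per-condition mean is
#' `depth * abundance * fold_change` (naive fold change is always 1).
#' A fold change of `Inf` is the reserved "expressed only when infected"
#' token: the naive mean (and hence count) is exactly zero.
#'
#' @param catalog Gene catalog from [sim_gene_catalog()].
#' @param fold_change Named numeric vector of true fold changes (default 1 for
#'   every gene). Values must be positive or `Inf`; controls must stay at 1.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   0 gives Poisson counts.
#' @param depths Named integer vector `c(infected = , naive = )` of expected
#'   library depths (reads assigned to nuclear genes).
#' @param seed Integer seed.
#'
#' @return A list with `counts` (tibble: `gene_id`, `reads_infected`,
#'   `reads_naive`, `transcript_length`), `truth` (tibble of true fold
#'   changes, abundances and means) and `depths`.
#' @export
#' @examples
#' cat <- sim_gene_catalog(n_genes = 50, seed = 1)
#' ex <- sim_count_experiment(cat, seed = 2)
#' head(ex$counts)
sim_count_experiment <- function(catalog,
                                 fold_change = NULL,
                                 dispersion = 0.1,
                                 depths = c(infected = 55000, naive = 62000),
                                 seed = 1) {
  stopifnot(is.data.frame(catalog), all(c("gene_id", "transcript_length") %in% names(catalog)))
  check_scalar_number(dispersion, "dispersion", min = 0)
  check_seed(seed)
  if (!all(c("infected", "naive") %in% names(depths))) {
    abort("`depths` must be named c(infected = , naive = ).",
      class = "pyroimmune_parameter_error"
    )
  }
  if (any(depths <= 0)) {
    abort("Library depths must be positive.", class = "pyroimmune_parameter_error")
  }

  fc <- setNames(rep(1, nrow(catalog)), catalog$gene_id)
  if (!is.null(fold_change)) {
    unknown <- setdiff(names(fold_change), catalog$gene_id)
    if (length(unknown) > 0) {
      abort(paste0("fold_change names absent from catalog: ", paste(unknown, collapse = ", ")),
        class = "pyroimmune_parameter_error"
      )
    }
    fc[names(fold_change)] <- fold_change
  }
  if (any(is.na(fc)) || any(fc <= 0)) {
    abort("Fold changes must be strictly positive (or Inf for infected-only).",
      class = "pyroimmune_parameter_error"
    )
  }
  ctrl <- catalog$gene_id[catalog$is_control]
  if (any(fc[ctrl] != 1)) {
    abort("Endogenous control genes must have true fold change 1.",
      class = "pyroimmune_parameter_error"
    )
  }

  withr::with_seed(seed, {
    n <- nrow(catalog)
    w <- rgamma(n, shape = 0.5, scale = 1)
    # Controls mimic RpL32/GAPDH: force them into the top expression range.
    w[catalog$is_control] <- max(w) * runif(sum(catalog$is_control), 1, 2)
    w <- w / sum(w)
    infected_only <- is.infinite(fc)
    mu_inf <- depths[["infected"]] * w * ifelse(infected_only, 1, fc)
    mu_naive <- ifelse(infected_only, 0, depths[["naive"]] * w)
    draw <- function(mu) {
      if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
    }
    counts <- tibble(
      gene_id = catalog$gene_id,
      reads_infected = draw(mu_inf),
      reads_naive = draw(mu_naive),
      transcript_length = catalog$transcript_length
    )
    truth <- tibble(
      gene_id = catalog$gene_id,
      true_fold_change = unname(fc),
      abundance = w,
      mu_infected = unname(mu_inf),
      mu_naive = unname(mu_naive)
    )
    list(counts = counts, truth = truth, depths = depths)
  })
}
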