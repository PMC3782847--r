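#' Simulate daily survival counts under a logistic time-mortality model
#'
#' Each fly's death time is drawn from a logistic distribution with location
#' `lt50_true` (days) and scale `1/slope`; the count of flies alive is taken
#' at the end of each day (a fly with death time <= t is dead at day t).
#' Under this model the cumulative death fraction at integer days follows
#' exactly the logit-linear curve assumed by the binomial GLM estimator in
#' [fit_lt50()].
#'
#' @param n_flies Number of flies per replicate (>= 10).
#' @param lt50_true True median lethal time in days.
#' @param slope Logistic slope (> 0, per day); `Inf` gives a step curve with
#'   every death at `lt50_true`.
#' @param horizon Last observation day (>= 1).
#' @param n_replicates Number of independent replicates.
#' @param seed Integer seed.
#'
#' @return Tibble with `replicate`, `day` (0..horizon), `alive`, `n_start`;
#'   `alive` is non-increasing within a replicate.
#' @export
sim_survival_counts <- function(n_flies = 20,
                                lt50_true = 6,
                                slope = 1,
                                horizon = 12,
                                n_replicates = 1,
                                seed = 1) {
  check_scalar_number(n_flies, "n_flies", min = 10, integerish = TRUE)
  check_scalar_number(lt50_true, "lt50_true", min = 0)
  if (!is.numeric(slope) || length(slope) != 1 || is.na(slope) || slope <= 0) {
    abort("`slope` must be a positive number (Inf allowed).",
      class = "pyroimmune_parameter_error"
    )
  }
  check_scalar_number(horizon, "horizon", min = 1, integerish = TRUE)
  check_scalar_number(n_replicates, "n_replicates", min = 1, integerish = TRUE)
  check_seed(seed)

  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      death <- if (is.infinite(slope)) {
        rep(lt50_true, n_flies)
      } else {
        rlogis(n_flies, location = lt50_true, scale = 1 / slope)
      }
      days <- 0:horizon
      tibble(
        replicate = r,
        day = days,
        alive = vapply(days, function(t) sum(death > t), integer(1)),
        n_start = n_flies
      )
    })
  })
}
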