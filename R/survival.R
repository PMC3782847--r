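#' Estimate the median lethal time (LT50) from daily survival counts
#'
#' Fits a binomial generalized linear model of cumulative deaths against day
#' (logit link by default, probit available) and reports
#' `LT50 = -intercept / slope` with a delta-method standard error. A series
#' with complete separation (all flies alive one day, all dead the next, no
#' intermediate observation) cannot be fitted by the GLM; it falls back to
#' the midpoint between the last all-alive day and the first all-dead day and
#' is flagged.
#'
#' @param series Tibble with columns `day`, `alive`, `n_start` for one
#'   replicate; `alive` must be non-increasing and at most `n_start`.
#' @param link `"logit"` (default) or `"probit"`.
#' @return Object of class `lt50_fit` with elements `lt50`, `se`, `slope`,
#'   `coefficients`, `vcov`, `link`, `method` (`"glm"` or `"midpoint"`),
#'   `model` and `series`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' s <- sim_survival_counts(n_flies = 200, lt50_true = 6, seed = 1)
#' fit_lt50(s)
fit_lt50 <- function(series, link = c("logit", "probit")) {
  link <- match.arg(link)
  stopifnot(is.data.frame(series), all(c("day", "alive", "n_start") %in% names(series)))
  if ("replicate" %in% names(series) && length(unique(series$replicate)) > 1) {
    abort("`series` holds several replicates; fit them separately (see compare_lt50).",
      class = "pyroimmune_parameter_error"
    )
  }
  if (any(series$alive > series$n_start) || is.unsorted(rev(series$alive))) {
    abort("`alive` must be non-increasing and at most `n_start`.",
      class = "pyroimmune_parameter_error"
    )
  }
  series <- arrange(series, .data$day)
  dead <- series$n_start - series$alive
  partial <- dead > 0 & dead < series$n_start

  if (!any(partial)) {
    last_alive <- suppressWarnings(max(series$day[dead == 0]))
    first_dead <- suppressWarnings(min(series$day[dead == series$n_start]))
    if (!is.finite(last_alive) || !is.finite(first_dead)) {
      abort("Series never crosses 50% mortality; LT50 not estimable.",
        class = "pyroimmune_estimation_error"
      )
    }
    lt50 <- (last_alive + first_dead) / 2
    return(structure(
      list(
        lt50 = lt50, se = NA_real_, slope = NA_real_,
        coefficients = c(intercept = NA_real_, day = NA_real_),
        vcov = NULL, link = link, method = "midpoint",
        model = NULL, series = series
      ),
      class = "lt50_fit"
    ))
  }
  if (sum(partial) < 1 || length(unique(series$day)) < 3) {
    abort("Need at least 3 distinct days with a partially dying cohort.",
      class = "pyroimmune_parameter_error"
    )
  }

  fit <- suppressWarnings(glm(
    cbind(dead, alive) ~ day,
    family = binomial(link = link),
    data = tibble(day = series$day, dead = dead, alive = series$alive)
  ))
  b <- coef(fit)
  v <- vcov(fit)
  lt50 <- -b[[1]] / b[[2]]
  grad <- c(-1 / b[[2]], b[[1]] / b[[2]]^2)
  se <- sqrt(drop(t(grad) %*% v %*% grad))
  structure(
    list(
      lt50 = lt50, se = se, slope = b[[2]],
      coefficients = c(intercept = b[[1]], day = b[[2]]),
      vcov = v, link = link, method = "glm",
      model = fit, series = series
    ),
    class = "lt50_fit"
  )
}

#' @export
print.lt50_fit <- function(x, ...) {
  cat(sprintf(
    "LT50 fit (%s, %s link): LT50 = %.3f days (SE %.3f), slope = %.3f\n",
    x$method, x$link, x$lt50, x$se, x$slope
  ))
  invisible(x)
}

#' @export
tidy.lt50_fit <- function(x, ...) {
  if (x$method == "midpoint") {
    return(tibble(term = "lt50", estimate = x$lt50, std.error = NA_real_))
  }
  se <- sqrt(diag(x$vcov))
  tibble(
    term = c("intercept", "day", "lt50"),
    estimate = c(x$coefficients, lt50 = x$lt50),
    std.error = c(se, x$se)
  )
}

#' @export
glance.lt50_fit <- function(x, ...) {
  tibble(
    lt50 = x$lt50,
    se = x$se,
    slope = x$slope,
    link = x$link,
    method = x$method,
    deviance = if (is.null(x$model)) NA_real_ else x$model$deviance,
    n_days = nrow(x$series)
  )
}

#' Compare LT50 between two groups of replicates
#'
#' Fits per-replicate LT50s for both groups, averages them and reports the
#' group-A over group-B ratio.
#'
#' @param series_a,series_b Survival tibbles (with a `replicate` column for
#'   multiple replicates) for the two groups.
#' @param link Passed to [fit_lt50()].
#' @return List with `summary` (tibble: group, mean_lt50, n_replicates),
#'   `ratio` (mean A / mean B) and the per-replicate `fits`.
#' @export
compare_lt50 <- function(series_a, series_b, link = "logit") {
  fit_group <- function(series) {
    if (!"replicate" %in% names(series)) series$replicate <- 1L
    series |>
      group_by(.data$replicate) |>
      dplyr::group_map(~ fit_lt50(.x, link = link))
  }
  fits_a <- fit_group(series_a)
  fits_b <- fit_group(series_b)
  mean_a <- mean(purrr::map_dbl(fits_a, "lt50"))
  mean_b <- mean(purrr::map_dbl(fits_b, "lt50"))
  list(
    summary = tibble(
      group = c("A", "B"),
      mean_lt50 = c(mean_a, mean_b),
      n_replicates = c(length(fits_a), length(fits_b))
    ),
    ratio = mean_a / mean_b,
    fits = list(A = fits_a, B = fits_b)
  )
}
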