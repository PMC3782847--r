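# ggplot2 visualisations for fitted objects and summary tables.

#' @export
autoplot.lt50_fit <- function(object, ...) {
  s <- object$series
  df <- tibble(
    day = s$day,
    dead_fraction = (s$n_start - s$alive) / s$n_start
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$dead_fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "Day", y = "Cumulative death fraction",
      title = sprintf("LT50 = %.2f days", object$lt50)
    )
  if (object$method == "glm") {
    grid <- tibble(day = seq(min(df$day), max(df$day), length.out = 200))
    eta <- object$coefficients[["intercept"]] + object$coefficients[["day"]] * grid$day
    grid$dead_fraction <- if (object$link == "logit") plogis(eta) else stats::pnorm(eta)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p + ggplot2::geom_vline(xintercept = object$lt50, colour = "firebrick", linetype = "dotted")
}

#' Effector-panel plot
#'
#' Bar panel of effector genes per species, ordered by infected-library TMM,
#' coloured by regulation category (expression seen only after infection,
#' strong/weak induction, weak/strong suppression), mirroring the standard
#' effector-summary figure of comparative infection studies.
#'
#' @param summary Tibble from [effector_summary()].
#' @return A ggplot object.
#' @export
plot_effector_summary <- function(summary) {
  palette <- c(
    infected_only = "#c0392b", up_strong = "#e67e22", up_weak = "#f5cba7",
    unchanged = "grey80", down_weak = "#aed6f1", down_strong = "#2e86c1",
    undefined = "grey50"
  )
  df <- summary |>
    group_by(.data$species) |>
    mutate(rank = row_number()) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$gene_id, -.data$rank),
    y = .data$tmm_infected, fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), hjust = -0.3, size = 3) +
    ggplot2::scale_fill_manual(values = palette, drop = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "TMM (infected)", fill = "Regulation")
}
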