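#' Plot a glucose programme
#'
#' @param object A [glucose_profile()].
#' @param dt_min Rendering grid (minutes).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glucose_profile <- function(object, dt_min = 5, ...) {
  df <- render_profile(object, dt_min = dt_min)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$conc_pct)) +
    ggplot2::geom_area(fill = "orange", alpha = 0.4) +
    ggplot2::geom_line(colour = "darkorange") +
    ggplot2::labs(x = "time (h)", y = "extracellular glucose (% w/v)")
}

#' Tidy a simulated trajectory into long form
#'
#' @param x An `hxt_trajectory` from [simulate_hxt()].
#' @param ... Unused.
#' @return Long tibble: `time_h, variable, value, genotype, profile`.
#' @export
tidy.hxt_trajectory <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-"time_h", names_to = "variable", values_to = "value") |>
    dplyr::mutate(
      genotype = attr(x, "genotype"),
      profile = attr(x, "profile_name")
    )
}

#' Plot a simulated trajectory
#'
#' States are faceted; the glucose programme is drawn in the `ge` facet.
#'
#' @param object An `hxt_trajectory`.
#' @param vars State columns to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hxt_trajectory <- function(object, vars = c("H", "M", "S", "G1", "G2", "ge"), ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$variable %in% vars) |>
    dplyr::mutate(variable = factor(.data$variable, levels = vars))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(
      x = "time (h)", y = NULL,
      title = paste0(attr(object, "genotype"), " under ", attr(object, "profile_name"))
    )
}

#' Plot posterior promoter-model probabilities
#'
#' @param object An `hxt_posterior`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hxt_posterior <- function(object, ...) {
  df <- dplyr::arrange(object$models, .data$probability)
  df$structure <- factor(df$structure, levels = df$structure)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probability, y = .data$structure)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "posterior probability", y = NULL,
      title = paste0("promoter models for ", object$hxt)
    )
}

#' Plot a bootstrap repression summary
#'
#' One panel per repressor pair, glucose on a log axis, mean with the 95 %
#' bootstrap interval.
#'
#' @param summary A tibble from [bootstrap_repression()] (possibly row-bound
#'   over HXTs).
#' @return A ggplot.
#' @export
plot_repression <- function(summary) {
  ggplot2::ggplot(
    summary,
    ggplot2::aes(
      x = .data$glucose_pct, y = .data$mean,
      colour = if ("hxt" %in% names(summary)) .data$hxt else NULL
    )
  ) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(
      x = "glucose (% w/v)", y = "steady-state repression weight",
      colour = NULL
    )
}

#' Plot experiment datasets against model predictions
#'
#' @param dataset An `hxt_dataset`.
#' @param fit Optional `hxt_fit`; when given, model predictions are overlaid.
#' @return A ggplot.
#' @export
plot_dataset <- function(dataset, fit = NULL) {
  df <- tibble::as_tibble(dataset)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$mean_au)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_au - .data$sem_au,
        ymax = .data$mean_au + .data$sem_au
      ),
      fill = "grey80"
    ) +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::facet_grid(genotype ~ profile, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "fluorescence (a.u., normalised)")
  if (!is.null(fit)) {
    pred <- dataset_predictions(fit$params, fit$promoter, dataset)
    gg <- gg + ggplot2::geom_line(
      data = pred, ggplot2::aes(y = .data$pred_au), colour = "firebrick"
    )
  }
  gg
}
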