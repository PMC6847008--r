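# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_histogram geom_vline labs theme_minimal after_stat
#' @export
ggplot2::autoplot

#' Plot a FRET-efficiency histogram (with fitted peaks, if present)
#'
#' Bars show the pooled molecule-frame counts; when the object carries a
#' Gaussian-mixture fit, the individual components and their cumulative curve
#' are overlaid.
#'
#' @param object A `fret_histogram` or `fret_mixture`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fret_histogram <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = attr(object, "bin_width"), fill = "grey70",
             colour = "grey40", linewidth = 0.1) +
    labs(x = "FRET efficiency", y = "Molecule-frame count") +
    theme_minimal()
  comps <- attr(object, "components")
  if (!is.null(comps)) {
    grid <- seq(min(object$bin_lo), max(object$bin_hi), length.out = 400)
    comp_df <- purrr::list_rbind(purrr::pmap(
      comps[, c("mean", "sd", "amplitude")],
      function(mean, sd, amplitude) {
        tibble::tibble(component = sprintf("peak %.2f", mean), x = grid,
                       y = amplitude * exp(-(grid - mean)^2 / (2 * sd^2)))
      }
    ))
    total_df <- comp_df |>
      dplyr::summarise(y = sum(.data$y), .by = "x")
    p <- p +
      geom_line(data = comp_df,
                aes(x = .data$x, y = .data$y, group = .data$component),
                colour = "black") +
      geom_line(data = total_df, aes(x = .data$x, y = .data$y),
                colour = "red", linewidth = 0.8)
  }
  p
}

#' Plot a bootstrap distribution of average unfolding rates
#'
#' @param object A `rate_bootstrap`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_bootstrap <- function(object, bins = 60, ...) {
  df <- tibble::tibble(mean_rate = object$resampled_means)
  ggplot(df, aes(x = .data$mean_rate)) +
    geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = object$gaussian_mean, linetype = 2) +
    geom_vline(xintercept = c(object$ci_low, object$ci_high),
               linetype = 3, colour = "grey40") +
    labs(x = "Bootstrap average unfolding rate (1/s)", y = "Sets") +
    theme_minimal()
}

#' Plot one or more percent-remaining spot series
#'
#' @param object A `spot_count_series`.
#' @param ... Further `spot_count_series` to overlay.
#' @return A ggplot.
#' @export
autoplot.spot_count_series <- function(object, ...) {
  extra <- purrr::keep(list(...), \(x) inherits(x, "spot_count_series"))
  all_series <- c(list(object), extra)
  df <- purrr::list_rbind(purrr::map(all_series, function(s) {
    tibble::tibble(condition = attr(s, "condition_name") %||% "series",
                   time_s = s$time_s,
                   percent_remaining = s$percent_remaining)
  }))
  ggplot(df, aes(x = .data$time_s, y = .data$percent_remaining,
                 colour = .data$condition)) +
    geom_line() +
    geom_point() +
    labs(x = "Time (s)", y = "Molecules remaining (%)", colour = NULL) +
    theme_minimal()
}

#' Plot an smFRET trace with the detection thresholds
#'
#' @param fret Tibble from [compute_fret()].
#' @param molecule_id Molecule to plot.
#' @param params [event_params()] supplying the threshold lines.
#' @param frame_interval Seconds per frame; defaults to the attribute.
#' @return A ggplot.
#' @export
plot_fret_trace <- function(fret, molecule_id, params = event_params(),
                            frame_interval = NULL) {
  fi <- frame_interval_of(fret, frame_interval)
  df <- dplyr::filter(fret, .data$molecule_id == !!molecule_id)
  if (nrow(df) == 0L) {
    abort(sprintf("molecule %s not found.", molecule_id))
  }
  ggplot(df, aes(x = .data$frame * fi, y = .data$efret)) +
    geom_line(colour = "steelblue", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(params$low_threshold,
                                       params$high_threshold),
                        linetype = 2, colour = "red") +
    labs(x = "Time (s)", y = "FRET efficiency", title = molecule_id) +
    theme_minimal()
}
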