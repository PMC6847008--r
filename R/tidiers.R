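# broom-style tidiers for the fitted/estimated objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a condition-level rate estimate
#'
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @return One-row tibble: `condition_name`, `n_molecules`, `n_events`,
#'   `total_time`, `pooled_rate`, `mean_of_rates`.
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble::tibble(
    condition_name = x$condition_name,
    n_molecules = x$n_molecules,
    n_events = x$n_events,
    total_time = x$total_time,
    pooled_rate = x$pooled_rate,
    mean_of_rates = x$mean_of_rates
  )
}

#' @export
glance.rate_estimate <- function(x, ...) {
  tidy.rate_estimate(x)
}

#' Tidy a bootstrap distribution of average rates
#'
#' `tidy()` returns the resampled means (one row per bootstrap set);
#' `glance()` the one-row summary.
#'
#' @param x A `rate_bootstrap`.
#' @param ... Unused.
#' @export
tidy.rate_bootstrap <- function(x, ...) {
  tibble::tibble(set = seq_len(x$n_boot), mean_rate = x$resampled_means)
}

#' @rdname tidy.rate_bootstrap
#' @export
glance.rate_bootstrap <- function(x, ...) {
  tibble::tibble(
    n_boot = x$n_boot, n_molecules = x$n_molecules, seed = x$seed,
    gaussian_mean = x$gaussian_mean, gaussian_sd = x$gaussian_sd,
    ci_low = x$ci_low, ci_high = x$ci_high,
    sd_resampled = sd(x$resampled_means)
  )
}

#' Tidy a fitted FRET-histogram mixture
#'
#' `tidy()` returns one row per Gaussian component (`mean`, `sd`, `weight`,
#' `amplitude`); `glance()` the fit summary.
#'
#' @param x A `fret_mixture` from [fit_gaussian_mixture()].
#' @param ... Unused.
#' @export
tidy.fret_mixture <- function(x, ...) {
  attr(x, "components")
}

#' @rdname tidy.fret_mixture
#' @export
glance.fret_mixture <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(attr(x, "components")),
    residual_norm = attr(x, "residual_norm"),
    n_bins = nrow(x),
    n_pooled = attr(x, "n_pooled"),
    n_molecules = attr(x, "n_molecules")
  )
}

#' @export
tidy.relative_rate_result <- function(x, ...) {
  tibble::tibble(
    condition_name = x$condition_name,
    reference_name = x$reference_name,
    relative_rate = x$relative_rate,
    relative_percent = round(100 * x$relative_rate)
  )
}

#' @export
tidy.relative_activity_result <- function(x, ...) {
  tibble::tibble(
    condition_name = x$condition_name,
    reference_name = x$reference_name,
    t_ref = x$t_ref,
    removed_fraction_condition = x$removed_fraction_condition,
    removed_fraction_reference = x$removed_fraction_reference,
    relative_activity = x$relative_activity,
    replicate_sd = x$replicate_sd
  )
}
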