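# Surface-spot counting for the cumulative-unfolding assay: local-maxima
# detection on TIRF-like frames, percent-remaining series, and
# reference-normalized activity at a fixed time.

#' Parameters for spot detection
#'
#' @param threshold_sigmas Candidate pixels must exceed the robust background
#'   (median) by this many background SDs (MAD-based).
#' @param psf_sigma Expected PSF sigma, pixels; sets the local-maximum
#'   neighborhood to `(2 * ceiling(2 * psf_sigma) + 1)^2`.
#' @param min_separation Maxima closer than this (pixels) are merged, keeping
#'   the brighter one.
#' @return A validated `spot_params` list.
#' @export
spot_params <- function(threshold_sigmas = 5, psf_sigma = 1.3,
                        min_separation = 4) {
  check_number(threshold_sigmas, "threshold_sigmas",
               min = .Machine$double.eps)
  check_number(psf_sigma, "psf_sigma", min = .Machine$double.eps)
  check_number(min_separation, "min_separation", min = 1)
  structure(list(threshold_sigmas = threshold_sigmas, psf_sigma = psf_sigma,
                 min_separation = min_separation),
            class = "spot_params")
}

shift_matrix <- function(m, dy, dx, fill = -Inf) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) - dy
  xs <- seq_len(nc) - dx
  keep_y <- ys >= 1L & ys <= nr
  keep_x <- xs >= 1L & xs <= nc
  out[which(keep_y), which(keep_x)] <- m[ys[keep_y], xs[keep_x]]
  out
}

#' Detect diffraction-limited spots in a single frame
#'
#' Background level and noise are estimated robustly (median and MAD over the
#' whole frame). Candidate pixels are local maxima within a
#' `(2 * ceiling(2 * psf_sigma) + 1)^2` neighborhood that exceed
#' `background + threshold_sigmas * SD`; candidates closer than
#' `min_separation` pixels are merged, keeping the brighter one. Because the
#' threshold is expressed in background SD multiples, the count is invariant
#' to uniform intensity rescaling.
#'
#' @param image 2-D nonnegative numeric matrix (rows = y, columns = x).
#' @param params A [spot_params()].
#' @return Tibble of detected spots: `x`, `y` (0-based pixels), `intensity`.
#' @export
detect_spots <- function(image, params = spot_params()) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a 2-D numeric matrix.")
  }
  stopifnot(inherits(params, "spot_params"))
  bg <- median(image)
  noise <- mad(image)
  if (noise <= 0) noise <- sd(image)
  cutoff <- bg + params$threshold_sigmas * noise

  r <- as.integer(ceiling(2 * params$psf_sigma))
  nbr_max <- matrix(-Inf, nrow(image), ncol(image))
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (dy == 0L && dx == 0L) next
      nbr_max <- pmax(nbr_max, shift_matrix(image, dy, dx))
    }
  }
  cand <- which(image >= nbr_max & image > cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(tibble::tibble(x = numeric(), y = numeric(),
                          intensity = numeric()))
  }
  spots <- tibble::tibble(
    x = cand[, "col"] - 1,
    y = cand[, "row"] - 1,
    intensity = image[cand]
  )
  # Non-maximum suppression: brightest first, drop anything too close.
  spots <- dplyr::arrange(spots, dplyr::desc(.data$intensity))
  keep <- logical(nrow(spots))
  min_sep2 <- params$min_separation^2
  for (i in seq_len(nrow(spots))) {
    kept <- which(keep)
    if (length(kept) == 0L ||
        min((spots$x[kept] - spots$x[i])^2 +
            (spots$y[kept] - spots$y[i])^2) >= min_sep2) {
      keep[i] <- TRUE
    }
  }
  spots[keep, ]
}

#' Build a percent-remaining spot-count series
#'
#' Either pass pre-counted spots (`counts`) or a list of frames to count
#' with [detect_spots()]. Counts are normalized so the first timepoint reads
#' 100%.
#'
#' @param counts Integer vector of spot counts, one per timepoint.
#' @param times Imaging times, seconds (strictly increasing).
#' @param frames Optional list of image matrices, counted when `counts` is
#'   missing.
#' @param params [spot_params()] used when counting `frames`.
#' @param condition_name Label attached to the series.
#' @return A `spot_count_series` tibble: `time_s`, `count`,
#'   `percent_remaining`.
#' @export
count_series <- function(counts = NULL, times, frames = NULL,
                         params = spot_params(),
                         condition_name = "condition") {
  if (is.null(counts)) {
    if (is.null(frames)) abort("supply either `counts` or `frames`.")
    counts <- vapply(frames, function(f) nrow(detect_spots(f, params)),
                     integer(1))
  }
  if (length(counts) != length(times)) {
    abort("`counts` and `times` must have the same length.")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.")
  }
  if (counts[1L] <= 0) {
    abort("initial spot count must be positive to normalize to 100%.")
  }
  out <- tibble::tibble(
    time_s = as.numeric(times),
    count = as.numeric(counts),
    percent_remaining = 100 * counts / counts[1L]
  )
  structure(out,
            class = c("spot_count_series", class(out)),
            condition_name = condition_name)
}

percent_at <- function(series, t_ref) {
  if (t_ref < min(series$time_s) || t_ref > max(series$time_s)) {
    abort(sprintf("series does not bracket t_ref = %g s.", t_ref))
  }
  approx(series$time_s, series$percent_remaining, xout = t_ref)$y
}

#' Relative cumulative activity at a reference time
#'
#' The removed fraction at `t_ref` is `1 - percent_remaining(t_ref) / 100`,
#' with percent remaining linearly interpolated between the bracketing
#' timepoints (the time-lapse schedule need not hit `t_ref` exactly).
#' Relative activity is the condition's removed fraction divided by the
#' reference's, so the reference reads 1.0. Lists of replicate series (paired
#' by position) yield the mean relative activity and the sample SD across
#' replicates.
#'
#' @param series_cond,series_ref A `spot_count_series` each, or lists of
#'   replicate series of equal length.
#' @param t_ref Reference time, seconds (default 600).
#' @return A `relative_activity_result` list: `condition_name`,
#'   `reference_name`, `t_ref`, `removed_fraction_condition`,
#'   `removed_fraction_reference`, `relative_activity`, `replicate_sd`.
#' @export
relative_activity <- function(series_cond, series_ref, t_ref = 600) {
  check_number(t_ref, "t_ref", min = 0)
  as_list <- function(x) {
    if (inherits(x, "spot_count_series")) list(x) else x
  }
  conds <- as_list(series_cond)
  refs <- as_list(series_ref)
  if (length(conds) != length(refs)) {
    abort("condition and reference must have the same number of replicates.")
  }
  removed <- function(s) 1 - percent_at(s, t_ref) / 100
  rem_c <- vapply(conds, removed, numeric(1))
  rem_r <- vapply(refs, removed, numeric(1))
  if (any(rem_r <= 0)) {
    abort("reference removed fraction is zero at t_ref; cannot normalize.")
  }
  ratios <- rem_c / rem_r
  structure(
    list(
      condition_name = attr(conds[[1L]], "condition_name") %||% "condition",
      reference_name = attr(refs[[1L]], "condition_name") %||% "reference",
      t_ref = t_ref,
      removed_fraction_condition = mean(rem_c),
      removed_fraction_reference = mean(rem_r),
      relative_activity = mean(ratios),
      replicate_sd = if (length(ratios) > 1L) sd(ratios) else NA_real_
    ),
    class = "relative_activity_result"
  )
}

#' @export
print.relative_activity_result <- function(x, ...) {
  cat(sprintf(
    "<relative_activity_result> %s vs %s at %g s: removed %.3f vs %.3f -> relative activity %.3f%s\n",
    x$condition_name, x$reference_name, x$t_ref,
    x$removed_fraction_condition, x$removed_fraction_reference,
    x$relative_activity,
    if (is.na(x$replicate_sd)) "" else sprintf(" +/- %.3f", x$replicate_sd)))
  invisible(x)
}

#' Estimate the removal hazard from a percent-remaining series
#'
#' Fits `log(fraction remaining) = -lambda * t` by least squares through the
#' origin (valid when photobleaching is negligible, as in the no-ATP
#' control).
#'
#' @param series A `spot_count_series`.
#' @return A list with `lambda` (s^-1) and its standard error `se`.
#' @export
estimate_removal_hazard <- function(series) {
  keep <- series$count > 0 & series$time_s > 0
  if (sum(keep) < 2L) {
    abort("need at least two positive-count timepoints after t = 0.")
  }
  y <- log(series$percent_remaining[keep] / 100)
  t <- series$time_s[keep]
  fit <- stats::lm(y ~ 0 + t)
  list(lambda = -unname(coef(fit)[1L]),
       se = unname(summary(fit)$coefficients[1L, 2L]))
}
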