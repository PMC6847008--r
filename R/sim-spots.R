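# Synthetic surface-spot assay: exponential removal/bleach clocks per spot,
# plus an optional image renderer so the detector can be validated on a
# realistic substrate.

sample_spot_positions <- function(n_spots, field_size, min_separation,
                                  max_attempts = 200L) {
  xs <- numeric(0)
  ys <- numeric(0)
  margin <- 2
  for (i in seq_len(n_spots)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- runif(1L, margin, field_size - 1 - margin)
      y <- runif(1L, margin, field_size - 1 - margin)
      if (length(xs) == 0L ||
          min((xs - x)^2 + (ys - y)^2) >= min_separation^2) {
        xs <- c(xs, x)
        ys <- c(ys, y)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(
        "could not place %d spots with `min_spot_separation` %g in a %d px field.",
        n_spots, min_separation, field_size))
    }
  }
  tibble::tibble(spot_id = seq_len(n_spots), x = xs, y = ys)
}

#' Simulate the spot-count time-lapse of the cumulative-unfolding assay
#'
#' Each surface-bound donor molecule draws an independent exponential removal
#' time (helicase unfolds the GQ and unwinds the duplex, releasing the
#' labelled strand) and an independent photobleach time. The count at each
#' timepoint is the number of spots whose removal and bleach times both
#' exceed it, so counts are non-increasing. With both hazards zero the series
#' reproduces the no-ATP control: a constant spot count.
#'
#' @param config A [spot_sim_config()].
#' @return A list with `series` (a [count_series()]-style tibble of class
#'   `spot_count_series`: `time_s`, `count`, `percent_remaining`) and `truth`
#'   (per-spot tibble: `spot_id`, `x`, `y`, `removal_time`, `bleach_time`).
#' @export
#' @examples
#' sim <- simulate_spot_counts(spot_sim_config(n_spots = 100, seed = 2))
#' sim$series
simulate_spot_counts <- function(config) {
  stopifnot(inherits(config, "spot_sim_config"))
  if (length(config$timepoints) == 0L) {
    abort("`timepoints` must not be empty.")
  }
  set.seed(config$seed)
  pos <- sample_spot_positions(config$n_spots, config$field_size,
                               config$min_spot_separation)
  draw_times <- function(hazard) {
    if (hazard <= 0) rep(Inf, config$n_spots) else rexp(config$n_spots, hazard)
  }
  removal <- draw_times(config$removal_hazard)
  bleach <- draw_times(config$bleach_hazard)
  survives <- outer(pmin(removal, bleach), config$timepoints, `>`)
  counts <- colSums(survives)
  truth <- dplyr::mutate(pos, removal_time = removal, bleach_time = bleach)
  series <- count_series(counts = counts, times = config$timepoints)
  list(series = series, truth = truth)
}

#' Render one synthetic TIRF frame from surviving spot positions
#'
#' Draws a Gaussian background and adds one symmetric 2-D Gaussian PSF per
#' surviving spot; pixel values are clipped at zero. Coordinates are 0-based
#' pixel units.
#'
#' @param config A [spot_sim_config()].
#' @param positions Data frame with columns `x`, `y` (0-based pixels) of the
#'   spots present in this frame.
#' @return A `field_size` x `field_size` numeric matrix of counts; rows index
#'   y, columns x.
#' @export
render_spot_frame <- function(config, positions) {
  stopifnot(inherits(config, "spot_sim_config"))
  fs <- config$field_size
  if (nrow(positions) > 0 &&
      (any(positions$x < 0 | positions$x > fs - 1) ||
       any(positions$y < 0 | positions$y > fs - 1))) {
    abort("spot positions must lie inside the field.")
  }
  img <- matrix(rnorm(fs * fs, config$background_mean, config$background_sd),
                nrow = fs, ncol = fs)
  if (nrow(positions) > 0) {
    s2 <- 2 * config$psf_sigma^2
    halfw <- ceiling(4 * config$psf_sigma)
    for (i in seq_len(nrow(positions))) {
      cx <- positions$x[i]
      cy <- positions$y[i]
      xr <- max(0, floor(cx - halfw)):min(fs - 1, ceiling(cx + halfw))
      yr <- max(0, floor(cy - halfw)):min(fs - 1, ceiling(cy + halfw))
      psf <- config$spot_amplitude *
        exp(-outer((yr - cy)^2, (xr - cx)^2, `+`) / s2)
      img[yr + 1, xr + 1] <- img[yr + 1, xr + 1] + psf
    }
  }
  pmax(img, 0)
}

#' Write/read a spot time-lapse as a 16-bit TIFF stack
#'
#' One slice per timepoint. Values are scaled by `scale` into the 16-bit
#' range on write and unscaled on read.
#'
#' @param frames List of numeric matrices (one per timepoint).
#' @param path File path.
#' @param scale Counts per unit intensity; default 1.
#' @return `write_spot_stack()` returns `path` invisibly; `read_spot_stack()`
#'   returns a list of matrices.
#' @export
write_spot_stack <- function(frames, path, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to write TIFF stacks.")
  }
  imgs <- lapply(frames, function(f) pmin(pmax(f / scale, 0), 65535) / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_spot_stack
#' @export
read_spot_stack <- function(path, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to read TIFF stacks.")
  }
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(m) m * 65535 * scale)
}
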