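# FRET-efficiency computation, photobleach-bounded observation windows, and
# histogram construction/fitting.

#' Compute per-frame FRET efficiency (proximity ratio)
#'
#' Adds an `efret` column: `acceptor / (donor + acceptor)` after clamping
#' negative (background-subtracted) intensities to zero. No gamma or
#' donor-leakage correction is applied — thresholding operates on the raw
#' proximity ratio, with the donor-only population modelled as its own peak
#' rather than subtracted. Frames whose summed intensity is not positive are
#' undefined (`NA`) and are skipped by histograms and event detection.
#' Molecules with no defined frame at all are dropped with a warning.
#'
#' @param traces Tibble with columns `molecule_id`, `frame`, `donor`,
#'   `acceptor` (as returned by [read_traces()] or [simulate_condition()]).
#' @return The input tibble with columns `total` and `efret` added; the
#'   `frame_interval` attribute is preserved.
#' @export
#' @examples
#' tr <- tibble::tibble(molecule_id = "m1", frame = 0:2,
#'                      donor = c(100, 0, 88), acceptor = c(0, 50, 12))
#' compute_fret(tr)$efret
compute_fret <- function(traces) {
  stopifnot(all(c("molecule_id", "frame", "donor", "acceptor") %in%
                  names(traces)))
  fi <- attr(traces, "frame_interval")
  out <- traces |>
    dplyr::mutate(
      donor = pmax(.data$donor, 0),
      acceptor = pmax(.data$acceptor, 0),
      total = .data$donor + .data$acceptor,
      efret = dplyr::if_else(.data$total > 0,
                             .data$acceptor / .data$total, NA_real_)
    )
  bad <- out |>
    dplyr::summarise(ok = any(!is.na(.data$efret)),
                     .by = "molecule_id") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    warn(sprintf("dropping %d molecule(s) with no defined FRET frame: %s",
                 nrow(bad), paste(bad$molecule_id, collapse = ", ")))
    out <- dplyr::filter(out, !.data$molecule_id %in% bad$molecule_id)
  }
  attr(out, "frame_interval") <- fi
  out
}

running_median <- function(x, window) {
  k <- as.integer(window)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, length(x))
  if (k %% 2L == 0L) k <- k - 1L
  if (k <= 1L) return(x)
  stats::runmed(x, k, endrule = "median")
}

window_one_molecule <- function(donor, acceptor, drop_fraction, window) {
  n <- length(donor)
  if (n < window) return(n)
  total <- pmax(donor, 0) + pmax(acceptor, 0)
  med_tot <- running_median(total, window)
  init_tot <- median(total[seq_len(min(window, n))])
  # Donor bleach (or full signal loss): first sustained drop of the summed
  # intensity below drop_fraction of its starting level.
  end_total <- which(med_tot < drop_fraction * init_tot)
  end_total <- if (length(end_total)) end_total[1L] - 1L else n
  # Acceptor-only bleach: total is sustained but the acceptor stays below
  # drop_fraction of its starting level for the *rest* of the trace
  # (a permanence rule — transient unfolding dwells also depress the
  # acceptor and must not truncate the window).
  med_acc <- running_median(pmax(acceptor, 0), window)
  init_acc <- median(pmax(acceptor[seq_len(min(window, n))], 0))
  above <- which(med_acc >= drop_fraction * init_acc)
  end_acc <- if (length(above)) {
    if (above[length(above)] == n) n else above[length(above)]
  } else {
    0L
  }
  min(end_total, end_acc)
}

#' Bound each trace's valid observation window at photobleaching
#'
#' Observation time runs from the start of recording until photobleaching or
#' the end of the movie, whichever comes first. Donor bleach is detected as
#' the first frame where the running median of the summed intensity drops
#' below `drop_fraction` of its initial level; acceptor-only bleach as the
#' first frame from which the acceptor running median stays below
#' `drop_fraction` of its initial level for the remainder of the trace while
#' total intensity is sustained (the donor channel inherits the emission).
#'
#' @param traces Tibble with `molecule_id`, `frame`, `donor`, `acceptor`.
#' @param drop_fraction Fraction of the initial level that counts as bleached.
#' @param window Running-median window, frames (rounded up to odd).
#' @param frame_interval Seconds per frame; defaults to the tibble's
#'   `frame_interval` attribute.
#' @return Tibble with one row per molecule: `molecule_id`,
#'   `observation_end_frame` (exclusive, 0-based) and `observation_time`
#'   (seconds).
#' @export
detect_observation_window <- function(traces, drop_fraction = 0.5,
                                      window = 5L, frame_interval = NULL) {
  check_number(drop_fraction, "drop_fraction", min = 0, max = 1)
  window <- check_count(window, "window", min = 1L)
  fi <- frame_interval_of(traces, frame_interval)
  traces |>
    dplyr::arrange(.data$molecule_id, .data$frame) |>
    dplyr::summarise(
      observation_end_frame = window_one_molecule(
        .data$donor, .data$acceptor, drop_fraction, window),
      .by = "molecule_id"
    ) |>
    dplyr::mutate(observation_time = .data$observation_end_frame * fi)
}

#' Pool early frames of every molecule into a FRET-efficiency histogram
#'
#' Mirrors the short-movie practice used to characterise folded states: the
#' first `first_k_frames` defined efficiencies of each molecule (clipped to
#' its observation window, when supplied) are pooled into fixed-width bins
#' spanning \[-0.2, 1.2\].
#'
#' @param fret Tibble from [compute_fret()].
#' @param first_k_frames Frames pooled per molecule (default 15, one short
#'   movie).
#' @param bin_width Bin width on the efficiency axis.
#' @param windows Optional window tibble from [detect_observation_window()].
#' @return A `fret_histogram` object: tibble of bins (`bin_lo`, `bin_hi`,
#'   `mid`, `count`) with attributes; pass to [fit_gaussian_mixture()].
#' @export
build_fret_histogram <- function(fret, first_k_frames = 15L,
                                 bin_width = 0.02, windows = NULL) {
  first_k_frames <- check_count(first_k_frames, "first_k_frames", min = 1L)
  check_number(bin_width, "bin_width", min = 1e-6)
  dat <- dplyr::filter(fret, !is.na(.data$efret))
  if (!is.null(windows)) {
    dat <- dat |>
      dplyr::inner_join(windows[, c("molecule_id", "observation_end_frame")],
                        by = "molecule_id") |>
      dplyr::filter(.data$frame < .data$observation_end_frame)
  }
  dat <- dat |>
    dplyr::arrange(.data$molecule_id, .data$frame) |>
    dplyr::mutate(rank = dplyr::row_number(), .by = "molecule_id") |>
    dplyr::filter(.data$rank <= first_k_frames)
  if (nrow(dat) == 0L) {
    abort("no defined FRET frames to pool into a histogram.")
  }
  edges <- seq(-0.2, 1.2 + bin_width / 2, by = bin_width)
  cuts <- cut(pmin(pmax(dat$efret, -0.2), max(edges) - 1e-9), edges,
              right = FALSE, labels = FALSE)
  counts <- tabulate(cuts, nbins = length(edges) - 1L)
  bins <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1L],
    mid = (edges[-length(edges)] + edges[-1L]) / 2,
    count = counts
  )
  structure(bins,
            class = c("fret_histogram", class(bins)),
            bin_width = bin_width,
            n_pooled = nrow(dat),
            n_molecules = dplyr::n_distinct(dat$molecule_id),
            components = NULL)
}

gaussian_sum <- function(mid, means, sds, amps) {
  rowSums(vapply(seq_along(means), function(i) {
    amps[i] * exp(-(mid - means[i])^2 / (2 * sds[i]^2))
  }, numeric(length(mid))))
}

#' Fit a sum of Gaussians to a binned FRET histogram
#'
#' Least-squares fit of `n_components` Gaussian peaks to the binned counts
#' (the standard presentation of folded-state FRET histograms), via
#' Levenberg-Marquardt. Deterministic given `init_means`. Components are
#' returned sorted by mean, with weights as area fractions.
#'
#' @param hist A `fret_histogram` from [build_fret_histogram()].
#' @param n_components Number of Gaussian peaks.
#' @param init_means Initial peak positions (length `n_components`).
#' @param init_sds Initial peak SDs (recycled; default 0.05).
#' @return The histogram with a `components` attribute (tibble `mean`, `sd`,
#'   `weight`, `amplitude`) and `residual_norm`; class `fret_mixture` added.
#'   Access tidily via [tidy()] / [glance()].
#' @export
fit_gaussian_mixture <- function(hist, n_components, init_means,
                                 init_sds = 0.05) {
  stopifnot(inherits(hist, "fret_histogram"))
  n_components <- check_count(n_components, "n_components", min = 1L)
  if (length(init_means) != n_components) {
    abort("`init_means` must have length `n_components`.")
  }
  if (sum(hist$count) == 0L || length(unique(hist$count)) < 3L) {
    abort("histogram counts are degenerate; nothing to fit.")
  }
  init_sds <- rep_len(init_sds, n_components)
  mid <- hist$mid
  count <- hist$count
  init_amps <- vapply(init_means, function(m) {
    max(count[which.min(abs(mid - m))], 1)
  }, numeric(1))

  par0 <- c(init_means, log(init_sds), log(init_amps))
  fn <- function(p) {
    means <- p[seq_len(n_components)]
    sds <- exp(p[n_components + seq_len(n_components)])
    amps <- exp(p[2 * n_components + seq_len(n_components)])
    count - gaussian_sum(mid, means, sds, amps)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) {
    rn <- if (is.null(fit)) NA_real_ else sqrt(sum(fit$fvec^2))
    abort(sprintf(
      "Gaussian-mixture fit did not converge (residual norm %s; init means %s).",
      format(rn), paste(format(init_means), collapse = ", ")))
  }
  p <- fit$par
  means <- p[seq_len(n_components)]
  sds <- exp(p[n_components + seq_len(n_components)])
  amps <- exp(p[2 * n_components + seq_len(n_components)])
  ord <- order(means)
  areas <- amps[ord] * sds[ord]
  comps <- tibble::tibble(
    mean = means[ord], sd = sds[ord],
    weight = areas / sum(areas), amplitude = amps[ord]
  )
  out <- hist
  attr(out, "components") <- comps
  attr(out, "residual_norm") <- sqrt(sum(fit$fvec^2))
  class(out) <- unique(c("fret_mixture", class(hist)))
  out
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("<fret_histogram> %d frames from %d molecules, bin width %g\n",
              attr(x, "n_pooled"), attr(x, "n_molecules"),
              attr(x, "bin_width")))
  comps <- attr(x, "components")
  if (!is.null(comps)) {
    cat(sprintf("  %d Gaussian components (residual norm %.4g):\n",
                nrow(comps), attr(x, "residual_norm")))
    for (i in seq_len(nrow(comps))) {
      cat(sprintf("    mean %.3f  sd %.3f  weight %.3f\n",
                  comps$mean[i], comps$sd[i], comps$weight[i]))
    }
  }
  invisible(x)
}
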