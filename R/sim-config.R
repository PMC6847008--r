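#' Configuration for simulating smFRET trajectories
#'
#' Defines the generative model for single-molecule FRET trajectories of a
#' surface-tethered G-quadruplex (GQ) that a helicase repeatedly unfolds.
#' Each molecule carries a two-state continuous-time Markov chain
#' (folded <-> unfolded) with the given hazards; the folded FRET level depends
#' on the folding conformer (parallel at ~0.70, antiparallel/hybrid at ~0.59),
#' the unfolded level sits well below the 0.45 detection threshold, and a
#' donor-only subpopulation emits constantly at the leakage level ~0.12.
#' Donor and acceptor photobleach as independent exponential clocks; use
#' `Inf` lifetimes to disable bleaching.
#'
#' @param n_molecules Number of molecules per condition.
#' @param n_frames Frames per trajectory.
#' @param frame_interval Frame integration time, seconds.
#' @param k_unfold,k_refold Hazards (s^-1) of the folded->unfolded and
#'   unfolded->folded transitions.
#' @param frac_parallel Fraction of FRET-active molecules starting in the
#'   parallel conformer (higher FRET level).
#' @param frac_donor_only Fraction of molecules without an active acceptor.
#' @param e_parallel,e_antiparallel,e_unfolded,e_donor_only Mean FRET
#'   efficiencies of the emitting states.
#' @param e_noise_sd Per-frame Gaussian noise SD on the FRET scale, applied
#'   through the intensity partition.
#' @param total_intensity Mean summed donor+acceptor counts per frame.
#' @param intensity_noise_sd Additive per-channel Gaussian SD, counts.
#' @param tau_bleach_acceptor,tau_bleach_donor Exponential photobleach
#'   lifetimes, seconds (`Inf` = no bleaching).
#' @param seed Integer RNG seed used by [simulate_condition()].
#'
#' @return A validated `trace_sim_config` list.
#' @seealso [simulate_condition()], [simulate_trace()]
#' @export
#' @examples
#' cfg <- trace_sim_config(n_molecules = 10, n_frames = 400)
#' sim <- simulate_condition(cfg)
#' head(sim$traces)
trace_sim_config <- function(n_molecules = 500L,
                             n_frames = 12000L,
                             frame_interval = 0.05,
                             k_unfold = 0.05,
                             k_refold = 0.5,
                             frac_parallel = 0.6,
                             frac_donor_only = 0.2,
                             e_parallel = 0.70,
                             e_antiparallel = 0.59,
                             e_unfolded = 0.30,
                             e_donor_only = 0.12,
                             e_noise_sd = 0.05,
                             total_intensity = 1000,
                             intensity_noise_sd = 40,
                             tau_bleach_acceptor = 30,
                             tau_bleach_donor = 60,
                             seed = 1L) {
  n_molecules <- check_count(n_molecules, "n_molecules")
  n_frames <- check_count(n_frames, "n_frames", min = 1L)
  check_number(frame_interval, "frame_interval", min = .Machine$double.eps)
  check_number(k_unfold, "k_unfold", min = 0)
  check_number(k_refold, "k_refold", min = 0)
  check_number(frac_parallel, "frac_parallel", min = 0, max = 1)
  check_number(frac_donor_only, "frac_donor_only", min = 0, max = 1)
  check_number(e_parallel, "e_parallel", min = 0, max = 1)
  check_number(e_antiparallel, "e_antiparallel", min = 0, max = 1)
  check_number(e_unfolded, "e_unfolded", min = 0, max = 1)
  check_number(e_donor_only, "e_donor_only", min = 0, max = 1)
  if (e_unfolded >= 0.45) {
    abort("`e_unfolded` must sit below the 0.45 unfolding threshold.")
  }
  if (e_parallel < 0.55 || e_antiparallel < 0.55) {
    abort("folded means (`e_parallel`, `e_antiparallel`) must be >= 0.55.")
  }
  check_number(e_noise_sd, "e_noise_sd", min = 0)
  check_number(total_intensity, "total_intensity", min = 0)
  check_number(intensity_noise_sd, "intensity_noise_sd", min = 0)
  check_number(tau_bleach_acceptor, "tau_bleach_acceptor", min = 0,
               allow_inf = TRUE)
  check_number(tau_bleach_donor, "tau_bleach_donor", min = 0,
               allow_inf = TRUE)
  seed <- check_count(seed, "seed")

  structure(
    list(
      n_molecules = n_molecules, n_frames = n_frames,
      frame_interval = frame_interval,
      k_unfold = k_unfold, k_refold = k_refold,
      frac_parallel = frac_parallel, frac_donor_only = frac_donor_only,
      e_parallel = e_parallel, e_antiparallel = e_antiparallel,
      e_unfolded = e_unfolded, e_donor_only = e_donor_only,
      e_noise_sd = e_noise_sd, total_intensity = total_intensity,
      intensity_noise_sd = intensity_noise_sd,
      tau_bleach_acceptor = tau_bleach_acceptor,
      tau_bleach_donor = tau_bleach_donor,
      seed = seed
    ),
    class = "trace_sim_config"
  )
}

#' @export
print.trace_sim_config <- function(x, ...) {
  cat("<trace_sim_config>\n")
  cat(sprintf("  %d molecules x %d frames @ %.3g s (%.1f s total)\n",
              x$n_molecules, x$n_frames, x$frame_interval,
              x$n_frames * x$frame_interval))
  cat(sprintf("  k_unfold %.3g /s, k_refold %.3g /s\n", x$k_unfold, x$k_refold))
  cat(sprintf("  FRET levels: parallel %.2f, antiparallel %.2f, unfolded %.2f, donor-only %.2f\n",
              x$e_parallel, x$e_antiparallel, x$e_unfolded, x$e_donor_only))
  cat(sprintf("  fractions: parallel %.2f (of FRET-active), donor-only %.2f\n",
              x$frac_parallel, x$frac_donor_only))
  cat(sprintf("  bleach lifetimes: acceptor %s s, donor %s s; seed %d\n",
              format(x$tau_bleach_acceptor), format(x$tau_bleach_donor),
              x$seed))
  invisible(x)
}

#' Configuration for simulating the surface-spot time-lapse assay
#'
#' Models the cumulative-unfolding assay: donor-labelled strands tethered to a
#' surface leave it once the GQ has been unfolded and the adjacent duplex
#' unwound, so the spot count decays over the time-lapse. Each spot draws an
#' independent exponential removal time (`removal_hazard`) and, separately, a
#' photobleach time (`bleach_hazard`, negligible under the low-excitation
#' time-lapse of the assay). Optional image rendering places Gaussian PSFs on
#' a noisy background so spot detection can be validated end to end.
#'
#' @param n_spots Number of surface-bound molecules at time zero.
#' @param timepoints Strictly increasing imaging times, seconds.
#' @param removal_hazard Per-second hazard of unwinding-driven strand removal.
#' @param bleach_hazard Per-second photobleach hazard (control channel).
#' @param field_size Side of the square imaging field, pixels.
#' @param psf_sigma Gaussian PSF sigma, pixels.
#' @param spot_amplitude Peak amplitude of one spot, counts.
#' @param background_mean,background_sd Background level and noise, counts.
#' @param min_spot_separation Minimum centre-to-centre spot distance, pixels.
#' @param seed Integer RNG seed.
#'
#' @return A validated `spot_sim_config` list.
#' @seealso [simulate_spot_counts()], [render_spot_frame()]
#' @export
spot_sim_config <- function(n_spots = 300L,
                            timepoints = seq(0, 1200, by = 120),
                            removal_hazard = 1.2e-3,
                            bleach_hazard = 0,
                            field_size = 512L,
                            psf_sigma = 1.3,
                            spot_amplitude = 800,
                            background_mean = 100,
                            background_sd = 10,
                            min_spot_separation = 4,
                            seed = 1L) {
  n_spots <- check_count(n_spots, "n_spots")
  if (!is.numeric(timepoints) || length(timepoints) == 0L ||
      anyNA(timepoints)) {
    abort("`timepoints` must be a non-empty numeric vector.")
  }
  if (any(timepoints < 0) || is.unsorted(timepoints, strictly = TRUE)) {
    abort("`timepoints` must be strictly increasing and >= 0.")
  }
  check_number(removal_hazard, "removal_hazard", min = 0)
  check_number(bleach_hazard, "bleach_hazard", min = 0)
  field_size <- check_count(field_size, "field_size", min = 8L)
  check_number(psf_sigma, "psf_sigma", min = .Machine$double.eps)
  check_number(spot_amplitude, "spot_amplitude", min = 0)
  check_number(background_mean, "background_mean", min = 0)
  check_number(background_sd, "background_sd", min = 0)
  check_number(min_spot_separation, "min_spot_separation", min = 1)
  seed <- check_count(seed, "seed")

  structure(
    list(
      n_spots = n_spots, timepoints = as.numeric(timepoints),
      removal_hazard = removal_hazard, bleach_hazard = bleach_hazard,
      field_size = field_size, psf_sigma = psf_sigma,
      spot_amplitude = spot_amplitude, background_mean = background_mean,
      background_sd = background_sd,
      min_spot_separation = min_spot_separation, seed = seed
    ),
    class = "spot_sim_config"
  )
}

#' @export
print.spot_sim_config <- function(x, ...) {
  cat("<spot_sim_config>\n")
  cat(sprintf("  %d spots, %d timepoints over [%g, %g] s\n", x$n_spots,
              length(x$timepoints), min(x$timepoints), max(x$timepoints)))
  cat(sprintf("  removal hazard %.3g /s, bleach hazard %.3g /s\n",
              x$removal_hazard, x$bleach_hazard))
  cat(sprintf("  field %d px, PSF sigma %.2f px, amplitude %g on background %g +/- %g\n",
              x$field_size, x$psf_sigma, x$spot_amplitude, x$background_mean,
              x$background_sd))
  invisible(x)
}
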