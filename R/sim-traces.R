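# Two-state CTMC trajectory generator with frame integration, channel noise
# and single-step photobleaching. Ground truth carries every state boundary
# so downstream detection can be scored exactly.

sample_state_path <- function(k_unfold, k_refold, total_time) {
  state <- "folded"
  t <- 0
  states <- character()
  starts <- numeric()
  while (t < total_time) {
    rate <- if (state == "folded") k_unfold else k_refold
    dwell <- if (rate <= 0) Inf else rexp(1L, rate)
    states <- c(states, state)
    starts <- c(starts, t)
    t <- t + dwell
    state <- if (state == "folded") "unfolded" else "folded"
  }
  tibble::tibble(
    state = states,
    start = starts,
    end = c(starts[-1L], total_time)
  )
}

# Fraction of each frame spent in the folded state, from the piecewise path.
# Cumulative folded time is piecewise linear in t; differencing it at frame
# edges gives exact occupancy-weighted mixing of the boundary frames.
folded_occupancy <- function(path, n_frames, frame_interval) {
  knots <- c(path$start, path$end[nrow(path)])
  folded_dt <- ifelse(path$state == "folded", path$end - path$start, 0)
  cum_folded <- c(0, cumsum(folded_dt))
  edges <- (0:n_frames) * frame_interval
  f_edges <- approx(knots, cum_folded, xout = edges, rule = 2L)$y
  diff(f_edges) / frame_interval
}

#' Simulate one smFRET trajectory with ground truth
#'
#' Samples a molecule's conformer, a folded/unfolded continuous-time Markov
#' path, photobleach times, and per-frame donor/acceptor intensities. State
#' changes are instantaneous, but the frame crossing a transition mixes the
#' two FRET levels in proportion to the time spent in each (frame
#' integration). After acceptor photobleaching the trace reads at the
#' donor-leakage level; after donor photobleaching both channels fall to
#' background. Uses the current RNG state; for reproducible conditions call
#' [simulate_condition()], which seeds from the config.
#'
#' @param config A [trace_sim_config()].
#' @param molecule_id Identifier for the molecule.
#' @return A list with `trace` (tibble: `molecule_id`, `frame`, `donor`,
#'   `acceptor`) and `truth` (one-row tibble: `molecule_id`, `conformer`,
#'   `bleach_donor`, `bleach_acceptor`, list-columns `event_times` and
#'   `state_path`).
#' @export
simulate_trace <- function(config, molecule_id) {
  stopifnot(inherits(config, "trace_sim_config"))
  n <- config$n_frames
  dt <- config$frame_interval
  total_time <- n * dt

  conformer <- if (runif(1L) < config$frac_donor_only) {
    "donor_only"
  } else if (runif(1L) < config$frac_parallel) {
    "parallel"
  } else {
    "antiparallel"
  }

  bleach_acc <- if (is.finite(config$tau_bleach_acceptor)) {
    rexp(1L, 1 / config$tau_bleach_acceptor)
  } else {
    Inf
  }
  bleach_don <- if (is.finite(config$tau_bleach_donor)) {
    rexp(1L, 1 / config$tau_bleach_donor)
  } else {
    Inf
  }

  if (conformer == "donor_only") {
    path <- tibble::tibble(state = "donor_only", start = 0, end = total_time)
    e_state <- rep(config$e_donor_only, n)
    event_times <- numeric()
  } else {
    e_folded <- if (conformer == "parallel") {
      config$e_parallel
    } else {
      config$e_antiparallel
    }
    path <- sample_state_path(config$k_unfold, config$k_refold, total_time)
    occ <- folded_occupancy(path, n, dt)
    e_state <- occ * e_folded + (1 - occ) * config$e_unfolded
    event_times <- path$start[path$state == "unfolded"]
  }

  frame_start <- (0:(n - 1L)) * dt
  # Acceptor gone: emission collapses into the donor channel except leakage.
  e_state[frame_start >= bleach_acc] <- config$e_donor_only
  e_noisy <- e_state + rnorm(n, 0, config$e_noise_sd)

  alive <- frame_start < bleach_don
  donor <- ifelse(alive, config$total_intensity * (1 - e_noisy), 0) +
    rnorm(n, 0, config$intensity_noise_sd)
  acceptor <- ifelse(alive, config$total_intensity * e_noisy, 0) +
    rnorm(n, 0, config$intensity_noise_sd)

  trace <- tibble::tibble(
    molecule_id = molecule_id,
    frame = 0:(n - 1L),
    donor = donor,
    acceptor = acceptor
  )
  truth <- tibble::tibble(
    molecule_id = molecule_id,
    conformer = conformer,
    bleach_donor = bleach_don,
    bleach_acceptor = bleach_acc,
    event_times = list(event_times),
    state_path = list(path)
  )
  list(trace = trace, truth = truth)
}

#' Simulate a full condition of smFRET trajectories
#'
#' Generates `config$n_molecules` independent trajectories, seeding the RNG
#' once from `config$seed` so the same config always reproduces byte-identical
#' output.
#'
#' @param config A [trace_sim_config()].
#' @return A list with `traces` (tibble of per-frame intensities for all
#'   molecules, carrying a `frame_interval` attribute) and `truth` (one row
#'   per molecule, see [simulate_trace()]).
#' @export
#' @examples
#' sim <- simulate_condition(trace_sim_config(n_molecules = 5, n_frames = 200))
#' dplyr::count(sim$truth, conformer)
simulate_condition <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  set.seed(config$seed)
  ids <- sprintf("mol%05d", seq_len(config$n_molecules))
  sims <- purrr::map(ids, function(id) simulate_trace(config, id))
  traces <- purrr::list_rbind(purrr::map(sims, "trace"))
  truth <- purrr::list_rbind(purrr::map(sims, "truth"))
  if (config$n_molecules == 0L) {
    traces <- tibble::tibble(molecule_id = character(), frame = integer(),
                             donor = numeric(), acceptor = numeric())
    truth <- tibble::tibble(molecule_id = character(), conformer = character(),
                            bleach_donor = numeric(),
                            bleach_acceptor = numeric(),
                            event_times = list(), state_path = list())
  }
  attr(traces, "frame_interval") <- config$frame_interval
  list(traces = traces, truth = truth)
}

#' Ground-truth unfolding times and the effective (detectable) event rate
#'
#' `true_events()` flattens per-molecule ground truth into one row per true
#' folded->unfolded transition, with the duration of the ensuing unfolded
#' sojourn. `true_event_rate()` returns the rate of transitions whose sojourn
#' lasts at least `min_dwell_s` seconds within the observation window — the
#' quantity a dual-threshold detector with the matching minimum dwell is
#' designed to estimate — divided by the summed observation time.
#'
#' @param truth Ground-truth tibble from [simulate_condition()].
#' @param windows Optional tibble (`molecule_id`, `observation_time`) limiting
#'   each molecule to its analysed window; defaults to the full trace.
#' @param total_time Fallback per-molecule observation time (seconds) when
#'   `windows` is `NULL`.
#' @param min_dwell_s Minimum unfolded sojourn, seconds, for an event to count.
#' @return `true_events()`: tibble (`molecule_id`, `time`, `dwell`).
#'   `true_event_rate()`: a single rate, s^-1.
#' @export
true_events <- function(truth) {
  purrr::list_rbind(purrr::pmap(
    list(truth$molecule_id, truth$state_path),
    function(id, path) {
      unf <- path[path$state == "unfolded", , drop = FALSE]
      tibble::tibble(molecule_id = id, time = unf$start,
                     dwell = unf$end - unf$start)
    }
  ))
}

#' @rdname true_events
#' @export
true_event_rate <- function(truth, windows = NULL, total_time = NULL,
                            min_dwell_s = 0) {
  ev <- true_events(truth)
  if (is.null(windows)) {
    if (is.null(total_time)) {
      abort("supply either `windows` or `total_time`.")
    }
    windows <- tibble::tibble(molecule_id = truth$molecule_id,
                              observation_time = total_time)
  }
  ev <- dplyr::inner_join(ev, windows, by = "molecule_id")
  n_ev <- sum(ev$time < ev$observation_time & ev$dwell >= min_dwell_s)
  n_ev / sum(windows$observation_time)
}
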