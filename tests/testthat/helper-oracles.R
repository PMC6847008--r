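# Independent oracles used to verify the implementation.

# Hand-specified DFA for the dual-threshold detector, built directly from the
# rule text: states are 1 = disarmed, 2..(d+1) = armed with 0..d-1
# consecutive low frames accumulated, d+2 = unfolded. Symbols (1-based
# columns): 1 = low, 2 = between, 3 = high, 4 = undefined/skip. Independent
# of the package's vectorized sweep.
make_event_dfa <- function(min_dwell) {
  d <- min_dwell
  n_states <- d + 2L
  trans <- matrix(0L, n_states, 4L)
  emit_dip <- matrix(0L, n_states, 4L)
  emit_rise <- matrix(0L, n_states, 4L)
  disarmed <- 1L
  armed0 <- 2L
  unfolded <- d + 2L
  # disarmed
  trans[disarmed, ] <- c(disarmed, disarmed, armed0, disarmed)
  # armed with j lows so far (state armed0 + j)
  for (j in 0:(d - 1L)) {
    s <- armed0 + j
    next_low <- if (j + 1L == d) unfolded else s + 1L
    trans[s, ] <- c(next_low, armed0, armed0, s)
    if (j + 1L == d) emit_dip[s, 1L] <- 1L
  }
  # unfolded
  trans[unfolded, ] <- c(unfolded, unfolded, armed0, unfolded)
  emit_rise[unfolded, 3L] <- 1L
  list(trans = trans, emit_dip = emit_dip, emit_rise = emit_rise)
}

# Run the DFA over a symbol matrix (rows = traces, 0-based symbols as in
# count_events_symbolic); returns at_dip / full_cycle counts per row.
dfa_event_oracle <- function(sym, min_dwell) {
  if (is.vector(sym)) sym <- matrix(as.integer(sym), nrow = 1L)
  dfa <- make_event_dfa(min_dwell)
  n <- nrow(sym)
  state <- rep(1L, n)
  dips <- integer(n)
  rises <- integer(n)
  for (j in seq_len(ncol(sym))) {
    s <- sym[, j] + 1L
    idx <- cbind(state, s)
    dips <- dips + dfa$emit_dip[idx]
    rises <- rises + dfa$emit_rise[idx]
    state <- dfa$trans[idx]
  }
  data.frame(at_dip = dips, full_cycle = rises)
}

# All 3^len threshold-symbol traces of a given length, one per row.
# (Arithmetic in doubles: 3^12 * 12 exceeds the integer range mid-division.)
enumerate_symbol_traces <- function(len) {
  n <- 3^len
  idx <- seq_len(n) - 1
  vapply(seq_len(len), function(j) as.integer((idx %/% 3^(j - 1)) %% 3),
         integer(n))
}

# Expected number of folded->unfolded transitions in [0, total_time] for a
# two-state chain started folded: integral of k_unfold * p_folded(t), with
# p_folded(t) = pi + (1 - pi) exp(-k t), pi = k_refold / k, k = sum of
# hazards. Cross-checked against numerical integration.
expected_unfolding_events <- function(k_unfold, k_refold, total_time) {
  k <- k_unfold + k_refold
  pi_f <- k_refold / k
  closed <- k_unfold * (pi_f * total_time +
                          (1 - pi_f) * (1 - exp(-k * total_time)) / k)
  numeric <- stats::integrate(function(t) {
    k_unfold * (pi_f + (1 - pi_f) * exp(-k * t))
  }, 0, total_time)$value
  stopifnot(abs(closed - numeric) < 1e-6 * max(1, closed))
  closed
}

# Build a FRET tibble from a plain efficiency vector (test fixture).
fret_fixture <- function(efret, molecule_id = "m1", frame_interval = 0.05) {
  out <- tibble::tibble(molecule_id = molecule_id,
                        frame = seq_along(efret) - 1L,
                        efret = efret)
  attr(out, "frame_interval") <- frame_interval
  out
}

# Build an intensity-trace tibble from an efficiency vector (total = 1000).
trace_fixture <- function(efret, molecule_id = "m1", total = 1000,
                          frame_interval = 0.05) {
  out <- tibble::tibble(molecule_id = molecule_id,
                        frame = seq_along(efret) - 1L,
                        donor = total * (1 - efret),
                        acceptor = total * efret)
  attr(out, "frame_interval") <- frame_interval
  out
}
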