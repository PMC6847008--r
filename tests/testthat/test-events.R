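test_that("event_params validates its invariants", {
  expect_error(event_params(low_threshold = 0.6, high_threshold = 0.55),
               "strictly below")
  expect_error(event_params(min_dwell_frames = 0), "min_dwell_frames")
  expect_silent(event_params())
})

test_that("hand-enumerated traces give the expected event counts", {
  # never dips
  expect_equal(count_unfolding_events(fret_fixture(rep(0.7, 20)))$n_events, 0L)
  # two full unfold/refold cycles, both count modes agree
  ef <- rep(c(0.7, 0.3, 0.7, 0.3, 0.7), times = c(10, 5, 10, 5, 5))
  for (mode in c("at_dip", "full_cycle")) {
    rec <- count_unfolding_events(fret_fixture(ef),
                                  event_params(count_mode = mode))
    expect_equal(rec$n_events, 2L)
  }
  # single-point dip is conservatively not an event at min_dwell 2
  ef1 <- rep(c(0.7, 0.3, 0.7), times = c(10, 1, 10))
  expect_equal(count_unfolding_events(fret_fixture(ef1))$n_events, 0L)
  expect_equal(
    count_unfolding_events(fret_fixture(ef1),
                           event_params(min_dwell_frames = 1))$n_events, 1L)
  # detector never arms if the trace starts unfolded and stays low
  expect_equal(count_unfolding_events(fret_fixture(rep(0.3, 20)))$n_events, 0L)
  # dip interrupted by bleach/end of trace: counted at_dip, not full_cycle
  ef2 <- rep(c(0.7, 0.3), times = c(10, 6))
  expect_equal(count_unfolding_events(fret_fixture(ef2))$n_events, 1L)
  expect_equal(
    count_unfolding_events(fret_fixture(ef2),
                           event_params(count_mode = "full_cycle"))$n_events,
    0L)
  # hysteresis: two dips separated only by between-threshold wander are one
  # event — the detector must re-arm at the high threshold first
  ef3 <- rep(c(0.7, 0.5, 0.3, 0.5, 0.3, 0.7), times = c(5, 3, 2, 3, 2, 5))
  expect_equal(count_unfolding_events(fret_fixture(ef3))$n_events, 1L)
  ef4 <- rep(c(0.7, 0.3, 0.6, 0.3, 0.7), times = c(5, 2, 3, 2, 5))
  expect_equal(count_unfolding_events(fret_fixture(ef4))$n_events, 2L)
})

test_that("event frames locate dips (at_dip) and rises (full_cycle)", {
  ef <- rep(c(0.7, 0.3, 0.7), times = c(10, 5, 10))
  rec <- count_unfolding_events(fret_fixture(ef))
  expect_equal(rec$event_frames[[1]], 10L)
  rec2 <- count_unfolding_events(
    fret_fixture(ef), event_params(count_mode = "full_cycle"))
  expect_equal(rec2$event_frames[[1]], 15L)
})

test_that("detector matches the DFA oracle exhaustively (short traces)", {
  for (len in 1:7) {
    sym <- enumerate_symbol_traces(len)
    for (d in 1:3) {
      got <- count_events_symbolic(sym, min_dwell_frames = d)
      want <- dfa_event_oracle(sym, d)
      expect_identical(got$at_dip, want$at_dip)
      expect_identical(got$full_cycle, want$full_cycle)
    }
  }
})

test_that("undefined frames are skipped without resetting the detector", {
  ef <- rep(c(0.7, 0.3, 0.7), times = c(10, 4, 10))
  with_na <- c(ef[1:11], NA, NA, ef[12:length(ef)])
  expect_equal(count_unfolding_events(fret_fixture(with_na))$n_events, 1L)
  # NA inside the dip does not break the consecutive-low requirement
  ef2 <- c(rep(0.7, 5), 0.3, NA, 0.3, rep(0.7, 5))
  expect_equal(count_unfolding_events(fret_fixture(ef2))$n_events, 1L)
})

test_that("events beyond the observation window are ignored", {
  ef <- rep(c(0.7, 0.3, 0.7, 0.3, 0.7), times = c(10, 5, 10, 5, 10))
  fx <- fret_fixture(ef)
  win <- tibble::tibble(molecule_id = "m1", observation_end_frame = 20L,
                        observation_time = 1.0)
  rec <- count_unfolding_events(fx, windows = win)
  expect_equal(rec$n_events, 1L)
  expect_equal(rec$observation_time, 1.0)
  expect_equal(rec$rate, 1L / 1.0)
})

test_that("raising the low threshold never decreases the event count", {
  set.seed(31)
  for (i in 1:20) {
    ef <- runif(80, 0, 1)
    lows <- c(0.25, 0.35, 0.45)
    counts <- vapply(lows, function(lo) {
      count_unfolding_events(
        fret_fixture(ef), event_params(low_threshold = lo))$n_events
    }, integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("pooled rate equals the time-weighted mean of per-molecule rates", {
  set.seed(4)
  rec <- tibble::tibble(
    molecule_id = sprintf("m%d", 1:50),
    n_events = rpois(50, 3),
    observation_time = runif(50, 10, 100)
  )
  est <- summarize_condition(rec, "x")
  rates <- rec$n_events / rec$observation_time
  expect_equal(est$pooled_rate,
               sum(rates * rec$observation_time) / sum(rec$observation_time))
  expect_equal(est$mean_of_rates, mean(rates))
  expect_equal(est$n_events, sum(rec$n_events))
})

test_that("summarize_condition handles edge cases", {
  zero <- tibble::tibble(n_events = c(0, 0), observation_time = c(10, 20))
  expect_equal(summarize_condition(zero)$pooled_rate, 0)
  expect_error(summarize_condition(zero[0, ]), "at least one")
  bad <- tibble::tibble(n_events = 1, observation_time = 0)
  expect_error(summarize_condition(bad), "positive")
})

test_that("relative rate normalizes to the reference and needs a nonzero one", {
  a <- summarize_condition(
    tibble::tibble(n_events = 10, observation_time = 100), "lig")
  b <- summarize_condition(
    tibble::tibble(n_events = 20, observation_time = 100), "ref")
  expect_equal(relative_rate(a, b)$relative_rate, 0.5)
  expect_equal(relative_rate(a, a)$relative_rate, 1.0)
  zero <- summarize_condition(
    tibble::tibble(n_events = 0, observation_time = 100), "zero")
  expect_error(relative_rate(a, zero), "positive")
})

test_that("event recovery scoring implements greedy one-to-one matching", {
  perfect <- score_event_recovery(c(10, 50), c(0.5, 2.5), 0.05, tolerance = 2)
  expect_equal(perfect$precision, 1.0)
  expect_equal(perfect$recall, 1.0)
  none <- score_event_recovery(integer(0), c(0.5), 0.05)
  expect_equal(none$precision, 1.0)
  expect_equal(none$recall, 0.0)
  # one true event cannot absorb two detections
  double <- score_event_recovery(c(10, 11), c(0.5), 0.05, tolerance = 2)
  expect_equal(double$precision, 0.5)
  expect_equal(double$recall, 1.0)
})

test_that("noiseless simulated traces are recovered perfectly at dwell >= 3", {
  cfg <- trace_sim_config(n_molecules = 25, n_frames = 3000,
                          k_unfold = 0.05, k_refold = 0.3,
                          frac_donor_only = 0, e_noise_sd = 0,
                          intensity_noise_sd = 0,
                          tau_bleach_acceptor = Inf, tau_bleach_donor = Inf,
                          seed = 21)
  sim <- simulate_condition(cfg)
  fret <- compute_fret(sim$traces)
  rec <- count_unfolding_events(fret)
  te <- true_events(sim$truth)
  for (i in seq_len(nrow(rec))) {
    id <- rec$molecule_id[i]
    keep <- te$molecule_id == id & te$dwell >= 3 * 0.05
    sc <- score_event_recovery(rec$event_frames[[i]], te$time[keep], 0.05,
                               tolerance = 3)
    expect_equal(sc$recall, 1.0)
  }
})
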