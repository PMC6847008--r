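test_that("proximity ratio matches hand values and stays in [0, 1]", {
  tr <- tibble::tibble(molecule_id = "m1", frame = 0:3,
                       donor = c(100, 0, 88, -5),
                       acceptor = c(0, 50, 12, 10))
  ef <- compute_fret(tr)$efret
  expect_equal(ef[1], 0.0)
  expect_equal(ef[2], 1.0)
  expect_equal(ef[3], 0.12)  # the donor-leakage level
  expect_equal(ef[4], 1.0)   # negative donor clamped to 0
  set.seed(1)
  rnd <- tibble::tibble(molecule_id = "m", frame = 0:99,
                        donor = runif(100, 0, 500),
                        acceptor = runif(100, 0, 500))
  ef2 <- compute_fret(rnd)$efret
  expect_true(all(ef2 >= 0 & ef2 <= 1, na.rm = TRUE))
})

test_that("FRET is invariant under common positive scaling of both channels", {
  set.seed(2)
  tr <- tibble::tibble(molecule_id = "m", frame = 0:49,
                       donor = runif(50, 1, 100), acceptor = runif(50, 1, 100))
  scaled <- dplyr::mutate(tr, donor = donor * 7.3, acceptor = acceptor * 7.3)
  expect_equal(compute_fret(tr)$efret, compute_fret(scaled)$efret)
})

test_that("zero-total frames are undefined; all-undefined traces are dropped", {
  tr <- tibble::tibble(molecule_id = rep(c("ok", "dead"), each = 3),
                       frame = rep(0:2, 2),
                       donor = c(50, 0, 50, 0, 0, 0),
                       acceptor = c(50, 0, 50, 0, 0, 0))
  expect_warning(out <- compute_fret(tr), "dead")
  expect_setequal(unique(out$molecule_id), "ok")
  expect_true(is.na(out$efret[out$frame == 1]))
})

test_that("constant-intensity traces keep the full observation window", {
  tr <- trace_fixture(rep(0.7, 200))
  win <- detect_observation_window(tr)
  expect_equal(win$observation_end_frame, 200L)
  expect_equal(win$observation_time, 10)
})

test_that("donor bleach truncates the window near the injected frame", {
  set.seed(3)
  n <- 800
  bleach_at <- 500
  e <- 0.7
  donor <- c(rep(1000 * (1 - e), bleach_at), rep(0, n - bleach_at)) +
    rnorm(n, 0, 30)
  acceptor <- c(rep(1000 * e, bleach_at), rep(0, n - bleach_at)) +
    rnorm(n, 0, 30)
  tr <- tibble::tibble(molecule_id = "m", frame = 0:(n - 1),
                       donor = donor, acceptor = acceptor)
  win <- detect_observation_window(tr, frame_interval = 0.05)
  expect_lt(abs(win$observation_end_frame - bleach_at), 3)
})

test_that("acceptor-only bleach ends the window; transient dips do not", {
  set.seed(4)
  dt <- 0.05
  bleach_frame <- round(54.3 / dt)
  n <- 1400
  # folded at 0.7 with two genuine unfolding dwells, then acceptor bleach:
  # emission collapses to the donor channel (leakage level 0.12)
  e <- rep(0.7, n)
  e[300:360] <- 0.30
  e[700:790] <- 0.30
  e[(bleach_frame + 1):n] <- 0.12
  tr <- tibble::tibble(molecule_id = "m", frame = 0:(n - 1),
                       donor = 1000 * (1 - e) + rnorm(n, 0, 30),
                       acceptor = 1000 * e + rnorm(n, 0, 30))
  win <- detect_observation_window(tr, frame_interval = dt)
  expect_lt(abs(win$observation_time - 54.3), 5 * dt)
})

test_that("histogram pools the first k defined frames per molecule", {
  one <- fret_fixture(rep(0.7, 30))
  h <- build_fret_histogram(one, first_k_frames = 15, bin_width = 0.02)
  expect_s3_class(h, "fret_histogram")
  expect_equal(sum(h$count), 15L)
  hit <- h$count[h$bin_lo <= 0.7 & h$bin_hi > 0.7]
  expect_equal(hit, 15L)
  # two equal populations -> two equal modes
  two <- purrr::list_rbind(list(fret_fixture(rep(0.3, 15), "a"),
                                fret_fixture(rep(0.7, 15), "b")))
  attr(two, "frame_interval") <- 0.05
  h2 <- build_fret_histogram(two, first_k_frames = 15)
  expect_equal(sum(h2$count[h2$bin_lo <= 0.3 & h2$bin_hi > 0.3]), 15L)
  expect_equal(sum(h2$count[h2$bin_lo <= 0.7 & h2$bin_hi > 0.7]), 15L)
  # total = sum over molecules of min(k, defined frames)
  short <- purrr::list_rbind(list(fret_fixture(rep(0.5, 7), "a"),
                                  fret_fixture(rep(0.6, 40), "b")))
  attr(short, "frame_interval") <- 0.05
  expect_equal(sum(build_fret_histogram(short, first_k_frames = 15)$count),
               7L + 15L)
  expect_error(
    build_fret_histogram(fret_fixture(NA_real_)), "no defined")
})

test_that("observation windows clip the frames entering the histogram", {
  fx <- fret_fixture(c(rep(0.7, 10), rep(0.12, 20)))
  win <- tibble::tibble(molecule_id = "m1", observation_end_frame = 10L,
                        observation_time = 0.5)
  h <- build_fret_histogram(fx, first_k_frames = 15, windows = win)
  expect_equal(sum(h$count), 10L)
})

test_that("single-Gaussian histograms are recovered by the sampling oracle", {
  set.seed(5)
  fx <- fret_fixture(rnorm(1e5, 0.5, 0.05))
  h <- build_fret_histogram(fx, first_k_frames = 1e5)
  fit <- fit_gaussian_mixture(h, 1, init_means = 0.4)
  comps <- tidy(fit)
  expect_lt(abs(comps$mean - 0.5), 0.005)
  expect_lt(abs(comps$sd - 0.05), 0.005)
  expect_equal(comps$weight, 1)
})

test_that("a one-component fit of bimodal data lands between the modes", {
  set.seed(6)
  fx <- fret_fixture(c(rnorm(5e3, 0.12, 0.02), rnorm(5e3, 0.70, 0.03)))
  h <- build_fret_histogram(fx, first_k_frames = 1e4)
  fit <- fit_gaussian_mixture(h, 1, init_means = 0.4, init_sds = 0.3)
  m <- tidy(fit)$mean
  expect_gt(m, 0.12)
  expect_lt(m, 0.70)
})

test_that("adding a component never worsens the least-squares residual", {
  set.seed(7)
  fx <- fret_fixture(c(rnorm(4e4, 0.12, 0.02), rnorm(3e4, 0.59, 0.05),
                       rnorm(3e4, 0.70, 0.03)))
  h <- build_fret_histogram(fx, first_k_frames = 1e5)
  f1 <- fit_gaussian_mixture(h, 1, init_means = 0.4, init_sds = 0.25)
  # refine: seed the larger model with the smaller model's solution
  m1 <- tidy(f1)
  f2 <- fit_gaussian_mixture(h, 2, init_means = c(m1$mean, 0.12),
                             init_sds = c(m1$sd, 0.05))
  m2 <- tidy(f2)
  f3 <- fit_gaussian_mixture(h, 3, init_means = c(m2$mean, 0.65),
                             init_sds = c(m2$sd, 0.05))
  r <- c(glance(f1)$residual_norm, glance(f2)$residual_norm,
         glance(f3)$residual_norm)
  expect_true(all(diff(r) <= 1e-8 + 1e-6 * r[-3]))
})

test_that("mixture fitting is deterministic given the initializer", {
  set.seed(8)
  fx <- fret_fixture(c(rnorm(2e4, 0.2, 0.05), rnorm(2e4, 0.7, 0.05)))
  h <- build_fret_histogram(fx, first_k_frames = 4e4)
  f_a <- fit_gaussian_mixture(h, 2, init_means = c(0.25, 0.65))
  f_b <- fit_gaussian_mixture(h, 2, init_means = c(0.25, 0.65))
  expect_identical(tidy(f_a), tidy(f_b))
})
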