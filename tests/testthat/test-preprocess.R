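test_that("resampling preserves length arithmetic and sinusoid amplitude", {
  expect_length(resample_series(rep(3.5, 2048), 2048, 200), 200)
  expect_equal(resample_series(rep(3.5, 1000), 500, 250), rep(3.5, 500),
               tolerance = 1e-6)
  t <- seq(0, 5 - 1/2048, by = 1/2048)
  x <- sin(2 * pi * 5 * t)
  y <- resample_series(x, 2048, 200)
  mid <- y[100:900]  # away from filter edge transients
  expect_lt(abs(diff(range(mid)) / 2 - 1), 0.01)
  expect_error(resample_series(x, 200, 2048), "upsampling")
})

test_that("band-pass filtering rejects DC, passes 10 Hz, attenuates 80 Hz", {
  fs <- 200
  n <- 60 * fs
  dc <- bandpass_filter(rep(5, n), fs)
  expect_lt(max(abs(dc[(n/4):(3*n/4)])), 0.05)
  t <- (0:(n-1)) / fs
  g10 <- diff(range(bandpass_filter(sin(2*pi*10*t), fs)[(n/4):(3*n/4)])) / 2
  g80 <- diff(range(bandpass_filter(sin(2*pi*80*t), fs)[(n/4):(3*n/4)])) / 2
  expect_equal(g10, 1, tolerance = 0.01)
  expect_lt(g80, 0.01)
  expect_error(bandpass_filter(rnorm(100), fs, low = 1, high = 120),
               "Nyquist|rate/2")
})

test_that("zero-phase filtering does not shift peak latency", {
  fs <- 200
  t_ms <- seq(0, 60000 - 5, by = 5)
  x <- gauss_bump(t_ms, 30000, 40, 5)
  y <- bandpass_filter(x, fs)
  expect_equal(t_ms[which.max(y)], 30000, tolerance = 5)
})

test_that("pupil size change equals the frame difference", {
  psc <- compute_psc(rep(4.2, 100), 200)
  expect_equal(psc$values, rep(0, 99))
  expect_equal(psc$t0, 1/200)
  ramp <- compute_psc(seq(4, 5, length.out = 101), 200)
  expect_equal(ramp$values, rep(0.01, 100))
  set.seed(8)
  x <- cumsum(rnorm(50))
  expect_equal(compute_psc(x, 200)$values,
               x[2:50] - x[1:49])  # brute-force differencing oracle
  expect_error(compute_psc(c(1, NA, 3), 200), "invalid")
  expect_error(compute_psc(4, 200), "2 samples")
})

test_that("blink interpolation bridges gaps linearly and enforces the cap", {
  x <- c(1, 2, NA, NA, 5, 6)
  expect_equal(interpolate_blinks(x), c(1, 2, 3, 4, 5, 6))
  expect_equal(interpolate_blinks(c(NA, 2, 3))[1], 2)  # edge fill
  expect_error(interpolate_blinks(x, max_gap = 1), "max_gap")
  expect_error(interpolate_blinks(c(NA, NA, 1)), "fewer than 2")
})

test_that("epoch extraction yields the documented span and counts", {
  cfg <- preprocess_config()
  sched <- build_schedule(paradigm_config())
  n <- ceiling(sched$total_duration / 1000 * 200)
  values <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("Fz", "Cz")))
  ep <- extract_epochs(values, 200, events_to_table(sched), cfg)
  expect_equal(dim(ep$data), c(500, 200, 2))
  expect_equal(sum(ep$labels == "target"), 50)
  expect_equal(sum(ep$labels == "nontarget"), 450)
  expect_equal(ep$time_ms[1], -200)
  expect_equal(ep$time_ms[200], 795)
  # epoch_start = 0 begins exactly at the onset sample
  cfg0 <- preprocess_config(epoch_start = 0, epoch_end = 800,
                            baseline_window = NULL)
  ev1 <- data.frame(onset_ms = 1000, label = "nontarget")
  ep0 <- extract_epochs(values, 200, ev1, cfg0)
  expect_equal(ep0$data[1, 1, 1], values[201, 1])
  # out-of-range events are excluded and counted
  ev_bad <- data.frame(onset_ms = c(1000, sched$total_duration + 5000),
                       label = c("target", "target"))
  expect_message(ep_bad <- extract_epochs(values, 200, ev_bad, cfg),
                 "excluded 1")
  expect_equal(ep_bad$n_excluded, 1)
  expect_equal(dim(ep_bad$data)[1], 1)
})

test_that("event-to-sample alignment takes the nearest sample, earlier on ties", {
  values <- matrix(seq_len(1000), ncol = 1)
  cfg <- preprocess_config(epoch_start = 0, epoch_end = 50,
                           baseline_window = NULL)
  near <- function(onset_ms) {
    ev <- data.frame(onset_ms = onset_ms, label = "nontarget")
    unname(extract_epochs(values, 200, ev, cfg)$data[1, 1, 1])
  }
  expect_equal(near(1000), values[201])   # exact grid point
  expect_equal(near(1001), values[201])   # 0.2 samples late -> same sample
  expect_equal(near(1004), values[202])   # 0.8 samples -> next sample
  expect_equal(near(1002.5), values[201]) # exact midpoint -> earlier sample
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  cfg <- preprocess_config()
  ev <- data.frame(onset_ms = c(2000, 3000),
                   label = c("target", "nontarget"))
  values <- matrix(rnorm(2000, mean = 7), ncol = 1)
  ep <- extract_epochs(values, 200, ev, cfg)
  bc <- baseline_correct(ep)
  sel <- bc$time_ms >= -200 & bc$time_ms < 0
  expect_equal(max(abs(rowMeans(bc$data[, sel, 1]))), 0, tolerance = 1e-12)
  expect_equal(baseline_correct(bc)$data, bc$data, tolerance = 1e-12)
  # constant epochs become all-zero
  ep2 <- extract_epochs(matrix(3, 2000, 1), 200, ev, cfg)
  expect_equal(max(abs(baseline_correct(ep2)$data)), 0)
  expect_error(baseline_correct(ep, c(-500, -300)), "no samples")
})

test_that("condition averaging is the pointwise mean with symmetry and n bookkeeping", {
  cfg <- preprocess_config()
  x <- rnorm(400)
  values <- matrix(c(x, x, x, -x, numeric(400)), ncol = 1)
  ev <- data.frame(onset_ms = c(100, 2100, 4100, 6100) + 200,
                   label = c("target", "target", "nontarget", "nontarget"))
  ep <- extract_epochs(values, 200, ev, cfg)
  avg <- average_epochs(ep)
  expect_equal(avg$n_used, c(target = 2, nontarget = 2))
  expect_equal(avg$target[, 1], ep$data[1, , 1])     # identical epochs
  expect_equal(max(abs(avg$nontarget)), 0, tolerance = 1e-12)  # +x, -x cancel
  ep_nt <- extract_epochs(values, 200, ev[3:4, ], cfg)
  expect_error(average_epochs(ep_nt), "target")
})

test_that("averaging 450 stochastic epochs reduces variance (law of large numbers)", {
  set.seed(42)
  sched <- build_schedule(paradigm_config())
  n <- ceiling(sched$total_duration / 1000 * 200)
  values <- matrix(rnorm(n), ncol = 1)
  ep <- extract_epochs(values, 200, events_to_table(sched),
                       preprocess_config())
  avg <- average_epochs(ep)
  nt <- ep$labels == "nontarget"
  single_var <- mean(apply(ep$data[nt, , 1], 1, var))
  expect_lt(var(avg$nontarget[, 1]), single_var / 100)
})

test_that("preprocessing a recording is deterministic", {
  sched <- build_schedule(tiny_paradigm())
  rec <- simulate_subject(sched, seed = 6, eeg_rate = 256)
  p1 <- preprocess_subject(rec)
  p2 <- preprocess_subject(rec)
  expect_identical(p1, p2)
  expect_equal(unname(p1$n_epochs), c(20, 20))
})
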