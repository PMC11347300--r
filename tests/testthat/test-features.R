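# exhaustive scan over window samples: the independent oracle for the
# amplitude (max - min) and latency (time of first maximum) features
scan_window <- function(values, time_ms, start, end) {
  lo <- Inf; hi <- -Inf; t_hi <- NA_real_
  for (i in seq_along(values)) {
    if (time_ms[i] >= start && time_ms[i] <= end) {
      if (values[i] < lo) lo <- values[i]
      if (values[i] > hi) { hi <- values[i]; t_hi <- time_ms[i] }
    }
  }
  list(amp = hi - lo, lat = t_hi)
}

test_that("amplitude and latency agree with the exhaustive window scan", {
  set.seed(21)
  time_ms <- seq(-200, 795, by = 5)
  w <- feature_windows()
  for (rep in 1:10) {
    m <- matrix(rnorm(2 * length(time_ms)), ncol = 2,
                dimnames = list(NULL, c("Fz", "Cz")))
    avg <- fake_avg(m, -m, time_ms, c("Fz", "Cz"))
    for (wi in seq_len(nrow(w))) {
      for (ch in c("Fz", "Cz")) {
        oracle_t <- scan_window(m[, ch], time_ms, w$start[wi], w$end[wi])
        oracle_n <- scan_window(-m[, ch], time_ms, w$start[wi], w$end[wi])
        expect_equal(window_amplitude(avg, ch, w[wi, ], "target"),
                     oracle_t$amp)
        expect_equal(window_latency(avg, ch, w[wi, ], "target"),
                     oracle_t$lat)
        expect_equal(window_amplitude(avg, ch, w[wi, ], "nontarget"),
                     oracle_n$amp)
        expect_equal(window_latency(avg, ch, w[wi, ], "nontarget"),
                     oracle_n$lat)
      }
    }
  }
})

test_that("closed-form epochs give closed-form features", {
  time_ms <- seq(-200, 795, by = 5)
  w <- feature_windows()
  flat <- fake_avg(matrix(0, length(time_ms), 1,
                          dimnames = list(NULL, "Fz")),
                   time_ms = time_ms, channels = "Fz")
  expect_equal(window_amplitude(flat, "Fz", w[1, ]), 0)
  # triangular bump of height 7 peaking at 300 ms on a zero baseline
  tri <- pmax(0, 7 * (1 - abs(time_ms - 300) / 50))
  bump <- fake_avg(matrix(tri, ncol = 1, dimnames = list(NULL, "Fz")),
                   time_ms = time_ms, channels = "Fz")
  expect_equal(window_amplitude(bump, "Fz", w[1, ]), 7)
  expect_equal(window_latency(bump, "Fz", w[1, ]), 300)
  # monotonically increasing segment peaks at the window end
  ramp <- fake_avg(matrix(time_ms, ncol = 1, dimnames = list(NULL, "Fz")),
                   time_ms = time_ms, channels = "Fz")
  expect_equal(window_latency(ramp, "Fz", w[1, ]), 350)
  # ties go to the earliest sample
  const <- fake_avg(matrix(1, length(time_ms), 1,
                           dimnames = list(NULL, "Fz")),
                    time_ms = time_ms, channels = "Fz")
  expect_equal(window_latency(const, "Fz", w[2, ]), 400)
})

test_that("amplitude ignores offsets; latency ignores positive scaling", {
  set.seed(3)
  time_ms <- seq(-200, 795, by = 5)
  w <- feature_windows()[3, ]
  m <- matrix(rnorm(length(time_ms)), ncol = 1,
              dimnames = list(NULL, "Pz"))
  a0 <- fake_avg(m, time_ms = time_ms, channels = "Pz")
  a_shift <- fake_avg(m + 11.5, time_ms = time_ms, channels = "Pz")
  a_scale <- fake_avg(m * 3.7, time_ms = time_ms, channels = "Pz")
  expect_equal(window_amplitude(a_shift, "Pz", w),
               window_amplitude(a0, "Pz", w))
  expect_equal(window_latency(a_scale, "Pz", w),
               window_latency(a0, "Pz", w))
})

test_that("feature tables have the documented shape and column order", {
  time_ms <- seq(-200, 795, by = 5)
  chans <- c("Fz", "Cz", "Pz", "Oz")
  mk <- function(id) {
    m <- matrix(rnorm(length(time_ms) * 4), ncol = 4,
                dimnames = list(NULL, chans))
    fake_avg(m, -m, time_ms, chans, subject_id = id)
  }
  one <- build_feature_table(list(mk("S01")))
  expect_equal(nrow(one), 2)
  avg30 <- lapply(sprintf("S%02d", 1:30), mk)
  tab <- build_feature_table(avg30)
  expect_equal(nrow(tab), 60)                      # 30 subjects x 2 conditions
  expect_equal(ncol(tab) - 2, 12)                  # 4 channels x 3 windows
  expect_equal(names(tab)[3:5], c("Fz_P3a_amp", "Fz_P3b_amp", "Fz_LPP_amp"))
  # pupil tables carry 3 amplitude features
  pup <- lapply(sprintf("S%02d", 1:4), function(id) {
    m <- matrix(rnorm(length(time_ms)), ncol = 1,
                dimnames = list(NULL, "pupil"))
    fake_avg(m, -m, time_ms, "pupil", subject_id = id, modality = "ErPR")
  })
  ptab <- build_feature_table(pup)
  expect_equal(ncol(ptab) - 2, 3)
  # latency doubles the column count
  full <- build_feature_table(avg30, include_latency = TRUE)
  expect_equal(ncol(full) - 2, 24)
  # missing condition is reported with the subject
  broken <- avg30[1:2]
  broken[[2]]$nontarget <- NULL
  broken[[2]]$subject_id <- "S99"
  expect_error(build_feature_table(broken), "S99")
})

test_that("feature tables round-trip through the TSV writer", {
  time_ms <- seq(-200, 795, by = 5)
  m <- matrix(rnorm(length(time_ms)), ncol = 1,
              dimnames = list(NULL, "pupil"))
  tab <- build_feature_table(list(fake_avg(m, -m, time_ms, "pupil")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back, tab, tolerance = 1e-12)
})
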