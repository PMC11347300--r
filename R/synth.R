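#' Event-locked component template
#'
#' Describes one positive event-locked component (P3a, P3b or LPP) as a
#' Gaussian-in-time bump added to the signal at every stimulus onset. The
#' amplitude depends on the stimulus condition (larger for targets than for
#' nontargets, mirroring the familiar-face effect), on a per-subject offset
#' shared between the EEG and pupil modalities, and on trial-to-trial
#' variability.
#'
#' @param window_name One of `"P3a"`, `"P3b"`, `"LPP"`.
#' @param center_latency Mean peak latency, ms post-stimulus; must lie inside
#'   the component's canonical window (200-350, 400-490 or 530-750 ms).
#' @param width Gaussian standard deviation of the bump, ms.
#' @param target_amplitude Mean peak amplitude for target stimuli
#'   (signal units: microvolts for EEG, millimetres of drive for pupil).
#' @param nontarget_amplitude Mean peak amplitude for nontarget stimuli.
#' @param subject_sd SD of the per-subject amplitude offset.
#' @param trial_sd SD of the trial-to-trial amplitude jitter.
#' @param latency_jitter_sd SD of the trial-to-trial latency jitter, ms.
#' @return An object of class `component_template`.
#' @export
component_template <- function(window_name,
                               center_latency,
                               width,
                               target_amplitude,
                               nontarget_amplitude,
                               subject_sd = 0,
                               trial_sd = 0,
                               latency_jitter_sd = 0) {
  window_name <- match.arg(window_name, c("P3a", "P3b", "LPP"))
  bounds <- switch(window_name,
                   P3a = c(200, 350), P3b = c(400, 490), LPP = c(530, 750))
  if (center_latency < bounds[1] || center_latency > bounds[2]) {
    config_stop("center_latency",
                sprintf("must lie inside the %s window [%g, %g] ms",
                        window_name, bounds[1], bounds[2]))
  }
  if (width <= 0) config_stop("width", "must be positive")
  if (target_amplitude <= nontarget_amplitude) {
    config_stop("target_amplitude", "must exceed `nontarget_amplitude`")
  }
  structure(
    list(window_name = window_name, center_latency = center_latency,
         width = width, target_amplitude = target_amplitude,
         nontarget_amplitude = nontarget_amplitude, subject_sd = subject_sd,
         trial_sd = trial_sd, latency_jitter_sd = latency_jitter_sd),
    class = "component_template"
  )
}

#' Default component templates
#'
#' EEG templates are in microvolts; pupil templates are in millimetres of
#' dilation drive (the drive is low-pass filtered into a slow diameter
#' response, so pupil-size-change feature values are on a smaller,
#' scale-dependent unit). Amplitude means are chosen so that a 30-subject
#' cohort yields target-vs-nontarget effect sizes (Cohen's d around 2) of the
#' magnitude typical for familiar-face RSVP protocols.
#'
#' @param modality `"eeg"` or `"pupil"`.
#' @return List of three [component_template()] objects (P3a, P3b, LPP).
#' @export
default_templates <- function(modality = c("eeg", "pupil")) {
  modality <- match.arg(modality)
  # trial_sd is set near 40% of the target mean and latency jitter to
  # 25-30 ms: single-trial P3-family responses are highly variable, and that
  # variability is what makes few-trial averages unstable.
  if (modality == "eeg") {
    list(
      component_template("P3a", 275, 35, 8.0, 3.5,
                         subject_sd = 1.0, trial_sd = 3.0,
                         latency_jitter_sd = 25),
      component_template("P3b", 445, 28, 7.0, 3.0,
                         subject_sd = 1.0, trial_sd = 2.6,
                         latency_jitter_sd = 25),
      component_template("LPP", 640, 55, 6.0, 2.5,
                         subject_sd = 1.0, trial_sd = 2.2,
                         latency_jitter_sd = 30)
    )
  } else {
    list(
      component_template("P3a", 275, 35, 0.12, 0.050,
                         subject_sd = 0.015, trial_sd = 0.045,
                         latency_jitter_sd = 25),
      component_template("P3b", 445, 28, 0.10, 0.042,
                         subject_sd = 0.013, trial_sd = 0.038,
                         latency_jitter_sd = 25),
      component_template("LPP", 640, 55, 0.09, 0.038,
                         subject_sd = 0.012, trial_sd = 0.034,
                         latency_jitter_sd = 30)
    )
  }
}

#' Noise model for synthetic recordings
#'
#' @param eeg_noise_sd SD of the EEG background noise, microvolts.
#' @param spectral_exponent Exponent beta of the 1/f^beta EEG noise spectrum.
#' @param pupil_drift_sd SD of the slow pupil diameter drift, mm.
#' @param pupil_noise_sd SD of white pupil measurement noise, mm.
#' @param blink_rate Blink events per minute (Poisson).
#' @param blink_duration Duration of one blink gap, ms. Blink samples are
#'   marked invalid (`NA`), never set to zero.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(eeg_noise_sd = 10,
                        spectral_exponent = 1,
                        pupil_drift_sd = 0.05,
                        pupil_noise_sd = 0.01,
                        blink_rate = 12,
                        blink_duration = 150) {
  vals <- c(eeg_noise_sd = eeg_noise_sd,
            spectral_exponent = spectral_exponent,
            pupil_drift_sd = pupil_drift_sd,
            pupil_noise_sd = pupil_noise_sd,
            blink_rate = blink_rate,
            blink_duration = blink_duration)
  bad <- names(vals)[!is.finite(vals) | vals < 0]
  if (length(bad)) config_stop(bad[1], "must be nonnegative")
  structure(as.list(vals), class = "noise_model")
}

#' Generate 1/f^beta Gaussian noise
#'
#' Random-phase spectral synthesis: amplitudes follow `f^(-beta/2)` so the
#' power spectrum follows `1/f^beta`; the series is rescaled to the requested
#' standard deviation.
#'
#' @param n Number of samples.
#' @param sd Target standard deviation.
#' @param beta Spectral exponent (0 gives white noise).
#' @return Numeric vector of length `n`, mean zero, sd `sd`.
#' @export
pink_noise <- function(n, sd = 1, beta = 1) {
  if (n < 2 || sd == 0) return(numeric(n))
  k <- c(0, seq_len(n - 1))
  f <- pmin(k, n - k)                     # two-sided frequency index
  amp <- ifelse(f == 0, 0, f^(-beta / 2))
  ph <- stats::runif(n, 0, 2 * pi)
  x <- Re(stats::fft(amp * exp(1i * ph), inverse = TRUE))
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}

# Add one Gaussian bump (peak `amp` at `center_s` seconds, sd `width_s`) to
# `x` sampled at `rate`; only touches samples within 5 sd of the center.
add_bump <- function(x, rate, center_s, width_s, amp) {
  i0 <- max(1L, floor((center_s - 5 * width_s) * rate) + 1L)
  i1 <- min(length(x), ceiling((center_s + 5 * width_s) * rate) + 1L)
  if (i0 > i1) return(x)
  t <- (seq(i0, i1) - 1) / rate
  x[i0:i1] <- x[i0:i1] + amp * exp(-0.5 * ((t - center_s) / width_s)^2)
  x
}

#' Simulate one subject's EEG and pupil recording
#'
#' Each stimulus adds, per EEG channel, one positive Gaussian bump per
#' component with amplitude drawn around the condition mean; channel gains
#' (Fz, Cz, Pz, Oz) scale the bumps to mimic a scalp topography. The pupil
#' diameter responds to the same event structure: the per-event component
#' bumps form a dilation drive which is low-pass filtered by a first-order
#' kernel (time constant `pupil_tau`), so the frame-difference trace
#' (pupil size change) expresses the components. The per-subject amplitude
#' offsets are drawn once per component and shared between modalities, which
#' makes ERP and ErPR features correlated across subjects. True per-event
#' amplitudes and latencies are returned as ground truth.
#'
#' @param schedule An `rsvp_schedule` from [build_schedule()].
#' @param eeg_templates,pupil_templates Lists of [component_template()]s
#'   covering P3a, P3b and LPP.
#' @param noise A [noise_model()].
#' @param seed Integer seed; the recording is bit-reproducible from it.
#' @param subject_id Identifier stored in the recording.
#' @param eeg_rate,pupil_rate Sampling rates, Hz (defaults 2048 and 200).
#' @param pupil_tau Pupil response time constant, ms.
#' @param channel_gains Named gains for the four EEG channels.
#' @return An object of class `subject_recording` with elements `subject_id`,
#'   `eeg` (`values` matrix samples x channels, `rate`), `pupil` (`values`
#'   vector with `NA` during blinks, `rate`), `events` (event table) and
#'   `ground_truth` (data frame: event row, component, condition, true
#'   amplitude and latency).
#' @export
simulate_subject <- function(schedule,
                             eeg_templates = default_templates("eeg"),
                             pupil_templates = default_templates("pupil"),
                             noise = noise_model(),
                             seed = 1L,
                             subject_id = "S01",
                             eeg_rate = 2048,
                             pupil_rate = 200,
                             pupil_tau = 500,
                             channel_gains = c(Fz = 1, Cz = 1.05,
                                               Pz = 0.9, Oz = 0.55)) {
  stopifnot(inherits(schedule, "rsvp_schedule"))
  check_templates(eeg_templates, eeg_rate)
  check_templates(pupil_templates, pupil_rate)

  dur_s <- schedule$total_duration / 1000
  n_eeg <- ceiling(dur_s * eeg_rate)
  n_pup <- ceiling(dur_s * pupil_rate)
  events <- events_to_table(schedule)
  n_ev <- nrow(events)
  comp_names <- vapply(eeg_templates, `[[`, "", "window_name")

  with_seed(seed, {
    # per-subject standard-normal component factors, shared across modalities
    z <- stats::rnorm(length(comp_names))
    names(z) <- comp_names

    truth <- vector("list", length(comp_names))
    drives <- list(eeg = vector("list", length(comp_names)),
                   pupil = vector("list", length(comp_names)))
    for (ci in seq_along(comp_names)) {
      te <- eeg_templates[[ci]]
      tp <- pupil_templates[[ci]]
      base_e <- ifelse(events$label == "target",
                       te$target_amplitude, te$nontarget_amplitude)
      base_p <- ifelse(events$label == "target",
                       tp$target_amplitude, tp$nontarget_amplitude)
      amp_e <- pmax(0, base_e + z[ci] * te$subject_sd +
                      stats::rnorm(n_ev, 0, te$trial_sd))
      amp_p <- pmax(0, base_p + z[ci] * tp$subject_sd +
                      stats::rnorm(n_ev, 0, tp$trial_sd))
      lat <- te$center_latency + stats::rnorm(n_ev, 0, te$latency_jitter_sd)
      truth[[ci]] <- data.frame(
        event = seq_len(n_ev), component = comp_names[ci],
        condition = events$label, eeg_amplitude = amp_e,
        pupil_amplitude = amp_p, latency_ms = lat,
        stringsAsFactors = FALSE
      )
      drives$eeg[[ci]] <- list(amp = amp_e, lat = lat, width = te$width)
      drives$pupil[[ci]] <- list(amp = amp_p, lat = lat, width = tp$width)
    }
    ground_truth <- do.call(rbind, truth)

    # EEG: 1/f noise per channel plus gain-scaled component bumps. The bump
    # track is identical across channels up to the channel gain, so it is
    # synthesized once per component.
    onset_s <- events$onset_ms / 1000
    signal_track <- numeric(n_eeg)
    for (ci in seq_along(comp_names)) {
      d <- drives$eeg[[ci]]
      for (e in seq_len(n_ev)) {
        signal_track <- add_bump(signal_track, eeg_rate,
                                 onset_s[e] + d$lat[e] / 1000,
                                 d$width / 1000, d$amp[e])
      }
    }
    eeg <- matrix(0, n_eeg, length(channel_gains),
                  dimnames = list(NULL, names(channel_gains)))
    for (ch in seq_along(channel_gains)) {
      eeg[, ch] <- pink_noise(n_eeg, noise$eeg_noise_sd,
                              noise$spectral_exponent) +
        channel_gains[ch] * signal_track
    }

    # pupil: component drive -> first-order low-pass -> diameter trace
    drive <- numeric(n_pup)
    for (ci in seq_along(comp_names)) {
      d <- drives$pupil[[ci]]
      for (e in seq_len(n_ev)) {
        drive <- add_bump(drive, pupil_rate, onset_s[e] + d$lat[e] / 1000,
                          d$width / 1000, d$amp[e])
      }
    }
    a <- exp(-1000 / (pupil_tau * pupil_rate))
    response <- stats::filter(drive * (1 - a), a, method = "recursive")
    response <- as.numeric(response)

    drift <- slow_drift(n_pup, pupil_rate, noise$pupil_drift_sd)
    pupil <- 4 + drift + response +
      stats::rnorm(n_pup, 0, noise$pupil_noise_sd)
    pupil <- inject_blinks(pupil, noise$blink_rate, noise$blink_duration,
                           pupil_rate, seed = stats::runif(1, 1, 2^30))

    structure(
      list(subject_id = subject_id,
           eeg = list(values = eeg, rate = eeg_rate,
                      channels = names(channel_gains)),
           pupil = list(values = pupil, rate = pupil_rate),
           events = events,
           schedule_config = schedule$config,
           ground_truth = ground_truth,
           total_duration = schedule$total_duration),
      class = "subject_recording"
    )
  })
}

# Smooth, slowly varying drift: exponentially smoothed white noise rescaled
# to the requested sd (time constant 10 s).
slow_drift <- function(n, rate, sd) {
  if (sd == 0 || n < 2) return(numeric(n))
  a <- exp(-1 / (10 * rate))
  x <- stats::filter(stats::rnorm(n), a, method = "recursive")
  x <- as.numeric(x)
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}

check_templates <- function(templates, rate) {
  for (tp in templates) {
    stopifnot(inherits(tp, "component_template"))
    if (tp$width / 1000 * rate < 2) {
      config_stop("width", sprintf(
        "of %g ms cannot be resolved at %g Hz (needs >= 2 samples per sd)",
        tp$width, rate
      ))
    }
  }
  invisible(TRUE)
}

#' Mark blink gaps in a pupil series as invalid
#'
#' Blink onsets are Poisson-placed over the recording; each blink replaces
#' `blink_duration` ms of samples with `NA`. The gap count and placement are
#' reproducible from the seed.
#'
#' @param x Pupil diameter series, mm.
#' @param blink_rate Blinks per minute.
#' @param blink_duration Blink duration, ms; must be shorter than the series.
#' @param rate Sampling rate, Hz.
#' @param seed Integer seed.
#' @return `x` with blink samples set to `NA`.
#' @export
inject_blinks <- function(x, blink_rate, blink_duration, rate, seed = 1L) {
  if (blink_rate == 0) return(x)
  n <- length(x)
  gap <- round(blink_duration / 1000 * rate)
  if (gap >= n) {
    stop("`blink_duration` must be shorter than the series", call. = FALSE)
  }
  with_seed(seed, {
    dur_min <- n / rate / 60
    k <- stats::rpois(1, blink_rate * dur_min)
    if (k > 0) {
      starts <- sample.int(n - gap, k, replace = TRUE)
      for (s in starts) x[s:(s + gap - 1)] <- NA_real_
    }
  })
  x
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' two cohorts simulated with the same master seed are identical.
#'
#' @param n_subjects Number of subjects (default 30).
#' @param schedule An `rsvp_schedule`; the same schedule is reused for all
#'   subjects.
#' @param seed Master seed.
#' @param ... Passed on to [simulate_subject()].
#' @return List of `subject_recording`s named by subject id.
#' @export
simulate_cohort <- function(n_subjects = 30, schedule = NULL, seed = 1L, ...) {
  if (n_subjects < 1) config_stop("n_subjects", "must be >= 1")
  if (is.null(schedule)) schedule <- build_schedule(paradigm_config())
  seeds <- derive_seeds(seed, n_subjects)
  ids <- sprintf("S%02d", seq_len(n_subjects))
  recs <- lapply(seq_len(n_subjects), function(i) {
    simulate_subject(schedule, seed = seeds[i], subject_id = ids[i], ...)
  })
  names(recs) <- ids
  recs
}

#' Per-subject seeds used by [simulate_cohort()]
#'
#' Exposed so that streaming pipelines can regenerate individual subjects
#' without materializing the whole cohort.
#'
#' @param seed Master seed.
#' @param n_subjects Cohort size.
#' @return Integer vector of subject seeds.
#' @export
cohort_seeds <- function(seed, n_subjects) derive_seeds(seed, n_subjects)
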