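# Shared fixtures: small schedules and clean (noise/jitter-free) generator
# settings so tests run on second-scale simulations.

tiny_paradigm <- function(...) {
  paradigm_config(n_blocks = 2, trials_per_block = 2, stimuli_per_trial = 5,
                  inter_trial_interval = 500, inter_block_interval = 1000,
                  preparation_period = 2000, relaxation_period = 2000, ...)
}

quiet_noise <- function(eeg_noise_sd = 0, ...) {
  noise_model(eeg_noise_sd = eeg_noise_sd, pupil_drift_sd = 0,
              pupil_noise_sd = 0, blink_rate = 0, ...)
}

# single-component deterministic templates; nontarget amplitude is made
# negligible so target epochs are uncontaminated by neighbouring stimuli
clean_p3a_eeg <- function(target_amp = 5) {
  list(component_template("P3a", 275, 35, target_amp, 1e-9))
}

clean_p3a_pupil <- function(target_amp = 0.1) {
  list(component_template("P3a", 275, 35, target_amp, 1e-12))
}

# full three-component templates with all stochastic terms switched off
clean_templates <- function(modality) {
  lapply(default_templates(modality), function(tp) {
    tp$subject_sd <- 0
    tp$trial_sd <- 0
    tp$latency_jitter_sd <- 0
    tp
  })
}

# no-filter preprocessing at the simulator rate: epoch/baseline/average only
raw_prep_config <- function(rate = 200) {
  preprocess_config(target_rate = rate, band_low = NULL)
}

# synthetic averaged-epoch object with known values, for feature-level tests
fake_avg <- function(target, nontarget = target, time_ms, channels,
                     subject_id = "S01", modality = "ERP") {
  structure(
    list(target = target, nontarget = nontarget, time_ms = time_ms,
         channels = channels,
         n_used = c(target = 1, nontarget = 1),
         subject_id = subject_id, modality = modality),
    class = "avg_epochs"
  )
}

# analytic Gaussian bump evaluated on a time axis (ms)
gauss_bump <- function(time_ms, center, width, amp) {
  amp * exp(-0.5 * ((time_ms - center) / width)^2)
}
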