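#' RSVP paradigm configuration
#'
#' Describes the temporal structure of a rapid serial visual presentation
#' (RSVP) oddball task: blocks of trials, each trial a rapid stream of face
#' photographs among which a single familiar (target) face is hidden. The
#' defaults reproduce the canonical protocol used throughout this package:
#' 10 blocks of 5 trials, 10 stimuli per trial shown for 100 ms each and
#' followed by a 100 ms blank, a 2 s inter-trial interval after every trial,
#' a 5 s interval between blocks, and one target per trial. With these
#' defaults the core task lasts 245 s and comprises 500 stimuli (50 targets).
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials in each block.
#' @param stimuli_per_trial Stimuli flashed in each trial.
#' @param stimulus_duration Photograph on-screen duration, ms.
#' @param blank_duration Blank-screen duration between photographs, ms.
#' @param inter_trial_interval Pause after every trial (including the last of
#'   a block), ms.
#' @param inter_block_interval Pause between consecutive blocks, ms.
#' @param targets_per_trial Number of target stimuli per trial; must be less
#'   than `stimuli_per_trial`.
#' @param preparation_period Rest before the task, ms. The initial fixation
#'   cross is modeled as part of this period.
#' @param relaxation_period Rest after the task, ms.
#' @param seed Default seed used by [build_schedule()] when none is given.
#' @return An object of class `paradigm_config`.
#' @seealso [build_schedule()]
#' @export
#' @examples
#' cfg <- paradigm_config()
#' sched <- build_schedule(cfg)
#' sched$core_duration / 1000  # 245 s
paradigm_config <- function(n_blocks = 10,
                            trials_per_block = 5,
                            stimuli_per_trial = 10,
                            stimulus_duration = 100,
                            blank_duration = 100,
                            inter_trial_interval = 2000,
                            inter_block_interval = 5000,
                            targets_per_trial = 1,
                            preparation_period = 30000,
                            relaxation_period = 30000,
                            seed = 1L) {
  cfg <- list(
    n_blocks = check_count(n_blocks, "n_blocks"),
    trials_per_block = check_count(trials_per_block, "trials_per_block"),
    stimuli_per_trial = check_count(stimuli_per_trial, "stimuli_per_trial"),
    stimulus_duration = check_duration(stimulus_duration, "stimulus_duration"),
    blank_duration = check_duration(blank_duration, "blank_duration"),
    inter_trial_interval = check_duration(inter_trial_interval,
                                          "inter_trial_interval",
                                          allow_zero = TRUE),
    inter_block_interval = check_duration(inter_block_interval,
                                          "inter_block_interval",
                                          allow_zero = TRUE),
    targets_per_trial = check_count(targets_per_trial, "targets_per_trial",
                                    min = 0L),
    preparation_period = check_duration(preparation_period,
                                        "preparation_period",
                                        allow_zero = TRUE),
    relaxation_period = check_duration(relaxation_period, "relaxation_period",
                                       allow_zero = TRUE),
    seed = check_count(seed, "seed")
  )
  if (cfg$targets_per_trial >= cfg$stimuli_per_trial) {
    config_stop("targets_per_trial", "must be less than `stimuli_per_trial`")
  }
  structure(cfg, class = "paradigm_config")
}

#' Duration of one trial in milliseconds
#' @param config A [paradigm_config()].
#' @return Trial length in ms (`stimuli_per_trial * (stimulus + blank)`).
#' @export
trial_duration <- function(config) {
  config$stimuli_per_trial * (config$stimulus_duration + config$blank_duration)
}

#' Duration of one block in milliseconds
#'
#' Every trial, including the last of a block, is followed by one
#' inter-trial interval, so a block of five 2 s trials with 2 s intervals
#' spans 20 s.
#' @param config A [paradigm_config()].
#' @return Block length in ms.
#' @export
block_duration <- function(config) {
  config$trials_per_block * (trial_duration(config) + config$inter_trial_interval)
}

#' Core task duration in milliseconds
#'
#' Excludes the preparation and relaxation periods. Inter-block intervals
#' separate consecutive blocks only.
#' @param config A [paradigm_config()].
#' @return Core duration in ms.
#' @export
core_duration <- function(config) {
  config$n_blocks * block_duration(config) +
    (config$n_blocks - 1) * config$inter_block_interval
}

#' Build an RSVP stimulus schedule
#'
#' Lays out every stimulus onset for the configured task and draws the target
#' position within each trial uniformly from a seeded generator. Onsets are
#' measured from the start of the recording, so the first stimulus appears
#' after the preparation period. Placeholder stimulus identifiers are
#' generated (unique for every nontarget slot); use [assign_stimuli()] to
#' substitute real photograph identifiers.
#'
#' @param config A [paradigm_config()].
#' @param seed Seed for target placement; defaults to `config$seed`.
#' @return An object of class `rsvp_schedule` with elements `config`,
#'   `events` (data frame with columns `onset`, `block`, `trial`, `position`,
#'   `label`, `stimulus_id`; indices are 0-based, onsets in ms),
#'   `core_duration` and `total_duration` (ms).
#' @export
build_schedule <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "paradigm_config"))
  soa <- config$stimulus_duration + config$blank_duration
  n_trials <- config$n_blocks * config$trials_per_block
  n_events <- n_trials * config$stimuli_per_trial

  target_pos <- with_seed(seed, {
    replicate(n_trials,
              sort(sample.int(config$stimuli_per_trial,
                              config$targets_per_trial)),
              simplify = FALSE)
  })

  block <- integer(n_events)
  trial <- integer(n_events)
  position <- integer(n_events)
  onset <- numeric(n_events)
  label <- character(n_events)

  i <- 0L
  for (b in seq_len(config$n_blocks) - 1L) {
    block_start <- config$preparation_period +
      b * (block_duration(config) + config$inter_block_interval)
    for (tr in seq_len(config$trials_per_block) - 1L) {
      trial_start <- block_start +
        tr * (trial_duration(config) + config$inter_trial_interval)
      global_trial <- b * config$trials_per_block + tr
      tpos <- target_pos[[global_trial + 1L]]
      for (p in seq_len(config$stimuli_per_trial) - 1L) {
        i <- i + 1L
        block[i] <- b
        trial[i] <- tr
        position[i] <- p
        onset[i] <- trial_start + p * soa
        label[i] <- if ((p + 1L) %in% tpos) "target" else "nontarget"
      }
    }
  }

  events <- data.frame(
    onset = onset, block = block, trial = trial, position = position,
    label = label, stimulus_id = NA_character_,
    stringsAsFactors = FALSE
  )
  events$stimulus_id <- ifelse(
    events$label == "target",
    sprintf("tgt_%03d", cumsum(events$label == "target")),
    sprintf("nt_%04d", cumsum(events$label == "nontarget"))
  )

  structure(
    list(
      config = config,
      events = events,
      core_duration = core_duration(config),
      total_duration = core_duration(config) + config$preparation_period +
        config$relaxation_period
    ),
    class = "rsvp_schedule"
  )
}

#' @export
print.rsvp_schedule <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "RSVP schedule: %d blocks x %d trials x %d stimuli (%d events, %d targets)\n",
    cfg$n_blocks, cfg$trials_per_block, cfg$stimuli_per_trial,
    nrow(x$events), sum(x$events$label == "target")
  ))
  cat(sprintf("  core duration %.1f s, total %.1f s\n",
              x$core_duration / 1000, x$total_duration / 1000))
  invisible(x)
}

#' Assign photograph identifiers to schedule slots
#'
#' Nontarget slots are filled by seeded sampling *without* replacement so that
#' no stranger face is ever repeated (repeated exposure would familiarize it);
#' the sampled order is a seeded shuffle, i.e. counterbalanced. Target slots
#' are filled by seeded sampling *with* replacement from the familiar-face
#' pool.
#'
#' @param schedule An `rsvp_schedule`.
#' @param target_pool Character vector of familiar-face identifiers
#'   (nonempty).
#' @param nontarget_pool Character vector of stranger-face identifiers; must
#'   be at least as large as the number of nontarget slots.
#' @param seed Seed for the assignment.
#' @return The schedule with `events$stimulus_id` replaced.
#' @export
assign_stimuli <- function(schedule, target_pool, nontarget_pool,
                           seed = schedule$config$seed) {
  stopifnot(inherits(schedule, "rsvp_schedule"))
  if (length(target_pool) < 1L) {
    stop("`target_pool` must contain at least one identifier", call. = FALSE)
  }
  is_tgt <- schedule$events$label == "target"
  n_nt <- sum(!is_tgt)
  if (length(nontarget_pool) < n_nt) {
    stop(sprintf(
      "nontarget pool too small: %d identifiers required but %d available",
      n_nt, length(nontarget_pool)
    ), call. = FALSE)
  }
  ids <- with_seed(seed, {
    nt <- sample(nontarget_pool, n_nt)
    tg <- sample(target_pool, sum(is_tgt), replace = TRUE)
    list(nt = nt, tg = tg)
  })
  schedule$events$stimulus_id[!is_tgt] <- ids$nt
  schedule$events$stimulus_id[is_tgt] <- ids$tg
  schedule
}

#' Convert a schedule to an event table
#'
#' @param schedule An `rsvp_schedule`.
#' @return Data frame with one row per stimulus and columns `onset_ms`,
#'   `block`, `trial`, `position`, `label`, `stimulus_id` (0-based indices,
#'   integer milliseconds).
#' @export
events_to_table <- function(schedule) {
  stopifnot(inherits(schedule, "rsvp_schedule"))
  ev <- schedule$events
  data.frame(
    onset_ms = as.integer(round(ev$onset)),
    block = ev$block,
    trial = ev$trial,
    position = ev$position,
    label = ev$label,
    stimulus_id = ev$stimulus_id,
    stringsAsFactors = FALSE
  )
}

#' Write / read an event table
#'
#' Tab-separated text with one header row; onsets in integer milliseconds,
#' block/trial/position 0-based. `read_events` round-trips the output of
#' `write_events` losslessly.
#'
#' @param events Event table as returned by [events_to_table()].
#' @param path File path.
#' @return `read_events` returns the event table data frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "integer", "integer",
                                         "integer", "character", "character"))
  required <- c("onset_ms", "block", "trial", "position", "label",
                "stimulus_id")
  if (!identical(names(ev), required)) {
    stop("event table must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  ev
}

# Global 0-based trial index (order in time) for each event row.
global_trial_index <- function(events, trials_per_block) {
  events$block * trials_per_block + events$trial
}
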