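#' Write / read a signal stream
#'
#' Tab-separated text with a comment header line `# rate_hz=<float>` followed
#' by a column header (`sample_index`, then one column per channel) and one
#' row per sample. Invalid (blink) samples are stored as `NA`. Reading the
#' written file reproduces values and rate to full precision.
#'
#' @param values Numeric matrix (samples x channels) or vector.
#' @param rate Sampling rate, Hz.
#' @param path File path.
#' @param channels Channel names (defaults to matrix column names).
#' @return `read_recording` returns a list with `values` (matrix), `rate`,
#'   `channels`.
#' @export
write_recording <- function(values, rate, path, channels = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  if (is.null(channels)) {
    channels <- colnames(values)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  }
  writeLines(sprintf("# rate_hz=%.17g", rate), path)
  df <- data.frame(sample_index = seq_len(nrow(values)) - 1L, values)
  names(df) <- c("sample_index", channels)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# rate_hz=", header)) {
    stop(sprintf("'%s': missing '# rate_hz=' header line", path),
         call. = FALSE)
  }
  rate <- suppressWarnings(as.numeric(sub("^# rate_hz=", "", header)))
  if (!is.finite(rate) || rate <= 0) {
    stop(sprintf("'%s': invalid sampling rate in header", path),
         call. = FALSE)
  }
  df <- as.data.frame(data.table::fread(path, sep = "\t", skip = 1L,
                                        header = TRUE))
  if (!identical(names(df)[1], "sample_index")) {
    stop(sprintf("'%s': first column must be 'sample_index'", path),
         call. = FALSE)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  list(values = values, rate = rate, channels = colnames(values))
}

#' Save / load a subject recording as plain-text files
#'
#' Writes `<id>_eeg.tsv`, `<id>_pupil.tsv`, `<id>_events.tsv` and
#' `<id>_truth.json` into a directory.
#'
#' @param recording A `subject_recording`.
#' @param dir Output directory (created if missing).
#' @return `read_subject_recording` returns a `subject_recording`.
#' @export
write_subject_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- recording$subject_id
  write_recording(recording$eeg$values, recording$eeg$rate,
                  file.path(dir, paste0(id, "_eeg.tsv")))
  write_recording(recording$pupil$values, recording$pupil$rate,
                  file.path(dir, paste0(id, "_pupil.tsv")),
                  channels = "pupil")
  write_events(recording$events, file.path(dir, paste0(id, "_events.tsv")))
  jsonlite::write_json(recording$ground_truth,
                       file.path(dir, paste0(id, "_truth.json")),
                       digits = NA)
  invisible(dir)
}

#' @rdname write_subject_recording
#' @param subject_id Subject identifier (file-name prefix).
#' @export
read_subject_recording <- function(dir, subject_id) {
  eeg <- read_recording(file.path(dir, paste0(subject_id, "_eeg.tsv")))
  pup <- read_recording(file.path(dir, paste0(subject_id, "_pupil.tsv")))
  events <- read_events(file.path(dir, paste0(subject_id, "_events.tsv")))
  truth_path <- file.path(dir, paste0(subject_id, "_truth.json"))
  truth <- if (file.exists(truth_path)) {
    jsonlite::fromJSON(truth_path)
  } else NULL
  structure(
    list(subject_id = subject_id,
         eeg = list(values = eeg$values, rate = eeg$rate,
                    channels = eeg$channels),
         pupil = list(values = as.numeric(pup$values[, 1]),
                      rate = pup$rate),
         events = events, ground_truth = truth),
    class = "subject_recording"
  )
}

#' Load / save a run configuration
#'
#' YAML round-trip of the paradigm and preprocessing settings plus cohort
#' parameters.
#'
#' @param config List with elements `paradigm` (arguments for
#'   [paradigm_config()]), `preprocess` (arguments for
#'   [preprocess_config()]), `n_subjects`, `classifiers`, `seed`.
#' @param path File path.
#' @return `read_run_config` returns the list with `paradigm` and
#'   `preprocess` instantiated.
#' @export
write_run_config <- function(config, path) {
  plain <- config
  plain$paradigm <- unclass(plain$paradigm)
  plain$preprocess <- unclass(plain$preprocess)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- raw
  out$paradigm <- do.call(paradigm_config, as.list(raw$paradigm %||% list()))
  pp <- as.list(raw$preprocess %||% list())
  if (!is.null(pp$baseline_window)) {
    pp$baseline_window <- as.numeric(unlist(pp$baseline_window))
  }
  out$preprocess <- do.call(preprocess_config, pp)
  out$n_subjects <- raw$n_subjects %||% 30
  out$seed <- raw$seed %||% 1L
  out$classifiers <- raw$classifiers %||% supported_classifiers
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulated cohort pipeline end to end
#'
#' Simulate -> preprocess -> features -> stats -> evaluate, streaming subject
#' by subject so that raw cohort recordings never need to be held in memory
#' at once. Returns everything downstream analyses need; when `out_dir` is
#' given, also writes feature tables, the statistics report, the classifier
#' table and a manifest JSON.
#'
#' @param n_subjects Cohort size (default 30).
#' @param schedule_config A [paradigm_config()].
#' @param preprocess_cfg A [preprocess_config()].
#' @param eeg_templates,pupil_templates Component templates.
#' @param noise A [noise_model()].
#' @param seed Master seed; subject seeds are derived from it.
#' @param classifiers Classifier names to evaluate (quadratic discriminant
#'   analysis needs more training samples per class than features, so small
#'   cohorts should restrict this set).
#' @param keep_epochs Keep per-subject epoch sets (enables [trial_sweep()]).
#' @param out_dir Optional output directory.
#' @param eeg_rate,pupil_rate Simulator sampling rates, Hz.
#' @return An object of class `pipeline_result`: `erp_features`,
#'   `erpr_features` (amplitude tables), `erp_features_full`,
#'   `erpr_features_full` (with latency), `stats` (condition tests per
#'   modality), `agreement`, `classification` (per-modality classifier
#'   tables), `subject_preps` (when `keep_epochs`), `ground_truth`,
#'   `manifest`.
#' @export
run_pipeline <- function(n_subjects = 30,
                         schedule_config = paradigm_config(),
                         preprocess_cfg = preprocess_config(),
                         eeg_templates = default_templates("eeg"),
                         pupil_templates = default_templates("pupil"),
                         noise = noise_model(),
                         seed = 1L,
                         classifiers = supported_classifiers,
                         keep_epochs = FALSE,
                         out_dir = NULL,
                         eeg_rate = 2048,
                         pupil_rate = 200) {
  schedule <- build_schedule(schedule_config)
  seeds <- cohort_seeds(seed, n_subjects)
  ids <- sprintf("S%02d", seq_len(n_subjects))

  erp_avgs <- list()
  erpr_avgs <- list()
  preps <- if (keep_epochs) vector("list", n_subjects) else NULL
  truths <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    rec <- simulate_subject(schedule, eeg_templates, pupil_templates, noise,
                            seed = seeds[i], subject_id = ids[i],
                            eeg_rate = eeg_rate, pupil_rate = pupil_rate)
    prep <- preprocess_subject(rec, preprocess_cfg,
                               keep_epochs = keep_epochs)
    erp_avgs[[i]] <- prep$erp
    erpr_avgs[[i]] <- prep$erpr
    truths[[i]] <- cbind(subject = ids[i], rec$ground_truth)
    if (keep_epochs) preps[[i]] <- prep
  }

  windows <- feature_windows()
  erp_features <- build_feature_table(erp_avgs, windows)
  erpr_features <- build_feature_table(erpr_avgs, windows)
  erp_full <- build_feature_table(erp_avgs, windows, include_latency = TRUE)
  erpr_full <- build_feature_table(erpr_avgs, windows, include_latency = TRUE)

  # family size for the threshold: amplitude + latency contrasts over both
  # modalities (24 ERP + 6 ErPR hypotheses)
  n_family <- 2 * (ncol(erp_features) - 2) + 2 * (ncol(erpr_features) - 2)
  stats_erp <- condition_tests(erp_full, n_tests = n_family)
  stats_erpr <- condition_tests(erpr_full, n_tests = n_family)
  agreement <- agreement_analysis(erp_features, erpr_features)

  classification <- list(
    erp = evaluate_all_classifiers(erp_features, seed = seed,
                                   classifiers = classifiers),
    erpr = evaluate_all_classifiers(erpr_features, seed = seed,
                                    classifiers = classifiers)
  )

  manifest <- list(
    n_subjects = n_subjects,
    n_feature_rows = nrow(erp_features),
    n_erp_features = ncol(erp_features) - 2L,
    n_erpr_features = ncol(erpr_features) - 2L,
    bonferroni_threshold = bonferroni_alpha(0.05, n_family),
    seed = seed,
    subject_seeds = seeds,
    eeg_rate = eeg_rate,
    pupil_rate = pupil_rate
  )

  result <- structure(
    list(erp_features = erp_features, erpr_features = erpr_features,
         erp_features_full = erp_full, erpr_features_full = erpr_full,
         stats = list(erp = stats_erp, erpr = stats_erpr),
         agreement = agreement, classification = classification,
         subject_preps = preps,
         ground_truth = do.call(rbind, truths),
         manifest = manifest),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(erp_features, file.path(out_dir, "erp_features.tsv"))
    write_feature_table(erpr_features,
                        file.path(out_dir, "erpr_features.tsv"))
    utils::write.table(rbind(cbind(modality = "ERP", stats_erp),
                             cbind(modality = "ErPR", stats_erpr)),
                       file.path(out_dir, "stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(rbind(cbind(modality = "ERP", classification$erp),
                             cbind(modality = "ErPR", classification$erpr)),
                       file.path(out_dir, "classification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "pipeline_result: %d subjects, %d feature rows (%d ERP / %d ErPR amplitude features)\n",
    m$n_subjects, m$n_feature_rows, m$n_erp_features, m$n_erpr_features
  ))
  cat("ERP classifiers:\n")
  print(x$classification$erp, row.names = FALSE)
  cat("ErPR classifiers:\n")
  print(x$classification$erpr, row.names = FALSE)
  invisible(x)
}
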