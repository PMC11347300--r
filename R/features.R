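#' Canonical feature windows
#'
#' The three successive positive components are operationalized as fixed
#' post-stimulus windows: P3a 200-350 ms, P3b 400-490 ms, LPP 530-750 ms.
#'
#' @return Data frame with columns `name`, `start`, `end` (ms).
#' @export
feature_windows <- function() {
  data.frame(
    name = c("P3a", "P3b", "LPP"),
    start = c(200, 400, 530),
    end = c(350, 490, 750),
    stringsAsFactors = FALSE
  )
}

window_samples <- function(avg, window) {
  sel <- avg$time_ms >= window$start & avg$time_ms <= window$end
  if (sum(sel) < 2) {
    stop(sprintf("window %s [%g, %g] ms has fewer than 2 samples in the epoch",
                 window$name, window$start, window$end), call. = FALSE)
  }
  sel
}

#' Peak-to-peak amplitude within a feature window
#'
#' The amplitude feature is the difference between the highest and lowest
#' points of the averaged epoch inside the window: `max - min`, always
#' nonnegative.
#'
#' @param avg An `avg_epochs` object.
#' @param channel Channel name.
#' @param window One row of [feature_windows()] (or a list with `name`,
#'   `start`, `end`).
#' @param condition `"target"` or `"nontarget"`.
#' @return Amplitude in signal units.
#' @export
window_amplitude <- function(avg, channel, window,
                             condition = c("target", "nontarget")) {
  condition <- match.arg(condition)
  sel <- window_samples(avg, window)
  v <- avg[[condition]][sel, channel]
  max(v) - min(v)
}

#' Peak latency within a feature window
#'
#' The latency feature is the time of the highest point of the averaged epoch
#' inside the window (ms post-stimulus). Ties are broken by the earliest
#' sample.
#'
#' @inheritParams window_amplitude
#' @return Latency in ms, within `[window$start, window$end]`.
#' @export
window_latency <- function(avg, channel, window,
                           condition = c("target", "nontarget")) {
  condition <- match.arg(condition)
  sel <- window_samples(avg, window)
  t <- avg$time_ms[sel]
  v <- avg[[condition]][sel, channel]
  t[which.max(v)]
}

#' Build a subject-by-feature table from averaged epochs
#'
#' One row per (subject, condition). Columns are ordered channel-major,
#' window-minor: `Fz_P3a_amp, Fz_P3b_amp, Fz_LPP_amp, Cz_P3a_amp, ...`, with
#' `_lat` columns appended in the same order when `include_latency = TRUE`.
#' An amplitude-only ERP table over the four EEG channels has 12 feature
#' columns; an ErPR table (single `pupil` channel) has 3.
#'
#' @param avg_list List of `avg_epochs`, one per subject.
#' @param windows Window definition data frame (default [feature_windows()]).
#' @param channels Channels to extract; defaults to the channels present.
#' @param include_latency Append latency features.
#' @return Data frame with columns `subject`, `condition`, then features.
#' @export
build_feature_table <- function(avg_list, windows = feature_windows(),
                                channels = NULL, include_latency = FALSE) {
  if (!length(avg_list)) stop("`avg_list` is empty", call. = FALSE)
  if (is.null(channels)) channels <- avg_list[[1]]$channels
  missing_cond <- vapply(avg_list, function(a) {
    is.null(a$target) || is.null(a$nontarget)
  }, logical(1))
  if (any(missing_cond)) {
    stop("missing averaged condition for subject(s): ",
         paste(vapply(avg_list[missing_cond], `[[`, "", "subject_id"),
               collapse = ", "), call. = FALSE)
  }
  feat_names <- as.vector(t(outer(channels, windows$name, paste, sep = "_")))
  cols_amp <- paste0(feat_names, "_amp")
  cols <- cols_amp
  if (include_latency) cols <- c(cols, paste0(feat_names, "_lat"))

  rows <- list()
  for (a in avg_list) {
    for (cond in c("target", "nontarget")) {
      vals <- numeric(0)
      for (ch in channels) {
        for (wi in seq_len(nrow(windows))) {
          vals <- c(vals, window_amplitude(a, ch, windows[wi, ], cond))
        }
      }
      if (include_latency) {
        for (ch in channels) {
          for (wi in seq_len(nrow(windows))) {
            vals <- c(vals, window_latency(a, ch, windows[wi, ], cond))
          }
        }
      }
      row <- as.data.frame(as.list(vals))
      names(row) <- cols
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject = a$subject_id, condition = cond,
                   stringsAsFactors = FALSE),
        row
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature matrix and labels from a feature table
#'
#' @param features Output of [build_feature_table()].
#' @return List with `x` (numeric matrix) and `y` (factor with levels
#'   `nontarget`, `target`).
#' @export
feature_matrix <- function(features) {
  x <- as.matrix(features[, setdiff(names(features),
                                    c("subject", "condition")), drop = FALSE])
  y <- factor(features$condition, levels = c("nontarget", "target"))
  list(x = x, y = y)
}

#' Write / read a feature table
#'
#' Tab-separated with a header row; numeric columns at full precision.
#'
#' @param features Feature table.
#' @param path File path.
#' @return `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(features, path) {
  data.table::fwrite(features, path, sep = "\t")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
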