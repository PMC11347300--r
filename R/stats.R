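#' Paired-samples t-test with Cohen's d
#'
#' Two-sided paired t statistic on aligned per-subject values, with the
#' paired-design effect size `d = mean(diff) / sd(diff)` (0.20 / 0.50 / 0.80
#' conventionally read as small / medium / large). When all differences are
#' exactly zero the statistic is degenerate and reported as `t = 0`, `d = 0`,
#' `p = 1` with `degenerate = TRUE`; a nonzero constant difference (zero
#' variance, nonzero mean) is an error because the statistic is undefined.
#'
#' @param x,y Numeric vectors of equal length (>= 3), aligned by subject.
#' @return An object of class `paired_test`: `t`, `df`, `p`, `cohens_d`,
#'   `mean_diff`, `sd_diff`, `n_pairs`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) {
      return(structure(
        list(t = 0, df = n - 1L, p = 1, cohens_d = 0, mean_diff = 0,
             sd_diff = 0, n_pairs = n, degenerate = TRUE),
        class = "paired_test"
      ))
    }
    stop("differences have zero variance with nonzero mean; statistic undefined",
         call. = FALSE)
  }
  tval <- m / (s / sqrt(n))
  structure(
    list(t = tval, df = n - 1L, p = 2 * stats::pt(-abs(tval), n - 1),
         cohens_d = m / s, mean_diff = m, sd_diff = s, n_pairs = n,
         degenerate = FALSE),
    class = "paired_test"
  )
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g, Cohen's d = %.3f (n = %d)\n",
              x$df, x$t, x$p, x$cohens_d, x$n_pairs))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' Family-wise error control by threshold division: `alpha / n_tests`.
#' With the default family of 30 hypotheses (24 ERP and 6 ErPR amplitude and
#' latency comparisons) at alpha 0.05 the threshold is 0.0017 (4 dp).
#'
#' @param family_alpha Family-wise alpha.
#' @param n_tests Number of individual hypotheses (>= 1).
#' @return Adjusted per-test threshold.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_tests = 30) {
  n_tests <- check_count(n_tests, "n_tests")
  family_alpha / n_tests
}

#' Shapiro-Wilk normality diagnostic
#'
#' Pass-through gate reported alongside paired comparisons; `p > 0.05` is
#' read as "no evidence against normality of the paired differences".
#'
#' @param x Numeric vector (3 to 5000 values).
#' @return List with `W` and `p`.
#' @export
normality_check <- function(x) {
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] returning the quantities the
#' agreement analysis consumes.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Computes the mean difference, the 95% limits of agreement
#' `mean_diff +/- 1.96 * sd_diff`, and the proportion of pairs whose
#' difference lies within the limits. The qualitative category follows the
#' proportion: `good` when at least `good_cutoff` (default all) pairs lie
#' within the limits, `fairly good` when at least `fair_cutoff` (default
#' 0.95) do, otherwise `poor`. Inputs measured on different scales (e.g. ERP
#' microvolts vs ErPR millimetre differences) should be z-scored by the
#' caller first; see [agreement_analysis()].
#'
#' @param x,y Numeric vectors of equal length (>= 3), on comparable scales.
#' @param good_cutoff,fair_cutoff Category cutoffs on the within-limits
#'   proportion.
#' @return An object of class `agreement_report`: `mean_diff`, `sd_diff`,
#'   `upper_limit`, `lower_limit`, `proportion_within`, `category`, `n`.
#' @export
bland_altman <- function(x, y, good_cutoff = 1.0, fair_cutoff = 0.95) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  upper <- m + 1.96 * s
  lower <- m - 1.96 * s
  prop <- mean(d >= lower & d <= upper)
  category <- if (prop >= good_cutoff) "good"
  else if (prop >= fair_cutoff) "fairly good"
  else "poor"
  structure(
    list(mean_diff = m, sd_diff = s, upper_limit = upper,
         lower_limit = lower, proportion_within = prop,
         category = category, n = length(x)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: mean diff %.4g, limits [%.4g, %.4g], %.1f%% within (%s, n = %d)\n",
    x$mean_diff, x$lower_limit, x$upper_limit, 100 * x$proportion_within,
    x$category, x$n
  ))
  invisible(x)
}

#' Condition contrasts for every feature column
#'
#' Runs a paired t-test (target vs nontarget, paired by subject) for each
#' feature column of a table built by [build_feature_table()] and flags
#' significance at the Bonferroni-adjusted threshold.
#'
#' @param features Feature table with `subject` and `condition` columns.
#' @param alpha Family-wise alpha.
#' @param n_tests Size of the hypothesis family used for the threshold;
#'   defaults to the number of feature columns.
#' @return Data frame with one row per feature: `feature`, `t`, `df`, `p`,
#'   `cohens_d`, `shapiro_p`, `significant`.
#' @export
condition_tests <- function(features, alpha = 0.05, n_tests = NULL) {
  feat_cols <- setdiff(names(features), c("subject", "condition"))
  if (is.null(n_tests)) n_tests <- length(feat_cols)
  thr <- bonferroni_alpha(alpha, n_tests)
  tg <- features[features$condition == "target", ]
  nt <- features[features$condition == "nontarget", ]
  tg <- tg[order(tg$subject), ]
  nt <- nt[order(nt$subject), ]
  stopifnot(identical(tg$subject, nt$subject))
  out <- lapply(feat_cols, function(fc) {
    pt <- paired_t(tg[[fc]], nt[[fc]])
    data.frame(feature = fc, t = pt$t, df = pt$df, p = pt$p,
               cohens_d = pt$cohens_d,
               shapiro_p = normality_check(tg[[fc]] - nt[[fc]])$p,
               significant = pt$p < thr,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "bonferroni_threshold") <- thr
  res
}

#' ERP vs ErPR agreement across subjects
#'
#' For every EEG channel and component window, correlates the ERP feature
#' with the matching ErPR feature over all (subject, condition) rows, and
#' runs a Bland-Altman analysis on the z-scored values pooled over the three
#' windows per channel (z-scoring makes the microvolt and millimetre scales
#' comparable; with 60 rows and 3 windows each pooled analysis has n = 180).
#'
#' @param erp_features,erpr_features Amplitude (or latency) feature tables
#'   for the two modalities, aligned row-for-row.
#' @param measure `"amp"` or `"lat"` — which feature suffix to compare.
#' @return List with `correlations` (data frame: channel, window, r, p, n)
#'   and `agreement` (list of `agreement_report` per channel, z-scored,
#'   windows pooled).
#' @export
agreement_analysis <- function(erp_features, erpr_features, measure = "amp") {
  key <- paste(erp_features$subject, erp_features$condition)
  stopifnot(identical(key, paste(erpr_features$subject,
                                 erpr_features$condition)))
  windows <- feature_windows()$name
  erp_cols <- grep(paste0("_", measure, "$"), names(erp_features),
                   value = TRUE)
  channels <- unique(sub("_(P3a|P3b|LPP)_.*$", "", erp_cols))
  cors <- list()
  agreement <- list()
  for (ch in channels) {
    zx <- c(); zy <- c()
    for (w in windows) {
      x <- erp_features[[paste(ch, w, measure, sep = "_")]]
      y <- erpr_features[[paste("pupil", w, measure, sep = "_")]]
      pc <- pearson_cor(x, y)
      cors[[length(cors) + 1L]] <- data.frame(
        channel = ch, window = w, r = pc$r, p = pc$p, n = pc$n,
        stringsAsFactors = FALSE
      )
      zx <- c(zx, as.numeric(scale(x)))
      zy <- c(zy, as.numeric(scale(y)))
    }
    agreement[[ch]] <- bland_altman(zx, zy)
  }
  list(correlations = do.call(rbind, cors), agreement = agreement)
}

#' Permutation test for classifier significance
#'
#' Repeats the cross-validated evaluation with permuted condition labels and
#' reports `p = (1 + #{permuted accuracy >= observed}) / (1 + n_permutations)`.
#' Labels are permuted before fold construction so the whole CV protocol runs
#' on each permutation.
#'
#' @param features Feature table ([build_feature_table()]).
#' @param classifier One of `"LSVM"`, `"QDA"`, `"NB"`, `"LR"`, `"RBF-SVM"`.
#' @param n_permutations Number of permutations (>= 100; 10000 for
#'   publication-scale runs).
#' @param k Folds.
#' @param seed Seed controlling both the CV folds and the permutations.
#' @return List with `p`, `observed_accuracy`, `n_permutations`.
#' @export
permutation_test <- function(features, classifier, n_permutations = 1000,
                             k = 5, seed = 1L) {
  if (n_permutations < 100) {
    stop("`n_permutations` must be >= 100", call. = FALSE)
  }
  fm <- feature_matrix(features)
  if (length(unique(fm$y)) < 2) {
    stop("labels contain a single class; permutation test undefined",
         call. = FALSE)
  }
  obs <- crossval_evaluate(features, classifier, k = k, seed = seed)$accuracy
  perm_seeds <- derive_seeds(seed, n_permutations)
  count <- 0L
  for (i in seq_len(n_permutations)) {
    pf <- features
    pf$condition <- with_seed(perm_seeds[i], sample(features$condition))
    acc <- crossval_evaluate(pf, classifier, k = k, seed = seed)$accuracy
    if (acc >= obs) count <- count + 1L
  }
  list(p = (1 + count) / (1 + n_permutations), observed_accuracy = obs,
       n_permutations = n_permutations)
}
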