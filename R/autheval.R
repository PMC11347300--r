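#' Authentication metrics from confusion counts
#'
#' Positive class = target (the familiar, enrolled face). Accuracy is
#' `100 * (TP + TN) / (TP + FN + TN + FP)` on the 0-100 scale. The false
#' acceptance rate is the fraction of impostor (nontarget) samples accepted,
#' `FAR = FP / (FP + TN)`; the false rejection rate is the fraction of
#' genuine (target) samples rejected, `FRR = FN / (FN + TP)`.
#'
#' @param tp,fn,tn,fp Nonnegative confusion counts.
#' @return List with `accuracy` (percent), `far`, `frr`.
#' @export
metrics_from_counts <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("confusion counts must be nonnegative",
                            call. = FALSE)
  if (fp + tn == 0) {
    stop("no nontarget samples (FP + TN = 0); FAR undefined", call. = FALSE)
  }
  if (fn + tp == 0) {
    stop("no target samples (FN + TP = 0); FRR undefined", call. = FALSE)
  }
  list(
    accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
    far = fp / (fp + tn),
    frr = fn / (fn + tp)
  )
}

supported_classifiers <- c("LSVM", "QDA", "NB", "LR", "RBF-SVM")

# Stratified k-fold assignment: within each class, shuffle then deal out
# fold ids cyclically. Returns an integer vector of fold ids.
make_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < k) {
        stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                     cl, length(idx), k), call. = FALSE)
      }
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# z-score columns using training-fold statistics only (no leakage);
# zero-variance columns are left centred but unscaled.
scale_train_test <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sdev <- apply(xtr, 2, stats::sd)
  sdev[sdev == 0] <- 1
  list(
    train = sweep(sweep(xtr, 2, mu), 2, sdev, "/"),
    test = sweep(sweep(xte, 2, mu), 2, sdev, "/")
  )
}

# Fit one classifier and predict classes plus a score oriented so that
# larger values favour the target class.
fit_predict <- function(classifier, xtr, ytr, xte) {
  ytr <- droplevels(ytr)
  dtr <- data.frame(xtr)
  dte <- data.frame(xte)
  colnames(dte) <- colnames(dtr)
  if (classifier %in% c("LSVM", "RBF-SVM")) {
    kern <- if (classifier == "LSVM") "linear" else "radial"
    fit <- e1071::svm(xtr, ytr, kernel = kern, scale = FALSE)
    pr <- stats::predict(fit, xte, decision.values = TRUE)
    score <- as.numeric(attr(pr, "decision.values"))
    # orient the decision axis by the training-set class means
    tr_dv <- as.numeric(attr(
      stats::predict(fit, xtr, decision.values = TRUE), "decision.values"))
    if (mean(tr_dv[ytr == "target"]) < mean(tr_dv[ytr == "nontarget"])) {
      score <- -score
    }
    list(class = as.character(pr), score = score)
  } else if (classifier == "QDA") {
    fit <- MASS::qda(xtr, grouping = ytr)
    pr <- stats::predict(fit, xte)
    list(class = as.character(pr$class),
         score = pr$posterior[, "target"])
  } else if (classifier == "NB") {
    fit <- e1071::naiveBayes(dtr, ytr)
    post <- stats::predict(fit, dte, type = "raw")
    cls <- colnames(post)[max.col(post, ties.method = "first")]
    list(class = cls, score = post[, "target"])
  } else if (classifier == "LR") {
    df <- dtr
    df$.y <- as.integer(ytr == "target")
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial())
    )
    p <- suppressWarnings(
      as.numeric(stats::predict(fit, dte, type = "response")))
    list(class = ifelse(p >= 0.5, "target", "nontarget"), score = p)
  } else {
    stop(sprintf("unknown classifier '%s'; supported: %s", classifier,
                 paste(supported_classifiers, collapse = ", ")),
         call. = FALSE)
  }
}

#' Cross-validated authentication evaluation
#'
#' Stratified k-fold cross-validation of one classifier on a
#' (subject, condition) feature table. Feature columns are z-scored inside
#' each training fold only. The headline accuracy is the mean of the fold
#' accuracies; FAR and FRR are computed from the confusion counts pooled
#' over folds, and AUC from the pooled decision scores.
#'
#' @param features Feature table from [build_feature_table()], or a numeric
#'   matrix if `labels` is given.
#' @param classifier One of `"LSVM"` (linear SVM), `"QDA"` (quadratic
#'   discriminant analysis), `"NB"` (naive Bayes), `"LR"` (logistic
#'   regression), `"RBF-SVM"` (radial-kernel SVM).
#' @param labels Optional factor/character labels overriding the table's
#'   `condition` column.
#' @param k Number of folds (default 5).
#' @param seed Seed for fold construction.
#' @return An object of class `classification_report`: `classifier`,
#'   `accuracy` (fold-mean, percent), `pooled_accuracy`, `auc`, `far`,
#'   `frr`, `counts` (pooled TP/FN/TN/FP), `per_fold` (list of fold
#'   counts), `fold_accuracies`, `n_folds`, `seed`.
#' @export
crossval_evaluate <- function(features, classifier, labels = NULL, k = 5,
                              seed = 1L) {
  classifier <- match.arg(classifier, supported_classifiers)
  if (is.data.frame(features)) {
    fm <- feature_matrix(features)
    x <- fm$x
    y <- if (is.null(labels)) fm$y else
      factor(labels, levels = c("nontarget", "target"))
  } else {
    x <- as.matrix(features)
    if (is.null(labels)) stop("`labels` required with a matrix input",
                              call. = FALSE)
    y <- factor(labels, levels = c("nontarget", "target"))
  }
  fold <- make_folds(y, k, seed)
  per_fold <- vector("list", k)
  fold_acc <- numeric(k)
  scores <- numeric(length(y))
  pred <- character(length(y))
  for (f in seq_len(k)) {
    te <- fold == f
    sc <- scale_train_test(x[!te, , drop = FALSE], x[te, , drop = FALSE])
    fp <- fit_predict(classifier, sc$train, y[!te], sc$test)
    pred[te] <- fp$class
    scores[te] <- fp$score
    cm <- c(
      tp = sum(fp$class == "target" & y[te] == "target"),
      fn = sum(fp$class == "nontarget" & y[te] == "target"),
      tn = sum(fp$class == "nontarget" & y[te] == "nontarget"),
      fp = sum(fp$class == "target" & y[te] == "nontarget")
    )
    per_fold[[f]] <- as.list(cm)
    fold_acc[f] <- 100 * (cm["tp"] + cm["tn"]) / sum(cm)
  }
  pooled <- Reduce(function(a, b) Map(`+`, a, b), per_fold)
  m <- metrics_from_counts(pooled$tp, pooled$fn, pooled$tn, pooled$fp)
  auc <- as.numeric(pROC::auc(
    pROC::roc(response = y, predictor = scores,
              levels = c("nontarget", "target"), direction = "<",
              quiet = TRUE)
  ))
  structure(
    list(classifier = classifier, accuracy = mean(fold_acc),
         pooled_accuracy = m$accuracy, auc = auc, far = m$far, frr = m$frr,
         counts = pooled, per_fold = per_fold, fold_accuracies = fold_acc,
         n_folds = k, seed = seed),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "%s (%d-fold CV): accuracy %.1f%%, AUC %.3f, FAR %.3f, FRR %.3f\n",
    x$classifier, x$n_folds, x$accuracy, x$auc, x$far, x$frr
  ))
  invisible(x)
}

#' Evaluate a set of classifiers on one feature table
#'
#' @inheritParams crossval_evaluate
#' @param classifiers Classifier names to evaluate (default: all five
#'   supported models).
#' @return Data frame with one row per classifier: accuracy (fold-mean, %),
#'   AUC, FAR, FRR.
#' @export
evaluate_all_classifiers <- function(features, k = 5, seed = 1L,
                                     classifiers = supported_classifiers) {
  rows <- lapply(classifiers, function(cl) {
    r <- crossval_evaluate(features, cl, k = k, seed = seed)
    data.frame(classifier = cl, accuracy = r$accuracy, auc = r$auc,
               far = r$far, frr = r$frr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Authentication accuracy as a function of trial count
#'
#' Re-averages each subject's epochs using only the first `n` trials (each
#' trial contributes 1 target and 9 nontarget epochs with the default
#' paradigm, so the 1:9 class ratio is held), rebuilds the feature table and
#' re-runs the cross-validated evaluation for each requested trial count.
#'
#' @param subject_preps List of [preprocess_subject()] results obtained with
#'   `keep_epochs = TRUE`.
#' @param n_trials_list Trial counts to evaluate (each must not exceed the
#'   total trial count; violations are skipped with a warning).
#' @param classifier Classifier name.
#' @param modality `"erpr"` or `"erp"` — which epoch sets to sweep.
#' @param windows Feature window definitions.
#' @param k,seed Cross-validation parameters.
#' @return Data frame with one row per trial count: `n_trials`, `accuracy`,
#'   `auc`, `far`, `frr`; the full `classification_report`s are attached as
#'   attribute `"reports"`.
#' @export
trial_sweep <- function(subject_preps, n_trials_list, classifier = "QDA",
                        modality = c("erpr", "erp"),
                        windows = feature_windows(), k = 5, seed = 1L) {
  modality <- match.arg(modality)
  ep_field <- paste0(modality, "_epochs")
  if (is.null(subject_preps[[1]][[ep_field]])) {
    stop("subject preparations lack stored epochs; rerun preprocess_subject()",
         " with keep_epochs = TRUE", call. = FALSE)
  }
  tpb <- NULL
  rows <- list()
  reports <- list()
  for (n in sort(n_trials_list)) {
    avg_list <- list()
    ok <- TRUE
    for (sp in subject_preps) {
      ep <- sp[[ep_field]]
      tpb <- max(ep$events$trial) + 1L
      gtrial <- global_trial_index(ep$events, tpb)
      sel <- gtrial < n
      if (!any(ep$labels[sel] == "target") ||
          max(gtrial) + 1L < n) {
        ok <- FALSE
        break
      }
      avg_list[[length(avg_list) + 1L]] <- average_epochs(ep, sel)
    }
    if (!ok) {
      warning(sprintf("trial count %d not representable; skipped", n),
              call. = FALSE)
      next
    }
    feats <- build_feature_table(avg_list, windows)
    rep <- crossval_evaluate(feats, classifier, k = k, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      n_trials = n, accuracy = rep$accuracy, auc = rep$auc,
      far = rep$far, frr = rep$frr
    )
    reports[[as.character(n)]] <- rep
  }
  if (!length(rows)) {
    out <- data.frame(n_trials = integer(0), accuracy = numeric(0),
                      auc = numeric(0), far = numeric(0), frr = numeric(0))
  } else {
    out <- do.call(rbind, rows)
  }
  attr(out, "reports") <- reports
  out
}
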