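#' Confusion-matrix metrics
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, specificity `TN/(FP+TN)`. A zero denominator yields `NA`
#' (undefined) with a warning, never 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return One-row data.frame with columns tp, tn, fp, fn, accuracy,
#'   sensitivity, precision, specificity.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  safe <- function(num, den, what) {
    if (den == 0) {
      warnf("%s undefined: zero denominator", what)
      return(NA_real_)
    }
    num / den
  }
  data.frame(tp = tp, tn = tn, fp = fp, fn = fn,
             accuracy = safe(tp + tn, tp + tn + fp + fn, "accuracy"),
             sensitivity = safe(tp, tp + fn, "sensitivity"),
             precision = safe(tp, tp + fp, "precision"),
             specificity = safe(tn, fp + tn, "specificity"))
}

confusion_counts <- function(pred, truth) {
  confusion_metrics(tp = sum(pred == 1 & truth == 1),
                    tn = sum(pred == 0 & truth == 0),
                    fp = sum(pred == 1 & truth == 0),
                    fn = sum(pred == 0 & truth == 1))
}

#' Repeated stratified k-fold cross-validation plan
#'
#' Within each repeat the samples are partitioned into k stratified folds:
#' fold sizes differ by at most one and each fold's class ratio is within one
#' sample of the global ratio. Repeats differ by derived seeds.
#'
#' @param labels Binary labels.
#' @param k Folds (default 5); every class must have at least k samples.
#' @param repeats Independent repetitions (default 5).
#' @param seed Base seed; repeat `r` uses `seed + r - 1`.
#' @return A `cv_plan`: `assignment` (list of per-repeat fold vectors), `k`,
#'   `repeats`, `seed`.
#' @export
make_cv_plan <- function(labels, k = 5L, repeats = 5L, seed = 1L) {
  labels <- as.integer(labels)
  tab <- table(labels)
  if (length(tab) < 2) stopf("both classes must be present")
  if (min(tab) < k) stopf("smallest class (%d) has fewer samples than k = %d",
                          min(tab), k)
  assignment <- lapply(seq_len(repeats), function(r) {
    with_seed(seed + r - 1L, {
      fold <- integer(length(labels))
      for (cl in names(tab)) {
        idx <- sample(which(labels == as.integer(cl)))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
      fold
    })
  })
  structure(list(assignment = assignment, k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 stratified = TRUE),
            class = "cv_plan")
}

# Stable content hash of a plan (used to assert that model and baselines
# consume identical fold assignments).
plan_hash <- function(plan) {
  v <- unlist(plan$assignment)
  sprintf("k%dr%d-%d-%.0f", plan$k, plan$repeats, plan$seed,
          sum(v * seq_along(v) %% 1e9))
}

aggregate_report <- function(folds, plan) {
  num <- c("accuracy", "sensitivity", "precision", "specificity")
  summary <- data.frame(metric = num,
                        mean = vapply(num, function(m) mean(folds[[m]], na.rm = TRUE), 0),
                        sd = vapply(num, function(m) stats::sd(folds[[m]][!is.na(folds[[m]])]), 0))
  structure(list(folds = folds, summary = summary, plan_hash = plan_hash(plan)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("<metrics_report: %d fold evaluations>\n", nrow(x$folds)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.*f +/- %.*f\n", s$metric[i], digits, s$mean[i],
                digits, s$sd[i]))
  }
  invisible(x)
}

#' Cross-validated evaluation of the full classifier
#'
#' For every (repeat, fold): standardisation statistics are fitted on the
#' training windows only, tensors are assembled for both splits, the network
#' is trained on the training split and evaluated on the held-out fold. The
#' report aggregates the per-fold confusion metrics as mean and standard
#' deviation across all `k * repeats` evaluations.
#'
#' @param block A `feature_block` restricted to the selected features.
#' @param labels Binary labels per window.
#' @param layout A [build_grid_layout()].
#' @param config A [model_config()].
#' @param plan A [make_cv_plan()] for `labels`.
#' @param verbose Print per-fold progress.
#' @return A `metrics_report` with per-fold rows (repeat, fold, counts,
#'   metrics) and the plan hash.
#' @export
run_cv <- function(block, labels, layout, config = model_config("small"),
                   plan = make_cv_plan(labels), verbose = FALSE) {
  stopifnot(inherits(block, "feature_block"))
  folds <- data.frame()
  for (r in seq_len(plan$repeats)) {
    fold <- plan$assignment[[r]]
    for (f in seq_len(plan$k)) {
      tr <- which(fold != f); te <- which(fold == f)
      tr_block <- subset_block(block, tr)
      te_block <- subset_block(block, te)
      stats <- suppressWarnings(fit_scaler(tr_block, layout))
      ts_tr <- assemble_tensor_set(tr_block, layout, labels[tr], stats)
      ts_te <- assemble_tensor_set(te_block, layout, labels[te], stats)
      cfg <- config
      cfg$seed <- config$seed + (r - 1) * plan$k + (f - 1)
      model <- train_model(ts_tr, cfg)
      pred <- max.col(model_forward(model, ts_te)) - 1
      cm <- suppressWarnings(confusion_counts(pred, labels[te]))
      folds <- rbind(folds, cbind(data.frame(repeat_ = r, fold = f), cm))
      if (verbose) {
        message(sprintf("repeat %d fold %d: acc %.3f", r, f, cm$accuracy))
      }
    }
  }
  aggregate_report(folds, plan)
}

subset_block <- function(block, idx) {
  structure(list(values = block$values[idx, , , , drop = FALSE],
                 feature_names = block$feature_names,
                 channel_names = block$channel_names),
            class = "feature_block")
}

#' Flatten a feature block to one vector per window
#'
#' Concatenates step x feature x channel values, the 1-D input the baseline
#' classifiers consume.
#'
#' @param block A `feature_block`.
#' @return Matrix windows x (steps * features * channels).
#' @export
flatten_features <- function(block) {
  d <- dim(block$values)
  matrix(block$values, d[1], prod(d[2:4]))
}

baseline_cv <- function(X, labels, plan, fit_predict) {
  folds <- data.frame()
  for (r in seq_len(plan$repeats)) {
    fold <- plan$assignment[[r]]
    for (f in seq_len(plan$k)) {
      tr <- fold != f; te <- fold == f
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- scale(X[tr, , drop = FALSE], mu, sdv)
      Xte <- scale(X[te, , drop = FALSE], mu, sdv)
      pred <- fit_predict(Xtr, labels[tr], Xte)
      cm <- suppressWarnings(confusion_counts(pred, labels[te]))
      folds <- rbind(folds, cbind(data.frame(repeat_ = r, fold = f), cm))
    }
  }
  aggregate_report(folds, plan)
}

#' KNN baseline on flattened feature vectors
#'
#' 5-nearest-neighbour classification (Euclidean = Minkowski p = 2) under
#' the same cross-validation plan as the network; features are standardised
#' with training-fold statistics.
#'
#' @param X Matrix from [flatten_features()].
#' @param labels Binary labels.
#' @param plan A [make_cv_plan()].
#' @param k Neighbour count (default 5).
#' @return A `metrics_report`.
#' @export
baseline_knn <- function(X, labels, plan, k = 5L) {
  baseline_cv(X, labels, plan, function(Xtr, ytr, Xte) {
    as.integer(as.character(class::knn(Xtr, Xte, factor(ytr), k = k)))
  })
}

#' SVM baseline on flattened feature vectors
#'
#' RBF-kernel support vector machine (one-vs-one decision, C = 1, kernel
#' width `1 / (n_features * var(X))`) under the same plan as the network.
#'
#' @inheritParams baseline_knn
#' @return A `metrics_report`.
#' @export
baseline_svm <- function(X, labels, plan) {
  baseline_cv(X, labels, plan, function(Xtr, ytr, Xte) {
    gamma <- 1 / (ncol(Xtr) * max(stats::var(as.vector(Xtr)), 1e-12))
    fit <- e1071::svm(Xtr, factor(ytr), kernel = "radial", cost = 1,
                      gamma = gamma, scale = FALSE)
    as.integer(as.character(stats::predict(fit, Xte)))
  })
}
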