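#' Equal-frequency discretisation
#'
#' Continuous inputs are cut into `bins` classes at empirical quantiles;
#' inputs with at most `bins` distinct values are used as categories directly.
#'
#' @param x Numeric or discrete vector.
#' @param bins Number of bins.
#' @return Integer factor codes.
#' @export
discretize_ef <- function(x, bins) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 1))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

#' Plug-in mutual information (nats)
#'
#' Continuous inputs are discretised by equal-frequency binning into
#' `min(ceiling(sqrt(n)), 16)` bins, then the plug-in estimate
#' `sum p(a,b) ln( p(a,b) / (p(a) p(b)) )` is returned. Non-negative and
#' symmetric; `MI(a, a)` equals the entropy of `a` for discrete `a`.
#'
#' @param a,b Vectors of equal length >= 2.
#' @param bins Bin count; default `min(ceiling(sqrt(n)), 16)`.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(a, b, bins = NULL) {
  if (length(a) != length(b)) {
    stopf("length mismatch: %d vs %d", length(a), length(b))
  }
  if (length(a) < 2) stopf("need at least 2 observations")
  bins <- bins %||% min(ceiling(sqrt(length(a))), 16)
  da <- discretize_ef(a, bins)
  db <- discretize_ef(b, bins)
  j <- table(da, db) / length(a)
  pa <- rowSums(j); pb <- colSums(j)
  nz <- j > 0
  sum(j[nz] * log(j[nz] / outer(pa, pb)[nz]))
}

#' Build the feature matrix used for ranking
#'
#' By default each candidate variable is one feature averaged over channels
#' and steps (four variables: HFD, ApEn, SampEn, FuzzyEn); with
#' `per_channel = TRUE` every (feature, channel) pair becomes a variable.
#'
#' @param fb A `feature_block`.
#' @param labels Binary labels, one per window.
#' @param per_channel Keep per-channel granularity (default FALSE).
#' @return A `feature_matrix`: numeric matrix `X` (windows x variables) with
#'   `variable_names`, plus `y`.
#' @export
build_feature_matrix <- function(fb, labels, per_channel = FALSE) {
  stopifnot(inherits(fb, "feature_block"))
  d <- dim(fb$values)
  if (length(labels) != d[1]) stopf("labels length != number of windows")
  if (per_channel) {
    X <- matrix(0, d[1], d[3] * d[4])
    nm <- character(d[3] * d[4])
    k <- 0
    for (f in seq_len(d[3])) for (ch in seq_len(d[4])) {
      k <- k + 1
      X[, k] <- apply(fb$values[, , f, ch, drop = FALSE], 1, mean)
      nm[k] <- paste0(fb$feature_names[f], ".", fb$channel_names[ch])
    }
  } else {
    X <- sapply(seq_len(d[3]), function(f) {
      apply(fb$values[, , f, , drop = FALSE], 1, mean)
    })
    X <- matrix(X, nrow = d[1])
    nm <- fb$feature_names
  }
  colnames(X) <- nm
  if (anyNA(X)) stopf("feature matrix contains missing values")
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  structure(list(X = X, y = as.integer(labels), variable_names = nm),
            class = "feature_matrix")
}

#' Rank variables by minimum-redundancy-maximum-relevance
#'
#' The first variable selected maximises relevance `I(x; y)`; each subsequent
#' variable maximises `I(x_j; y) - mean over selected x_i of I(x_i; x_j)`.
#' Ties are broken by variable-name order. The importance reported for each
#' variable is its score at the step it was selected (the first variable's
#' score is its relevance), both raw and min-max rescaled to \[0, 1\].
#'
#' @param fm A [build_feature_matrix()] result, or a numeric matrix plus `y`.
#' @param y Labels (required if `fm` is a plain matrix).
#' @return A `selection_result`: `ranked_names`, `importance` (rescaled),
#'   `importance_raw`, `relevance`, `chosen_k` (NA until a sweep sets it).
#' @export
mrmr_rank <- function(fm, y = NULL) {
  if (is.matrix(fm)) fm <- build_feature_matrix_raw(fm, y)
  stopifnot(inherits(fm, "feature_matrix"))
  vars <- fm$variable_names
  p <- length(vars)
  if (p < 1) stopf("empty candidate set")
  rel <- vapply(seq_len(p), function(j) mutual_information(fm$X[, j], fm$y), 0)
  names(rel) <- vars
  # pairwise MI cache, filled lazily
  mi_pair <- matrix(NA_real_, p, p)
  pair_mi <- function(i, j) {
    if (is.na(mi_pair[i, j])) {
      v <- mutual_information(fm$X[, i], fm$X[, j])
      mi_pair[i, j] <<- v; mi_pair[j, i] <<- v
    }
    mi_pair[i, j]
  }
  selected <- integer(0)
  scores <- numeric(p)
  remaining <- seq_len(p)
  for (step in seq_len(p)) {
    cand_scores <- vapply(remaining, function(j) {
      if (length(selected) == 0) return(rel[j])
      rel[j] - mean(vapply(selected, function(i) pair_mi(i, j), 0))
    }, 0)
    ord <- order(-cand_scores, vars[remaining])
    best <- remaining[ord[1]]
    scores[step] <- cand_scores[ord[1]]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  rng <- range(scores)
  rescaled <- if (diff(rng) > 0) (scores - rng[1]) / diff(rng) else rep(1, p)
  structure(list(ranked_names = vars[selected],
                 importance = rescaled,
                 importance_raw = scores,
                 relevance = rel,
                 chosen_k = NA_integer_),
            class = "selection_result")
}

# Wrap a plain matrix + labels as a feature_matrix.
build_feature_matrix_raw <- function(X, y) {
  if (is.null(colnames(X))) colnames(X) <- sprintf("v%02d", seq_len(ncol(X)))
  if (anyNA(X)) stopf("feature matrix contains missing values")
  if (length(y) != nrow(X)) stopf("labels length != rows of X")
  if (length(unique(y)) < 2) stopf("both classes must be present")
  structure(list(X = X, y = as.integer(y), variable_names = colnames(X)),
            class = "feature_matrix")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n  rank  variable  importance\n")
  for (i in seq_along(x$ranked_names)) {
    cat(sprintf("  %4d  %-10s %.4f\n", i, x$ranked_names[i], x$importance[i]))
  }
  if (!is.na(x$chosen_k)) cat(sprintf("  chosen_k: %d\n", x$chosen_k))
  invisible(x)
}

#' Choose how many ranked variables to keep via an accuracy sweep
#'
#' Evaluates the classifier accuracy with the top-j ranked variables for
#' j = 1..k_max under a fixed cross-validation plan and seed, and returns the
#' smallest j achieving the maximum accuracy. The default evaluator is the
#' fast 5-nearest-neighbour baseline under 5-fold CV.
#'
#' @param fm A `feature_matrix`.
#' @param result A `selection_result` from [mrmr_rank()].
#' @param evaluator `function(X, y, seed) -> accuracy`; default seeded 5-fold
#'   KNN (k = 5).
#' @param k_max Largest candidate count (default all ranked variables).
#' @param seed Seed forwarded to the evaluator.
#' @return The input `selection_result` with `chosen_k` and the per-j
#'   `sweep_accuracy` filled in.
#' @export
feature_count_sweep <- function(fm, result, evaluator = NULL, k_max = NULL,
                                seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(result, "selection_result"))
  k_max <- k_max %||% length(result$ranked_names)
  if (k_max < 1) stopf("k_max must be >= 1")
  if (k_max > length(result$ranked_names)) stopf("k_max exceeds ranked variables")
  evaluator <- evaluator %||% knn_cv_accuracy
  acc <- vapply(seq_len(k_max), function(j) {
    keep <- match(result$ranked_names[seq_len(j)], fm$variable_names)
    evaluator(fm$X[, keep, drop = FALSE], fm$y, seed)
  }, 0)
  result$sweep_accuracy <- acc
  result$chosen_k <- chosen_k_from_accuracies(acc)
  result
}

# Smallest j achieving the maximum accuracy.
chosen_k_from_accuracies <- function(acc) which.max(acc)

# Default sweep evaluator: mean 5-fold CV accuracy of 5-NN.
knn_cv_accuracy <- function(X, y, seed = 1L, k = 5L, folds = 5L) {
  plan <- make_cv_plan(y, k = folds, repeats = 1L, seed = seed)
  fold <- plan$assignment[[1]]
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold != f; te <- fold == f
    pred <- class::knn(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                       factor(y[tr]), k = k)
    mean(pred == factor(y[te], levels = levels(pred)))
  }, 0)
  mean(acc)
}

#' Serialize a selection result to JSON
#'
#' @param result A `selection_result`.
#' @param path Output JSON path.
#' @param seed,bins Provenance fields recorded alongside the ranking.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(result, path, seed = NA_integer_,
                                 bins = "min(ceiling(sqrt(n)), 16)") {
  jsonlite::write_json(
    list(ranked_names = result$ranked_names,
         importance = result$importance,
         importance_raw = result$importance_raw,
         chosen_k = result$chosen_k,
         binning = bins, seed = seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
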