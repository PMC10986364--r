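#' Run the full seizure-prediction pipeline on recordings
#'
#' Filters each recording (0.5-75 Hz), cuts labelled 6-s windows against the
#' 15-to-5-minute prediction horizon, balances classes 1:1, extracts the four
#' nonlinear features per channel and 3-s step, ranks them by mRMR with an
#' accuracy sweep to pick the retained count, tensorizes the selected
#' features onto the 4x7 electrode grid, and evaluates the classifier with
#' repeated stratified k-fold cross-validation (standardisation fitted inside
#' each training fold). KNN and SVM baselines run on the same fold
#' assignments.
#'
#' @param recordings List of [recording()] objects.
#' @param spec A [label_spec()].
#' @param params A [feature_params()].
#' @param config A [model_config()].
#' @param layout A [build_grid_layout()]; defaults to the canonical grid for
#'   the first recording's channels.
#' @param k,repeats Cross-validation folds and repeats.
#' @param n_keep Number of top-ranked features to keep; `NULL` (default) runs
#'   the accuracy sweep and keeps its choice.
#' @param baselines Also evaluate KNN/SVM baselines (default TRUE).
#' @param seed Seed for balancing, selection sweep and the CV plan.
#' @param verbose Print progress.
#' @return A `pipeline_result`: `selection`, `report`, optional
#'   `knn`/`svm` reports, the balanced `labels`, `block` (selected
#'   features), `plan`, `layout`.
#' @export
run_pipeline <- function(recordings, spec = label_spec(),
                         params = feature_params(),
                         config = model_config("small"),
                         layout = NULL, k = 5L, repeats = 1L,
                         n_keep = NULL, baselines = TRUE, seed = 1L,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("filtering and windowing %d recording(s)", length(recordings))
  sets <- lapply(recordings, function(r) {
    label_windows(bandpass_filter(r), spec)
  })
  ws <- balance_classes(bind_window_sets(sets), seed = seed)
  say("%d balanced windows (%d positive)", length(ws$labels),
      sum(ws$labels == 1))
  steps <- split_steps(ws)
  say("extracting features")
  block <- extract_feature_block(steps, params)
  fm <- build_feature_matrix(block, ws$labels)
  sel <- mrmr_rank(fm)
  if (is.null(n_keep)) {
    sel <- feature_count_sweep(fm, sel, seed = seed)
    n_keep <- sel$chosen_k
  } else {
    sel$chosen_k <- as.integer(n_keep)
  }
  keep <- sel$ranked_names[seq_len(n_keep)]
  say("mRMR ranking: %s; keeping %d", paste(sel$ranked_names, collapse = " > "),
      n_keep)
  block_sel <- select_features(block, keep)
  layout <- layout %||% build_grid_layout(block$channel_names)
  cfg <- config
  cfg$grid_shape <- c(length(keep), layout$n_rows, layout$n_cols)
  # feature-axis kernels must be odd; span the whole axis when possible
  kd <- if (length(keep) %% 2 == 1) length(keep) else max(1, length(keep) - 1)
  cfg$p3d_kernels <- lapply(cfg$p3d_kernels, function(ks) {
    if (ks[1] > 1) c(kd, ks[2:3]) else ks
  })
  plan <- make_cv_plan(ws$labels, k = k, repeats = repeats, seed = seed)
  say("cross-validating the network (%d x %d folds)", repeats, k)
  report <- run_cv(block_sel, ws$labels, layout, cfg, plan, verbose = verbose)
  out <- list(selection = sel, report = report, labels = ws$labels,
              block = block_sel, plan = plan, layout = layout, config = cfg)
  if (baselines) {
    say("evaluating baselines")
    X1d <- flatten_features(block_sel)
    out$knn <- baseline_knn(X1d, ws$labels, plan)
    out$svm <- baseline_svm(X1d, ws$labels, plan)
  }
  structure(out, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== feature selection ==\n")
  print(x$selection)
  cat("== network (cross-validated) ==\n")
  print(x$report)
  if (!is.null(x$knn)) { cat("== KNN baseline ==\n"); print(x$knn) }
  if (!is.null(x$svm)) { cat("== SVM baseline ==\n"); print(x$svm) }
  invisible(x)
}
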