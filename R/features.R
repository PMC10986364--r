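#' Parameters of the nonlinear feature estimators
#'
#' @param kmax Maximum delay for the Higuchi fractal dimension (default 10).
#' @param m Embedding dimension for the three entropies (default 2).
#' @param r_frac Similarity threshold as a fraction of the series' standard
#'   deviation (default 0.2).
#' @param fuzzy_n Exponent of the Gaussian similarity function in fuzzy
#'   entropy (default 2).
#' @return A `feature_params` list.
#' @export
feature_params <- function(kmax = 10, m = 2, r_frac = 0.2, fuzzy_n = 2) {
  if (kmax < 2) stopf("kmax must be >= 2")
  if (m < 1) stopf("m must be >= 1")
  if (r_frac <= 0) stopf("r_frac must be positive")
  if (fuzzy_n <= 0) stopf("fuzzy_n must be positive")
  structure(list(kmax = as.integer(kmax), m = as.integer(m), r_frac = r_frac,
                 fuzzy_n = fuzzy_n), class = "feature_params")
}

#' All recognised feature names, in canonical order
#' @return Character vector `c("HFD", "ApEn", "SampEn", "FuzzyEn")`.
#' @export
all_feature_names <- function() c("HFD", "ApEn", "SampEn", "FuzzyEn")

# Higuchi curve lengths L(k) for k = 1..kmax.
higuchi_curve <- function(x, kmax) higuchi_curve_cpp(x, kmax)

#' Higuchi fractal dimension
#'
#' Builds the delayed subseries curve lengths `L(k)` and returns the
#' least-squares slope of `ln L(k)` against `ln(1/k)` over `k = 1..kmax`.
#' A straight-line series gives exactly 1; white noise approaches 2.
#'
#' @param x Numeric series, `length(x) > kmax`, not constant.
#' @param kmax Maximum delay (>= 2).
#' @return Fractal dimension estimate (scalar).
#' @export
higuchi_fd <- function(x, kmax = 10) {
  if (length(x) <= kmax) stopf("series length (%d) must exceed kmax (%d)",
                               length(x), kmax)
  if (kmax < 2) stopf("kmax must be >= 2")
  if (stats::sd(x) == 0) stopf("degenerate series: constant input has undefined log curve length")
  L <- higuchi_curve(x, kmax)
  lk <- log(1 / seq_len(kmax))
  stats::cov(lk, log(L)) / stats::var(lk)
}

#' Approximate entropy
#'
#' Chebyshev template matching at embedding dimensions `m` and `m+1` with the
#' self-match included (counts use `d <= r`), threshold `r` equal to `r_frac * sd(x)`. Returns
#' `phi(m, r) - phi(m + 1, r)` where `phi` is the mean log relative match
#' count. A constant series returns 0.
#'
#' @param x Numeric series of length >= m + 2.
#' @param m Embedding dimension.
#' @param r_frac Threshold as a fraction of `sd(x)`.
#' @return Non-negative scalar (up to floating tolerance).
#' @export
approximate_entropy <- function(x, m = 2, r_frac = 0.2) {
  if (length(x) < m + 2) stopf("series too short (n=%d) for m=%d", length(x), m)
  s <- stats::sd(x)
  if (s == 0) return(0)
  agg <- apen_sampen_aggregates(x, m, r_frac * s)
  agg$phi_m - agg$phi_m1
}

#' Sample entropy
#'
#' Match ratios `B^m` and `B^(m+1)` computed with strict `d < r` and
#' self-matches excluded; returns `-ln(B^(m+1) / B^m)`. The threshold `r`
#' equals `r_frac * sd(x)`, making the estimate invariant to affine
#' rescaling of the series. A constant series returns 0; zero matches at dimension `m+1`
#' is an error (the statistic is undefined).
#'
#' @inheritParams approximate_entropy
#' @return Non-negative scalar.
#' @export
sample_entropy <- function(x, m = 2, r_frac = 0.2) {
  if (length(x) < m + 2) stopf("series too short (n=%d) for m=%d", length(x), m)
  s <- stats::sd(x)
  if (s == 0) return(0)
  agg <- apen_sampen_aggregates(x, m, r_frac * s)
  if (agg$B_m1 <= 0) stopf("sample entropy undefined (no matches at dimension m+1)")
  -log(agg$B_m1 / agg$B_m)
}

#' Fuzzy entropy
#'
#' Templates are mean-removed; similarity is the Gaussian membership
#' `exp(-d^n / r)` of the Chebyshev distance `d`, with threshold `r` equal to `r_frac * sd(x)`.
#' Returns `ln Phi^m - ln Phi^(m+1)`. Mean removal makes the estimate exactly
#' invariant to constant offsets; a constant series returns 0.
#'
#' @inheritParams approximate_entropy
#' @param n Gaussian exponent (default 2).
#' @return Non-negative scalar.
#' @export
fuzzy_entropy <- function(x, m = 2, r_frac = 0.2, n = 2) {
  if (length(x) < m + 2) stopf("series too short (n=%d) for m=%d", length(x), m)
  s <- stats::sd(x)
  if (s == 0) return(0)
  agg <- fuzzyen_aggregates(x, m, r_frac * s, n)
  log(agg$Phi_m) - log(agg$Phi_m1)
}

#' Intermediate aggregates of the four estimators
#'
#' Exposes the quantities the estimators are built from: the ApEn aggregates
#' `phi_m`/`phi_m1`, the SampEn match ratios `B_m`/`B_m1`, the FuzzyEn
#' aggregates `Phi_m`/`Phi_m1`, and the Higuchi log-log curve points.
#'
#' @inheritParams approximate_entropy
#' @param params A [feature_params()].
#' @return An `entropy_trace` list.
#' @export
entropy_trace <- function(x, params = feature_params()) {
  s <- stats::sd(x)
  if (s == 0) stopf("degenerate series")
  a <- apen_sampen_aggregates(x, params$m, params$r_frac * s)
  f <- fuzzyen_aggregates(x, params$m, params$r_frac * s, params$fuzzy_n)
  structure(list(phi_m = a$phi_m, phi_m1 = a$phi_m1, B_m = a$B_m,
                 B_m1 = a$B_m1, Phi_m = f$Phi_m, Phi_m1 = f$Phi_m1,
                 curve_k = seq_len(params$kmax),
                 curve_L = higuchi_curve(x, params$kmax)),
            class = "entropy_trace")
}

feature_fun <- function(name, params) {
  switch(name,
    HFD = function(x) higuchi_fd(x, params$kmax),
    ApEn = function(x) approximate_entropy(x, params$m, params$r_frac),
    SampEn = function(x) sample_entropy(x, params$m, params$r_frac),
    FuzzyEn = function(x) fuzzy_entropy(x, params$m, params$r_frac,
                                        params$fuzzy_n),
    stopf("unknown feature '%s'", name))
}

#' Compute nonlinear features per window, step and channel
#'
#' @param steps Step array from [split_steps()]: n x 2 x channels x samples.
#' @param params A [feature_params()].
#' @param feature_names Subset of [all_feature_names()] to compute.
#' @param channel_names Channel labels; taken from `dimnames(steps)[[3]]` if
#'   present.
#' @return A `feature_block`: `values` array n x steps x features x channels
#'   (all finite; an estimator failure on a single series is recorded as 0
#'   with a warning), plus `feature_names` and `channel_names`.
#' @export
extract_feature_block <- function(steps, params = feature_params(),
                                  feature_names = all_feature_names(),
                                  channel_names = NULL) {
  if (length(feature_names) == 0) stopf("feature_names must be non-empty")
  if (!all(feature_names %in% all_feature_names())) {
    stopf("unknown feature(s): %s",
          paste(setdiff(feature_names, all_feature_names()), collapse = ", "))
  }
  d <- dim(steps)
  channel_names <- channel_names %||% dimnames(steps)[[3]] %||%
    sprintf("ch%02d", seq_len(d[3]))
  vals <- array(0, c(d[1], d[2], length(feature_names), d[3]),
                dimnames = list(NULL, NULL, feature_names, channel_names))
  n_fail <- 0L
  # ApEn and SampEn share one template-matching sweep per series
  want_agg <- any(c("ApEn", "SampEn") %in% feature_names)
  for (w in seq_len(d[1])) for (s in seq_len(d[2])) for (ch in seq_len(d[3])) {
    x <- steps[w, s, ch, ]
    sdx <- stats::sd(x)
    agg <- if (want_agg && sdx > 0) {
      tryCatch(apen_sampen_aggregates(x, params$m, params$r_frac * sdx),
               error = function(e) NULL)
    } else NULL
    for (f in seq_along(feature_names)) {
      v <- tryCatch(switch(feature_names[f],
        HFD = higuchi_fd(x, params$kmax),
        ApEn = if (sdx == 0) 0 else if (is.null(agg)) NA_real_ else
          agg$phi_m - agg$phi_m1,
        SampEn = if (sdx == 0) 0 else if (is.null(agg) || agg$B_m1 <= 0)
          NA_real_ else -log(agg$B_m1 / agg$B_m),
        FuzzyEn = fuzzy_entropy(x, params$m, params$r_frac, params$fuzzy_n)),
        error = function(e) NA_real_)
      if (!is.finite(v)) { v <- 0; n_fail <- n_fail + 1L }
      vals[w, s, f, ch] <- v
    }
  }
  if (n_fail > 0) warnf("%d estimator failure(s) recorded as 0", n_fail)
  structure(list(values = vals, feature_names = feature_names,
                 channel_names = channel_names),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_block: %d windows x %d steps x %d features (%s) x %d channels>\n",
              d[1], d[2], d[3], paste(x$feature_names, collapse = ", "), d[4]))
  invisible(x)
}

#' Tidy long-format table of a feature block
#'
#' @param fb A `feature_block`.
#' @return data.frame with columns window_id, step, channel, feature, value.
#' @export
feature_table <- function(fb) {
  stopifnot(inherits(fb, "feature_block"))
  d <- dim(fb$values)
  g <- expand.grid(window_id = seq_len(d[1]), step = seq_len(d[2]),
                   feature = fb$feature_names, channel = fb$channel_names,
                   stringsAsFactors = FALSE)
  g$value <- as.vector(fb$values[cbind(g$window_id, g$step,
                                       match(g$feature, fb$feature_names),
                                       match(g$channel, fb$channel_names))])
  g[, c("window_id", "step", "channel", "feature", "value")]
}

#' Keep a subset of features, in the given order
#'
#' @param fb A `feature_block`.
#' @param feature_names Features to retain (must exist in `fb`).
#' @return A `feature_block` with the requested features.
#' @export
select_features <- function(fb, feature_names) {
  stopifnot(inherits(fb, "feature_block"))
  if (!all(feature_names %in% fb$feature_names)) {
    stopf("feature(s) not present: %s",
          paste(setdiff(feature_names, fb$feature_names), collapse = ", "))
  }
  idx <- match(feature_names, fb$feature_names)
  structure(list(values = fb$values[, , idx, , drop = FALSE],
                 feature_names = feature_names,
                 channel_names = fb$channel_names),
            class = "feature_block")
}
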