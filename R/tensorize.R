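#' Canonical 4x7 electrode grid layout
#'
#' Maps the 23 default electrode names onto a 4-row by 7-column scalp grid
#' (anterior to posterior rows, left to right columns), leaving 5 cells
#' empty:
#' \preformatted{
#'   .    AF7  AF3  .    AF4  AF8  .
#'   FT9  FT7  FC3  FCz  FC4  FT8  FT10
#'   T7   TP7  CP3  CPz  CP4  TP8  T8
#'   .    PO7  PO3  PO4  PO8  P8   .
#' }
#' Custom mappings are accepted: a named list `name -> c(row, col)` with rows
#' in 1..4 and columns in 1..7.
#'
#' @param channel_names Unique electrode names to place.
#' @param mapping Optional custom mapping covering all `channel_names`.
#' @return A `grid_layout`: `mapping` (named list of `c(row, col)`),
#'   `empty_cells`, `n_rows = 4`, `n_cols = 7`.
#' @export
build_grid_layout <- function(channel_names = default_channel_names(),
                              mapping = NULL) {
  if (anyDuplicated(channel_names)) {
    stopf("duplicate electrode name(s): %s",
          paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  }
  if (is.null(mapping)) mapping <- canonical_grid_mapping()
  unknown <- setdiff(channel_names, names(mapping))
  if (length(unknown)) {
    stopf("no grid cell for electrode(s): %s (supply a custom mapping)",
          paste(unknown, collapse = ", "))
  }
  mapping <- mapping[channel_names]
  cells <- vapply(mapping, function(rc) (rc[1] - 1) * 7 + rc[2], 0)
  if (anyDuplicated(cells)) stopf("duplicate target cell in mapping")
  if (any(vapply(mapping, function(rc) {
    rc[1] < 1 || rc[1] > 4 || rc[2] < 1 || rc[2] > 7
  }, logical(1)))) stopf("mapping rows must be in 1..4 and columns in 1..7")
  empty <- setdiff(seq_len(28), cells)
  structure(list(mapping = mapping,
                 empty_cells = lapply(empty, function(i) {
                   c((i - 1) %/% 7 + 1, (i - 1) %% 7 + 1)
                 }),
                 n_rows = 4L, n_cols = 7L),
            class = "grid_layout")
}

canonical_grid_mapping <- function() {
  rows <- list(
    c(NA, "AF7", "AF3", NA, "AF4", "AF8", NA),
    c("FT9", "FT7", "FC3", "FCz", "FC4", "FT8", "FT10"),
    c("T7", "TP7", "CP3", "CPz", "CP4", "TP8", "T8"),
    c(NA, "PO7", "PO3", "PO4", "PO8", "P8", NA))
  m <- list()
  for (r in 1:4) for (cc in 1:7) {
    nm <- rows[[r]][cc]
    if (!is.na(nm)) m[[nm]] <- c(r, cc)
  }
  m
}

#' Serialize / read a grid layout as JSON
#'
#' Schema: `{ "<electrode>": [row, col], ... }` (1-based indices).
#'
#' @param layout A `grid_layout`.
#' @param path JSON path.
#' @return Writer: `path` invisibly. Reader: a `grid_layout`.
#' @export
write_grid_layout_json <- function(layout, path) {
  jsonlite::write_json(layout$mapping, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_grid_layout_json
#' @param channel_names Names to place from the read mapping.
#' @export
read_grid_layout_json <- function(path, channel_names = NULL) {
  m <- lapply(jsonlite::read_json(path), function(v) as.numeric(unlist(v)))
  build_grid_layout(channel_names %||% names(m), mapping = m)
}

#' Fit per-(feature, cell) standardisation statistics on a training split
#'
#' Means and standard deviations are computed over all training windows and
#' steps, separately per feature and grid cell. Cells with zero variance are
#' flagged and later standardised to 0.
#'
#' @param train_block A `feature_block` restricted to training rows.
#' @param layout A `grid_layout`.
#' @return A `scaler_stats` object.
#' @export
fit_scaler <- function(train_block, layout) {
  stopifnot(inherits(train_block, "feature_block"),
            inherits(layout, "grid_layout"))
  d <- dim(train_block$values)
  mu <- sdev <- matrix(0, d[3], d[4],
                       dimnames = list(train_block$feature_names,
                                       train_block$channel_names))
  for (f in seq_len(d[3])) for (ch in seq_len(d[4])) {
    v <- as.vector(train_block$values[, , f, ch])
    mu[f, ch] <- mean(v)
    sdev[f, ch] <- stats::sd(v)
  }
  flagged <- which(sdev == 0 | !is.finite(sdev), arr.ind = TRUE)
  if (nrow(flagged)) {
    warnf("%d constant (feature, cell) column(s) standardised to 0", nrow(flagged))
  }
  structure(list(mean = mu, sd = sdev,
                 feature_names = train_block$feature_names,
                 channel_names = train_block$channel_names),
            class = "scaler_stats")
}

#' Apply standardisation statistics to a feature block
#'
#' @param block A `feature_block` (train or test rows).
#' @param stats A [fit_scaler()] result with matching feature and channel
#'   names.
#' @return A standardised `feature_block`.
#' @export
apply_scaler <- function(block, stats) {
  stopifnot(inherits(block, "feature_block"), inherits(stats, "scaler_stats"))
  if (!identical(block$feature_names, stats$feature_names) ||
      !identical(block$channel_names, stats$channel_names)) {
    stopf("scaler stats were fitted on different feature/channel names")
  }
  out <- block$values
  d <- dim(out)
  for (f in seq_len(d[3])) for (ch in seq_len(d[4])) {
    s <- stats$sd[f, ch]
    if (s > 0 && is.finite(s)) {
      out[, , f, ch] <- (out[, , f, ch] - stats$mean[f, ch]) / s
    } else {
      out[, , f, ch] <- 0
    }
  }
  structure(list(values = out, feature_names = block$feature_names,
                 channel_names = block$channel_names),
            class = "feature_block")
}

#' Assemble standardised features into spatio-temporal tensors
#'
#' Produces, per window, an array `T x N x H x W` (time steps x features x
#' grid rows x grid columns): `data[t, f, r, c]` is the standardised value of
#' feature `f` at the electrode mapped to `(r, c)` during step `t`; unmapped
#' cells carry 0 (the standardised mean), keeping convolutions well defined.
#' Placement is by electrode name, so channel order in the block is
#' irrelevant.
#'
#' @param block A `feature_block` containing exactly the selected features.
#' @param layout A `grid_layout`.
#' @param stats Optional [fit_scaler()] stats to apply first.
#' @return A `tensor_set`: `data` (n x T x N x H x W array), `labels` slot
#'   (filled by the caller or [assemble_tensor_set()]), `feature_names`,
#'   `layout`.
#' @export
assemble_tensor <- function(block, layout, stats = NULL) {
  stopifnot(inherits(block, "feature_block"), inherits(layout, "grid_layout"))
  if (!is.null(stats)) block <- apply_scaler(block, stats)
  d <- dim(block$values)
  if (d[2] < 2) stopf("feature block must contain both time steps")
  missing_ch <- setdiff(block$channel_names, names(layout$mapping))
  if (length(missing_ch)) {
    stopf("layout lacks cells for: %s", paste(missing_ch, collapse = ", "))
  }
  data <- array(0, c(d[1], d[2], d[3], layout$n_rows, layout$n_cols))
  for (ch in seq_along(block$channel_names)) {
    rc <- layout$mapping[[block$channel_names[ch]]]
    data[, , , rc[1], rc[2]] <- block$values[, , , ch]
  }
  structure(list(data = data, labels = NULL,
                 feature_names = block$feature_names, layout = layout),
            class = "tensor_set")
}

#' Assemble tensors with labels attached
#'
#' @inheritParams assemble_tensor
#' @param labels Binary labels, one per window.
#' @return A `tensor_set` with `labels`.
#' @export
assemble_tensor_set <- function(block, layout, labels, stats = NULL) {
  ts <- assemble_tensor(block, layout, stats)
  if (length(labels) != dim(ts$data)[1]) stopf("labels length mismatch")
  ts$labels <- as.integer(labels)
  ts
}

#' @export
print.tensor_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tensor_set: %d samples x (T=%d, N=%d, H=%d, W=%d)%s>\n",
              d[1], d[2], d[3], d[4], d[5],
              if (!is.null(x$labels)) sprintf(", %d positive", sum(x$labels == 1)) else ""))
  invisible(x)
}
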