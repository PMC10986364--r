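test_that("the canonical layout places 23 electrodes on a 4x7 grid", {
  layout <- build_grid_layout(default_channel_names())
  expect_length(layout$mapping, 23)
  expect_length(layout$empty_cells, 5)
  expect_equal(layout$n_rows, 4L)
  expect_equal(layout$n_cols, 7L)
  cells <- vapply(layout$mapping, function(rc) (rc[1] - 1) * 7 + rc[2], 0)
  expect_false(anyDuplicated(cells) > 0)
})

test_that("layout errors name the offending electrode", {
  expect_error(build_grid_layout(c("AF7", "AF7")), "duplicate")
  expect_error(build_grid_layout(c("AF7", "XX9")), "XX9")
  expect_error(build_grid_layout(c("A", "B"),
                                 mapping = list(A = c(1, 1), B = c(1, 1))),
               "duplicate target")
  expect_error(build_grid_layout("A", mapping = list(A = c(5, 1))), "rows")
})

test_that("layouts round-trip through JSON", {
  layout <- build_grid_layout(default_channel_names())
  path <- tempfile(fileext = ".json")
  write_grid_layout_json(layout, path)
  back <- read_grid_layout_json(path)
  expect_equal(back$mapping, layout$mapping)
})

make_block <- function(n = 12, features = c("A", "B", "C"),
                       channels = fixture_channels4, seed = 1) {
  set.seed(seed)
  structure(list(values = array(rnorm(n * 2 * length(features) *
                                        length(channels)),
                                c(n, 2, length(features), length(channels))),
                 feature_names = features, channel_names = channels),
            class = "feature_block")
}

test_that("fitted scalers standardise the training split exactly", {
  block <- make_block()
  layout <- build_grid_layout(fixture_channels4)
  stats <- fit_scaler(block, layout)
  std <- apply_scaler(block, stats)
  for (f in 1:3) for (ch in 1:4) {
    v <- as.vector(std$values[, , f, ch])
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(sd(v) - 1), 1e-10)
  }
})

test_that("constant columns standardise to zero with a warning", {
  block <- make_block()
  block$values[, , 2, 3] <- 4.2
  layout <- build_grid_layout(fixture_channels4)
  expect_warning(stats <- fit_scaler(block, layout), "constant")
  std <- apply_scaler(block, stats)
  expect_true(all(std$values[, , 2, 3] == 0))
})

test_that("scaler statistics depend only on the training rows", {
  block <- make_block(n = 20)
  layout <- build_grid_layout(fixture_channels4)
  tr <- p3dseize:::subset_block(block, 1:10)
  s1 <- fit_scaler(tr, layout)
  # swapping the held-out rows never changes the fitted stats
  block2 <- block
  block2$values[11:20, , , ] <- block2$values[20:11, , , ] * 3
  s2 <- fit_scaler(p3dseize:::subset_block(block2, 1:10), layout)
  expect_identical(s1, s2)
  # held-out rows standardised with training stats are generally off-centre
  te <- apply_scaler(p3dseize:::subset_block(block, 11:20), s1)
  expect_gt(max(abs(apply(te$values, 3:4, mean))), 1e-3)
})

test_that("scalers refuse mismatched blocks", {
  block <- make_block()
  layout <- build_grid_layout(fixture_channels4)
  stats <- fit_scaler(block, layout)
  other <- make_block(features = c("X", "Y", "Z"))
  expect_error(apply_scaler(other, stats), "different feature")
})

test_that("tensors carry each electrode to its named cell", {
  block <- make_block()
  layout <- build_grid_layout(fixture_channels4)
  ts <- assemble_tensor_set(block, layout, rep(0:1, 6))
  expect_equal(dim(ts$data), c(12, 2, 3, 4, 7))
  # round trip: the mapped cell holds exactly the block value
  for (ch in seq_along(block$channel_names)) {
    rc <- layout$mapping[[block$channel_names[ch]]]
    expect_equal(ts$data[, , , rc[1], rc[2]], block$values[, , , ch])
  }
  # empty cells are exactly zero
  for (rc in layout$empty_cells) {
    expect_true(all(ts$data[, , , rc[1], rc[2]] == 0))
  }
})

test_that("channel order in the block does not change the tensors", {
  block <- make_block()
  layout <- build_grid_layout(fixture_channels4)
  perm <- c(3, 1, 4, 2)
  block_p <- structure(list(values = block$values[, , , perm],
                            feature_names = block$feature_names,
                            channel_names = block$channel_names[perm]),
                       class = "feature_block")
  t1 <- assemble_tensor(block, layout)
  t2 <- assemble_tensor(block_p, layout)
  expect_equal(t1$data, t2$data)
})

test_that("differing steps yield differing tensor slices", {
  block <- make_block()
  layout <- build_grid_layout(fixture_channels4)
  ts <- assemble_tensor(block, layout)
  expect_false(isTRUE(all.equal(ts$data[1, 1, , , ], ts$data[1, 2, , , ])))
})

test_that("a block missing a step is rejected", {
  block <- make_block()
  block$values <- block$values[, 1, , , drop = FALSE]
  layout <- build_grid_layout(fixture_channels4)
  expect_error(assemble_tensor(block, layout), "both time steps")
})
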