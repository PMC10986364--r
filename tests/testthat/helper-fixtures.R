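# Small synthetic fixtures shared across test files.

fixture_channels4 <- c("FC3", "FC4", "CP3", "CP4")

# 4-channel recording with one onset at the end: 100 preictal and 50
# interictal windows under the default labelling.
fixture_recording <- function(seed = 11, duration_s = 1200,
                              matched_dynamics = FALSE,
                              preictal_noise = 10) {
  pre <- if (matched_dynamics) {
    synth_dynamics(sine_freq_hz = 10, sine_amp = 10,
                   noise_amp = preictal_noise, noise_color_exponent = 1)
  } else {
    synth_dynamics(sine_freq_hz = 8, sine_amp = 40,
                   noise_amp = preictal_noise, noise_color_exponent = 0.5)
  }
  cfg <- synth_config(n_channels = 4, channel_names = fixture_channels4,
                      duration_s = duration_s,
                      seizure_onsets_s = duration_s,
                      preictal_dynamics = pre, seed = seed)
  suppressWarnings(generate_recording(cfg))
}

# Balanced small window set + feature block on the 4-channel fixture.
fixture_feature_block <- function(seed = 11, features = c("HFD", "ApEn")) {
  rec <- fixture_recording(seed)
  ws <- balance_classes(label_windows(bandpass_filter(rec)), seed = seed)
  block <- extract_feature_block(split_steps(ws), feature_names = features)
  list(ws = ws, block = block)
}

# Tiny labelled tensor set with a class-mean shift, for model training tests.
fixture_tensor_set <- function(n = 80, shift = 1, seed = 42,
                               shape = c(3, 4, 7)) {
  set.seed(seed)
  data <- array(stats::rnorm(n * 2 * prod(shape), sd = 0.5),
                c(n, 2, shape))
  lab <- rep(0:1, each = n / 2)
  data[lab == 1, , , , ] <- data[lab == 1, , , , ] + shift
  structure(list(data = data, labels = lab,
                 feature_names = paste0("f", seq_len(shape[1])),
                 layout = NULL),
            class = "tensor_set")
}

tiny_model_config <- function(...) {
  model_config("small", grid_shape = c(3, 2, 3),
               p3d_channels = c(2, 2, 3, 3, 4, 4), convlstm_hidden = 3,
               attention_reduction = 2, head_hidden = 4, dropout = 0, ...)
}
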