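# Shared fixtures for the test suite: fast renderer/dynamics settings and a
# lazily trained classifier cached across test files (training is the
# expensive step; several end-to-end tests share one model).

fast_renderer <- function(...) {
  renderer_config(frame_size = 85, face_size = 75, ...)
}

noise_free_renderer <- function() {
  renderer_config(frame_size = 85, face_size = 75, noise_sd = 0,
                  jitter_px = 0, brightness_range = c(1, 1))
}

small_model_config <- function(n_classes = 3) {
  model_config(n_classes = n_classes, conv_filters = c(8, 16),
               dense_units = 32)
}

.model_cache <- new.env(parent = emptyenv())

# Classifier trained on ~2,000 simulator data points; cached for the session.
trained_model <- function() {
  if (!is.null(.model_cache$model)) return(.model_cache$model)
  dp <- simulate_training_datapoints(2300, renderer = fast_renderer(),
                                     seed = 101)
  tr <- subset_datapoints(dp, 1:2000)
  va <- subset_datapoints(dp, 2001:2300)
  m <- build_model(small_model_config(), seed = 7)
  m <- train_gaze_model(m, tr, va,
                        train_config(initial_lr = 1e-3, max_epochs = 12,
                                     seed = 5))
  .model_cache$model <- m
  m
}

# random label sequences for property tests
random_labels <- function(n) sample(gaze_levels(), n, replace = TRUE)
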