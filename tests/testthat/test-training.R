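ns <- asNamespace("adafnn")

test_that("class weights are inverse-frequency, normalized to sum 3", {
  expect_equal(compute_class_weights(rep(0:2, each = 5)), rep(1, 3))
  expect_equal(compute_class_weights(rep(0:2, c(3, 2, 1))),
               c(6 / 11, 9 / 11, 18 / 11), tolerance = 1e-12)
  set.seed(41)
  for (i in 1:20) {
    labs <- c(0:2, sample(0:2, 30, replace = TRUE))
    w <- compute_class_weights(labs)
    expect_equal(sum(w), 3, tolerance = 1e-9)
    expect_true(all(w > 0))
  }
  expect_error(compute_class_weights(c(0, 0, 1)), "every class")
})

test_that("weighted cross-entropy matches its closed form", {
  w <- c(1, 2, 0.5)
  expect_equal(weighted_cross_entropy(c(0, 1, 0) + c(1e-9, -2e-9, 1e-9), 1, w), 0,
               tolerance = 1e-6)
  expect_equal(weighted_cross_entropy(c(0.25, 0.5, 0.25), 1, w), 2 * log(2),
               tolerance = 1e-12)
  # linear in the weight
  l1 <- weighted_cross_entropy(c(0.2, 0.5, 0.3), 2, c(1, 1, 1))
  l2 <- weighted_cross_entropy(c(0.2, 0.5, 0.3), 2, c(1, 1, 2))
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  # balanced weights reduce to plain cross-entropy
  expect_equal(weighted_cross_entropy(c(0.2, 0.5, 0.3), 1, rep(1, 3)),
               -log(0.5), tolerance = 1e-12)
  expect_warning(
    expect_equal(weighted_cross_entropy(c(1 - 2e-13, 1e-13, 1e-13), 1, w,
                                        floor = 1e-12),
                 -2 * log(1e-12), tolerance = 1e-6),
    "clamped")
})

test_that("a frozen optimizer stops right after the patience window", {
  d <- tiny_fts(n = 9, J = 12, F_ = 1, seed = 2)
  spec <- adafnn_spec(K = 1, F = 1, micro_hidden = c(3, 2), mlp_hidden = c(4, 3),
                      dropout = 0)
  cfg <- training_config(learning_rate = 0, max_epochs = 50, patience = 1,
                         seed = 1, reg = reg_config())
  m <- train_model(d, spec, cfg)
  expect_equal(nrow(m$history), 2)
  expect_equal(m$best_epoch, 1)
})

test_that("training is bit-reproducible under a fixed seed", {
  d <- tiny_fts(n = 12, J = 16, F_ = 2, seed = 3)
  spec <- adafnn_spec(K = 2, F = 2, micro_hidden = c(4, 3), mlp_hidden = c(6, 4),
                      dropout = 0)
  cfg <- training_config(max_epochs = 12, patience = 11, seed = 7,
                         reg = reg_config(lambda1 = 0.1, lambda2 = 0.05,
                                          kR1 = 2, kR2 = 2))
  m1 <- train_model(d, spec, cfg)
  m2 <- train_model(d, spec, cfg)
  expect_identical(ns$flatten_params(m1$params), ns$flatten_params(m2$params))
  expect_identical(m1$history, m2$history)
})

test_that("training with dropout and penalties is also reproducible", {
  d <- tiny_fts(n = 12, J = 16, F_ = 2, seed = 3)
  spec <- adafnn_spec(K = 2, F = 2, micro_hidden = c(4, 3), mlp_hidden = c(6, 4),
                      dropout = 0.2)
  cfg <- training_config(max_epochs = 8, patience = 7, seed = 9,
                         reg = reg_config(lambda1 = 0.2, lambda2 = 0.1,
                                          kR1 = 1, kR2 = 2))
  expect_identical(train_model(d, spec, cfg)$history,
                   train_model(d, spec, cfg)$history)
})

test_that("class weights and early stopping never see the validation carve-out", {
  set.seed(44)
  d <- tiny_fts(n = 40, J = 12, F_ = 1, seed = 5)
  spec <- adafnn_spec(K = 1, F = 1, micro_hidden = c(3, 2), mlp_hidden = c(4, 3),
                      dropout = 0)
  cfg <- training_config(max_epochs = 3, patience = 2, seed = 11, reg = reg_config())
  m <- train_model(d, spec, cfg)
  tr_idx <- setdiff(seq_len(n_trials(d)), m$val_idx)
  expect_equal(m$class_weights, compute_class_weights(d$labels[tr_idx]))
  # the carve-out is stratified and non-trivial
  expect_gt(length(m$val_idx), 0)
  expect_true(all(table(d$labels[m$val_idx]) >= 1))
})

test_that("an over-capacity model fits a clean separable study", {
  bumps <- data.frame(channel = c(1L, 1L), class = c(1L, 2L),
                      center = c(0.3, 0.7), width = 0.07, amplitude = 1.5)
  spec_s <- synthetic_spec(n_per_class = c(12L, 12L, 12L), J = 64L, F = 2L,
                           bumps = bumps, facial_channels = 1L, bio_channels = 2L,
                           noise_sd = 0, pad_fraction_range = c(0, 0), seed = 6)
  d <- generate_trials(spec_s)$data
  spec <- adafnn_spec(K = 2, F = 2, micro_hidden = c(8, 4), mlp_hidden = c(16, 8),
                      dropout = 0, layer_norm_basis = FALSE)
  cfg <- training_config(max_epochs = 200, patience = 199, seed = 2,
                         reg = reg_config())
  m <- train_model(d, spec, cfg)
  acc <- mean(predict(m, d)$labels == d$labels)
  expect_gte(acc, 0.95)
})

test_that("non-finite parameters raise a numerical-state error naming the layer", {
  g <- time_grid(12)
  spec <- adafnn_spec(K = 2, F = 1, micro_hidden = c(3, 2), mlp_hidden = c(4, 3))
  m <- init_model(spec, g, seed = 7)
  m_bad <- m
  m_bad$params$basis[[1]][[2]]$W3[1] <- NaN
  expect_error(evaluate_bases(m_bad), "channel 1, basis 2")
  m_bad2 <- m
  m_bad2$params$out$W[] <- Inf
  expect_error(forward(m_bad2, array(rnorm(2 * 12), c(2, 12, 1))),
               "non-finite")
})

test_that("a degenerate one-option grid is returned as tuned, with a full CV table", {
  d <- tiny_fts(n = 18, J = 16, F_ = 2, seed = 8)
  grid <- hyperparam_grid(activation_pairs = list(c("tanh", "relu")),
                          K_options = 2L,
                          micro_width_options = list(c(3L, 2L)),
                          mlp_shape_options = list(c(4L, 3L)),
                          lambda1_levels = 0.1, lambda2_levels = 0,
                          kR1_options = 1L, kR2_options = 2L,
                          dropout_options = 0)
  cfg <- training_config(max_epochs = 5, patience = 4, reg = reg_config())
  res <- tune_hyperparameters(d, grid, base_cfg = cfg, n_folds = 3, seed = 4)
  expect_equal(res$best$spec_args$K, 2L)
  expect_equal(res$best$reg_args$lambda1, 0.1)
  expect_true(is.finite(res$best$cv_weighted_f1))
  # one row per evaluated configuration per fold (3 stages x 1 config x 3 folds)
  expect_equal(nrow(res$cv_table), 3 * 3)
  expect_equal(sort(unique(res$cv_table$fold)), 1:3)
})

test_that("tuning prefers at least two bases when one projection cannot separate", {
  bumps <- data.frame(channel = c(1L, 1L, 1L), class = c(1L, 2L, 2L),
                      center = c(0.3, 0.3, 0.7), width = 0.06,
                      amplitude = 1.5, jitter_sd = c(0.5, 0.5, 0))
  spec_s <- synthetic_spec(n_per_class = c(30L, 30L, 30L), J = 64L, F = 2L,
                           bumps = bumps, facial_channels = 1L, bio_channels = 2L,
                           noise_sd = 0.3, pad_fraction_range = c(0, 0), seed = 5)
  d <- generate_trials(spec_s)$data
  grid <- hyperparam_grid(activation_pairs = list(c("tanh", "relu")),
                          K_options = c(1L, 2L, 4L),
                          micro_width_options = list(c(8L, 4L)),
                          mlp_shape_options = list(c(16L, 8L)),
                          lambda1_levels = 0, lambda2_levels = 0,
                          kR1_options = 1L, kR2_options = 2L,
                          dropout_options = 0)
  cfg <- training_config(max_epochs = 150, patience = 149, reg = reg_config())
  res <- tune_hyperparameters(d, grid, base_cfg = cfg, seed = 3)
  expect_gte(res$best$spec_args$K, 2L)
})
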