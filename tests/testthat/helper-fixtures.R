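# Shared fixtures.  Heavy objects (the default synthetic study and the
# models trained on it) are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# the default synthetic study (the generator's shipped conditions)
default_study <- function() memo("default_study", generate_trials(synthetic_spec(seed = 11)))

# shipped desk-scale model/training configuration
small_model_spec <- function(F_) {
  def <- configuration_defaults("synthetic_small")
  do.call(adafnn_spec, c(def$spec_args, list(F = F_)))
}

small_train_config <- function(seed) {
  def <- configuration_defaults("synthetic_small")
  training_config(seed = seed, reg = do.call(reg_config, def$reg_args))
}

# one trained model per (channel-subset, run seed); shared between the
# synthetic-recovery and localization acceptance checks
trained_synthetic_model <- function(channels_key, run) {
  memo(sprintf("model_%s_%d", channels_key, run), {
    g <- default_study()
    d <- g$data
    chans <- switch(channels_key,
                    fused = seq_len(n_channels(d)),
                    facial = g$truth$facial_channels,
                    bio = g$truth$bio_channels)
    dc <- fts_channels(d, chans)
    sp <- stratified_split(d$labels, 0.7, seed = 100 + run)
    m <- train_model(fts_subset(dc, sp$train), small_model_spec(n_channels(dc)),
                     small_train_config(seed = run))
    pred <- predict(m, fts_subset(dc, sp$test))
    y <- d$labels[sp$test]
    list(model = m, accuracy = mean(pred$labels == y),
         weighted_f1 = weighted_f1(y, pred$labels),
         auc = one_vs_rest_auc(y, pred$probs))
  })
}

# quick random trial set for plumbing tests
tiny_fts <- function(n = 6, J = 16, F_ = 2, seed = 1) {
  set.seed(seed)
  fts(array(rnorm(n * J * F_), c(n, J, F_)), time_grid(J),
      labels = rep(0:2, length.out = n))
}
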