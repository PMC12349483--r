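#' Inverse-frequency class weights
#'
#' Weights \eqn{w_c \propto 1/N_c} computed from training labels and
#' normalized so that \eqn{\sum_c w_c = 3}, making misclassification of
#' rare (high-risk) classes costlier than of the majority class.
#'
#' @param labels Integer labels in `{0, 1, 2}`; every class must occur.
#' @return Numeric 3-vector of positive weights summing to 3.
#' @examples
#' compute_class_weights(rep(0:2, c(3, 2, 1)))  # 6/11, 9/11, 18/11
#' @export
compute_class_weights <- function(labels) {
  labels <- as.integer(labels)
  counts <- tabulate(labels + 1L, nbins = 3L)
  if (any(counts == 0L)) {
    stop("every class in {0,1,2} must be present to define class weights",
         call. = FALSE)
  }
  w <- 1 / counts
  3 * w / sum(w)
}

#' Weighted cross-entropy loss for one prediction
#'
#' \eqn{L = -w_c \log \hat p_c} for true class \eqn{c}.  Probabilities
#' below `floor` are clamped (with a warning) to avoid log underflow.
#'
#' @param probs Probability 3-vector (positive, summing to ~1).
#' @param label True class in `{0, 1, 2}`.
#' @param weights Class-weight 3-vector (see [compute_class_weights()]).
#' @param floor Probability clamp (default `1e-12`).
#' @return Non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(probs, label, weights, floor = 1e-12) {
  stopifnot(length(probs) == 3L, length(weights) == 3L, label %in% 0:2)
  if (any(probs <= 0) || abs(sum(probs) - 1) > 1e-6) {
    stop("`probs` must be positive and sum to 1", call. = FALSE)
  }
  p <- probs[label + 1L]
  if (p < floor) {
    warning("predicted probability clamped at the floor to avoid log underflow",
            call. = FALSE)
    p <- floor
  }
  -weights[label + 1L] * log(p)
}

#' Training configuration
#'
#' Optimization defaults: Adam with learning rate `1e-4`,
#' \eqn{\beta_1 = 0.9}, \eqn{\beta_2 = 0.999}; at most 500 epochs with
#' early stopping once the validation loss has not improved (by at least
#' `min_delta`) for `patience = 20` consecutive epochs; dropout 20% in
#' the classifier.  A stratified `val_fraction` share of the training
#' trials is carved out for early-stopping validation; those trials never
#' contribute to gradient updates or class-weight computation.
#'
#' @param learning_rate Adam learning rate.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs), must be `< max_epochs`.
#' @param min_delta Minimum decrease in validation loss that counts as an
#'   improvement.
#' @param dropout_rate Classifier dropout rate (overrides the model spec
#'   during training when not `NULL`).
#' @param batch_size Minibatch size; sets exceeding it are split into
#'   shuffled minibatches, tiny sets fall back to full batch.
#' @param val_fraction Fraction of training trials held out for
#'   early-stopping validation.
#' @param seed Seed for initialization, shuffling and dropout.
#' @param reg A [reg_config()] (or `NULL` for unpenalized training).
#' @return A `training_config` object.
#' @export
training_config <- function(learning_rate = 1e-4, adam_beta1 = 0.9,
                            adam_beta2 = 0.999, max_epochs = 500L,
                            patience = 20L, min_delta = 1e-6,
                            dropout_rate = NULL, batch_size = 32L,
                            val_fraction = 0.15, seed = 1L,
                            reg = reg_config()) {
  stopifnot(learning_rate >= 0, max_epochs >= 1L, patience >= 1L,
            patience < max_epochs, batch_size >= 1L,
            val_fraction > 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 dropout_rate = dropout_rate, batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 reg = reg),
            class = "training_config")
}

# stratified carve-out of a validation subset (indices into 1..n)
stratified_holdout <- function(labels, fraction) {
  idx_val <- integer(0)
  for (c_ in sort(unique(labels))) {
    pool <- which(labels == c_)
    n_val <- max(1L, floor(fraction * length(pool) + 0.5))
    n_val <- min(n_val, length(pool) - 1L)
    idx_val <- c(idx_val, sample(pool, n_val))
  }
  sort(idx_val)
}

#' Train a model by weighted cross-entropy with early stopping
#'
#' Optimizes all micro-network and classifier parameters jointly (the
#' gradient flows end-to-end through the trapezoid inner products) by
#' Adam on the penalized objective
#' \eqn{L = \mathrm{weightedCE} + \lambda_1 R_1 + \lambda_2 R_2}.
#' Class weights are computed on the gradient-training portion only.
#' Training stops at `max_epochs` or when the validation loss fails to
#' improve for `patience` consecutive epochs; the validation loss is the
#' same objective evaluated on the held-out validation trials, with the
#' penalties computed exhaustively (no subsampling) so it is
#' deterministic.  The returned parameters are those of the
#' best-validation epoch.
#'
#' @param data An [fts()] containing all three classes.
#' @param spec An [adafnn_spec()] with `F = n_channels(data)`.
#' @param cfg A [training_config()].
#' @return A trained `adafnn_model` carrying `history` (per-epoch train /
#'   validation losses), `class_weights`, `best_epoch`, and the index of
#'   the internal validation trials (`val_idx`).
#' @export
train_model <- function(data, spec, cfg = training_config()) {
  stopifnot(inherits(data, "fts"), inherits(spec, "adafnn_spec"),
            inherits(cfg, "training_config"))
  if (spec$F != n_channels(data)) {
    stop("spec$F must equal the number of channels in `data`", call. = FALSE)
  }
  labels <- data$labels
  if (length(unique(labels)) < 3L) {
    stop("training data must contain all three classes", call. = FALSE)
  }
  if (!is.null(cfg$dropout_rate)) spec$dropout <- cfg$dropout_rate
  grid <- data$grid
  reg <- cfg$reg
  use_reg <- !is.null(reg) && (reg$lambda1 > 0 || reg$lambda2 > 0)
  if (use_reg && (reg$kR1 > spec$K || reg$kR2 > spec$K)) {
    stop("kR1/kR2 cannot exceed K", call. = FALSE)
  }

  set.seed(cfg$seed)
  val_idx <- stratified_holdout(labels, cfg$val_fraction)
  tr_idx <- setdiff(seq_len(n_trials(data)), val_idx)
  Xtr <- data$values[tr_idx, , , drop = FALSE]; ytr <- labels[tr_idx]
  Xva <- data$values[val_idx, , , drop = FALSE]; yva <- labels[val_idx]
  class_w <- compute_class_weights(ytr)

  params <- init_params(spec)
  skeleton <- params
  theta <- flatten_params(params)
  opt <- adam_init(length(theta))
  sub_stream <- new_rng_stream(if (use_reg) reg$subsample_seed + cfg$seed else 0L)

  n_tr <- length(ytr)
  bs <- if (n_tr <= cfg$batch_size * 1.5) n_tr else cfg$batch_size
  best_loss <- Inf; best_theta <- theta; best_epoch <- 0L; wait <- 0L
  hist_tr <- hist_va <- numeric(0)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = bs)
    ep_loss <- 0
    for (s in starts) {
      bidx <- ord[s:min(s + bs - 1L, n_tr)]
      params <- unflatten_params(theta, skeleton)
      masks <- NULL
      if (spec$dropout > 0) {
        masks <- lapply(spec$mlp_hidden, function(d) {
          matrix(stats::rbinom(length(bidx) * d, 1L, 1 - spec$dropout),
                 length(bidx), d)
        })
      }
      reg_idx <- if (use_reg) {
        with_stream(sub_stream, draw_reg_indices(spec$K, spec$F, reg))
      }
      lg <- loss_and_grads(params, spec, grid,
                           Xtr[bidx, , , drop = FALSE], ytr[bidx], class_w,
                           reg = if (use_reg) reg, reg_idx = reg_idx,
                           train = TRUE, dropout_masks = masks)
      if (!is.finite(lg$loss)) {
        stop(sprintf("training loss diverged (non-finite) at epoch %d", epoch),
             call. = FALSE)
      }
      st <- adam_step(opt, theta, flatten_params(lg$grads), cfg$learning_rate,
                      cfg$adam_beta1, cfg$adam_beta2)
      opt <- st$state; theta <- st$theta
      ep_loss <- ep_loss + lg$loss * length(bidx)
    }
    hist_tr[epoch] <- ep_loss / n_tr

    # validation loss is the full training objective evaluated on the held-out
    # trials: weighted CE plus the penalties (exhaustive, so deterministic) --
    # symmetric with what the optimizer minimizes
    params <- unflatten_params(theta, skeleton)
    B <- eval_bases_internal(params, spec, grid)$B
    Cva <- coefficients_internal(Xva, B, grid)
    pva <- head_forward(params, spec, Cva)$probs
    pv <- pmax(pva[cbind(seq_along(yva), yva + 1L)], 1e-12)
    val_loss <- mean(class_w[yva + 1L] * (-log(pv)))
    if (use_reg) {
      ex <- exhaustive_reg_indices(spec$K, spec$F)
      if (reg$lambda1 > 0) val_loss <- val_loss +
          reg$lambda1 * r1_value_grad(B, grid, ex$r1)$value
      if (reg$lambda2 > 0) val_loss <- val_loss +
          reg$lambda2 * r2_value_grad(B, grid, ex$r2)$value
    }
    hist_va[epoch] <- val_loss

    if (best_loss - val_loss >= cfg$min_delta) {
      best_loss <- val_loss; best_theta <- theta; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }

  model <- structure(
    list(spec = spec, grid = grid,
         params = unflatten_params(best_theta, skeleton), seed = cfg$seed,
         history = data.frame(epoch = seq_along(hist_tr),
                              train_loss = hist_tr, val_loss = hist_va),
         class_weights = class_w, best_epoch = best_epoch,
         val_idx = val_idx, config = cfg),
    class = "adafnn_model")
  model
}
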