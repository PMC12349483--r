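#' Hyper-parameter search grid
#'
#' The two-stage search space: stage 1 compares activation pairs
#' (micro-network activation, classifier activation); stage 2, with the
#' winning pair fixed, searches capacity (number of bases `K`,
#' micro-network widths, classifier widths — small/medium/large style
#' option lists), then regularization (`lambda1 x lambda2` joint grid,
#' `kR1`/`kR2` subsample sizes and dropout rate).
#'
#' @param activation_pairs List of 2-vectors `c(micro, mlp)`.
#' @param K_options Candidate numbers of bases per channel.
#' @param micro_width_options List of 2-vectors of micro-network widths.
#' @param mlp_shape_options List of 2-vectors of classifier widths.
#' @param lambda1_levels,lambda2_levels Candidate penalty strengths.
#' @param kR1_options,kR2_options Candidate subsample counts.
#' @param dropout_options Candidate dropout rates.
#' @return A `hyperparam_grid` object.
#' @export
hyperparam_grid <- function(activation_pairs = list(c("tanh", "relu"),
                                                    c("tanh", "selu"),
                                                    c("relu", "relu"),
                                                    c("selu", "selu")),
                            K_options = c(2L, 4L, 6L),
                            micro_width_options = list(c(8L, 4L), c(16L, 8L), c(32L, 16L)),
                            mlp_shape_options = list(c(16L, 8L), c(32L, 16L), c(64L, 32L)),
                            lambda1_levels = c(0, 0.1, 0.3),
                            lambda2_levels = c(0, 0.05, 0.1),
                            kR1_options = 2L, kR2_options = 2L,
                            dropout_options = c(0, 0.10, 0.20)) {
  stopifnot(length(activation_pairs) >= 1L, length(K_options) >= 1L,
            length(micro_width_options) >= 1L, length(mlp_shape_options) >= 1L,
            length(lambda1_levels) >= 1L, length(lambda2_levels) >= 1L,
            length(dropout_options) >= 1L)
  structure(list(activation_pairs = activation_pairs, K_options = K_options,
                 micro_width_options = micro_width_options,
                 mlp_shape_options = mlp_shape_options,
                 lambda1_levels = lambda1_levels, lambda2_levels = lambda2_levels,
                 kR1_options = kR1_options, kR2_options = kR2_options,
                 dropout_options = dropout_options),
            class = "hyperparam_grid")
}

# per-fold weighted F1 of one candidate configuration under stratified k-fold CV
cv_weighted_f1 <- function(data, spec, cfg, fold) {
  k <- max(fold)
  f1s <- numeric(k)
  for (f_ in seq_len(k)) {
    tr <- which(fold != f_); te <- which(fold == f_)
    if (length(unique(data$labels[tr])) < 3L ||
        length(unique(data$labels[te])) < 1L) {
      stop("fold with a missing class", call. = FALSE)
    }
    model <- train_model(fts_subset(data, tr), spec, cfg)
    pred <- predict(model, fts_subset(data, te))
    f1s[f_] <- weighted_f1(data$labels[te], pred$labels)
  }
  f1s
}

#' Two-stage hyper-parameter tuning by stratified cross-validation
#'
#' Stage 1 fixes the activation pair that maximizes mean weighted F1
#' under stratified `n_folds`-fold cross-validation (all other settings
#' at the grid's middle options).  Stage 2 searches capacity
#' (`K`, micro widths, classifier widths), then regularization
#' (`lambda1 x lambda2` jointly, with `kR1`, `kR2`, dropout), each time
#' selecting the smallest configuration whose mean weighted F1 lies
#' within `plateau_tol` of the best ("smallest configuration within the
#' plateau"); candidates are ordered by parameter count so "smallest" is
#' well defined.
#'
#' @param train_set An [fts()] (the training subset; at least 3 trials
#'   per class for 3-fold CV).
#' @param grid A [hyperparam_grid()].
#' @param base_cfg A [training_config()] supplying optimizer settings.
#' @param n_folds CV folds (default 3).
#' @param plateau_tol Weighted-F1 tolerance defining the plateau
#'   (default 0.005).
#' @param seed Seed for fold assignment and training.
#' @return A list with `best` (list: `spec_args` and `reg_args` of the
#'   selected configuration, plus its CV score) and `cv_table` (one row
#'   per evaluated configuration and fold-average).
#' @export
tune_hyperparameters <- function(train_set, grid = hyperparam_grid(),
                                 base_cfg = training_config(), n_folds = 3L,
                                 plateau_tol = 0.005, seed = 1L) {
  stopifnot(inherits(train_set, "fts"), inherits(grid, "hyperparam_grid"))
  labels <- train_set$labels
  if (any(tabulate(labels + 1L, 3L) < n_folds)) {
    stop("each class needs at least `n_folds` trials for stratified CV",
         call. = FALSE)
  }
  fold <- with_preserved_rng(seed, make_folds(labels, n_folds))
  F_ <- n_channels(train_set)
  mid <- function(lst) lst[[ceiling(length(lst) / 2)]]
  midv <- function(v) v[ceiling(length(v) / 2)]

  cv_rows <- list()
  score <- function(acts, K, micro, mlp, l1, l2, kR1, kR2, dropout, stage) {
    spec <- adafnn_spec(K = K, F = F_, micro_hidden = micro,
                        micro_activation = acts[1L], mlp_hidden = mlp,
                        mlp_activation = acts[2L], dropout = dropout)
    cfg <- base_cfg
    cfg$seed <- as.integer(seed)
    cfg$reg <- reg_config(lambda1 = l1, lambda2 = l2,
                          kR1 = max(1L, min(kR1, K)),
                          kR2 = if (l2 > 0) min(max(kR2, 2L), max(K, 2L)) else max(kR2, 2L))
    f1s <- cv_weighted_f1(train_set, spec, cfg, fold)
    cv_rows[[length(cv_rows) + 1L]] <<- data.frame(
      stage = stage, micro_act = acts[1L], mlp_act = acts[2L], K = K,
      micro = paste(micro, collapse = "x"), mlp = paste(mlp, collapse = "x"),
      lambda1 = l1, lambda2 = l2, kR1 = kR1, kR2 = kR2, dropout = dropout,
      fold = seq_along(f1s), weighted_f1 = f1s)
    mean(f1s)
  }

  # stage 1: activation pair at middle capacity, no penalties
  s1 <- vapply(grid$activation_pairs, function(ap) {
    score(ap, midv(grid$K_options), mid(grid$micro_width_options),
          mid(grid$mlp_shape_options), 0, 0, midv(grid$kR1_options),
          midv(grid$kR2_options), midv(grid$dropout_options), "activations")
  }, numeric(1L))
  acts <- grid$activation_pairs[[which.max(s1)]]

  # stage 2a: capacity, coarse-to-fine over (K, micro, mlp) triples ordered
  # by parameter count; smallest configuration within the plateau wins
  caps <- expand.grid(iK = seq_along(grid$K_options),
                      im = seq_along(grid$micro_width_options),
                      ip = seq_along(grid$mlp_shape_options))
  n_par <- function(K, micro, mlp) {
    F_ * K * (2 * micro[1L] + micro[1L] * micro[2L] + 2 * micro[2L] + 2) +
      (F_ * K) * mlp[1L] + mlp[1L] * mlp[2L] + 3 * mlp[2L]
  }
  caps$size <- mapply(function(iK, im, ip) {
    n_par(grid$K_options[iK], grid$micro_width_options[[im]],
          grid$mlp_shape_options[[ip]])
  }, caps$iK, caps$im, caps$ip)
  caps <- caps[order(caps$size), ]
  cap_scores <- mapply(function(iK, im, ip) {
    score(acts, grid$K_options[iK], grid$micro_width_options[[im]],
          grid$mlp_shape_options[[ip]], 0, 0, midv(grid$kR1_options),
          midv(grid$kR2_options), midv(grid$dropout_options), "capacity")
  }, caps$iK, caps$im, caps$ip)
  in_plateau <- which(cap_scores >= max(cap_scores) - plateau_tol)
  pick <- in_plateau[1L]   # rows already ordered smallest-first
  K <- grid$K_options[caps$iK[pick]]
  micro <- grid$micro_width_options[[caps$im[pick]]]
  mlp <- grid$mlp_shape_options[[caps$ip[pick]]]

  # stage 2b: regularization (lambda1 x lambda2 joint) + kR + dropout
  regs <- expand.grid(l1 = grid$lambda1_levels, l2 = grid$lambda2_levels,
                      kR1 = grid$kR1_options, kR2 = grid$kR2_options,
                      dropout = grid$dropout_options)
  reg_scores <- mapply(function(l1, l2, kR1, kR2, dropout) {
    score(acts, K, micro, mlp, l1, l2, kR1, kR2, dropout, "regularization")
  }, regs$l1, regs$l2, regs$kR1, regs$kR2, regs$dropout)
  best_r <- which.max(reg_scores)

  cv_table <- do.call(rbind, cv_rows)
  list(
    best = list(
      spec_args = list(K = K, F = F_, micro_hidden = micro,
                       micro_activation = acts[1L], mlp_hidden = mlp,
                       mlp_activation = acts[2L], dropout = regs$dropout[best_r]),
      reg_args = list(lambda1 = regs$l1[best_r], lambda2 = regs$l2[best_r],
                      kR1 = regs$kR1[best_r], kR2 = regs$kR2[best_r]),
      cv_weighted_f1 = reg_scores[best_r]
    ),
    cv_table = cv_table,
    activation_scores = data.frame(
      micro_act = vapply(grid$activation_pairs, `[`, "", 1L),
      mlp_act = vapply(grid$activation_pairs, `[`, "", 2L),
      mean_weighted_f1 = s1)
  )
}
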