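#' Empirical distance correlation
#'
#' The standard empirical distance correlation between two samples:
#' pairwise Euclidean distance matrices are double-centred and the
#' normalized inner product of the centred matrices is returned.  Lies in
#' \eqn{[0, 1]}; zero signals (empirical) independence.  Used as the
#' screening statistic that ranks candidate functional predictors against
#' the current model residuals.
#'
#' @param x,y Numeric vectors or matrices with the same number of rows
#'   (observations).
#' @return Scalar in \eqn{[0, 1]}.  If either sample is constant (zero
#'   distance variance) the value is defined as 0, with a warning.
#' @export
distance_correlation <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (nrow(y) != n) stop("samples must have equal size", call. = FALSE)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  dc <- function(m) {
    d <- as.matrix(stats::dist(m))
    d - outer(rowMeans(d), colMeans(d), "+") + mean(d)
  }
  A <- dc(x); B <- dc(y)
  dcov2 <- mean(A * B)
  vx <- mean(A * A); vy <- mean(B * B)
  if (vx <= .Machine$double.eps || vy <= .Machine$double.eps) {
    warning("constant sample: distance correlation defined as 0", call. = FALSE)
    return(0)
  }
  sqrt(max(dcov2, 0) / sqrt(vx * vy))
}

#' B-spline basis coefficient features for one channel
#'
#' Projects each trial's curve on a fixed cubic B-spline basis (with
#' intercept, `K_sel` functions on \eqn{[0,1]}) by least squares.  This
#' fixed, data-independent expansion supplies the scalar features
#' \eqn{\xi_j} on which additive multinomial models are fitted during
#' selection.
#'
#' @param trials An [fts()].
#' @param channel Channel index (or name).
#' @param K_sel Number of spline basis functions (default 8, at least 4).
#' @return An `n x K_sel` feature matrix.
#' @export
expand_basis_coefficients <- function(trials, channel, K_sel = 8L) {
  stopifnot(inherits(trials, "fts"), K_sel >= 4L)
  if (is.character(channel)) channel <- match(channel, trials$channel_names)
  if (K_sel > trials$grid$J) {
    stop("K_sel exceeds the number of time points (rank-deficient design)",
         call. = FALSE)
  }
  t <- trials$grid$points
  Phi <- splines::bs(t, df = K_sel, degree = 3L, intercept = TRUE)
  Xf <- matrix(trials$values[, , channel], n_trials(trials), trials$grid$J)
  qr_ <- qr(Phi)
  t(qr.coef(qr_, t(Xf)))
}

#' Selection procedure configuration
#'
#' @param max_terms Maximum number of channels to select.
#' @param inner_folds Folds of the internal cross-validation used to
#'   score candidate models by out-of-sample multinomial deviance
#'   (default 5).
#' @param enter_threshold Minimum decrease in per-trial CV deviance for a
#'   forward addition to be accepted.  The default (0.02, about 1% of the
#'   three-class null deviance) sits above the fitting noise of the inner
#'   CV, so redundant channels — including exact duplicates — do not
#'   enter.
#' @param exit_threshold Maximum per-trial CV-deviance increase tolerated
#'   when removing an included channel in the backward step (a stand-in
#'   for a term-significance test).
#' @param K_sel Spline features per channel.
#' @param screen_top How many top-screened candidates are scored by CV at
#'   each forward step (screening uses distance correlation against the
#'   current residuals).
#' @return A `selection_config` object.
#' @export
selection_config <- function(max_terms = 10L, inner_folds = 5L,
                             enter_threshold = 0.02, exit_threshold = 0.02,
                             K_sel = 8L, screen_top = 3L) {
  stopifnot(inner_folds >= 2L, max_terms >= 1L)
  structure(list(max_terms = as.integer(max_terms),
                 inner_folds = as.integer(inner_folds),
                 enter_threshold = enter_threshold,
                 exit_threshold = exit_threshold,
                 K_sel = as.integer(K_sel),
                 screen_top = as.integer(screen_top)),
            class = "selection_config")
}

# stratified fold assignment
make_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (c_ in sort(unique(labels))) {
    pool <- sample(which(labels == c_))
    fold[pool] <- rep_len(seq_len(k), length(pool))
  }
  fold
}

# out-of-sample multinomial deviance (-2 log-lik of held-out trials) of a
# multinomial logistic model on the given feature matrix, averaged per trial
cv_multinomial_deviance <- function(feats, labels, fold) {
  k <- max(fold)
  dev <- 0
  for (f_ in seq_len(k)) {
    tr <- fold != f_; te <- !tr
    df_tr <- data.frame(y = factor(labels[tr], levels = 0:2), feats[tr, , drop = FALSE])
    fit <- nnet::multinom(y ~ ., data = df_tr, trace = FALSE, maxit = 200L,
                          decay = 1e-3)
    pr <- stats::predict(fit, newdata = data.frame(feats[te, , drop = FALSE]),
                         type = "probs")
    pr <- matrix(pr, nrow = sum(te))
    if (ncol(pr) < 3L) {     # binary fallback when a class is missing in a fold
      stop("fold with a missing class", call. = FALSE)
    }
    p_true <- pmax(pr[cbind(seq_len(sum(te)), labels[te] + 1L)], 1e-12)
    dev <- dev - 2 * sum(log(p_true))
  }
  dev / length(labels)
}

# residuals of the current multinomial fit (observed one-hot minus fitted
# probabilities), used as the screening target
current_residuals <- function(feats, labels) {
  n <- length(labels)
  Y <- matrix(0, n, 3L); Y[cbind(seq_len(n), labels + 1L)] <- 1
  if (is.null(feats) || ncol(feats) == 0L) {
    prev <- colMeans(Y)
    return(Y - matrix(prev, n, 3L, byrow = TRUE))
  }
  df <- data.frame(y = factor(labels, levels = 0:2), feats)
  fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 200L, decay = 1e-3)
  Y - matrix(stats::fitted(fit), n, 3L)
}

#' Forward-backward functional variable selection
#'
#' Greedy channel selection for multinomial classification, emulating the
#' behaviour of stepwise functional generalized additive model selectors:
#' at each forward step, the remaining candidate channels are ranked by
#' distance correlation between their spline coefficient features and the
#' residuals of the current fit; the top-ranked candidates are scored by
#' stratified `inner_folds`-fold cross-validated multinomial deviance,
#' and the best is added if it lowers the CV deviance by at least the
#' enter threshold.  After each addition, a backward sweep removes any
#' included channel whose removal does not raise the CV deviance beyond
#' the exit threshold.  The procedure stops when no addition qualifies or
#' `max_terms` is reached.
#'
#' @param trials An [fts()] (the training partition only; the selector
#'   never sees held-out data).
#' @param cfg A [selection_config()].
#' @param seed Seed controlling fold assignment (selection is
#'   deterministic given data and seed).
#' @return A list with `selected` (channel indices, in order of entry),
#'   `trace` (data frame of step, action, channel, CV deviance) and
#'   `null_deviance`.  An empty selection (no channel improves at step 1)
#'   is returned with a message, not an error.
#' @export
forward_backward_select <- function(trials, cfg = selection_config(), seed = 1L) {
  stopifnot(inherits(trials, "fts"))
  F_ <- n_channels(trials)
  if (F_ < 2L) stop("need at least 2 candidate channels", call. = FALSE)
  labels <- trials$labels
  if (length(unique(labels)) < 3L) stop("all classes must be present", call. = FALSE)

  feats_all <- lapply(seq_len(F_), function(f) {
    m <- expand_basis_coefficients(trials, f, cfg$K_sel)
    colnames(m) <- paste0("c", f, "_", seq_len(ncol(m)))
    m
  })
  with_preserved_rng(seed, {
    fold <- make_folds(labels, cfg$inner_folds)

    included <- integer(0)
    bind_feats <- function(idx) do.call(cbind, feats_all[idx])
    null_dev <- {
      n <- length(labels)
      prev <- tabulate(labels + 1L, 3L) / n
      -2 * sum(log(pmax(prev[labels + 1L], 1e-12))) / n
    }
    current_dev <- null_dev
    trace <- data.frame(step = 0L, action = "start", channel = NA_integer_,
                        cv_deviance = null_dev)
    step <- 0L
    repeat {
      if (length(included) >= cfg$max_terms) break
      remaining <- setdiff(seq_len(F_), included)
      if (length(remaining) == 0L) break
      res <- current_residuals(bind_feats(included), labels)
      screen <- vapply(remaining, function(f) {
        suppressWarnings(distance_correlation(feats_all[[f]], res))
      }, numeric(1L))
      cand <- remaining[order(screen, decreasing = TRUE)]
      cand <- cand[seq_len(min(cfg$screen_top, length(cand)))]
      devs <- vapply(cand, function(f) {
        cv_multinomial_deviance(bind_feats(c(included, f)), labels, fold)
      }, numeric(1L))
      best <- which.min(devs)
      if (current_dev - devs[best] < cfg$enter_threshold) {
        if (length(included) == 0L) {
          message("no channel improves the null model; returning empty selection")
        }
        break
      }
      included <- c(included, cand[best])
      current_dev <- devs[best]
      step <- step + 1L
      trace <- rbind(trace, data.frame(step = step, action = "add",
                                       channel = cand[best],
                                       cv_deviance = current_dev))
      # backward sweep
      repeat {
        if (length(included) < 2L) break
        drop_devs <- vapply(seq_along(included), function(i) {
          cv_multinomial_deviance(bind_feats(included[-i]), labels, fold)
        }, numeric(1L))
        i_best <- which.min(drop_devs)
        if (drop_devs[i_best] - current_dev <= cfg$exit_threshold) {
          removed <- included[i_best]
          included <- included[-i_best]
          current_dev <- drop_devs[i_best]
          step <- step + 1L
          trace <- rbind(trace, data.frame(step = step, action = "remove",
                                           channel = removed,
                                           cv_deviance = current_dev))
        } else break
      }
    }
    list(selected = included, trace = trace, null_deviance = null_dev)
  })
}
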