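#' Stratified train/test split
#'
#' Splits trial indices so that each class contributes
#' `round(train_fraction * N_c)` trials (round half up) to the training
#' set; any discrepancy against the rounded overall training size is
#' absorbed by the largest class.  Splits are disjoint and exhaustive.
#'
#' @param labels Integer labels in `{0, 1, 2}`; each class needs at least
#'   2 trials.
#' @param train_fraction Training share, strictly inside (0, 1);
#'   default 0.7.
#' @param seed Split seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  labels <- as.integer(labels)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly inside (0, 1)", call. = FALSE)
  }
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(c_) sum(labels == c_), integer(1L))
  if (any(counts < 2L)) stop("every class needs at least 2 trials", call. = FALSE)
  rhu <- function(x) floor(x + 0.5)
  n_tr <- rhu(train_fraction * counts)
  n_tr <- pmin(pmax(n_tr, 1L), counts - 1L)
  diff_total <- rhu(train_fraction * length(labels)) - sum(n_tr)
  if (diff_total != 0) {
    big <- which.max(counts)
    n_tr[big] <- min(max(n_tr[big] + diff_total, 1L), counts[big] - 1L)
  }
  train <- integer(0)
  with_preserved_rng(seed, {
    for (i in seq_along(classes)) {
      pool <- which(labels == classes[i])
      train <- c(train, sample(pool, n_tr[i]))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Prevalence-weighted F1 score
#'
#' \eqn{\sum_c (N_c/N) F1_c}, where \eqn{F1_c} is the harmonic mean of
#' class-`c` precision and recall on the 3-class confusion matrix.  A
#' class absent from `y_true` contributes zero weight; an undefined
#' per-class F1 (no true and no predicted members) counts as 0.
#'
#' @param y_true,y_pred Integer label vectors in `{0, 1, 2}`, same length.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
weighted_f1 <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop("label vectors must be non-empty and of equal length", call. = FALSE)
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  n <- length(y_true)
  out <- 0
  for (c_ in 0:2) {
    tp <- sum(y_true == c_ & y_pred == c_)
    fp <- sum(y_true != c_ & y_pred == c_)
    fn <- sum(y_true == c_ & y_pred != c_)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    out <- out + (sum(y_true == c_) / n) * f1
  }
  out
}

#' Macro-averaged one-vs-rest AUC
#'
#' For each class `c`, the area under the ROC curve of the predicted
#' probability of class `c` against the indicator `y == c`, computed by
#' the rank (Mann-Whitney) formulation with midranks for ties; the
#' unweighted mean over the three classes is returned.  Classes absent
#' from `y_true` are skipped with a warning.
#'
#' @param y_true Integer labels in `{0, 1, 2}`.
#' @param probs `n x 3` matrix of class probabilities (rows sum to ~1).
#' @return Scalar in \eqn{[0, 1]}.
#' @export
one_vs_rest_auc <- function(y_true, probs) {
  y_true <- as.integer(y_true)
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == length(y_true), ncol(probs) == 3L)
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  aucs <- numeric(0)
  for (c_ in 0:2) {
    pos <- y_true == c_
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L) {
      warning(sprintf("class %d absent from y_true; skipped in AUC average", c_),
              call. = FALSE)
      next
    }
    if (n0 == 0L) {
      warning(sprintf("class %d is the only class present; skipped", c_),
              call. = FALSE)
      next
    }
    r <- rank(probs[, c_ + 1L], ties.method = "average")
    aucs <- c(aucs, (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  mean(aucs)
}

#' ROC curve coordinates for one class (one-vs-rest)
#'
#' @param y_ind Logical/0-1 indicator of the positive class.
#' @param scores Numeric scores (higher = more positive).
#' @return A data frame with columns `fpr` and `tpr`, ordered from (0,0)
#'   to (1,1).
#' @export
roc_curve <- function(y_ind, scores) {
  y_ind <- as.logical(y_ind)
  ord <- order(scores, decreasing = TRUE)
  y <- y_ind[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(diff(s) != 0, TRUE)     # one point per distinct threshold
  data.frame(fpr = c(0, fp[keep] / max(1, sum(!y_ind))),
             tpr = c(0, tp[keep] / max(1, sum(y_ind))))
}

#' Classifier adapters for the evaluation harness
#'
#' [repeated_evaluation()] is model-agnostic: it consumes a classifier
#' adapter, a list with a `fit(train_fts, seed)` function returning a
#' fitted object and a `predict(fit, test_fts)` function returning an
#' `n x 3` probability matrix.  `adafnn_classifier()` adapts the adaptive
#' functional network; `majority_classifier()` is a degenerate baseline
#' that always predicts the training majority class (useful for protocol
#' checks).
#'
#' @param spec An [adafnn_spec()] (its `F` must match the data).
#' @param cfg A [training_config()]; its seed is overridden by the
#'   per-run seed supplied by the harness.
#' @return A classifier adapter list.
#' @export
adafnn_classifier <- function(spec, cfg = training_config()) {
  list(
    fit = function(train, seed) {
      cfg$seed <- as.integer(seed)
      train_model(train, spec, cfg)
    },
    predict = function(fit, test) predict(fit, test)$probs
  )
}

#' @rdname adafnn_classifier
#' @export
majority_classifier <- function() {
  list(
    fit = function(train, seed) {
      counts <- tabulate(train$labels + 1L, 3L)
      which.max(counts) - 1L
    },
    predict = function(fit, test) {
      p <- matrix(1e-6, n_trials(test), 3L)
      p[, fit + 1L] <- 1 - 2e-6
      p
    }
  )
}

#' Repeated stratified-split evaluation
#'
#' The evaluation protocol: `n_runs` independent stratified 70/30 splits
#' (run `r` uses split seed `base_seed + r`), each run training on its
#' training subset only and scoring accuracy, prevalence-weighted F1 and
#' macro one-vs-rest AUC on its held-out test subset.  Metrics are
#' aggregated as mean and sample SD.  The ROC curves (per class) of the
#' run with the highest weighted F1 are retained.  A leakage audit
#' records the train/test index sets of every run; `leakage_overlap`
#' counts indices appearing in both sets of the same run (always 0 unless
#' the protocol is broken).
#'
#' @param data An [fts()].
#' @param classifier A classifier adapter (see [adafnn_classifier()]).
#' @param n_runs Number of independent splits (paper-scale default 100).
#' @param base_seed Base seed of the split schedule; configurations being
#'   compared must share it so runs are paired.
#' @param train_fraction Training share per split.
#' @return A `repeated_eval` list: `runs` (per-run metric data frame),
#'   `summary` (mean/sd per metric), `best_run`, `roc_best` (per-class
#'   ROC coordinates of the best-F1 run), `splits`, `leakage_overlap`,
#'   and `failed` (indices of failed runs, excluded with a notice).
#' @export
repeated_evaluation <- function(data, classifier, n_runs = 100L,
                                base_seed = 7L, train_fraction = 0.7) {
  stopifnot(inherits(data, "fts"), n_runs >= 1L)
  labels <- data$labels
  runs <- vector("list", n_runs)
  splits <- vector("list", n_runs)
  roc_best <- NULL; best_f1 <- -Inf; best_run <- NA_integer_
  failed <- integer(0)
  for (r in seq_len(n_runs)) {
    sp <- stratified_split(labels, train_fraction, seed = base_seed + r)
    splits[[r]] <- sp
    res <- tryCatch({
      fit <- classifier$fit(fts_subset(data, sp$train), seed = base_seed + r)
      probs <- classifier$predict(fit, fts_subset(data, sp$test))
      y <- labels[sp$test]
      pred <- max.col(probs, ties.method = "first") - 1L
      list(accuracy = mean(pred == y),
           weighted_f1 = weighted_f1(y, pred),
           auc = one_vs_rest_auc(y, probs),
           probs = probs, y = y)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("run %d failed and is excluded: %s", r, conditionMessage(res)))
      failed <- c(failed, r)
      next
    }
    runs[[r]] <- data.frame(run = r, seed = base_seed + r,
                            accuracy = res$accuracy,
                            weighted_f1 = res$weighted_f1, auc = res$auc)
    if (res$weighted_f1 > best_f1) {
      best_f1 <- res$weighted_f1; best_run <- r
      roc_best <- lapply(0:2, function(c_) roc_curve(res$y == c_, res$probs[, c_ + 1L]))
      names(roc_best) <- paste0("class", 0:2)
    }
  }
  runs <- do.call(rbind, runs[!vapply(runs, is.null, logical(1L))])
  metrics <- c("accuracy", "weighted_f1", "auc")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(runs[[m]]), numeric(1L)),
    sd = vapply(metrics, function(m) {
      if (nrow(runs) < 2L) NA_real_ else stats::sd(runs[[m]])
    }, numeric(1L)),
    row.names = NULL
  )
  overlap <- sum(vapply(splits, function(sp) length(intersect(sp$train, sp$test)),
                        integer(1L)))
  structure(list(runs = runs, summary = summary, best_run = best_run,
                 roc_best = roc_best, splits = splits,
                 leakage_overlap = overlap, failed = failed,
                 base_seed = base_seed),
            class = "repeated_eval")
}

#' @export
print.repeated_eval <- function(x, ...) {
  cat(sprintf("<repeated_eval> %d runs (base seed %d)%s\n", nrow(x$runs),
              x$base_seed,
              if (length(x$failed)) sprintf(", %d failed", length(x$failed)) else ""))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.4f +/- %s\n", s$metric[i], s$mean[i],
                ifelse(is.na(s$sd[i]), "NA", sprintf("%.4f", s$sd[i]))))
  }
  invisible(x)
}

#' Normality-gated paired comparison of two metric series
#'
#' Compares paired per-run metric vectors from two configurations
#' evaluated on the same split schedule.  Each vector is first tested for
#' normality with the Shapiro-Wilk test at level `alpha`; if both pass, a
#' two-sided paired t-test is used, otherwise the Wilcoxon signed-rank
#' test on the paired differences (average-tie handling, normal
#' approximation at large n).  All-zero differences yield a degenerate
#' "no difference" result.
#'
#' @param metrics_a,metrics_b Equal-length paired numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @return A `comparison_result` list: per-vector Shapiro-Wilk p-values,
#'   `test_used` (`"paired_t"` or `"wilcoxon_signed_rank"`), `statistic`,
#'   `p_value`, and the `decision` at `alpha`.
#' @export
compare_configurations <- function(metrics_a, metrics_b, alpha = 0.05) {
  stopifnot(length(metrics_a) == length(metrics_b), length(metrics_a) >= 3L)
  d <- metrics_a - metrics_b
  if (all(d == 0)) {
    return(structure(list(normality_p = c(a = NA_real_, b = NA_real_),
                          test_used = "degenerate", statistic = NA_real_,
                          p_value = 1, decision = "no difference",
                          alpha = alpha),
                     class = "comparison_result"))
  }
  sw_p <- function(x) {
    if (length(unique(x)) < 3L) return(0)        # degenerate: treat as non-normal
    stats::shapiro.test(x)$p.value
  }
  pa <- sw_p(metrics_a); pb <- sw_p(metrics_b)
  if (pa > alpha && pb > alpha) {
    tt <- stats::t.test(metrics_a, metrics_b, paired = TRUE)
    test_used <- "paired_t"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(metrics_a, metrics_b,
                                              paired = TRUE, exact = FALSE))
    test_used <- "wilcoxon_signed_rank"
    statistic <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(normality_p = c(a = pa, b = pb), test_used = test_used,
                 statistic = statistic, p_value = p,
                 decision = if (p < alpha) "reject equal means" else "fail to reject",
                 alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, p = %.4g -> %s (alpha = %g)\n",
              x$test_used, x$statistic, x$p_value, x$decision, x$alpha))
  invisible(x)
}
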