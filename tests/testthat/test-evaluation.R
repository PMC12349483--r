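test_that("stratified splits honour per-class rounding and determinism", {
  labels <- rep(0:2, c(20, 10, 10))
  sp <- stratified_split(labels, 0.7, seed = 1)
  tr_counts <- table(factor(labels[sp$train], levels = 0:2))
  expect_equal(as.integer(tr_counts), c(14, 7, 7))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))

  expect_identical(stratified_split(labels, 0.7, seed = 9),
                   stratified_split(labels, 0.7, seed = 9))
  sp2 <- stratified_split(labels, 0.7, seed = 10)
  expect_false(identical(sp$train, sp2$train))
  tr2 <- table(factor(labels[sp2$train], levels = 0:2))
  expect_equal(as.integer(tr2), c(14, 7, 7))      # proportions preserved

  expect_error(stratified_split(labels, 1.0), "strictly inside")
  expect_error(stratified_split(labels, 0), "strictly inside")
  expect_error(stratified_split(c(0, 0, 1, 2, 2), 0.7), "at least 2")
})

test_that("weighted F1 matches hand values and the confusion-matrix oracle", {
  expect_equal(weighted_f1(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  # degenerate always-0 predictor on balanced truths: (1/3) * 0.5
  y <- rep(0:2, each = 4)
  expect_equal(weighted_f1(y, rep(0, 12)), 1 / 6, tolerance = 1e-12)

  set.seed(61)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    yt <- sample(0:2, n, replace = TRUE)
    yp <- sample(0:2, n, replace = TRUE)
    expect_equal(weighted_f1(yt, yp), oracle_weighted_f1(yt, yp),
                 tolerance = 1e-12)
  }
  expect_error(weighted_f1(integer(0), integer(0)), "non-empty")
})

test_that("one-vs-rest AUC is the midrank Mann-Whitney statistic averaged over classes", {
  # perfectly ordered probabilities
  y <- c(0, 0, 1, 1, 2, 2)
  p <- matrix(0.05, 6, 3); p[cbind(1:6, y + 1)] <- 0.9
  expect_equal(one_vs_rest_auc(y, p), 1)

  # label-independent probabilities: near 1/2 at n = 3000
  set.seed(62)
  n <- 3000
  yt <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  pr <- matrix(rexp(3 * n), n, 3); pr <- pr / rowSums(pr)
  expect_lt(abs(one_vs_rest_auc(yt, pr) - 0.5), 0.03)

  # pairwise-concordance oracle at n = 50, with ties present
  for (i in 1:5) {
    yt <- sample(0:2, 50, replace = TRUE)
    pr <- matrix(sample(seq(0.1, 0.9, 0.1), 150, replace = TRUE), 50, 3)
    pr <- pr / rowSums(pr)
    expect_equal(one_vs_rest_auc(yt, pr), oracle_ovr_auc(yt, pr),
                 tolerance = 1e-12)
  }

  # class absent from the truth: skipped with a warning
  expect_warning(v <- one_vs_rest_auc(c(0, 0, 1, 1), matrix(1 / 3, 4, 3)),
                 "absent")
  expect_equal(v, 0.5)
  expect_error(one_vs_rest_auc(c(0, 1), matrix(c(1, 1, 1, 1, 1, 1), 2, 3)), "sum")
})

test_that("perfect predictions maximize accuracy, weighted F1 and AUC together", {
  y <- rep(0:2, c(5, 3, 2))
  p <- matrix(0.01, 10, 3); p[cbind(1:10, y + 1)] <- 0.98
  pred <- max.col(p) - 1L
  expect_equal(mean(pred == y), 1)
  expect_equal(weighted_f1(y, pred), 1)
  expect_equal(one_vs_rest_auc(y, p), 1)
})

test_that("roc_curve runs from (0,0) to (1,1) and is monotone", {
  set.seed(63)
  y <- rbinom(40, 1, 0.4)
  s <- rnorm(40) + y
  rc <- roc_curve(y, s)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("repeated evaluation of the majority baseline reflects stratified prevalence", {
  spec_s <- synthetic_spec(J = 20L, F = 2L,
                           bumps = data.frame(channel = integer(0),
                                              class = integer(0),
                                              center = numeric(0),
                                              width = numeric(0),
                                              amplitude = numeric(0)),
                           facial_channels = 1L, bio_channels = 2L,
                           noise_sd = 0.3, pad_fraction_range = c(0, 0),
                           seed = 8)
  d <- generate_trials(spec_s)$data       # 120/60/42 labels
  ev <- repeated_evaluation(d, majority_classifier(), n_runs = 10, base_seed = 3)
  acc <- ev$summary$mean[ev$summary$metric == "accuracy"]
  expect_equal(acc, 120 / 222, tolerance = 0.02)
  expect_equal(ev$leakage_overlap, 0)
  expect_length(ev$failed, 0)

  # single run: SD undefined
  ev1 <- repeated_evaluation(d, majority_classifier(), n_runs = 1, base_seed = 3)
  expect_true(all(is.na(ev1$summary$sd)))

  # identical base seed -> identical summary
  ev2 <- repeated_evaluation(d, majority_classifier(), n_runs = 10, base_seed = 3)
  expect_identical(ev$summary, ev2$summary)
})

test_that("configuration comparison gates the test on Shapiro-Wilk normality", {
  set.seed(64)
  a <- rnorm(100, 0.6, 0.04)

  # constant shift with tiny difference noise: paired t rejects decisively
  b <- a + 0.05 + rnorm(100, 0, 1e-3)
  r <- compare_configurations(b, a)
  expect_equal(r$test_used, "paired_t")
  expect_lt(r$p_value, 1e-10)
  expect_equal(r$decision, "reject equal means")

  # identical vectors: degenerate, no difference
  r0 <- compare_configurations(a, a)
  expect_equal(r0$decision, "no difference")
  expect_equal(r0$p_value, 1)

  # heavy-tailed contamination sends the comparison down the Wilcoxon branch
  b2 <- a + rcauchy(100, 0, 0.05)
  r2 <- compare_configurations(a, b2)
  expect_equal(r2$test_used, "wilcoxon_signed_rank")
})
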