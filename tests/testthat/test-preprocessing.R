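test_that("landmark displacement reproduces Euclidean frame-to-frame distances", {
  # fixed landmark -> zero displacement
  coords <- array(0, c(5, 3, 2))
  coords[, , 1] <- 2; coords[, , 2] <- -1
  expect_equal(landmark_displacement_series(coords), matrix(0, 4, 3))

  # 3-4-5 right triangle step
  coords <- array(0, c(2, 1, 2))
  coords[2, 1, ] <- c(3, 4)
  expect_equal(landmark_displacement_series(coords)[1, 1], 5)

  # reversing the frame order leaves each distance unchanged
  set.seed(5)
  coords <- array(rnorm(6 * 4 * 2), c(6, 4, 2))
  fwd <- landmark_displacement_series(coords)
  rev_ <- landmark_displacement_series(coords[6:1, , , drop = FALSE])
  expect_equal(fwd, rev_[5:1, , drop = FALSE], tolerance = 1e-12)

  expect_error(landmark_displacement_series(coords[1, , , drop = FALSE]), "two frames")
})

test_that("moving-average downsampling averages full blocks and drops leftovers", {
  expect_equal(downsample_moving_average(matrix(1:10), 10)[1, 1], 5.5)
  expect_equal(downsample_moving_average(matrix(7, 30, 2), 10),
               matrix(7, 3, 2))
  # first block is the mean of samples 1..10, second of 11..20
  y <- matrix(rnorm(25), 25, 1)
  out <- downsample_moving_average(y, 10)
  expect_equal(nrow(out), 2)           # 5 leftover samples dropped
  expect_equal(out[1, 1], mean(y[1:10, 1]))
  expect_equal(out[2, 1], mean(y[11:20, 1]))
  expect_error(downsample_moving_average(matrix(1:5), 10), "shorter")
})

test_that("downsampling conserves block means and inverts constant repetition", {
  set.seed(6)
  v <- rnorm(12)
  raw <- matrix(rep(v, each = 10), ncol = 1)
  expect_equal(downsample_moving_average(raw, 10)[, 1], v, tolerance = 1e-12)
  y <- matrix(rnorm(47), ncol = 1)
  out <- downsample_moving_average(y, 5)
  expect_equal(mean(out), mean(y[1:45, ]), tolerance = 1e-12)
})

test_that("zero-padding appends exactly the missing rows", {
  trials <- list(matrix(1, 5282, 1), matrix(2, 5100, 1))
  p <- pad_trials(trials, 5300)
  expect_equal(dim(p$values), c(2, 5300, 1))
  expect_equal(sum(!p$pad_mask[1, ]), 18)
  expect_equal(sum(p$values[1, 5283:5300, ]), 0)
  expect_equal(sum(p$values[2, 5101:5300, ]), 0)

  # trial already at target length is unchanged, mask all-true
  q <- pad_trials(list(matrix(3, 7, 2)), 7)
  expect_true(all(q$pad_mask))
  expect_equal(q$values[1, , ], matrix(3, 7, 2))

  expect_error(pad_trials(list(matrix(0, 10, 1)), 8), "longer")
})

test_that("Tukey fences flag gross outliers and nothing in degenerate series", {
  expect_false(any(tukey_outlier_flags(rep(4.2, 10))))
  flags <- tukey_outlier_flags(c(1:8, 1000))
  expect_identical(which(flags), 9L)
  # type-7 quartiles of 1..8,1000: check the bound arithmetic directly
  q <- quantile(c(1:8, 1000), c(0.25, 0.75), type = 7, names = FALSE)
  expect_true(1000 > q[2] + 1.5 * (q[2] - q[1]))
  expect_error(tukey_outlier_flags(c(1, 2, 3)), "at least 4")
})

test_that("Tukey flag rate on a standard normal sample is near the theoretical 0.7%", {
  set.seed(12)
  x <- rnorm(10000)
  rate <- mean(tukey_outlier_flags(x))
  # theoretical fence-crossing rate for the normal is 2*P(Z > 2.698) = 0.70%
  expect_gt(rate, 0.003)
  expect_lt(rate, 0.013)
})

test_that("configuration assembly produces the documented channel blocks", {
  n <- 4; J <- 12; L <- 5
  set.seed(7)
  facial <- array(rnorm(n * J * L), c(n, J, L))
  bio <- array(rnorm(n * J * 2), c(n, J, 2))
  g <- time_grid(J)
  labs <- c(0, 1, 2, 0)

  full <- assemble_configuration(facial, bio, dataset_configuration("full_fusion"),
                                 g, labs)
  expect_equal(n_channels(full), L + 2)
  expect_equal(full$values[, , L + 1], bio[, , 1])       # bio block after facial
  expect_equal(full$channel_names[(L + 1):(L + 2)], c("ECG", "EDA"))

  sel <- assemble_configuration(facial, bio,
                                dataset_configuration("selected_facial_plus_bio",
                                                      selected_indices = c(2, 4)),
                                g, labs)
  expect_equal(n_channels(sel), 4)
  expect_equal(sel$values[, , 1], facial[, , 2])

  bio_only <- assemble_configuration(NULL, bio, dataset_configuration("bio_only"),
                                     g, labs)
  expect_equal(n_channels(bio_only), 2)

  facial_only <- assemble_configuration(facial, NULL,
                                        dataset_configuration("facial_only"), g, labs)
  expect_equal(n_channels(facial_only), L)

  expect_error(dataset_configuration("selected_facial"), "selected_indices")
  expect_error(assemble_configuration(facial, bio,
                                      dataset_configuration("selected_facial",
                                                            selected_indices = 9),
                                      g, labs),
               "out of range")
  expect_error(assemble_configuration(facial[, 1:6, , drop = FALSE], bio,
                                      dataset_configuration("full_fusion"), g, labs),
               "share")
})

test_that("delimited readers parse biosignal and landmark files", {
  dir <- withr::local_tempdir()
  bio <- data.frame(ECG = rnorm(30), EDA = runif(30))
  write.table(bio, file.path(dir, "b.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  rec <- read_biosignal(file.path(dir, "b.tsv"))
  expect_equal(dim(rec$samples), c(30, 2))
  expect_equal(rec$samples[, 1], bio$ECG, tolerance = 1e-12)
  expect_equal(rec$rate, 300)

  # headerless variant
  write.table(bio, file.path(dir, "b2.tsv"), sep = "\t", row.names = FALSE,
              col.names = FALSE)
  expect_equal(read_biosignal(file.path(dir, "b2.tsv"))$samples[, 2], bio$EDA,
               tolerance = 1e-12)

  lm <- expand.grid(frame = 1:4, landmark_id = 1:3)
  lm$x <- rnorm(12); lm$y <- rnorm(12)
  write.table(lm, file.path(dir, "l.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  coords <- read_landmarks(file.path(dir, "l.tsv"))
  expect_equal(dim(coords), c(4, 3, 2))
  expect_equal(coords[2, 3, 1], lm$x[lm$frame == 2 & lm$landmark_id == 3],
               tolerance = 1e-12)
})
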