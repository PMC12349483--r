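ns <- asNamespace("adafnn")

test_that("a zeroed micro-network yields a constant basis at its output bias", {
  spec <- adafnn_spec(K = 1, F = 1, micro_hidden = c(4, 3))
  m <- init_model(spec, time_grid(20), seed = 1)
  net <- m$params$basis[[1]][[1]]
  net$W1[] <- 0; net$b1[] <- 0; net$W2[] <- 0; net$b2[] <- 0
  net$W3[] <- 0; net$b3 <- 2.5
  m$params$basis[[1]][[1]] <- net
  B <- evaluate_bases(m)
  expect_equal(as.numeric(B[1, 1, ]), rep(2.5, 20))
})

test_that("tanh micro-networks give bases bounded by the output-layer L1 norm", {
  set.seed(21)
  for (i in 1:20) {
    spec <- adafnn_spec(K = 2, F = 1, micro_hidden = c(6, 4))
    m <- init_model(spec, time_grid(33), seed = i)
    # randomize all parameters beyond the structured init
    m$params$basis <- lapply(m$params$basis, function(ch) lapply(ch, function(net) {
      lapply(net, function(p) p + rnorm(length(p)))
    }))
    B <- evaluate_bases(m)
    for (k in 1:2) {
      net <- m$params$basis[[1]][[k]]
      expect_lte(max(abs(B[1, k, ])), sum(abs(net$W3)) + abs(net$b3) + 1e-12)
    }
  }
})

test_that("coefficients follow the channel-major trapezoid projection", {
  g <- time_grid(25)
  spec <- adafnn_spec(K = 3, F = 2, micro_hidden = c(4, 3))
  m <- init_model(spec, g, seed = 2)
  B <- evaluate_bases(m)

  # all-zero trial -> zero coefficient vector
  expect_equal(as.numeric(compute_coefficients(matrix(0, 25, 2), B, g)),
               rep(0, 6))

  # unit basis against unit curve integrates to one
  B1 <- array(1, c(1, 1, 25))
  expect_equal(compute_coefficients(matrix(1, 25, 1), B1, g)[1, 1], 1)

  # random batch against the per-entry trapezoid oracle, channel-major layout
  set.seed(22)
  X <- array(rnorm(4 * 25 * 2), c(4, 25, 2))
  C <- compute_coefficients(X, B, g)
  expect_equal(dim(C), c(4, 6))
  for (i in 1:4) for (f in 1:2) for (k in 1:3) {
    expect_equal(C[i, (f - 1) * 3 + k],
                 oracle_trapezoid(B[f, k, ], X[i, , f], g$points),
                 tolerance = 1e-12)
  }
  expect_error(compute_coefficients(matrix(0, 10, 2), B, g), "length")
})

test_that("forward pass produces normalized, deterministic probabilities", {
  g <- time_grid(15)
  spec <- adafnn_spec(K = 2, F = 2, micro_hidden = c(4, 3), dropout = 0.5)
  m <- init_model(spec, g, seed = 3)
  set.seed(30)
  X <- array(rnorm(5 * 15 * 2), c(5, 15, 2))

  p <- forward(m, X)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p > 0))
  # eval mode has no stochastic layers: bitwise repeatable
  expect_identical(p, forward(m, X))

  # zeroed output layer -> uniform class probabilities
  m0 <- m
  m0$params$out$W[] <- 0; m0$params$out$b[] <- 0
  expect_equal(forward(m0, X), matrix(1 / 3, 5, 3), tolerance = 1e-12)

  # batch forward equals the per-trial loop
  rows <- t(vapply(1:5, function(i) forward(m, X[i, , ])[1, ], numeric(3)))
  expect_equal(rows, p, tolerance = 1e-12)
})

test_that("prediction takes the argmax with ties to the lowest class", {
  g <- time_grid(15)
  spec <- adafnn_spec(K = 2, F = 1, micro_hidden = c(4, 3))
  m <- init_model(spec, g, seed = 4)
  d <- fts(array(rnorm(3 * 15 * 1), c(3, 15, 1)), g, labels = c(0, 1, 2))
  pr <- predict(m, d)
  expect_equal(pr$labels, max.col(pr$probs, ties.method = "first") - 1L)

  # exact three-way tie resolves to class 0
  m$params$out$W[] <- 0; m$params$out$b[] <- 0
  expect_equal(predict(m, d)$labels, rep(0L, 3))
  expect_error(predict(m, fts_subset(d, integer(0))), "trial")
})

test_that("coefficient layout round-trips through reshape", {
  g <- time_grid(12)
  spec <- adafnn_spec(K = 4, F = 3, micro_hidden = c(4, 3))
  m <- init_model(spec, g, seed = 5)
  B <- evaluate_bases(m)
  set.seed(23)
  x <- matrix(rnorm(12 * 3), 12, 3)
  C <- compute_coefficients(x, B, g)
  M <- matrix(C[1, ], nrow = 4)      # K x F, channel-major columns
  for (f in 1:3) for (k in 1:4) {
    expect_equal(M[k, f], oracle_trapezoid(B[f, k, ], x[, f], g$points),
                 tolerance = 1e-12)
  }
})

test_that("permuting channels together with their basis banks and head rows is a no-op", {
  g <- time_grid(18)
  K <- 2; F_ <- 3
  spec <- adafnn_spec(K = K, F = F_, micro_hidden = c(4, 3))
  m <- init_model(spec, g, seed = 6)
  set.seed(24)
  X <- array(rnorm(4 * 18 * F_), c(4, 18, F_))
  p0 <- forward(m, X)

  perm <- c(3, 1, 2)
  coef_perm <- as.vector(vapply(perm, function(f) (f - 1) * K + seq_len(K),
                                numeric(K)))
  m2 <- m
  m2$params$basis <- m$params$basis[perm]
  m2$params$ln0$gamma <- m$params$ln0$gamma[coef_perm]
  m2$params$ln0$beta <- m$params$ln0$beta[coef_perm]
  m2$params$head[[1]]$W <- m$params$head[[1]]$W[coef_perm, , drop = FALSE]
  m2$params$head[[1]]$P <- m$params$head[[1]]$P[coef_perm, , drop = FALSE]
  p1 <- forward(m2, X[, , perm, drop = FALSE])
  expect_equal(p1, p0, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences end to end", {
  set.seed(25)
  spec <- adafnn_spec(K = 2, F = 2, micro_hidden = c(4, 3),
                      micro_activation = "tanh", mlp_hidden = c(5, 4),
                      mlp_activation = "tanh", dropout = 0)
  grid <- time_grid(16)
  params <- ns$with_preserved_rng(7, ns$init_params(spec))
  X <- array(rnorm(5 * 16 * 2), c(5, 16, 2))
  y <- c(0, 1, 2, 1, 0)
  w <- compute_class_weights(y)
  reg <- reg_config(lambda1 = 0.4, lambda2 = 0.3, kR1 = 2, kR2 = 2)
  idx <- ns$with_preserved_rng(8, ns$draw_reg_indices(2, 2, reg))

  lg <- ns$loss_and_grads(params, spec, grid, X, y, w, reg = reg, reg_idx = idx)
  theta <- ns$flatten_params(params)
  f <- function(th) ns$loss_and_grads(ns$unflatten_params(th, params), spec, grid,
                                      X, y, w, reg = reg, reg_idx = idx)$loss
  # small step: the steep first-layer weights of the interval init make the
  # O(h^2) truncation term the dominant finite-difference error
  g_num <- ns$numeric_gradient(f, theta, h = 1e-7)
  g_an <- ns$flatten_params(lg$grads)
  rel <- abs(g_an - g_num) / pmax(1, abs(g_an) + abs(g_num))
  expect_lt(max(rel), 1e-5)
})

test_that("checkpoints round-trip parameters and architecture", {
  g <- time_grid(14)
  spec <- adafnn_spec(K = 2, F = 2, micro_hidden = c(4, 3))
  m <- init_model(spec, g, seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$spec, m$spec)
  expect_identical(ns$flatten_params(m2$params), ns$flatten_params(m$params))
  X <- array(rnorm(2 * 14 * 2), c(2, 14, 2))
  expect_identical(forward(m, X), forward(m2, X))
})
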