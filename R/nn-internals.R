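# Internal neural-network machinery: activations, layer normalization,
# forward caches, analytic backpropagation, parameter (un)flattening and
# the Adam optimizer.  Everything here is deterministic given its inputs;
# all randomness (init, dropout, shuffling, penalty subsampling) is drawn
# by the callers.

act_fun <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(s, a) 1 - a^2),
    relu = list(f = function(s) pmax(s, 0), df = function(s, a) (s > 0) * 1),
    selu = {
      alpha <- 1.6732632423543772; lambda <- 1.0507009873554805
      list(
        f = function(s) lambda * ifelse(s > 0, s, alpha * (exp(s) - 1)),
        df = function(s, a) lambda * ifelse(s > 0, 1, alpha * exp(pmin(s, 0)))
      )
    },
    stop("unknown activation: ", name, call. = FALSE)
  )
}

# add a bias row-vector to every row of a matrix (column-major trick)
add_bias <- function(M, b) M + rep(b, each = nrow(M))

LN_EPS <- 1e-5

layer_norm_forward <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  y <- add_bias(xhat * rep(gamma, each = nrow(x)), beta)
  list(y = y, xhat = xhat, inv = inv)
}

layer_norm_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(gamma, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- parameter initialization -------------------------------------------

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# Localized-interval-feature initialization.  Layer 1 units are steep tanh
# transitions at sorted random points of [0,1]; layer 2 takes differences of
# adjacent transitions, so its units respond on random subintervals (soft
# indicator functions), analogous to spreading spline knots over the domain.
# The linear output layer starts near zero: initial bases are tiny random
# combinations of local features, and training only has to re-weight local
# features rather than reshape the network, which is what makes the L1
# sparsity penalty able to carve localized bases within the epoch budget.
init_micro_net <- function(hidden) {
  h1 <- hidden[1L]; h2 <- hidden[2L]
  centers <- sort(stats::runif(h1))
  steep <- stats::runif(h1, 20, 40)
  W2 <- matrix(0, h1, h2)
  for (j in seq_len(h2)) {
    i <- 1L + ((j - 1L) %% max(h1 - 1L, 1L))
    W2[i, j] <- 2
    if (i + 1L <= h1) W2[i + 1L, j] <- -2
  }
  list(
    W1 = matrix(steep, 1L, h1),
    b1 = -steep * centers,
    W2 = W2 + matrix(stats::rnorm(h1 * h2, 0, 0.01), h1, h2),
    b2 = numeric(h2),
    W3 = matrix(stats::runif(h2, -0.005, 0.005), h2, 1L),
    b3 = numeric(1L)
  )
}

init_params <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- spec$K; F_ <- spec$F; D <- K * F_
  basis <- lapply(seq_len(F_), function(f) {
    lapply(seq_len(K), function(k) init_micro_net(spec$micro_hidden))
  })
  dims <- c(D, spec$mlp_hidden)
  layers <- lapply(seq_along(spec$mlp_hidden), function(l) {
    din <- dims[l]; dout <- dims[l + 1L]
    lay <- list(W = glorot(din, dout), b = numeric(dout))
    if (spec$layer_norm_mlp) { lay$gamma <- rep(1, dout); lay$beta <- numeric(dout) }
    if (spec$residual && din != dout) lay$P <- glorot(din, dout)
    lay
  })
  params <- list(basis = basis, head = layers,
                 out = list(W = glorot(dims[length(dims)], spec$n_classes),
                            b = numeric(spec$n_classes)))
  if (spec$layer_norm_basis) params$ln0 <- list(gamma = rep(1, D), beta = numeric(D))
  params
}

# ---- basis evaluation ----------------------------------------------------

micro_net_forward <- function(net, tm, af) {
  s1 <- add_bias(tm %*% net$W1, net$b1); a1 <- af$f(s1)
  s2 <- add_bias(a1 %*% net$W2, net$b2); a2 <- af$f(s2)
  out <- drop(a2 %*% net$W3) + net$b3
  list(s1 = s1, a1 = a1, s2 = s2, a2 = a2, out = out)
}

# returns list(B = F x K x J array, caches = per-channel per-basis activations)
eval_bases_internal <- function(params, spec, grid, keep_cache = FALSE) {
  J <- grid$J; tm <- matrix(grid$points, J, 1L)
  af <- act_fun(spec$micro_activation)
  B <- array(0, c(spec$F, spec$K, J))
  caches <- if (keep_cache) vector("list", spec$F)
  for (f in seq_len(spec$F)) {
    if (keep_cache) caches[[f]] <- vector("list", spec$K)
    for (k in seq_len(spec$K)) {
      fw <- micro_net_forward(params$basis[[f]][[k]], tm, af)
      if (any(!is.finite(fw$out))) {
        stop(sprintf("non-finite basis values in micro-network (channel %d, basis %d)", f, k),
             call. = FALSE)
      }
      B[f, k, ] <- fw$out
      if (keep_cache) caches[[f]][[k]] <- fw
    }
  }
  list(B = B, caches = caches)
}

micro_net_backward <- function(net, cache, g, tm, af) {
  # g: J-vector of dL/d out(t_j)
  gm <- matrix(g, ncol = 1L)
  dW3 <- crossprod(cache$a2, gm)
  db3 <- sum(g)
  da2 <- gm %*% t(net$W3)
  ds2 <- da2 * af$df(cache$s2, cache$a2)
  dW2 <- crossprod(cache$a1, ds2)
  db2 <- colSums(ds2)
  da1 <- ds2 %*% t(net$W2)
  ds1 <- da1 * af$df(cache$s1, cache$a1)
  dW1 <- crossprod(tm, ds1)
  db1 <- colSums(ds1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

# ---- coefficients --------------------------------------------------------

# X: n x J x F array, B: F x K x J -> n x (K*F) channel-major coefficients
coefficients_internal <- function(X, B, grid) {
  n <- dim(X)[1L]; J <- dim(X)[2L]; F_ <- dim(B)[1L]; K <- dim(B)[2L]
  C <- matrix(0, n, K * F_)
  w <- grid$weights
  for (f in seq_len(F_)) {
    Bf <- matrix(B[f, , ], K, J)              # K x J
    Xf <- matrix(X[, , f], n, J)              # n x J
    C[, (f - 1L) * K + seq_len(K)] <- Xf %*% (t(Bf) * w)
  }
  C
}

# ---- classifier head -----------------------------------------------------

head_forward <- function(params, spec, C, train = FALSE, dropout_masks = NULL,
                         keep_cache = FALSE) {
  af <- act_fun(spec$mlp_activation)
  cache <- list()
  z <- C
  if (spec$layer_norm_basis) {
    ln0 <- layer_norm_forward(z, params$ln0$gamma, params$ln0$beta)
    cache$ln0 <- ln0
    z <- ln0$y
  }
  cache$z <- list(z)   # z[[l]] = input to layer l
  for (l in seq_along(params$head)) {
    lay <- params$head[[l]]
    s <- add_bias(z %*% lay$W, lay$b)
    a <- af$f(s)
    lc <- list(s = s, a = a)
    if (spec$layer_norm_mlp) {
      ln <- layer_norm_forward(a, lay$gamma, lay$beta)
      lc$ln <- ln
      a <- ln$y
    }
    if (train && spec$dropout > 0) {
      mask <- dropout_masks[[l]]
      a <- a * mask / (1 - spec$dropout)
      lc$mask <- mask
    }
    if (spec$residual) {
      skip <- if (!is.null(lay$P)) z %*% lay$P else z
      znew <- a + skip
    } else znew <- a
    cache[[paste0("layer", l)]] <- lc
    z <- znew
    cache$z[[l + 1L]] <- z
  }
  logits <- add_bias(z %*% params$out$W, params$out$b)
  if (any(!is.finite(logits))) stop("non-finite values at classifier output", call. = FALSE)
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits)
  if (keep_cache) out$cache <- cache
  out
}

head_backward <- function(params, spec, dlogits, cache, train = FALSE) {
  af <- act_fun(spec$mlp_activation)
  nl <- length(params$head)
  grads <- list(head = vector("list", nl))
  zs <- cache$z
  grads$out <- list(W = crossprod(zs[[nl + 1L]], dlogits), b = colSums(dlogits))
  dz <- dlogits %*% t(params$out$W)
  for (l in rev(seq_len(nl))) {
    lay <- params$head[[l]]
    lc <- cache[[paste0("layer", l)]]
    g <- list()
    da <- dz
    dz_prev_skip <- NULL
    if (spec$residual) {
      if (!is.null(lay$P)) {
        g$P <- crossprod(zs[[l]], dz)
        dz_prev_skip <- dz %*% t(lay$P)
      } else dz_prev_skip <- dz
    }
    if (train && spec$dropout > 0) da <- da * lc$mask / (1 - spec$dropout)
    if (spec$layer_norm_mlp) {
      lb <- layer_norm_backward(da, lc$ln, lay$gamma)
      g$gamma <- lb$dgamma; g$beta <- lb$dbeta
      da <- lb$dx
    }
    ds <- da * af$df(lc$s, lc$a)
    g$W <- crossprod(zs[[l]], ds)
    g$b <- colSums(ds)
    dz <- ds %*% t(lay$W)
    if (!is.null(dz_prev_skip)) dz <- dz + dz_prev_skip
    # reorder gradient fields to match the parameter layout of the layer
    grads$head[[l]] <- g[names(lay)]
  }
  if (spec$layer_norm_basis) {
    lb <- layer_norm_backward(dz, cache$ln0, params$ln0$gamma)
    grads$ln0 <- list(gamma = lb$dgamma, beta = lb$dbeta)
    dz <- lb$dx
  }
  grads$dC <- dz
  grads
}

# ---- full loss + gradient ------------------------------------------------

# X: n x J x F batch, y: labels 0..2, class_w: 3-vector.
# reg: NULL or reg_config; reg_idx: pre-drawn subsample indices
# (list(r1 = list per channel, r2 = list per channel)).
loss_and_grads <- function(params, spec, grid, X, y, class_w,
                           reg = NULL, reg_idx = NULL,
                           train = FALSE, dropout_masks = NULL) {
  n <- dim(X)[1L]
  eb <- eval_bases_internal(params, spec, grid, keep_cache = TRUE)
  C <- coefficients_internal(X, eb$B, grid)
  hf <- head_forward(params, spec, C, train = train,
                     dropout_masks = dropout_masks, keep_cache = TRUE)
  probs <- hf$probs
  wvec <- class_w[y + 1L]
  p_true <- pmax(probs[cbind(seq_len(n), y + 1L)], 1e-12)
  data_loss <- mean(wvec * (-log(p_true)))

  Y <- matrix(0, n, spec$n_classes); Y[cbind(seq_len(n), y + 1L)] <- 1
  dlogits <- (probs - Y) * wvec / n
  hb <- head_backward(params, spec, dlogits, hf$cache, train = train)

  # dL/dB from the coefficient layer: dB[f,k,j] = w_j * sum_i dC[i,fk] X[i,j,f]
  F_ <- spec$F; K <- spec$K; J <- grid$J
  dB <- array(0, c(F_, K, J))
  for (f in seq_len(F_)) {
    dCf <- hb$dC[, (f - 1L) * K + seq_len(K), drop = FALSE]   # n x K
    Xf <- matrix(X[, , f], n, J)
    dB[f, , ] <- crossprod(dCf, Xf) * rep(grid$weights, each = K)
  }

  r1 <- r2 <- 0
  if (!is.null(reg) && (reg$lambda1 > 0 || reg$lambda2 > 0)) {
    if (reg$lambda1 > 0) {
      t1 <- r1_value_grad(eb$B, grid, reg_idx$r1)
      r1 <- t1$value
      dB <- dB + reg$lambda1 * t1$grad
    }
    if (reg$lambda2 > 0) {
      t2 <- r2_value_grad(eb$B, grid, reg_idx$r2)
      r2 <- t2$value
      dB <- dB + reg$lambda2 * t2$grad
    }
  }

  # micro-network backprop
  tm <- matrix(grid$points, J, 1L)
  af <- act_fun(spec$micro_activation)
  gbasis <- vector("list", F_)
  for (f in seq_len(F_)) {
    gbasis[[f]] <- vector("list", K)
    for (k in seq_len(K)) {
      gbasis[[f]][[k]] <- micro_net_backward(params$basis[[f]][[k]],
                                             eb$caches[[f]][[k]], dB[f, k, ], tm, af)
    }
  }
  grads <- list(basis = gbasis, head = hb$head, out = hb$out)
  if (spec$layer_norm_basis) grads$ln0 <- hb$ln0
  # match top-level ordering of params for flatten/unflatten round trips
  grads <- grads[names(params)]
  total <- data_loss +
    (if (is.null(reg)) 0 else reg$lambda1 * r1 + reg$lambda2 * r2)
  list(loss = total, data_loss = data_loss, r1 = r1, r2 = r2,
       grads = grads, probs = probs)
}

# ---- flatten / unflatten / Adam -----------------------------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(node) {
    if (is.list(node)) return(lapply(node, walk))
    n <- length(node)
    out <- vec[pos + seq_len(n)]
    pos <<- pos + n
    if (!is.null(dim(node))) dim(out) <- dim(node)
    out
  }
  out <- walk(skeleton)
  stopifnot(pos == length(vec))
  out
}

adam_init <- function(n_par) {
  list(m = numeric(n_par), v = numeric(n_par), t = 0L)
}

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}

# central finite-difference gradient of f at theta (used by tests and the
# gradient-integrity check)
numeric_gradient <- function(f, theta, h = 1e-5) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    g[i] <- (f(tp) - f(tm)) / (2 * h)
  }
  g
}
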