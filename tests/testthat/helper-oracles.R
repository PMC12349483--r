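# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations they check.

oracle_trapezoid <- function(a, b, pts) {
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    f1 <- a[i] * b[i]; f2 <- a[i + 1L] * b[i + 1L]
    total <- total + (f1 + f2) / 2 * (pts[i + 1L] - pts[i])
  }
  total
}

oracle_weighted_f1 <- function(y_true, y_pred) {
  n <- length(y_true)
  out <- 0
  for (c_ in 0:2) {
    tp <- fp <- fn <- 0
    for (i in seq_len(n)) {
      if (y_pred[i] == c_ && y_true[i] == c_) tp <- tp + 1
      if (y_pred[i] == c_ && y_true[i] != c_) fp <- fp + 1
      if (y_pred[i] != c_ && y_true[i] == c_) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out <- out + sum(y_true == c_) / n * f1
  }
  out
}

oracle_ovr_auc <- function(y_true, probs) {
  aucs <- c()
  for (c_ in 0:2) {
    pos <- which(y_true == c_); neg <- which(y_true != c_)
    if (length(pos) == 0L || length(neg) == 0L) next
    s <- 0
    for (i in pos) for (j in neg) {
      if (probs[i, c_ + 1L] > probs[j, c_ + 1L]) s <- s + 1
      else if (probs[i, c_ + 1L] == probs[j, c_ + 1L]) s <- s + 0.5
    }
    aucs <- c(aucs, s / (length(pos) * length(neg)))
  }
  mean(aucs)
}

oracle_dcor <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  dmat <- function(m) {
    d <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    d
  }
  center <- function(d) {
    A <- matrix(0, n, n)
    rm_ <- rowMeans(d); cm <- colMeans(d); gm <- mean(d)
    for (i in 1:n) for (j in 1:n) A[i, j] <- d[i, j] - rm_[i] - cm[j] + gm
    A
  }
  A <- center(dmat(x)); B <- center(dmat(y))
  dcov2 <- 0; vx <- 0; vy <- 0
  for (i in 1:n) for (j in 1:n) {
    dcov2 <- dcov2 + A[i, j] * B[i, j]
    vx <- vx + A[i, j]^2; vy <- vy + B[i, j]^2
  }
  dcov2 <- dcov2 / n^2; vx <- vx / n^2; vy <- vy / n^2
  if (vx <= 0 || vy <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(vx * vy))
}
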