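#' Regularization configuration for learned basis functions
#'
#' Controls the two penalties applied to the adaptive bases during
#' training: an L1 sparsity penalty \eqn{R_1} promoting localized basis
#' functions, and a squared-cosine-similarity penalty \eqn{R_2} pushing
#' bases within a channel towards orthogonality (less redundancy).  To
#' keep the per-step cost bounded when `K` is large, each penalty is
#' evaluated on a random subsample of bases per channel (`kR1` bases for
#' \eqn{R_1}; `kR2` bases, all unordered pairs among them, for \eqn{R_2}),
#' redrawn every optimization step from a dedicated seeded stream so that
#' training stays reproducible.  Both penalties are averaged over their
#' sampled terms, so their scale does not grow with the channel count.
#'
#' @param lambda1 Sparsity strength (\eqn{\ge 0}).
#' @param lambda2 Orthogonality strength (\eqn{\ge 0}).
#' @param kR1 Number of bases subsampled per channel for \eqn{R_1}.
#' @param kR2 Number of bases subsampled per channel for \eqn{R_2}
#'   (at least 2).
#' @param subsample_seed Seed of the dedicated subsampling stream.
#' @param pooled If `TRUE`, subsample from the pooled `F * K` bases across
#'   channels (`kR1 * F` bases for \eqn{R_1}, pairs among `kR2` pooled
#'   bases for \eqn{R_2}) instead of per channel.  Default `FALSE`,
#'   matching the per-channel basis layers.
#' @return A `reg_config` object.
#' @export
reg_config <- function(lambda1 = 0, lambda2 = 0, kR1 = 1L, kR2 = 2L,
                       subsample_seed = 1L, pooled = FALSE) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, is.finite(lambda1), is.finite(lambda2),
            kR1 >= 1L, kR2 >= 2L)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 kR1 = as.integer(kR1), kR2 = as.integer(kR2),
                 subsample_seed = as.integer(subsample_seed),
                 pooled = isTRUE(pooled)),
            class = "reg_config")
}

# Subsample indices for one optimization step.
# r1: integer matrix, columns (f, k), one row per sampled basis.
# r2: list of integer matrices (same layout); pairs are formed within each
#     group.  Per-channel mode: one group per channel.  Pooled: one group.
draw_reg_indices <- function(K, F_, cfg) {
  if (!cfg$pooled) {
    r1 <- do.call(rbind, lapply(seq_len(F_), function(f) {
      cbind(f, sample.int(K, min(cfg$kR1, K)))
    }))
    r2 <- lapply(seq_len(F_), function(f) {
      cbind(f, sample.int(K, min(cfg$kR2, K)))
    })
  } else {
    total <- K * F_
    pick <- function(m) {
      g <- sample.int(total, min(m, total))
      cbind((g - 1L) %/% K + 1L, (g - 1L) %% K + 1L)
    }
    r1 <- pick(cfg$kR1 * F_)
    r2 <- list(pick(cfg$kR2))
  }
  list(r1 = r1, r2 = r2)
}

# exhaustive (non-subsampled) index sets: all bases per channel for R1,
# all within-channel pairs for R2; used for deterministic validation loss
exhaustive_reg_indices <- function(K, F_) {
  list(
    r1 = cbind(rep(seq_len(F_), each = K), rep(seq_len(K), F_)),
    r2 = lapply(seq_len(F_), function(f) cbind(f, seq_len(K)))
  )
}

# R1 = mean over the sampled bases of the trapezoid integral of |beta|
r1_value_grad <- function(B, grid, sel) {
  grad <- array(0, dim(B))
  total <- 0
  for (r in seq_len(nrow(sel))) {
    f <- sel[r, 1L]; k <- sel[r, 2L]
    b <- B[f, k, ]
    total <- total + sum(grid$weights * abs(b))
    grad[f, k, ] <- grad[f, k, ] + grid$weights * sign(b)
  }
  list(value = total / nrow(sel), grad = grad / nrow(sel))
}

# R2 = mean over unordered pairs within each sampled group of the squared
# cosine similarity under the trapezoid inner product
r2_value_grad <- function(B, grid, groups, warn_degenerate = FALSE) {
  grad <- array(0, dim(B))
  total <- 0; nterms <- 0L
  w <- grid$weights
  for (g in groups) {
    m <- nrow(g)
    if (m < 2L) next
    for (a_ in seq_len(m - 1L)) for (b_ in seq(a_ + 1L, m)) {
      f1 <- g[a_, 1L]; k1 <- g[a_, 2L]
      f2 <- g[b_, 1L]; k2 <- g[b_, 2L]
      u <- B[f1, k1, ]; v <- B[f2, k2, ]
      nu <- sum(w * u * u); nv <- sum(w * v * v); s <- sum(w * u * v)
      nterms <- nterms + 1L
      if (nu <= 0 || nv <= 0) {
        if (warn_degenerate) {
          warning("zero-norm basis in orthogonality penalty; pair term set to 0",
                  call. = FALSE)
        }
        next
      }
      total <- total + s^2 / (nu * nv)
      grad[f1, k1, ] <- grad[f1, k1, ] +
        2 * w * (s * v / (nu * nv) - s^2 * u / (nu^2 * nv))
      grad[f2, k2, ] <- grad[f2, k2, ] +
        2 * w * (s * u / (nu * nv) - s^2 * v / (nu * nv^2))
    }
  }
  if (nterms == 0L) return(list(value = 0, grad = grad))
  list(value = total / nterms, grad = grad / nterms)
}

#' Sparsity penalty of a basis tensor
#'
#' \eqn{R_1}: the mean, over `kR1` randomly subsampled bases per channel,
#' of the trapezoidal approximation of \eqn{\int_0^1 |\beta(t)|\,dt}.
#' Zero exactly when every sampled basis vanishes on the grid.  With
#' `kR1 = K` the subsampling degenerates to the exhaustive mean over all
#' bases.
#'
#' @param bases `F x K x J` array of basis values on `grid$points`.
#' @param grid A [time_grid()].
#' @param cfg A [reg_config()]; the subsample is drawn from the stream
#'   seeded by `cfg$subsample_seed`.
#' @return A non-negative scalar.
#' @export
sparsity_penalty <- function(bases, grid, cfg) {
  K <- dim(bases)[2L]
  if (cfg$kR1 > K) stop("kR1 exceeds the number of bases per channel", call. = FALSE)
  idx <- with_preserved_rng(cfg$subsample_seed,
                            draw_reg_indices(K, dim(bases)[1L], cfg))
  r1_value_grad(bases, grid, idx$r1)$value
}

#' Orthogonality penalty of a basis tensor
#'
#' \eqn{R_2}: the mean squared cosine similarity
#' \eqn{\langle\beta_i,\beta_j\rangle^2 /
#'      (\langle\beta_i,\beta_i\rangle\langle\beta_j,\beta_j\rangle)}
#' over all unordered pairs among `kR2` subsampled bases per channel,
#' inner products taken by the trapezoid rule.  Lies in \eqn{[0,1]};
#' zero for orthogonal pairs; invariant to positive rescaling of any
#' basis; blind to sign flips.  A zero-norm basis makes its pair terms 0
#' with a warning.
#'
#' @inheritParams sparsity_penalty
#' @return A scalar in \eqn{[0, 1]}.
#' @export
orthogonality_penalty <- function(bases, grid, cfg) {
  K <- dim(bases)[2L]
  if (cfg$kR2 > K) stop("kR2 exceeds the number of bases per channel", call. = FALSE)
  idx <- with_preserved_rng(cfg$subsample_seed,
                            draw_reg_indices(K, dim(bases)[1L], cfg))
  r2_value_grad(bases, grid, idx$r2, warn_degenerate = TRUE)$value
}
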