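#' Specification of a synthetic multivariate functional study
#'
#' Describes a synthetic 3-class trial set emulating the statistical
#' structure of synchronized multi-channel recordings: class-dependent
#' localized temporal signal (Gaussian bumps), channel-specific white
#' noise, class imbalance, and zero-padded trailing segments from
#' variable trial lengths.
#'
#' The default design mirrors a two-modality study on five channels:
#' channels 1-3 play the role of "facial" channels (low-amplitude bumps),
#' channels 4-5 of "bio" channels (a higher-amplitude bump).  Channels 1
#' and 2 carry a bump (center 0.25) present in classes 1 and 2 only, so
#' the facial modality separates class 0 from classes 1 and 2; channel 4
#' carries a bump (center 0.7) present in class 2 only, so the bio
#' modality separates class 2 from the rest.  Channels 3 and 5 are pure
#' noise.  Only the fusion of both modalities makes all three classes
#' separable, giving the synthetic analogue of a fusion-beats-single-
#' modality study.
#'
#' @param n_per_class Integer 3-vector of trials per class (default
#'   `c(120, 60, 42)`, imbalanced towards the low-risk class).
#' @param J Time points per trial (default 200; use larger values for
#'   full-scale emulation).
#' @param F Number of channels (default 5).
#' @param bumps Data frame with columns `channel`, `class`, `center`,
#'   `width`, `amplitude` describing the class signal
#'   \eqn{a \exp\{-(t - \mu)^2 / (2 w^2)\}} added to informative
#'   channels.  An optional `jitter_sd` column scales each bump by an
#'   independent per-trial factor \eqn{1 + N(0, \mathrm{jitter\_sd}^2)}
#'   (default 0: fixed amplitudes), which creates designs where a single
#'   projection per channel cannot disentangle amplitude variation from
#'   the presence of a second bump.
#' @param facial_channels,bio_channels Index vectors partitioning the
#'   channels into the two emulated modalities.
#' @param noise_sd White-noise SD, scalar or per channel (default 0.5).
#' @param noise_df If non-`NULL`, noise is drawn from a scaled Student-t
#'   with this many degrees of freedom (heavy-tailed alternative) instead
#'   of Gaussian.
#' @param pad_fraction_range Range of the per-trial fraction of trailing
#'   time points that are truncated and zero-padded (default `c(0, 0.1)`).
#' @param seed Generation seed.
#' @return A `synthetic_spec` object.  `informative_channels` is derived
#'   from `bumps`.
#' @export
synthetic_spec <- function(n_per_class = c(120L, 60L, 42L), J = 200L, F = 5L,
                           bumps = default_bumps(),
                           facial_channels = 1:3, bio_channels = 4:5,
                           noise_sd = 0.5, noise_df = NULL,
                           pad_fraction_range = c(0, 0.1), seed = 1L) {
  stopifnot(length(n_per_class) == 3L, all(n_per_class >= 1L), J >= 2L, F >= 1L,
            all(noise_sd >= 0), length(pad_fraction_range) == 2L,
            pad_fraction_range[1L] >= 0, pad_fraction_range[2L] < 1)
  stopifnot(all(c("channel", "class", "center", "width", "amplitude") %in% names(bumps)))
  stopifnot(all(bumps$center >= 0 & bumps$center <= 1), all(bumps$width > 0),
            all(bumps$channel >= 1 & bumps$channel <= F),
            all(bumps$class %in% 0:2))
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, F)
  stopifnot(length(noise_sd) == F)
  structure(list(n_per_class = as.integer(n_per_class), J = as.integer(J),
                 F = as.integer(F), bumps = bumps,
                 facial_channels = as.integer(facial_channels),
                 bio_channels = as.integer(bio_channels),
                 informative_channels = sort(unique(bumps$channel[bumps$amplitude != 0])),
                 noise_sd = noise_sd, noise_df = noise_df,
                 pad_fraction_range = pad_fraction_range,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_bumps <- function() {
  data.frame(
    channel   = c(1L, 1L, 2L, 2L, 4L),
    class     = c(1L, 2L, 1L, 2L, 2L),
    center    = c(0.25, 0.25, 0.25, 0.25, 0.70),
    width     = c(0.05, 0.05, 0.05, 0.05, 0.05),
    amplitude = c(1.0, 1.0, 1.0, 1.0, 1.5)
  )
}

# mean curve of class c on channel f over grid points t
class_signal_curve <- function(spec, f, c_, t) {
  rows <- spec$bumps[spec$bumps$channel == f & spec$bumps$class == c_, , drop = FALSE]
  out <- numeric(length(t))
  for (r in seq_len(nrow(rows))) {
    out <- out + rows$amplitude[r] *
      exp(-(t - rows$center[r])^2 / (2 * rows$width[r]^2))
  }
  out
}

# one trial's signal matrix (J x F) for class c_, drawing per-bump amplitude
# jitter where requested
draw_signal <- function(spec, c_, t) {
  out <- matrix(0, length(t), spec$F)
  rows <- spec$bumps[spec$bumps$class == c_, , drop = FALSE]
  jit <- if ("jitter_sd" %in% names(rows)) rows$jitter_sd else rep(0, nrow(rows))
  for (r in seq_len(nrow(rows))) {
    mult <- if (jit[r] > 0) 1 + stats::rnorm(1L, 0, jit[r]) else 1
    out[, rows$channel[r]] <- out[, rows$channel[r]] +
      mult * rows$amplitude[r] *
      exp(-(t - rows$center[r])^2 / (2 * rows$width[r]^2))
  }
  out
}

#' Generate a synthetic trial set
#'
#' Draws trials: class-`c` trials carry the sum of that class's bumps on
#' each informative channel plus white noise; non-informative channels
#' are pure noise.  A per-trial fraction drawn from
#' `pad_fraction_range` of trailing time points is truncated and
#' zero-padded.  Label prevalence matches `n_per_class` exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `data` (an [fts()]) and `truth` (ground-truth
#'   record: the bump table, informative channels, modality partition,
#'   and per-channel signal windows `center +/- 3 width`).
#' @export
generate_trials <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  grid <- time_grid(spec$J)
  n <- sum(spec$n_per_class)
  labels <- rep(0:2, spec$n_per_class)
  values <- array(0, c(n, spec$J, spec$F))
  pad_mask <- matrix(TRUE, n, spec$J)
  has_jitter <- "jitter_sd" %in% names(spec$bumps) && any(spec$bumps$jitter_sd > 0)
  with_preserved_rng(spec$seed, {
    signal <- lapply(0:2, function(c_) {
      vapply(seq_len(spec$F), function(f) class_signal_curve(spec, f, c_, grid$points),
             numeric(spec$J))
    })
    for (i in seq_len(n)) {
      noise <- if (is.null(spec$noise_df)) {
        matrix(stats::rnorm(spec$J * spec$F), spec$J, spec$F)
      } else {
        sc <- sqrt(spec$noise_df / (spec$noise_df - 2))
        matrix(stats::rt(spec$J * spec$F, df = spec$noise_df) / sc, spec$J, spec$F)
      }
      noise <- noise * rep(spec$noise_sd, each = spec$J)
      sig <- if (has_jitter) draw_signal(spec, labels[i], grid$points)
             else signal[[labels[i] + 1L]]
      tri <- sig + noise
      u <- stats::runif(1L, spec$pad_fraction_range[1L], spec$pad_fraction_range[2L])
      J_obs <- spec$J - floor(u * spec$J)
      if (J_obs < spec$J) {
        tri[(J_obs + 1L):spec$J, ] <- 0
        pad_mask[i, (J_obs + 1L):spec$J] <- FALSE
      }
      values[i, , ] <- tri
    }
  })
  ch_names <- character(spec$F)
  ch_names[spec$facial_channels] <- paste0("facial", seq_along(spec$facial_channels))
  ch_names[spec$bio_channels] <- paste0("bio", seq_along(spec$bio_channels))
  ch_names[ch_names == ""] <- paste0("ch", which(ch_names == ""))
  truth <- list(
    bumps = spec$bumps,
    informative_channels = spec$informative_channels,
    facial_channels = spec$facial_channels,
    bio_channels = spec$bio_channels,
    windows = signal_windows(spec)
  )
  list(data = fts(values, grid, labels, pad_mask = pad_mask,
                  channel_names = ch_names),
       truth = truth)
}

#' Ground-truth signal windows of a synthetic design
#'
#' @param spec A [synthetic_spec()].
#' @param half_width_sds Half-width of each window in bump-width units
#'   (default 3, covering ~99.7% of each bump's mass).
#' @return A list, one element per channel, each a 2-column matrix of
#'   `(lo, hi)` intervals (possibly zero rows for noise channels).
#' @export
signal_windows <- function(spec, half_width_sds = 3) {
  lapply(seq_len(spec$F), function(f) {
    rows <- spec$bumps[spec$bumps$channel == f & spec$bumps$amplitude != 0, , drop = FALSE]
    if (nrow(rows) == 0L) return(matrix(numeric(0), 0L, 2L))
    iv <- unique(cbind(pmax(rows$center - half_width_sds * rows$width, 0),
                       pmin(rows$center + half_width_sds * rows$width, 1)))
    iv[order(iv[, 1L]), , drop = FALSE]
  })
}

#' Fraction of basis L1 mass inside the true signal windows
#'
#' Diagnostic for basis localization: over the bases attached to the
#' informative channels, the share of total trapezoidal
#' \eqn{\int |\beta|} mass that falls inside the union of that channel's
#' ground-truth signal windows.
#'
#' @param model A trained `adafnn_model`.
#' @param truth Ground-truth record from [generate_trials()].
#' @return Scalar in \eqn{[0, 1]}.
#' @export
basis_mass_in_windows <- function(model, truth) {
  B <- evaluate_bases(model)
  grid <- model$grid
  t <- grid$points
  total <- 0; inside <- 0
  for (f in truth$informative_channels) {
    iv <- truth$windows[[f]]
    in_win <- rep(FALSE, grid$J)
    for (r in seq_len(nrow(iv))) in_win <- in_win | (t >= iv[r, 1L] & t <= iv[r, 2L])
    for (k in seq_len(dim(B)[2L])) {
      m <- grid$weights * abs(B[f, k, ])
      total <- total + sum(m)
      inside <- inside + sum(m[in_win])
    }
  }
  inside / total
}

#' Emit raw-format streams for the preprocessing pipeline
#'
#' Writes, per trial, a long-format landmark coordinate file (30 fps
#' emulation; one landmark per facial channel, x-coordinates integrating
#' the channel's absolute curve so that the frame-to-frame displacement
#' recovers it) and a two-column biosignal file (300 Hz emulation; each
#' curve value repeated 10 times so that moving-average downsampling by
#' 10 recovers it exactly).  Facial curves pass through `abs()` because a
#' displacement magnitude is non-negative by construction; the returned
#' `target` tensor reflects this.
#'
#' @param spec A [synthetic_spec()] whose `bio_channels` has length 2.
#' @param dir Output directory.
#' @return A list with `dir`, `target` (the [fts()] the preprocessing
#'   pipeline should reproduce), and `truth`.
#' @export
generate_raw_streams <- function(spec, dir) {
  stopifnot(length(spec$bio_channels) == 2L)
  g <- generate_trials(spec)
  x <- g$data
  vals <- x$values
  for (f in spec$facial_channels) vals[, , f] <- abs(vals[, , f])
  target <- fts(vals, x$grid, x$labels, pad_mask = x$pad_mask,
                channel_names = x$channel_names)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- n_trials(target)
  obs_len <- as.integer(rowSums(target$pad_mask))
  lm_files <- sprintf("trial_%04d_landmarks.tsv", seq_len(n))
  bio_files <- sprintf("trial_%04d_bio.tsv", seq_len(n))
  for (i in seq_len(n)) {
    J_i <- obs_len[i]
    # landmarks: frame 0..J_i, landmark per facial channel, x = cumulated curve
    lm <- do.call(rbind, lapply(seq_along(spec$facial_channels), function(li) {
      f <- spec$facial_channels[li]
      d <- vals[i, seq_len(J_i), f]
      data.frame(frame = 0:J_i, landmark_id = li,
                 x = cumsum(c(0, d)), y = 0)
    }))
    utils::write.table(lm, file.path(dir, lm_files[i]), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    bio <- vals[i, seq_len(J_i), spec$bio_channels, drop = FALSE]
    bio_raw <- apply(matrix(bio, J_i, 2L), 2L, function(col) rep(col, each = 10L))
    utils::write.table(bio_raw, file.path(dir, bio_files[i]), sep = "\t",
                       row.names = FALSE, col.names = c("ECG", "EDA"), quote = FALSE)
  }
  manifest <- list(n = n, J = spec$J, labels = target$labels,
                   observed_length = obs_len,
                   facial_channels = spec$facial_channels,
                   bio_channels = spec$bio_channels,
                   landmark_files = lm_files, bio_files = bio_files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(dir = dir, target = target, truth = g$truth)
}

#' Preprocess a directory of raw streams into a configured trial set
#'
#' Runs the full raw pipeline: landmark displacement series, biosignal
#' moving-average downsampling (factor 10), zero-padding to `target_J`,
#' and modality assembly under a [dataset_configuration()].
#'
#' @param dir Directory written by [generate_raw_streams()] (or laid out
#'   the same way, with a `manifest.json`).
#' @param config A [dataset_configuration()].
#' @param target_J Standardized trial length; defaults to the manifest's
#'   `J`.
#' @return An [fts()].
#' @export
preprocess_stream_dir <- function(dir, config = dataset_configuration("full_fusion"),
                                  target_J = NULL) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  if (is.null(target_J)) target_J <- mf$J
  n <- mf$n
  facial_trials <- vector("list", n); bio_trials <- vector("list", n)
  for (i in seq_len(n)) {
    coords <- read_landmarks(file.path(dir, mf$landmark_files[i]))
    facial_trials[[i]] <- landmark_displacement_series(coords)
    rec <- read_biosignal(file.path(dir, mf$bio_files[i]))
    bio_trials[[i]] <- downsample_moving_average(rec$samples, 10L)
  }
  fa <- pad_trials(facial_trials, target_J)
  bi <- pad_trials(bio_trials, target_J)
  assemble_configuration(fa$values, bi$values, config, time_grid(target_J),
                         mf$labels, pad_mask = fa$pad_mask)
}
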