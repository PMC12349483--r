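#' Frame-to-frame landmark displacement series
#'
#' Converts a stream of per-frame landmark coordinates into displacement
#' trajectories: for each landmark, the Euclidean distance between its
#' positions in consecutive frames,
#' \eqn{d_{t,l} = \sqrt{(x_{t+1}-x_t)^2 + (y_{t+1}-y_t)^2}}.
#' Displacements are computed on the raw detector coordinates, with no
#' image-size normalization.
#'
#' @param coords Numeric array `T x L x 2` of (x, y) coordinates for `T`
#'   frames and `L` landmarks.
#' @return A `(T-1) x L` matrix of non-negative displacements.
#' @export
landmark_displacement_series <- function(coords) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3L] != 2L) {
    stop("`coords` must be a T x L x 2 array", call. = FALSE)
  }
  T_ <- dim(coords)[1L]
  if (T_ < 2L) stop("at least two frames are required", call. = FALSE)
  if (any(!is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  dx <- coords[-1L, , 1L, drop = FALSE] - coords[-T_, , 1L, drop = FALSE]
  dy <- coords[-1L, , 2L, drop = FALSE] - coords[-T_, , 2L, drop = FALSE]
  matrix(sqrt(dx^2 + dy^2), T_ - 1L, dim(coords)[2L])
}

#' Moving-average downsampling of a biosignal recording
#'
#' Collapses every block of `factor` consecutive samples into its mean,
#' per channel: output row \eqn{i} is the mean of input rows
#' \eqn{factor\,(i-1)+1, \dots, factor\,i}.  With `factor = 10` this
#' synchronizes a 300 Hz physiological recording with 30 fps video while
#' attenuating high-frequency noise.  Leftover samples beyond the last
#' full block are dropped.
#'
#' @param samples Numeric matrix `M x C` (a vector is treated as one
#'   channel).
#' @param factor Positive integer block length.
#' @return A `floor(M/factor) x C` matrix of block means.
#' @examples
#' downsample_moving_average(matrix(1:10), 10)  # 5.5
#' @export
downsample_moving_average <- function(samples, factor) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  if (length(factor) != 1L || factor < 1 || factor != round(factor)) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  M <- nrow(samples)
  if (M < factor) stop("recording shorter than one downsampling block", call. = FALSE)
  nout <- M %/% factor
  idx <- seq_len(nout * factor)
  out <- apply(samples[idx, , drop = FALSE], 2L, function(col) {
    colMeans(matrix(col, nrow = factor))
  })
  matrix(out, nout, ncol(samples))
}

#' Zero-pad ragged trials to a common length
#'
#' Standardizes a list of per-trial `J_i x F` matrices to a fixed number of
#' time points by appending zero rows, the way variable-length recordings
#' are brought to the length of the longest recording (plus margin) before
#' tensor assembly.
#'
#' @param trials List of numeric matrices, each `J_i x F` with a common `F`.
#' @param target_J Target length; must be at least `max(J_i)`.
#' @return A list with `values` (`n x target_J x F` array) and `pad_mask`
#'   (`n x target_J` logical, `FALSE` on appended rows).
#' @export
pad_trials <- function(trials, target_J) {
  stopifnot(is.list(trials), length(trials) >= 1L)
  trials <- lapply(trials, as.matrix)
  F_ <- ncol(trials[[1L]])
  lens <- vapply(trials, nrow, integer(1L))
  if (any(vapply(trials, ncol, integer(1L)) != F_)) {
    stop("all trials must share the same channel count", call. = FALSE)
  }
  if (any(lens > target_J)) {
    stop("trial longer than `target_J`; choose target at or above the maximum length",
         call. = FALSE)
  }
  n <- length(trials)
  values <- array(0, c(n, target_J, F_))
  pad_mask <- matrix(FALSE, n, target_J)
  for (i in seq_len(n)) {
    values[i, seq_len(lens[i]), ] <- trials[[i]]
    pad_mask[i, seq_len(lens[i])] <- TRUE
  }
  list(values = values, pad_mask = pad_mask)
}

#' Tukey interquartile-range outlier flags
#'
#' Flags values beyond the Tukey fences
#' \eqn{[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]}.  Quartiles
#' use linear interpolation between order statistics (`stats::quantile`
#' type 7); the convention is exposed so it can be switched.  Flags are
#' reported, never auto-removed: excluding a trial is an explicit user
#' action.
#'
#' @param series Numeric vector, length at least 4.
#' @param k Fence multiplier (default 1.5).
#' @param quantile_type Quantile algorithm passed to [stats::quantile()].
#' @return Logical vector, `TRUE` where the value falls outside the fences.
#' @export
tukey_outlier_flags <- function(series, k = 1.5, quantile_type = 7) {
  series <- as.numeric(series)
  if (length(series) < 4L) stop("need at least 4 values for quartiles", call. = FALSE)
  q <- stats::quantile(series, c(0.25, 0.75), type = quantile_type, names = FALSE)
  iqr <- q[2L] - q[1L]
  series > q[2L] + k * iqr | series < q[1L] - k * iqr
}

#' Dataset configuration descriptor
#'
#' The five evaluated input configurations: all facial channels, the two
#' biosignal channels, their full fusion, a reduced facial subset, and the
#' reduced subset plus biosignals.
#'
#' @param id One of `"facial_only"`, `"bio_only"`, `"full_fusion"`,
#'   `"selected_facial"`, `"selected_facial_plus_bio"`.
#' @param selected_indices Facial channel indices for the `selected_*`
#'   configurations.
#' @return A `dataset_configuration` object.
#' @export
dataset_configuration <- function(id = c("facial_only", "bio_only", "full_fusion",
                                         "selected_facial", "selected_facial_plus_bio"),
                                  selected_indices = NULL) {
  id <- match.arg(id)
  if (grepl("^selected", id) && length(selected_indices) == 0L) {
    stop("`selected_indices` is required for selected_* configurations", call. = FALSE)
  }
  structure(list(id = id, selected_indices = as.integer(selected_indices)),
            class = "dataset_configuration")
}

#' Assemble a configured trial set from facial and biosignal tensors
#'
#' Combines the two synchronized modality tensors into a single
#' [fts()] according to a [dataset_configuration()].  Channel order is
#' always the facial block first, then the biosignal block.
#'
#' @param facial `n x J x L` array of facial channel trajectories (may be
#'   `NULL` for `bio_only`).
#' @param bio `n x J x 2` array of biosignal channels (may be `NULL` for
#'   facial-only configurations).
#' @param config A [dataset_configuration()].
#' @param grid A [time_grid()] with `J` points.
#' @param labels Integer labels in `{0,1,2}`, length `n`.
#' @param pad_mask Optional `n x J` logical mask.
#' @param facial_names,bio_names Optional channel names per modality.
#' @return An [fts()] whose channel count depends on the configuration:
#'   `L`, `2`, `L + 2`, `|selected|`, or `|selected| + 2`.
#' @export
assemble_configuration <- function(facial, bio, config, grid, labels,
                                   pad_mask = NULL,
                                   facial_names = NULL, bio_names = c("ECG", "EDA")) {
  stopifnot(inherits(config, "dataset_configuration"), is_time_grid(grid))
  need_facial <- config$id != "bio_only"
  need_bio <- config$id %in% c("bio_only", "full_fusion", "selected_facial_plus_bio")
  if (need_facial && is.null(facial)) stop("configuration requires facial data", call. = FALSE)
  if (need_bio && is.null(bio)) stop("configuration requires biosignal data", call. = FALSE)
  if (need_bio && dim(bio)[3L] != 2L) stop("biosignal tensor must have 2 channels", call. = FALSE)
  if (need_facial && need_bio &&
      !all(dim(facial)[1:2] == dim(bio)[1:2])) {
    stop("facial and biosignal tensors must share n and J", call. = FALSE)
  }
  base <- if (need_facial) facial else bio
  if (dim(base)[2L] != grid$J) stop("tensor J must match grid$J", call. = FALSE)

  if (need_facial) {
    L <- dim(facial)[3L]
    if (is.null(facial_names)) facial_names <- paste0("lmk", seq_len(L))
    if (grepl("^selected", config$id)) {
      sel <- config$selected_indices
      if (any(sel < 1L) || any(sel > L)) {
        stop("selected facial index out of range", call. = FALSE)
      }
      facial <- facial[, , sel, drop = FALSE]
      facial_names <- facial_names[sel]
    }
  }
  parts <- list(); nms <- character()
  if (need_facial) { parts <- c(parts, list(facial)); nms <- c(nms, facial_names) }
  if (need_bio)    { parts <- c(parts, list(bio));    nms <- c(nms, bio_names) }
  n <- dim(parts[[1L]])[1L]; J <- grid$J
  F_ <- sum(vapply(parts, function(p) dim(p)[3L], integer(1L)))
  values <- array(0, c(n, J, F_))
  off <- 0L
  for (p in parts) {
    values[, , off + seq_len(dim(p)[3L])] <- p
    off <- off + dim(p)[3L]
  }
  fts(values, grid, labels, pad_mask = pad_mask, channel_names = nms)
}

#' Read a two-column biosignal recording from delimited text
#'
#' @param path File with two numeric columns (ECG, EDA); header optional,
#'   delimiter configurable.
#' @param delim Field delimiter (default tab; `","` for CSV exports).
#' @param rate Sampling rate in Hz (default 300).
#' @return A list with `samples` (`M x 2` matrix) and `rate`.
#' @export
read_biosignal <- function(path, delim = "\t", rate = 300) {
  first <- readLines(path, n = 1L)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(first, delim, fixed = TRUE)[[1L]])
  )))
  m <- as.matrix(utils::read.table(path, sep = delim, header = has_header))
  if (ncol(m) != 2L) stop("biosignal recording must have exactly two columns", call. = FALSE)
  storage.mode(m) <- "double"
  list(samples = m, rate = rate)
}

#' Read a landmark coordinate stream from long-format delimited text
#'
#' Expects columns `frame`, `landmark_id`, `x`, `y` (header required).
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return A `T x L x 2` array ordered by frame and landmark id.
#' @export
read_landmarks <- function(path, delim = "\t") {
  d <- utils::read.table(path, sep = delim, header = TRUE)
  need <- c("frame", "landmark_id", "x", "y")
  if (!all(need %in% names(d))) {
    stop("landmark file needs columns: frame, landmark_id, x, y", call. = FALSE)
  }
  frames <- sort(unique(d$frame)); lms <- sort(unique(d$landmark_id))
  out <- array(NA_real_, c(length(frames), length(lms), 2L))
  fi <- match(d$frame, frames); li <- match(d$landmark_id, lms)
  out[cbind(fi, li, 1L)] <- d$x
  out[cbind(fi, li, 2L)] <- d$y
  if (any(is.na(out))) stop("landmark stream has missing (frame, landmark) cells", call. = FALSE)
  out
}
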