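#' Multivariate functional trial set
#'
#' The central data container: `n` trials observed on a shared time grid,
#' each trial a `J x F` matrix of synchronized channels (e.g. facial
#' landmark displacement trajectories and downsampled ECG/EDA recordings),
#' with a 3-class integer label per trial.
#'
#' Trials shorter than the grid are zero-padded at the tail; `pad_mask`
#' records which entries are genuinely observed.  Padded entries must be
#' exactly zero.  The padding mask is diagnostic only: inner products are
#' taken over the full padded curve, matching the convention that
#' standardized-length curves (zeros appended) are integrated as-is.
#'
#' @param values Numeric array of dimension `n x J x F`.
#' @param grid A [time_grid()] with `J` points.
#' @param labels Integer vector of length `n` with values in `{0, 1, 2}`.
#' @param pad_mask Logical `n x J` matrix, `TRUE` where observed.  Default:
#'   all observed.
#' @param channel_names Character vector of length `F`.  Default `"ch1"...`.
#'
#' @return An object of class `fts` (a list with the validated fields).
#' @examples
#' g <- time_grid(10)
#' x <- array(rnorm(4 * 10 * 2), c(4, 10, 2))
#' d <- fts(x, g, labels = c(0, 1, 2, 0))
#' dim(d$values)
#' @export
fts <- function(values, grid, labels, pad_mask = NULL, channel_names = NULL) {
  stopifnot(is_time_grid(grid))
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be an n x J x F array", call. = FALSE)
  }
  n <- dim(values)[1L]; J <- dim(values)[2L]; F_ <- dim(values)[3L]
  if (J != grid$J) stop("second dimension of `values` must equal grid$J", call. = FALSE)
  if (F_ < 1L) stop("at least one channel is required", call. = FALSE)
  if (n < 1L) stop("at least one trial is required", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("`labels` must have one entry per trial", call. = FALSE)
  if (!all(labels %in% 0:2)) stop("labels must lie in {0, 1, 2}", call. = FALSE)
  if (is.null(pad_mask)) {
    pad_mask <- matrix(TRUE, n, J)
  } else {
    pad_mask <- as.matrix(pad_mask)
    if (!is.logical(pad_mask) || !all(dim(pad_mask) == c(n, J))) {
      stop("`pad_mask` must be a logical n x J matrix", call. = FALSE)
    }
  }
  if (any(rowSums(pad_mask) == 0L)) {
    stop("every trial needs at least one observed time point", call. = FALSE)
  }
  if (any(!pad_mask)) {
    for (f in seq_len(F_)) {
      vf <- matrix(values[, , f], n, J)
      if (any(vf[!pad_mask] != 0)) {
        stop("padded entries of `values` must be exactly zero", call. = FALSE)
      }
    }
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(F_))
  if (length(channel_names) != F_) {
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  }
  structure(
    list(values = values, grid = grid, labels = labels,
         pad_mask = pad_mask, channel_names = as.character(channel_names)),
    class = "fts"
  )
}

#' @export
print.fts <- function(x, ...) {
  cat(sprintf("<fts> %d trials x %d time points x %d channels\n",
              n_trials(x), x$grid$J, n_channels(x)))
  cat("  labels:", paste(sprintf("%d:%d", 0:2, tabulate(x$labels + 1L, 3L)),
                         collapse = "  "), "\n")
  invisible(x)
}

#' @rdname fts
#' @param x An `fts` object.
#' @export
n_trials <- function(x) dim(x$values)[1L]

#' @rdname fts
#' @export
n_channels <- function(x) dim(x$values)[3L]

#' Subset trials of a functional trial set
#'
#' @param x An [fts()] object.
#' @param i Trial indices to keep.
#' @return A new `fts` with the selected trials.
#' @export
fts_subset <- function(x, i) {
  fts(x$values[i, , , drop = FALSE], x$grid, x$labels[i],
      pad_mask = x$pad_mask[i, , drop = FALSE],
      channel_names = x$channel_names)
}

#' Select channels of a functional trial set
#'
#' @param x An [fts()] object.
#' @param channels Channel indices (or names) to keep, in the requested order.
#' @return A new `fts` restricted to those channels.
#' @export
fts_channels <- function(x, channels) {
  if (is.character(channels)) channels <- match(channels, x$channel_names)
  if (any(is.na(channels)) || any(channels < 1L) || any(channels > n_channels(x))) {
    stop("channel index out of range", call. = FALSE)
  }
  fts(x$values[, , channels, drop = FALSE], x$grid, x$labels,
      pad_mask = x$pad_mask, channel_names = x$channel_names[channels])
}
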