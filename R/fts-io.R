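#' Write a functional trial set to a plain-text container directory
#'
#' Serializes an [fts()] as one tab-delimited `J x F` matrix per trial
#' (`trial_0001.tsv`, ...) plus a `manifest.json` holding labels, channel
#' names, grid size and the per-trial observed lengths.  The format is
#' deliberately tool-agnostic: any environment that reads TSV and JSON can
#' consume it.
#'
#' @param x An [fts()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @seealso [read_fts_dir()], [write_fts_rds()] for a single-file binary
#'   container when speed matters.
#' @export
write_fts_dir <- function(x, dir) {
  stopifnot(inherits(x, "fts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- n_trials(x)
  files <- sprintf("trial_%04d.tsv", seq_len(n))
  for (i in seq_len(n)) {
    m <- matrix(x$values[i, , ], x$grid$J, n_channels(x))
    utils::write.table(m, file.path(dir, files[i]), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(
    n = n, J = x$grid$J, F = n_channels(x),
    labels = x$labels,
    channel_names = x$channel_names,
    observed_length = as.integer(rowSums(x$pad_mask)),
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a functional trial set from a plain-text container directory
#'
#' @param dir Directory written by [write_fts_dir()].
#' @return An [fts()] object.
#' @export
read_fts_dir <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  n <- mf$n; J <- mf$J; F_ <- mf$F
  values <- array(0, c(n, J, F_))
  for (i in seq_len(n)) {
    m <- as.matrix(utils::read.table(file.path(dir, mf$files[i]), sep = "\t"))
    if (!all(dim(m) == c(J, F_))) {
      stop(sprintf("trial file %s has wrong dimensions", mf$files[i]), call. = FALSE)
    }
    values[i, , ] <- m
  }
  pad_mask <- matrix(FALSE, n, J)
  for (i in seq_len(n)) pad_mask[i, seq_len(mf$observed_length[i])] <- TRUE
  fts(values, time_grid(J), mf$labels, pad_mask = pad_mask,
      channel_names = mf$channel_names)
}

#' Single-file binary container for a functional trial set
#'
#' RDS serialization of the same content as [write_fts_dir()]; used when
#' read speed matters (e.g. many repeated evaluation runs over one tensor).
#' The two container formats are interchangeable.
#'
#' @param x An [fts()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fts_rds <- function(x, path) {
  stopifnot(inherits(x, "fts"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_fts_rds
#' @export
read_fts_rds <- function(path) {
  x <- readRDS(path)
  # re-validate through the constructor so both readers enforce one contract
  fts(x$values, x$grid, x$labels, pad_mask = x$pad_mask,
      channel_names = x$channel_names)
}
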