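#' Model specification for a multi-channel adaptive functional network
#'
#' Defines the architecture: for each of the `F` input channels, a bank of
#' `K` micro-networks (scalar-in/scalar-out two-hidden-layer perceptrons)
#' whose outputs, evaluated over the time grid, act as learned basis
#' functions \eqn{\beta_{f,k}(t)}.  Each trial curve is projected onto its
#' channel's bases by trapezoidal inner products
#' \eqn{c_{f,k} = \int_0^1 \beta_{f,k}(t) X_f(t)\,dt}, the `K * F`
#' coefficients are concatenated channel-major, and a small residual MLP
#' with softmax output maps them to 3-class probabilities.
#'
#' @param K Number of basis functions per channel (the same `K` for every
#'   channel, keeping representation balanced across channels).
#' @param F Number of input channels.
#' @param micro_hidden Widths of the two micro-network hidden layers.
#' @param micro_activation Micro-network activation: `"tanh"` (default,
#'   giving smooth bounded bases), `"relu"`, or `"selu"`.  The output
#'   layer is always linear so bases take both signs.
#' @param mlp_hidden Widths of the two classifier hidden layers.
#' @param mlp_activation Classifier activation: `"relu"` (default) or
#'   `"selu"`; `"tanh"` is also accepted (smooth everywhere, used by the
#'   gradient-verification tests).
#' @param dropout Dropout rate in the classifier hidden layers (train
#'   time only).
#' @param layer_norm_basis Apply layer normalization to the fused
#'   coefficient vector before the MLP (stabilizes scale differences
#'   across modalities).
#' @param layer_norm_mlp Apply layer normalization after each MLP hidden
#'   activation.
#' @param residual Use skip connections around each MLP hidden layer
#'   (a learned linear projection is used on the skip path when widths
#'   differ).
#' @param n_classes Number of output classes (3).
#' @return An `adafnn_spec` object.
#' @export
adafnn_spec <- function(K, F, micro_hidden = c(16L, 8L),
                        micro_activation = c("tanh", "relu", "selu"),
                        mlp_hidden = c(32L, 16L),
                        mlp_activation = c("relu", "selu", "tanh"),
                        dropout = 0.2, layer_norm_basis = TRUE,
                        layer_norm_mlp = TRUE, residual = TRUE,
                        n_classes = 3L) {
  micro_activation <- match.arg(micro_activation)
  mlp_activation <- match.arg(mlp_activation)
  stopifnot(K >= 1, F >= 1, length(micro_hidden) == 2L, all(micro_hidden >= 1),
            length(mlp_hidden) == 2L, all(mlp_hidden >= 1),
            dropout >= 0, dropout < 1)
  structure(list(K = as.integer(K), F = as.integer(F),
                 micro_hidden = as.integer(micro_hidden),
                 micro_activation = micro_activation,
                 mlp_hidden = as.integer(mlp_hidden),
                 mlp_activation = mlp_activation,
                 dropout = dropout,
                 layer_norm_basis = isTRUE(layer_norm_basis),
                 layer_norm_mlp = isTRUE(layer_norm_mlp),
                 residual = isTRUE(residual),
                 n_classes = as.integer(n_classes)),
            class = "adafnn_spec")
}

#' Initialize a model from a specification
#'
#' Parameters are drawn with fan-in-scaled (Glorot) random initialization
#' under the given seed; first micro-network layers get wider weights and
#' uniform biases so that the initial basis functions vary across the
#' whole of \eqn{[0, 1]}.
#'
#' @param spec An [adafnn_spec()].
#' @param grid The [time_grid()] the model will operate on.
#' @param seed Integer seed for the initialization draw.
#' @return An `adafnn_model` (list with `spec`, `grid`, `params`).
#' @export
init_model <- function(spec, grid, seed = 1L) {
  stopifnot(inherits(spec, "adafnn_spec"), is_time_grid(grid))
  params <- with_preserved_rng(seed, init_params(spec))
  structure(list(spec = spec, grid = grid, params = params, seed = seed),
            class = "adafnn_model")
}

#' @export
print.adafnn_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<adafnn_model> F=%d channels x K=%d bases, micro [%s] (%s), MLP [%s] (%s)\n",
              s$F, s$K, paste(s$micro_hidden, collapse = ","), s$micro_activation,
              paste(s$mlp_hidden, collapse = ","), s$mlp_activation))
  cat(sprintf("  %d parameters; grid J=%d%s\n", length(flatten_params(x$params)),
              x$grid$J, if (!is.null(x$history)) "; trained" else ""))
  invisible(x)
}

#' Evaluate the learned basis functions on a grid
#'
#' Runs every micro-network over the grid points, yielding the current
#' basis functions \eqn{\beta_{f,k}(t)}.
#'
#' @param model An `adafnn_model`.
#' @param grid Optional [time_grid()]; defaults to the model's own grid.
#' @return An `F x K x J` numeric array.
#' @export
evaluate_bases <- function(model, grid = NULL) {
  stopifnot(inherits(model, "adafnn_model"))
  if (is.null(grid)) grid <- model$grid
  stopifnot(is_time_grid(grid))
  eval_bases_internal(model$params, model$spec, grid)$B
}

#' Inner-product coefficients of trial curves on a basis tensor
#'
#' Projects each channel of each trial onto that channel's basis
#' functions by the trapezoid rule:
#' \eqn{c_{f,k} = \langle \beta_{f,k}, X_f \rangle}.  Coefficients are
#' concatenated channel-major (all `K` bases of channel 1, then channel
#' 2, ...), the layout the classifier head is trained on.
#'
#' @param x A `J x F` matrix (single trial), an `n x J x F` array, or an
#'   [fts()].
#' @param bases `F x K x J` array of basis values (from
#'   [evaluate_bases()]).
#' @param grid A [time_grid()].
#' @return An `n x (K*F)` coefficient matrix (one row for a single trial).
#' @export
compute_coefficients <- function(x, bases, grid) {
  stopifnot(is_time_grid(grid))
  if (inherits(x, "fts")) x <- x$values
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  if (dim(x)[2L] != grid$J) stop("trial length must equal grid$J", call. = FALSE)
  if (dim(x)[3L] != dim(bases)[1L]) {
    stop("channel count of trials and bases must agree", call. = FALSE)
  }
  if (dim(bases)[3L] != grid$J) stop("bases must be evaluated on `grid`", call. = FALSE)
  coefficients_internal(x, bases, grid)
}

#' Forward pass for one trial or a batch
#'
#' Computes class probabilities: bases are evaluated over the grid, the
#' trial is projected to its coefficient vector, and the residual MLP
#' head with softmax output is applied.  In training mode dropout masks
#' are active (drawn from the current RNG); in evaluation mode the pass
#' is deterministic.
#'
#' @param model An `adafnn_model`.
#' @param x A `J x F` matrix, `n x J x F` array, or [fts()].
#' @param train_mode Apply dropout (default `FALSE`).
#' @return An `n x 3` matrix of class probabilities (rows sum to 1).
#' @export
forward <- function(model, x, train_mode = FALSE) {
  stopifnot(inherits(model, "adafnn_model"))
  spec <- model$spec; grid <- model$grid
  if (inherits(x, "fts")) x <- x$values
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  if (dim(x)[2L] != grid$J || dim(x)[3L] != spec$F) {
    stop("trial dimensions do not match the model", call. = FALSE)
  }
  B <- eval_bases_internal(model$params, spec, grid)$B
  C <- coefficients_internal(x, B, grid)
  masks <- NULL
  if (train_mode && spec$dropout > 0) {
    masks <- lapply(spec$mlp_hidden, function(d) {
      matrix(stats::rbinom(dim(x)[1L] * d, 1L, 1 - spec$dropout), dim(x)[1L], d)
    })
  }
  head_forward(model$params, spec, C, train = train_mode,
               dropout_masks = masks)$probs
}

#' Predict class labels for a trial set
#'
#' @param object A trained (or initialized) `adafnn_model`.
#' @param newdata An [fts()] or `n x J x F` array.
#' @param ... Unused.
#' @return A list with `labels` (argmax class in `{0,1,2}`, ties broken
#'   toward the lowest class index) and `probs` (`n x 3` matrix).
#' @export
predict.adafnn_model <- function(object, newdata, ...) {
  if (inherits(newdata, "fts")) {
    if (n_trials(newdata) < 1L) stop("empty trial set", call. = FALSE)
  }
  probs <- forward(object, newdata, train_mode = FALSE)
  labels <- max.col(probs, ties.method = "first") - 1L
  list(labels = labels, probs = probs)
}

#' Save / load a model checkpoint
#'
#' The parameter container is serialized to RDS next to a JSON sidecar
#' describing the architecture (`K`, widths, activations, flags) and grid,
#' so checkpoints are self-describing.
#'
#' @param model An `adafnn_model`.
#' @param path Checkpoint file path (`.rds`); the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "adafnn_model"))
  saveRDS(model$params, path)
  side <- c(unclass(model$spec), list(grid_J = model$grid$J, seed = model$seed))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- adafnn_spec(K = side$K, F = side$F, micro_hidden = side$micro_hidden,
                      micro_activation = side$micro_activation,
                      mlp_hidden = side$mlp_hidden,
                      mlp_activation = side$mlp_activation,
                      dropout = side$dropout,
                      layer_norm_basis = side$layer_norm_basis,
                      layer_norm_mlp = side$layer_norm_mlp,
                      residual = side$residual, n_classes = side$n_classes)
  structure(list(spec = spec, grid = time_grid(side$grid_J),
                 params = readRDS(path), seed = side$seed),
            class = "adafnn_model")
}
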