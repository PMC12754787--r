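# Model parameters, initialization and checkpointing.

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_gcn_params <- function(d, n_layers) {
  layers <- lapply(seq_len(n_layers), function(i)
    list(W = glorot(d, d), b = numeric(d)))
  list(W0 = glorot(4L, d), b0 = numeric(d), layers = layers)
}

#' Initialize a model state
#'
#' Draws all learnable parameters (Glorot-uniform weight matrices, zero
#' biases, unit batch-norm scale) for the configured architecture. Batch-norm
#' running statistics start at mean 0 / variance 1, so an untrained model in
#' inference mode normalizes with unit statistics.
#'
#' @param config A [model_config()].
#' @param seed Seed for the parameter draw; defaults to `config$seed`.
#'   Pass `NULL` to draw from the current RNG state.
#' @return An object of class `model_state`: a list with `config`, `params`
#'   (nested list of weight matrices), `bn` (running statistics) and
#'   `format_version`.
#' @export
init_model_state <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "model_config"))
  draw <- function() {
    d <- config$d
    k <- config$conv_kernels
    conv <- list(
      list(W = glorot(4L * k[1L], d), b = numeric(d),
           gamma = rep(1, d), beta = numeric(d)),
      list(W = glorot(d * k[2L], d), b = numeric(d),
           gamma = rep(1, d), beta = numeric(d)),
      list(W = glorot(d * k[3L], d), b = numeric(d),
           gamma = rep(1, d), beta = numeric(d))
    )
    fd <- config$ffn_mult * d
    tf <- lapply(seq_len(config$n_blocks), function(i)
      list(ln1_g = rep(1, d), ln1_b = numeric(d),
           Wq = glorot(d, d), bq = numeric(d),
           Wk = glorot(d, d), bk = numeric(d),
           Wv = glorot(d, d), bv = numeric(d),
           ln2_g = rep(1, d), ln2_b = numeric(d),
           W1 = glorot(d, fd), b1 = numeric(fd),
           W2 = glorot(fd, d), b2 = numeric(d)))
    params <- list(conv = conv, tf = tf)
    if (config$use_bpp) params$gcn_p <- init_gcn_params(d, config$gcn_layers)
    if (config$use_bpe) params$gcn_e <- init_gcn_params(d, config$gcn_layers)
    din <- d * (1L + config$use_bpp + config$use_bpe)
    params$mlp <- list(W1 = glorot(din, config$mlp_hidden),
                       b1 = numeric(config$mlp_hidden),
                       W2 = glorot(config$mlp_hidden, 2L), b2 = numeric(2L))
    params
  }
  params <- if (is.null(seed)) draw() else with_seed(seed, draw())
  bn <- lapply(1:3, function(i)
    list(mean = numeric(config$d), var = rep(1, config$d)))
  structure(list(config = config, params = params, bn = bn,
                 format_version = "ireseek-checkpoint-1"),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  n_par <- length(flatten_params(x$params))
  cat("model state:", n_par, "parameters\n")
  print(x$config)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file embedding the full configuration, all
#' parameters, batch-norm statistics and a format-version tag.
#'
#' @param state A `model_state` (or ensemble model for
#'   [save_ensemble()] / [load_ensemble()]).
#' @param path File path.
#' @return `load_model_state` returns the `model_state`.
#' @export
save_model_state <- function(state, path) {
  stopifnot(inherits(state, "model_state"))
  atomic_write(path, function(tmp) saveRDS(state, tmp))
}

#' @rdname save_model_state
#' @export
load_model_state <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  state <- readRDS(path)
  if (!inherits(state, "model_state") ||
      !identical(state$format_version, "ireseek-checkpoint-1"))
    stop("not a recognized model checkpoint: ", path)
  state
}
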