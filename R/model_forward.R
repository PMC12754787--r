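# Inference-mode forward operations of the dual-branch network. All of them
# are thin wrappers over the compiled core, which is also the training path,
# so there is a single source of truth for the arithmetic.

#' Convolutional front-end of the sequence branch
#'
#' Three 1D convolution blocks (kernel sizes from the configuration, stride
#' 1, same-padding), each followed by batch normalization (running
#' statistics in inference mode) and ReLU. Channels go 4 -> d -> d -> d, so
#' an `L x 4` one-hot input becomes an `L x d` token matrix.
#'
#' @param X `L x 4` one-hot matrix from [one_hot_encode()].
#' @param state A [init_model_state()] result.
#' @return `L x d` numeric matrix of sequence tokens.
#' @export
conv_stack_forward <- function(X, state) {
  stopifnot(inherits(state, "model_state"), is.matrix(X), ncol(X) == 4L)
  if (nrow(X) < max(state$config$conv_kernels))
    stop("sequence shorter than the largest convolution kernel (",
         max(state$config$conv_kernels), ")")
  cpp_conv_stack(X, state$params$conv, state$bn, state$config$conv_kernels)
}

#' Transformer stack of the sequence branch
#'
#' Adds a sinusoidal positional embedding once (unless disabled), then
#' applies `n_blocks` pre-norm transformer blocks: layer norm; Q/K/V linear
#' maps; multi-head attention `softmax(Q K^T / sqrt(d_head)) V`; a second
#' layer norm over the attention residual; and a position-wise feed-forward
#' network with its own residual. Length and width are preserved.
#'
#' @param S `L x d` token matrix.
#' @param state A `model_state`.
#' @param add_positional Add the positional embedding (defaults to the
#'   configuration flag). With it disabled, the stack is permutation
#'   equivariant over positions.
#' @return `L x d` numeric matrix.
#' @export
transformer_forward <- function(S, state, add_positional = NULL) {
  stopifnot(inherits(state, "model_state"), is.matrix(S),
            ncol(S) == state$config$d)
  add_pos <- add_positional %||% state$config$add_pos
  cpp_transformer(S, state$params$tf, state$config$n_heads, isTRUE(add_pos))
}

#' Global max pooling over sequence positions
#'
#' @param tokens `L x d` token matrix.
#' @return Numeric vector of length `d`; element `k` is
#'   `max(tokens[, k])`.
#' @export
pool_sequence <- function(tokens) {
  stopifnot(is.matrix(tokens), nrow(tokens) >= 1L)
  apply(tokens, 2L, max)
}

#' Structural branch: GCN over a normalized base-pair adjacency
#'
#' Node features start as a learned linear projection of the one-hot
#' nucleotides (4 -> d), then `gcn_layers` propagation steps
#' `F <- ReLU(A F W + b)` with `A` the symmetrically normalized adjacency,
#' followed by global max pooling over nodes. The BPP and BPE matrices are
#' processed by separate parameter sets (`kind`).
#'
#' @param adj `L x L` normalized adjacency from [normalized_adjacency()].
#' @param X `L x 4` one-hot matrix of the same sequence.
#' @param state A `model_state`.
#' @param kind `"bpp"` or `"bpe"` -- which branch's parameters to use; an
#'   error if that branch is disabled in the configuration.
#' @return Numeric vector of length `d` (the pooled structural feature).
#' @export
gcn_forward <- function(adj, X, state, kind = c("bpp", "bpe")) {
  kind <- match.arg(kind)
  stopifnot(inherits(state, "model_state"), is.matrix(adj), is.matrix(X),
            nrow(adj) == ncol(adj), nrow(adj) == nrow(X), ncol(X) == 4L)
  p <- if (kind == "bpp") {
    if (!state$config$use_bpp) stop("BPP branch is disabled in this model")
    state$params$gcn_p
  } else {
    if (!state$config$use_bpe) stop("BPE branch is disabled in this model")
    state$params$gcn_e
  }
  drop(cpp_gcn(adj, X, p)$pooled)
}

#' Fuse branch features and classify
#'
#' Concatenates the active features in fixed order (sequence, BPP, BPE) and
#' applies the fusion MLP (linear -> ReLU -> linear; dropout is a training-
#' time operation and is inactive here), returning two-class logits and
#' softmax probabilities. The supplied features must match the
#' configuration's ablation flags exactly.
#'
#' @param f_seq Length-`d` sequence feature.
#' @param f_stru_p,f_stru_e Optional length-`d` structural features.
#' @param state A `model_state`.
#' @return List with `logits` (length 2) and `probs` (length 2, sums to 1;
#'   element 2 is the positive/IRES class).
#' @export
fuse_and_classify <- function(f_seq, f_stru_p = NULL, f_stru_e = NULL, state) {
  stopifnot(inherits(state, "model_state"))
  cfg <- state$config
  if (cfg$use_bpp != !is.null(f_stru_p))
    stop("BPP feature presence does not match the configuration flag")
  if (cfg$use_bpe != !is.null(f_stru_e))
    stop("BPE feature presence does not match the configuration flag")
  z <- c(f_seq, f_stru_p, f_stru_e)
  if (length(z) != nrow(state$params$mlp$W1))
    stop("fused feature length ", length(z), " does not match the MLP input ",
         nrow(state$params$mlp$W1))
  mlp <- state$params$mlp
  h <- pmax(drop(z %*% mlp$W1) + mlp$b1, 0)
  logits <- drop(h %*% mlp$W2) + mlp$b2
  e <- exp(logits - max(logits))
  list(logits = unname(logits), probs = unname(e / sum(e)))
}

#' Mean binary cross-entropy loss
#'
#' `-(1/N) sum(y log p + (1 - y) log(1 - p))` over a batch, with
#' probabilities clamped at `1e-12` for numerical stability.
#'
#' @param probs Per-sample positive-class probabilities.
#' @param labels 0/1 labels of the same length.
#' @return Nonnegative scalar.
#' @export
ce_loss <- function(probs, labels) {
  if (length(probs) == 0L) stop("empty batch")
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)),
            all(probs >= 0 & probs <= 1))
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# Batched inference over a feature set; returns positive-class probabilities.
# features: list(X = list of L x 4, Ap = list | NULL, Ae = list | NULL).
# The compiled core stacks a batch, so records are grouped by length.
predict_scores_features <- function(state, features) {
  cfg <- state$config
  check_features(features, cfg)
  lens <- vapply(features$X, nrow, integer(1))
  out <- numeric(length(lens))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    f <- subset_features(features, idx)
    r <- cpp_nn_run(state$params, state$bn, f$X, f$Ap, f$Ae,
                    cfg_to_cpp(cfg), NULL, NULL, FALSE)
    out[idx] <- r$probs[, 2L]
  }
  unname(out)
}

check_features <- function(features, cfg) {
  stopifnot(is.list(features), is.list(features$X))
  n <- length(features$X)
  if (cfg$use_bpp && (is.null(features$Ap) || length(features$Ap) != n))
    stop("configuration uses the BPP branch but `features$Ap` is absent or ",
         "mismatched")
  if (cfg$use_bpe && (is.null(features$Ae) || length(features$Ae) != n))
    stop("configuration uses the BPE branch but `features$Ae` is absent or ",
         "mismatched")
  invisible(TRUE)
}
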