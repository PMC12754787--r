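# Architectural and training hyperparameter containers.

#' Model architecture configuration
#'
#' Defaults follow the best-performing configuration of the method: hidden
#' dimension 32, eight transformer blocks, convolution kernels (5, 3, 3),
#' eight GCN layers, and both structural branches (BPP and BPE) enabled.
#' The hyperparameter grid spans `gcn_layers` in {2, 4, 8} and `d` in
#' {16, 32, 64}.
#'
#' @param d Hidden dimension shared by the sequence and structural branches.
#' @param n_blocks Number of transformer blocks.
#' @param n_heads Attention heads; default `min(4, d/8)` keeps `d` divisible
#'   by the head count across the grid.
#' @param ffn_mult Feed-forward expansion factor.
#' @param conv_kernels Kernel sizes of the three 1D convolutions.
#' @param gcn_layers GCN depth (shared by both structural branches).
#' @param use_bpp,use_bpe Ablation flags for the structural branches.
#' @param mlp_hidden Hidden width of the fusion MLP.
#' @param dropout Dropout probability in the fusion MLP (training only).
#' @param add_pos Add the sinusoidal positional embedding before the first
#'   transformer block.
#' @param bn_momentum Running-statistics momentum of the batch-norm layers.
#' @param seed Seed for parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(d = 32L, n_blocks = 8L, n_heads = NULL,
                         ffn_mult = 4L, conv_kernels = c(5L, 3L, 3L),
                         gcn_layers = 8L, use_bpp = TRUE, use_bpe = TRUE,
                         mlp_hidden = 64L, dropout = 0.1, add_pos = TRUE,
                         bn_momentum = 0.1, seed = 1L) {
  d <- as.integer(d)
  if (is.null(n_heads)) n_heads <- min(4L, max(1L, d %/% 8L))
  stopifnot(d >= 1L, n_blocks >= 1L, d %% n_heads == 0L, ffn_mult >= 1L,
            length(conv_kernels) == 3L, all(conv_kernels %% 2L == 1L),
            gcn_layers >= 1L, mlp_hidden >= 1L,
            dropout >= 0, dropout < 1)
  structure(
    list(d = d, n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
         ffn_mult = as.integer(ffn_mult),
         conv_kernels = as.integer(conv_kernels),
         gcn_layers = as.integer(gcn_layers),
         use_bpp = isTRUE(use_bpp), use_bpe = isTRUE(use_bpe),
         mlp_hidden = as.integer(mlp_hidden), dropout = dropout,
         add_pos = isTRUE(add_pos), bn_momentum = bn_momentum,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  branches <- c("seq", if (x$use_bpp) "BPP", if (x$use_bpe) "BPE")
  cat(sprintf(
    "model config: d=%d, %d transformer blocks (%d heads), kernels (%s), %d GCN layers, branches: %s\n",
    x$d, x$n_blocks, x$n_heads, paste(x$conv_kernels, collapse = ","),
    x$gcn_layers, paste(branches, collapse = "+")))
  invisible(x)
}

# List form consumed by the C++ core.
cfg_to_cpp <- function(config) {
  list(d = config$d, n_blocks = config$n_blocks, n_heads = config$n_heads,
       ffn_mult = config$ffn_mult, gcn_layers = config$gcn_layers,
       mlp_hidden = config$mlp_hidden, use_bpp = config$use_bpp,
       use_bpe = config$use_bpe, add_pos = config$add_pos,
       kernels = config$conv_kernels, bn_momentum = config$bn_momentum,
       dropout = config$dropout)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to the
#'   weight matrices (biases and normalization parameters are exempt).
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience, in epochs without improvement of
#'   the validation criterion (validation AUROC, falling back to negative
#'   training loss when the validation split holds a single class).
#' @param val_fraction Fraction of the training data held out, stratified by
#'   class, as the validation set.
#' @param seed Master seed driving initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                         batch_size = 64L, max_epochs = 100L,
                         patience = 10L, val_fraction = 0.1, seed = 1L) {
  stopifnot(learning_rate >= 0, weight_decay >= 0, batch_size >= 1L,
            max_epochs >= 1L, patience >= 1L, val_fraction > 0,
            val_fraction < 1)
  structure(
    list(learning_rate = learning_rate, weight_decay = weight_decay,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         val_fraction = val_fraction, seed = as.integer(seed)),
    class = "train_config"
  )
}
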