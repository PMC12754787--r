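# Balanced-dataset construction, model training, soft-voting ensemble.

resample_dataset <- function(data, idx, strategy, seed) {
  records <- data$records[idx, , drop = FALSE]
  rownames(records) <- NULL
  out <- labeled_dataset(records)
  out$source_idx <- idx
  out$strategy <- strategy
  out$seed <- seed
  out
}

#' Oversampled balanced dataset
#'
#' Every positive record appears exactly twice and every negative exactly
#' once; the final order is a seeded shuffle. With the benchmark's training
#' counts (3949 positive, 9034 negative) this yields 7898 positives, i.e. a
#' near-balanced set.
#'
#' @param data A labeled dataset.
#' @param seed Shuffle seed.
#' @return A labeled dataset whose `source_idx` field maps each resampled
#'   record back to its row in `data`.
#' @export
make_oversampled <- function(data, seed = 1L) {
  stopifnot(inherits(data, "ireseek_dataset"))
  if (data$n_pos == 0L) stop("oversampling requires at least one positive")
  idx <- c(seq_len(nrow(data$records)), which(data$records$label == 1L))
  idx <- with_seed(seed, sample(idx))
  resample_dataset(data, idx, "over", seed)
}

#' Undersampled balanced dataset
#'
#' Keeps all positives and a uniformly random subset (without replacement)
#' of exactly `floor(n_neg / 3)` negatives. With the benchmark's training
#' counts this yields 3949 positives and 3011 negatives.
#'
#' @inheritParams make_oversampled
#' @export
make_undersampled <- function(data, seed = 1L) {
  stopifnot(inherits(data, "ireseek_dataset"))
  if (data$n_neg < 3L) stop("undersampling requires at least three negatives")
  neg <- which(data$records$label == 0L)
  idx <- with_seed(seed, {
    keep_neg <- sample(neg, data$n_neg %/% 3L)
    sample(c(which(data$records$label == 1L), keep_neg))
  })
  resample_dataset(data, idx, "under", seed)
}

#' Soft vote of two member probabilities
#'
#' The unweighted arithmetic mean of the positive-class probabilities of the
#' oversampling and undersampling models.
#'
#' @param p_over,p_under Probabilities in `[0, 1]` (vectorized).
#' @return Elementwise mean, bounded by the two inputs.
#' @export
soft_vote <- function(p_over, p_under) {
  if (any(p_over < 0 | p_over > 1 | p_under < 0 | p_under > 1, na.rm = FALSE))
    stop("probabilities must lie in [0, 1]")
  (p_over + p_under) / 2
}

# AdamW-style step: decoupled weight decay applied only where `decay_mask`
# is 1 (weight matrices; biases and normalization parameters are exempt).
adam_step <- function(theta, g, m, v, t, lr, decay_mask, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  list(theta = theta - lr * (mh / (sqrt(vh) + eps) +
                               weight_decay * decay_mask * theta),
       m = m, v = v)
}

# 1 for entries belonging to matrix-shaped parameters, 0 for vectors.
decay_mask_of <- function(params) {
  unlist(rapply(params, function(x)
    rep(if (is.matrix(x)) 1 else 0, length(x)), how = "unlist"))
}

#' Train a single model
#'
#' Minibatch Adam on the two-class cross-entropy, with a stratified
#' validation split carved from the (already resampled) training data and
#' early stopping on validation AUROC. The checkpoint with the best
#' validation criterion is returned. All randomness -- initialization,
#' shuffles, dropout -- derives from `train_cfg$seed`.
#'
#' @param data A labeled dataset (typically a [make_oversampled()] /
#'   [make_undersampled()] result).
#' @param features A [featurize_dataset()] result aligned with
#'   `data$records` row for row.
#' @param config A [model_config()].
#' @param train_cfg A [train_config()].
#' @return A `model_state` with an attached `history` data frame
#'   (`epoch`, `train_loss`, `val_auroc`).
#' @export
train_model <- function(data, features, config, train_cfg = train_config()) {
  stopifnot(inherits(data, "ireseek_dataset"),
            inherits(config, "model_config"),
            inherits(train_cfg, "train_config"))
  check_features(features, config)
  n <- nrow(data$records)
  if (length(features$X) != n)
    stop("features cover ", length(features$X), " records but the dataset has ", n)
  y <- data$records$label
  cfg_cpp <- cfg_to_cpp(config)

  with_seed(train_cfg$seed, {
    # stratified validation split, group-aware over record ids so that
    # oversampled duplicates of one record never straddle the split
    ids <- data$records$id
    uid <- unique(ids)
    y_uid <- y[match(uid, ids)]
    val_uid <- unlist(lapply(c(0L, 1L), function(cl) {
      cls <- uid[y_uid == cl]
      k <- floor(train_cfg$val_fraction * length(cls))
      if (k > 0) sample(cls, k) else character(0)
    }))
    val_idx <- which(ids %in% val_uid)
    train_idx <- setdiff(seq_len(n), val_idx)
    if (!length(train_idx)) stop("no training samples left after validation split")
    val_both <- length(unique(y[val_idx])) == 2L

    state <- init_model_state(config, seed = NULL)
    theta <- flatten_params(state$params)
    dmask <- decay_mask_of(state$params)
    m <- v <- numeric(length(theta))
    t_step <- 0L
    best <- list(crit = -Inf, params = state$params, bn = state$bn)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_auroc = numeric(0))
    stale <- 0L
    val_feats <- subset_features(features, val_idx)

    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample(train_idx)
      starts <- seq(1L, length(ord), by = train_cfg$batch_size)
      losses <- numeric(0)
      for (s in starts) {
        b_idx <- ord[s:min(s + train_cfg$batch_size - 1L, length(ord))]
        mask <- if (config$dropout > 0)
          matrix(rbinom(length(b_idx) * config$mlp_hidden, 1L,
                        1 - config$dropout),
                 length(b_idx), config$mlp_hidden)
        else NULL
        # the compiled core stacks the batch, so split by sequence length;
        # gradients of the sub-batches combine by their sample weight
        b_lens <- vapply(features$X[b_idx], nrow, integer(1))
        grad_sum <- NULL
        loss_sum <- 0
        for (L in unique(b_lens)) {
          sub <- b_idx[b_lens == L]
          bf <- subset_features(features, sub)
          sub_mask <- if (is.null(mask)) NULL
                      else mask[match(sub, b_idx), , drop = FALSE]
          run <- cpp_nn_run(state$params, state$bn, bf$X, bf$Ap, bf$Ae,
                            cfg_cpp, y[sub], sub_mask, TRUE)
          state$bn <- run$bn_state
          w <- length(sub) / length(b_idx)
          g <- flatten_params(run$grads) * w
          grad_sum <- if (is.null(grad_sum)) g else grad_sum + g
          loss_sum <- loss_sum + run$loss * w
        }
        losses <- c(losses, loss_sum)
        t_step <- t_step + 1L
        upd <- adam_step(theta, grad_sum, m, v, t_step,
                         train_cfg$learning_rate, dmask,
                         train_cfg$weight_decay)
        theta <- upd$theta; m <- upd$m; v <- upd$v
        state$params <- relist_params(theta, state$params)
      }
      crit <- if (val_both) {
        val_p <- predict_scores_features(state, val_feats)
        auroc(val_p, y[val_idx])
      } else NA_real_
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(losses), val_auroc = crit))
      eff_crit <- if (val_both) crit else -mean(losses)
      if (eff_crit > best$crit + 1e-12) {
        best <- list(crit = eff_crit, params = state$params, bn = state$bn)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= train_cfg$patience) break
      }
    }
    state$params <- best$params
    state$bn <- best$bn
    attr(state, "history") <- history
    state
  })
}

#' Train the over/under soft-voting ensemble
#'
#' Builds the oversampling plan (seed `seed + 1`) and undersampling plan
#' (seed `seed + 2`) from the training data, trains one model on each, and
#' returns an ensemble whose prediction is the soft vote of the member
#' probabilities. `strategy = "over"` / `"under"` return a single-member
#' ensemble (the degenerate vote is that member's probability).
#'
#' @inheritParams train_model
#' @param strategy `"ensemble"`, `"over"` or `"under"`.
#' @return An object of class `ensemble_model`.
#' @export
train_ensemble <- function(data, features, config,
                           train_cfg = train_config(),
                           strategy = c("ensemble", "over", "under")) {
  strategy <- match.arg(strategy)
  members <- list()
  if (strategy %in% c("ensemble", "over")) {
    plan <- make_oversampled(data, seed = train_cfg$seed + 1L)
    tc <- train_cfg; tc$seed <- train_cfg$seed + 1L
    members$over <- train_model(plan, subset_features(features, plan$source_idx),
                                config, tc)
  }
  if (strategy %in% c("ensemble", "under")) {
    plan <- make_undersampled(data, seed = train_cfg$seed + 2L)
    tc <- train_cfg; tc$seed <- train_cfg$seed + 2L
    members$under <- train_model(plan, subset_features(features, plan$source_idx),
                                 config, tc)
  }
  structure(list(members = members, strategy = strategy, config = config,
                 train_config = train_cfg),
            class = "ensemble_model")
}

#' Predict positive-class probabilities with an ensemble
#'
#' @param object An [train_ensemble()] result.
#' @param features A [featurize_dataset()] result.
#' @param ... Unused.
#' @return Data frame with one row per record: `id`, per-member
#'   probabilities (`prob_over` / `prob_under` where trained), the voted
#'   `prob` and the thresholded `call` at 0.5.
#' @export
predict.ensemble_model <- function(object, features, ...) {
  member_p <- lapply(object$members, predict_scores_features,
                     features = features)
  prob <- if (length(member_p) == 2L)
    soft_vote(member_p$over, member_p$under)
  else member_p[[1L]]
  out <- data.frame(id = features$ids %||% seq_along(prob))
  if (!is.null(member_p$over)) out$prob_over <- member_p$over
  if (!is.null(member_p$under)) out$prob_under <- member_p$under
  out$prob <- prob
  out$call <- as.integer(prob >= 0.5)
  out
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("ensemble model (strategy:", x$strategy, ") with member(s):",
      paste(names(x$members), collapse = ", "), "\n")
  print(x$config)
  invisible(x)
}

#' Save / load an ensemble model
#'
#' @param ensemble An `ensemble_model`.
#' @param path File path (single RDS container).
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  atomic_write(path, function(tmp) saveRDS(ensemble, tmp))
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  if (!file.exists(path)) stop("ensemble checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!inherits(obj, "ensemble_model")) stop("not an ensemble checkpoint: ", path)
  obj
}
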