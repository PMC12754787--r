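fake_dataset <- function(n_pos, n_neg, L = 10L) {
  dataset_from(replicate(n_pos + n_neg, random_rna(L)),
               rep(c(1L, 0L), c(n_pos, n_neg)))
}

test_that("sampling plans reproduce the benchmark arithmetic", {
  set.seed(1)
  big <- fake_dataset(3949L, 9034L, L = 5L)
  over <- make_oversampled(big, seed = 7)
  expect_equal(over$n_pos, 7898L)
  expect_equal(over$n_neg, 9034L)
  under <- make_undersampled(big, seed = 7)
  expect_equal(under$n_pos, 3949L)
  expect_equal(under$n_neg, 3011L)  # floor(9034 / 3)
})

test_that("oversampling doubles positives and keeps every record", {
  d <- fake_dataset(1L, 2L)
  over <- make_oversampled(d, seed = 1)
  expect_equal(over$n_pos, 2L)
  expect_equal(over$n_neg, 2L)
  expect_setequal(unique(over$records$id), d$records$id)
  # every positive exactly twice, negatives once
  tab <- table(over$records$id)
  expect_true(all(tab[d$records$id[d$records$label == 1L]] == 2L))
  expect_true(all(tab[d$records$id[d$records$label == 0L]] == 1L))
  expect_error(make_oversampled(fake_dataset(0L, 3L)), "positive")
})

test_that("undersampling keeps all positives and a third of negatives", {
  d <- fake_dataset(4L, 9L)
  under <- make_undersampled(d, seed = 2)
  expect_equal(under$n_pos, 4L)
  expect_equal(under$n_neg, 3L)
  # strict subset: no invented records, all positives retained
  expect_true(all(under$records$id %in% d$records$id))
  expect_true(all(d$records$id[d$records$label == 1L] %in%
                    under$records$id))
  expect_false(anyDuplicated(under$records$id) > 0)
  expect_error(make_undersampled(fake_dataset(3L, 2L)), "three negatives")
})

test_that("sampling plans are seed-deterministic and touch only indices", {
  d <- fake_dataset(5L, 12L)
  a <- make_undersampled(d, seed = 9)
  b <- make_undersampled(d, seed = 9)
  expect_identical(a$records, b$records)
  expect_identical(make_oversampled(d, seed = 4)$records,
                   make_oversampled(d, seed = 4)$records)
  # sequences are never mutated
  expect_true(all(a$records$canon_seq %in% d$records$canon_seq))
})

test_that("soft_vote is the mean, bounded, idempotent and validated", {
  expect_equal(soft_vote(0.6, 0.8), 0.7)
  expect_equal(soft_vote(0.31, 0.31), 0.31)
  p1 <- runif(20); p2 <- runif(20)
  v <- soft_vote(p1, p2)
  expect_true(all(v >= pmin(p1, p2) & v <= pmax(p1, p2)))
  expect_error(soft_vote(1.2, 0.5), "\\[0, 1\\]")
})

test_that("zero learning rate leaves parameters and the loss trace unchanged", {
  set.seed(3)
  d <- fake_dataset(6L, 10L, L = 12L)
  cfg <- tiny_config()
  feats <- featurize_dataset(d, cfg)
  # full-batch so every epoch sees the identical batch statistics
  tc <- train_config(learning_rate = 0, batch_size = 64L, max_epochs = 6L,
                     patience = 3L, seed = 5)
  st <- train_model(d, feats, cfg, tc)
  h <- attr(st, "history")
  expect_true(all(abs(h$train_loss - h$train_loss[1]) < 1e-12))
  # parameters never move: one epoch and six epochs end identically
  tc1 <- train_config(learning_rate = 0, batch_size = 64L, max_epochs = 1L,
                      seed = 5)
  st1 <- train_model(d, feats, cfg, tc1)
  expect_identical(ireseek:::flatten_params(st$params),
                   ireseek:::flatten_params(st1$params))
})

test_that("training is bitwise reproducible for a fixed seed", {
  set.seed(4)
  d <- fake_dataset(8L, 12L, L = 12L)
  cfg <- tiny_config(dropout = 0.1)
  feats <- featurize_dataset(d, cfg)
  tc <- train_config(max_epochs = 3L, batch_size = 8L, seed = 11)
  h1 <- attr(train_model(d, feats, cfg, tc), "history")
  h2 <- attr(train_model(d, feats, cfg, tc), "history")
  expect_identical(h1, h2)
})

test_that("training reduces the loss on strongly separable data", {
  ok <- 0L
  for (seed in 1:10) {
    train <- generate_dataset(synthetic_config(
      n_pos = 60L, n_neg = 140L, length = 40L, seed = 100L + seed))
    cfg <- model_config(d = 16L, n_blocks = 2L, gcn_layers = 2L,
                        seed = seed)
    feats <- featurize_dataset(train, cfg)
    st <- train_model(train, feats, cfg,
                      train_config(max_epochs = 5L, patience = 5L,
                                   seed = seed))
    h <- attr(st, "history")
    if (h$train_loss[nrow(h)] < h$train_loss[1L]) ok <- ok + 1L
  }
  expect_gte(ok, 9L)  # at least 95% of seeds, allowing one failure in ten
})

test_that("feature/flag mismatch errors before training starts", {
  d <- fake_dataset(4L, 6L, L = 12L)
  cfg <- tiny_config()  # uses both structural branches
  feats_seq_only <- list(ids = d$records$id,
                         X = lapply(d$records$canon_seq, one_hot_encode))
  expect_error(train_model(d, feats_seq_only, cfg, train_config(seed = 1)),
               "BPP")
})

test_that("ensemble predictions are the soft vote of the members", {
  set.seed(6)
  d <- fake_dataset(8L, 14L, L = 12L)
  cfg <- tiny_config()
  feats <- featurize_dataset(d, cfg)
  tc <- train_config(max_epochs = 2L, batch_size = 8L, seed = 21)
  ens <- train_ensemble(d, feats, cfg, tc)
  pred <- predict(ens, feats)
  expect_equal(pred$prob, soft_vote(pred$prob_over, pred$prob_under),
               tolerance = 1e-12)
  expect_equal(pred$prob,
               soft_vote(
                 ireseek:::predict_scores_features(ens$members$over, feats),
                 ireseek:::predict_scores_features(ens$members$under, feats)),
               tolerance = 1e-12)
  # single-member strategies: the vote is that member's probability
  solo <- train_ensemble(d, feats, cfg, tc, strategy = "under")
  pred_solo <- predict(solo, feats)
  expect_equal(pred_solo$prob,
               ireseek:::predict_scores_features(solo$members$under, feats),
               tolerance = 1e-12)
  expect_null(pred_solo$prob_over)
})

test_that("the ensemble vote is not much worse than its best member", {
  wins <- 0L
  for (seed in 1:5) {
    train <- generate_dataset(synthetic_config(
      n_pos = 80L, n_neg = 180L, length = 40L, seed = 200L + seed))
    test <- generate_dataset(synthetic_config(
      n_pos = 60L, n_neg = 60L, length = 40L, seed = 300L + seed))
    cfg <- model_config(d = 16L, n_blocks = 1L, gcn_layers = 2L, seed = seed)
    trf <- featurize_dataset(train, cfg)
    tef <- featurize_dataset(test, cfg)
    ens <- train_ensemble(train, trf, cfg,
                          train_config(max_epochs = 12L, patience = 12L,
                                       seed = seed))
    pred <- predict(ens, tef)
    y <- test$records$label
    members <- c(auroc(pred$prob_over, y), auroc(pred$prob_under, y))
    if (auroc(pred$prob, y) >= max(members) - 0.05) wins <- wins + 1L
  }
  expect_gte(wins, 3L)  # majority of seeds
})

test_that("ensembles round-trip through their checkpoint container", {
  set.seed(8)
  d <- fake_dataset(6L, 8L, L = 12L)
  cfg <- tiny_config()
  feats <- featurize_dataset(d, cfg)
  ens <- train_ensemble(d, feats, cfg,
                        train_config(max_epochs = 1L, seed = 2))
  f <- tempfile(fileext = ".rds")
  save_ensemble(ens, f)
  back <- load_ensemble(f)
  expect_identical(predict(back, feats), predict(ens, feats))
})
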