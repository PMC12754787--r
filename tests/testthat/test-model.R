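test_that("conv stack preserves length and maps 4 channels to d", {
  cfg <- model_config(d = 32L, seed = 9)
  st <- init_model_state(cfg)
  X <- one_hot_encode(random_rna(174L))
  S <- conv_stack_forward(X, st)
  expect_equal(dim(S), c(174L, 32L))
  expect_true(all(is.finite(S)))
  # deterministic in inference mode
  expect_identical(S, conv_stack_forward(X, st))
  expect_error(conv_stack_forward(X[1:4, , drop = FALSE], st), "kernel")
})

test_that("zeroed conv weights with unit batch-norm stats give zero output", {
  cfg <- tiny_config()
  st <- init_model_state(cfg)
  st$params$conv <- lapply(st$params$conv, function(b) {
    b$W[] <- 0; b$b[] <- 0; b$beta[] <- 0
    b
  })
  X <- one_hot_encode(random_rna(20L))
  expect_equal(max(abs(conv_stack_forward(X, st))), 0)
})

test_that("transformer stack preserves shape and applies all blocks", {
  cfg <- model_config(d = 32L, n_blocks = 8L, seed = 10)
  st <- init_model_state(cfg)
  S <- matrix(rnorm(174 * 32), 174, 32)
  H <- transformer_forward(S, st)
  expect_equal(dim(H), c(174L, 32L))
  # with fewer blocks the output differs: blocks are actually applied
  st1 <- st
  st1$params$tf <- st1$params$tf[1:2]
  expect_gt(max(abs(H - cpp_transformer(S, st1$params$tf, cfg$n_heads, TRUE))),
            1e-6)
})

test_that("attention without positional embedding is permutation equivariant", {
  cfg <- tiny_config(n_blocks = 2L)
  st <- init_model_state(cfg)
  set.seed(1)
  S <- matrix(rnorm(15 * cfg$d), 15, cfg$d)
  perm <- sample(15)
  out <- transformer_forward(S, st, add_positional = FALSE)
  out_perm <- transformer_forward(S[perm, ], st, add_positional = FALSE)
  expect_equal(out_perm, out[perm, ], tolerance = 1e-10)
  # with the positional embedding the equivariance breaks
  out_pos <- transformer_forward(S, st, add_positional = TRUE)
  out_pos_perm <- transformer_forward(S[perm, ], st, add_positional = TRUE)
  expect_gt(max(abs(out_pos_perm - out_pos[perm, ])), 1e-4)
})

test_that("pool_sequence is an elementwise position maximum", {
  tok <- matrix(c(1, 5, 3, 2, 0, -1), 3, 2)
  expect_equal(pool_sequence(tok), c(5, 2))
  # constant tokens pool to the constant
  expect_equal(pool_sequence(matrix(0.7, 10, 4)), rep(0.7, 4))
  # permutation invariance over positions
  set.seed(2)
  tok <- matrix(rnorm(40), 10, 4)
  expect_equal(pool_sequence(tok), pool_sequence(tok[sample(10), ]))
  # monotone: raising one entry never lowers any pooled value
  tok2 <- tok
  tok2[3, 2] <- tok2[3, 2] + 5
  expect_true(all(pool_sequence(tok2) >= pool_sequence(tok)))
})

test_that("gcn_forward handles identity adjacency and node relabeling", {
  cfg <- tiny_config()
  st <- init_model_state(cfg)
  L <- 12L
  seq <- random_rna(L)
  X <- one_hot_encode(seq)
  # identity adjacency: per-node transform + pooling, output length d
  f <- gcn_forward(diag(L), X, st, "bpp")
  expect_length(f, cfg$d)

  # pooled output invariant under consistent node permutation
  A <- adjacency_from_pair_matrix(compute_bpp(seq))
  set.seed(3)
  perm <- sample(L)
  f1 <- gcn_forward(A, X, st, "bpp")
  f2 <- gcn_forward(A[perm, perm], X[perm, ], st, "bpp")
  expect_equal(f1, f2, tolerance = 1e-12)

  # separate parameters per structural kind
  fe <- gcn_forward(A, X, st, "bpe")
  expect_gt(max(abs(f1 - fe)), 1e-8)
})

test_that("gcn branch errors when disabled and never reads its matrix", {
  cfg <- tiny_config(use_bpe = FALSE)
  st <- init_model_state(cfg)
  X <- one_hot_encode(random_rna(10L))
  expect_error(gcn_forward(diag(10), X, st, "bpe"), "disabled")
  # prediction works without Ae present at all
  feats <- list(ids = "a", X = list(X),
                Ap = list(diag(10)))
  p <- ireseek:::predict_scores_features(st, feats)
  expect_true(p >= 0 && p <= 1)
})

test_that("configured depth is honored in transformer and GCN stacks", {
  cfg <- model_config(d = 16L, n_blocks = 8L, gcn_layers = 8L, seed = 4)
  st <- init_model_state(cfg)
  expect_length(st$params$tf, 8L)
  expect_length(st$params$gcn_p$layers, 8L)
  expect_length(st$params$gcn_e$layers, 8L)
})

test_that("fuse_and_classify concatenates in fixed order and checks flags", {
  cfg <- tiny_config()
  st <- init_model_state(cfg)
  d <- cfg$d
  sc <- fuse_and_classify(rnorm(d), rnorm(d), rnorm(d), state = st)
  expect_equal(sum(sc$probs), 1, tolerance = 1e-12)
  expect_true(all(sc$probs > 0 & sc$probs < 1))
  # fused width: 3d with both structural branches at d = 32
  cfg32 <- model_config(d = 32L, seed = 5)
  st32 <- init_model_state(cfg32)
  expect_equal(nrow(st32$params$mlp$W1), 96L)
  # seq-only: fused length d
  cfg_seq <- tiny_config(use_bpp = FALSE, use_bpe = FALSE)
  st_seq <- init_model_state(cfg_seq)
  expect_equal(nrow(st_seq$params$mlp$W1), cfg_seq$d)
  # mismatch between features and flags is an error
  expect_error(fuse_and_classify(rnorm(d), NULL, rnorm(d), state = st),
               "BPP")
  expect_error(fuse_and_classify(rnorm(d), rnorm(d), rnorm(d),
                                 state = st_seq), "BP")
})

test_that("ce_loss matches closed forms", {
  expect_equal(ce_loss(rep(0.5, 7), rbinom(7, 1, 0.5)), log(2),
               tolerance = 1e-12)
  expect_lte(ce_loss(c(1, 0), c(1, 0)), 1e-10)
  expect_equal(ce_loss(c(0.8, 0.4), c(1, 0)), -(log(0.8) + log(0.6)) / 2,
               tolerance = 1e-12)
  expect_error(ce_loss(numeric(0), numeric(0)), "empty")
})

test_that("analytic gradients agree with numeric differentiation", {
  cfg <- tiny_config()
  st <- init_model_state(cfg)
  set.seed(12)
  n <- 3L
  L <- 10L
  seqs <- replicate(n, random_rna(L))
  X <- lapply(seqs, one_hot_encode)
  Ap <- lapply(seqs, function(s) adjacency_from_pair_matrix(compute_bpp(s)))
  Ae <- lapply(seqs, function(s)
    adjacency_from_pair_matrix(compute_bpe_standin(s)))
  y <- c(1L, 0L, 1L)
  ccfg <- ireseek:::cfg_to_cpp(cfg)
  run <- ireseek:::cpp_nn_run(st$params, st$bn, X, Ap, Ae, ccfg, y, NULL, TRUE)
  theta <- ireseek:::flatten_params(st$params)
  g <- ireseek:::flatten_params(run$grads)
  loss_at <- function(th) {
    p <- ireseek:::relist_params(th, st$params)
    ireseek:::cpp_nn_run(p, st$bn, X, Ap, Ae, ccfg, y, NULL, TRUE)$loss
  }
  idx <- sample(length(theta), 40L)
  eps <- 1e-5
  for (i in idx) {
    tp <- theta; tp[i] <- theta[i] + eps; up <- loss_at(tp)
    tp[i] <- theta[i] - eps; dn <- loss_at(tp)
    num <- (up - dn) / (2 * eps)
    expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-4)
  }
})

test_that("forward pass is deterministic for a fixed state", {
  cfg <- tiny_config()
  st <- init_model_state(cfg)
  seqs <- replicate(4, random_rna(12L))
  feats <- features_for(seqs, cfg)
  p1 <- ireseek:::predict_scores_features(st, feats)
  p2 <- ireseek:::predict_scores_features(st, feats)
  expect_identical(p1, p2)
})

test_that("checkpoints round-trip with config and version tag", {
  cfg <- tiny_config()
  st <- init_model_state(cfg)
  f <- tempfile(fileext = ".rds")
  save_model_state(st, f)
  back <- load_model_state(f)
  expect_identical(back$params, st$params)
  expect_identical(back$config, st$config)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_model_state(bad), "not a recognized")
})
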