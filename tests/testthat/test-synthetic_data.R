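test_that("generator honors counts, lengths and the default 4:9 ratio", {
  cfg <- synthetic_config(n_pos = 10L, n_neg = 20L, length = 174L, seed = 1)
  d <- generate_dataset(cfg)
  expect_equal(nrow(d$records), 30L)
  expect_true(all(nchar(d$records$canon_seq) == 174L))
  expect_equal(d$n_pos + d$n_neg, 30L)
  # defaults emulate the benchmark's imbalance
  def <- synthetic_config()
  expect_equal(def$n_pos, 400L)
  expect_equal(def$n_neg, 900L)
  expect_equal(def$length, 174L)
  s <- summarize_dataset(d)
  expect_equal(s$n_pos, 10L)
  expect_equal(s$n_neg, 20L)
  expect_error(synthetic_config(length = 25L), "length")
})

test_that("generation is a pure function of its configuration", {
  cfg <- synthetic_config(n_pos = 8L, n_neg = 12L, length = 60L, seed = 33)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$records, d2$records)
  f1 <- tempfile(); l1 <- tempfile(); f2 <- tempfile(); l2 <- tempfile()
  write_dataset(d1, f1, l1)
  write_dataset(d2, f2, l2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(l1), readLines(l2))
  # a different seed changes the draw
  d3 <- generate_dataset(synthetic_config(n_pos = 8L, n_neg = 12L,
                                          length = 60L, seed = 34))
  expect_false(identical(d1$records$canon_seq, d3$records$canon_seq))
})

test_that("positives are AU-enriched when the motif is planted", {
  gaps <- vapply(1:3, function(seed) {
    d <- generate_dataset(synthetic_config(n_pos = 60L, n_neg = 60L,
                                           length = 60L,
                                           structure_strength = 0,
                                           seed = seed))
    s <- summarize_dataset(d)
    s$freq_pos[["AU"]] - s$freq_neg[["AU"]]
  }, numeric(1))
  expect_true(all(gaps > 0))
  # and the enrichment disappears without any signal
  d0 <- generate_dataset(synthetic_config(n_pos = 200L, n_neg = 200L,
                                          length = 60L, motif_strength = 0,
                                          structure_strength = 0, seed = 4))
  s0 <- summarize_dataset(d0)
  expect_lt(abs(s0$freq_pos[["AU"]] - s0$freq_neg[["AU"]]), 0.03)
})

test_that("planted hairpins pair complementary bases at the stated indices", {
  cfg <- synthetic_config(n_pos = 20L, n_neg = 0L, length = 60L, seed = 5)
  d <- generate_dataset(cfg)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (i in seq_len(nrow(d$records))) {
    pr <- hairpin_pairs(d$records[i, ], cfg)
    expect_equal(nrow(pr), cfg$stem_len)
    ch <- strsplit(d$records$canon_seq[i], "")[[1]]
    expect_identical(ch[pr[, "j"]], unname(comp[ch[pr[, "i"]]]))
  }
})

test_that("planted stems carry elevated base-pair probability", {
  cfg <- synthetic_config(n_pos = 50L, n_neg = 0L, length = 60L, seed = 6)
  d <- generate_dataset(cfg)
  stem_mean <- vapply(seq_len(nrow(d$records)), function(i) {
    m <- compute_bpp(d$records$canon_seq[i])
    mean(m[hairpin_pairs(d$records[i, ], cfg)])
  }, numeric(1))
  # the stem dominates the ensemble for most records, and on average its
  # pairs are far above the level of any chance pairing
  expect_gte(mean(stem_mean > 0.5), 0.6)
  expect_gt(median(stem_mean), 0.5)
})

test_that("label noise flips approximately the requested fraction", {
  cfg <- synthetic_config(n_pos = 300L, n_neg = 300L, length = 40L,
                          label_noise = 0.2, seed = 7)
  d <- generate_dataset(cfg)
  flipped <- mean(d$records$label != d$truth)
  expect_gt(flipped, 0.12)
  expect_lt(flipped, 0.28)
})

test_that("benchmark verification accepts matching splits and flags others", {
  dir <- tempfile(); dir.create(dir)
  tr <- generate_dataset(synthetic_config(n_pos = 12L, n_neg = 27L,
                                          length = 50L, seed = 8), "tr")
  te <- generate_dataset(synthetic_config(n_pos = 5L, n_neg = 5L,
                                          length = 50L, seed = 9), "te")
  write_dataset(tr, file.path(dir, "train.fasta"), file.path(dir, "train.tsv"))
  write_dataset(te, file.path(dir, "test.fasta"), file.path(dir, "test.tsv"))
  expected <- list(train_pos = 12L, train_neg = 27L, test_pos = 5L,
                   test_neg = 5L, length = 50L)
  v <- verify_benchmark_dataset(file.path(dir, "train.fasta"),
                                file.path(dir, "train.tsv"),
                                file.path(dir, "test.fasta"),
                                file.path(dir, "test.tsv"), expected)
  expect_true(v$ok)
  expected$train_pos <- 13L
  v2 <- verify_benchmark_dataset(file.path(dir, "train.fasta"),
                                 file.path(dir, "train.tsv"),
                                 file.path(dir, "test.fasta"),
                                 file.path(dir, "test.tsv"), expected)
  expect_false(v2$ok)
})
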