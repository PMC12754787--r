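test_that("enumerate_structures lists exactly the admissible structures", {
  # no canonical pair can satisfy the 3-nt loop minimum at L = 4
  s <- enumerate_structures("AAAA")
  expect_length(s, 1L)
  expect_equal(nrow(s[[1]]$pairs), 0L)
  expect_equal(s[[1]]$weight, 1)

  # GAAAC: empty structure plus the single (1,5) GC pair
  s <- enumerate_structures("GAAAC")
  expect_length(s, 2L)
  weights <- sort(vapply(s, `[[`, numeric(1), "weight"))
  expect_equal(weights, c(1, exp(3.0 / 0.6163)))

  expect_error(enumerate_structures(random_rna(15)), "L <= 14")
})

test_that("enumeration count matches an independent counting recursion", {
  set.seed(101)
  for (L in c(8L, 11L, 14L)) {
    for (rep in 1:8) {
      seq <- random_rna(L)
      expect_equal(length(enumerate_structures(seq)),
                   count_structures_oracle(seq), info = seq)
    }
  }
})

test_that("compute_bpp matches the closed form on GAAAC and zeros on AAAA", {
  expect_equal(max(abs(compute_bpp("AAAA"))), 0)
  m <- compute_bpp("GAAAC")
  w <- exp(3.0 / 0.6163)
  expect_equal(m[1, 5], w / (1 + w), tolerance = 1e-12)
  expect_equal(sum(m != 0), 2L)  # (1,5) and its mirror
})

test_that("compute_bpp equals the enumeration oracle to 1e-9 on short RNAs", {
  set.seed(202)
  for (rep in 1:50) {
    seq <- random_rna(12L)
    expect_lt(max(abs(unclass(compute_bpp(seq)) - bpp_from_enumeration(seq))),
              1e-9)
  }
  # also at other lengths
  for (L in c(9L, 14L)) {
    seq <- random_rna(L)
    expect_lt(max(abs(unclass(compute_bpp(seq)) - bpp_from_enumeration(seq))),
              1e-9)
  }
})

test_that("compute_bpp row sums stay at most 1 up to L = 200", {
  set.seed(303)
  for (L in c(30L, 60L, 120L, 200L)) {
    m <- compute_bpp(random_rna(L))
    expect_lte(max(rowSums(m)), 1 + 1e-9)
    expect_true(isSymmetric(unclass(m)))
    expect_equal(max(abs(diag(m))), 0)
  }
})

test_that("built-in matrices are deterministic across calls", {
  seq <- random_rna(40L)
  expect_identical(compute_bpp(seq), compute_bpp(seq))
  expect_identical(compute_bpe_standin(seq), compute_bpe_standin(seq))
})

test_that("compute_bpe_standin applies the stacking-aware formula", {
  # (3,7) in GGGAAACCC: own GC pair, no admissible inner neighbor (span too
  # short), admissible outer GC neighbor at (2,8)
  m <- compute_bpe_standin("GGGAAACCC")
  expect_equal(m[3, 7], (-3.0 + 0.5 * (-3.0)) / 6)
  # non-canonical pairs are exactly zero
  expect_equal(m[1, 6], 0)  # G-A
  # symmetric, in range
  expect_true(isSymmetric(unclass(m)))
  expect_true(all(m >= -1 & m <= 1))
})

test_that("compute_bpe_standin is zero exactly on non-admissible entries", {
  set.seed(404)
  model <- energy_model()
  for (rep in 1:10) {
    seq <- random_rna(25L)
    chars <- strsplit(seq, "")[[1]]
    m <- unclass(compute_bpe_standin(seq, model))
    span <- abs(row(m) - col(m))
    canonical <- !is.na(outer(chars, chars, function(a, b)
      ireseek:::pair_energy_of(model, a, b)))
    admissible <- canonical & span > model$min_loop
    expect_true(all(m[!admissible] == 0))
    expect_true(all(m[admissible] < 0))  # energies are negative
  }
})

test_that("load_pair_matrix parses dot plots, plain matrices and errors", {
  # ViennaRNA-style dot plot: value is sqrt(p)
  ps <- tempfile(fileext = ".ps")
  writeLines(c("%!PS-Adobe-3.0", "%%Title: dot plot", "/ubox {} def",
               "1 5 0.5 ubox", "2 4 0.1 lbox"), ps)
  m <- load_pair_matrix(ps, "BPP", 6L)
  expect_equal(m[1, 5], 0.25)
  expect_equal(m[5, 1], 0.25)
  expect_equal(sum(m != 0), 2L)  # lbox records are ignored

  # plain numeric matrix round-trip
  pm <- compute_bpe_standin(random_rna(12L))
  f <- tempfile()
  write_pair_matrix(pm, f)
  back <- load_pair_matrix(f, "BPE", 12L)
  expect_equal(unclass(back), unclass(pm), tolerance = 1e-12)

  # zero matrix parses to zeros
  f0 <- tempfile()
  write.table(matrix(0, 3, 3), f0, row.names = FALSE, col.names = FALSE)
  expect_equal(max(abs(load_pair_matrix(f0, "BPP", 3L))), 0)

  # dimension mismatch and range clipping
  expect_error(load_pair_matrix(f0, "BPP", 4L), "expected 4")
  fbad <- tempfile()
  write.table(matrix(c(0, 1.5, 0, 1.5, 0, 0, 0, 0, 0), 3), fbad,
              row.names = FALSE, col.names = FALSE)
  expect_warning(mb <- load_pair_matrix(fbad, "BPE", 3L), "clipping")
  expect_equal(mb[1, 2], 1)
})

test_that("pair_matrix validates symmetry, range and diagonal", {
  expect_error(pair_matrix(matrix(c(0, 1, 0, 0), 2), "BPP"), "symmetric")
  expect_error(pair_matrix(diag(2), "BPP"), "diagonal")
  m <- matrix(c(0, 2, 2, 0), 2)
  expect_error(pair_matrix(m, "BPP"), "\\[0, 1\\]")
  expect_error(pair_matrix(-m, "BPE"), "\\[-1, 1\\]")
})
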