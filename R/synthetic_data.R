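# Synthetic labeled datasets with controllable sequence (AU-rich motif) and
# structural (planted hairpin) signal, emulating the benchmark's fixed
# length and 4:9 class imbalance.

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Default AU-rich motif profile
#'
#' An 8-column position weight profile over (A, C, G, U) with A and U at
#' probability 0.45 each and C, G at 0.05 -- a concrete stand-in for the
#' AU-rich consensus that distinguishes IRES positives.
#'
#' @return A `4 x 8` column-stochastic matrix with rownames A, C, G, U.
#' @export
default_motif_profile <- function() {
  matrix(rep(c(A = 0.45, C = 0.05, G = 0.05, U = 0.45), 8L), nrow = 4L,
         dimnames = list(c("A", "C", "G", "U"), NULL))
}

#' Synthetic dataset configuration
#'
#' Defaults mirror the benchmark's study conditions: a 4:9
#' positive:negative ratio, a uniform sequence length of 174 nt, and
#' positives that carry both an AU-rich sequence motif and a
#' structure-visible hairpin (8 bp stem, 4 nt loop).
#'
#' @param n_pos,n_neg Class counts.
#' @param length Sequence length in nt (at least 30).
#' @param motif_strength Probability that a positive receives the motif.
#' @param structure_strength Probability that a positive receives the
#'   hairpin.
#' @param label_noise Probability of flipping each label (in `[0, 0.5)`).
#' @param motif Position weight profile (columns sum to 1) for the motif.
#' @param stem_len,loop_len Hairpin geometry.
#' @param seed RNG seed; the generator is a pure function of this
#'   configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pos = 400L, n_neg = 900L, length = 174L,
                             motif_strength = 1, structure_strength = 1,
                             label_noise = 0,
                             motif = default_motif_profile(),
                             stem_len = 8L, loop_len = 4L, seed = 1L) {
  stopifnot(n_pos >= 0L, n_neg >= 0L, length >= 30L,
            motif_strength >= 0, motif_strength <= 1,
            structure_strength >= 0, structure_strength <= 1,
            label_noise >= 0, label_noise < 0.5,
            is.matrix(motif), nrow(motif) == 4L,
            max(abs(colSums(motif) - 1)) < 1e-9,
            stem_len >= 1L, loop_len >= 3L)
  if (ncol(motif) + 2L * stem_len + loop_len > length)
    stop("sequence length too short to host the motif and hairpin insertions")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length = as.integer(length),
                 motif_strength = motif_strength,
                 structure_strength = structure_strength,
                 label_noise = label_noise, motif = motif,
                 stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len), seed = as.integer(seed)),
            class = "synthetic_config")
}

reverse_complement <- function(chars) rev(unname(RNA_COMPLEMENT[chars]))

sample_background <- function(n) sample(c("A", "C", "G", "U"), n, replace = TRUE)

# Compose a sequence of total length L from background plus inserted
# segments (list of character vectors), placed in random order at random
# non-overlapping positions. Returns the sequence and each segment's start.
compose_sequence <- function(L, segments) {
  if (!length(segments))
    return(list(seq = sample_background(L), starts = integer(0)))
  segments <- segments[sample(length(segments))]
  seg_len <- sum(lengths(segments))
  bg_total <- L - seg_len
  k <- length(segments)
  cuts <- sort(sample.int(bg_total + 1L, k, replace = TRUE) - 1L)
  gaps <- diff(c(0L, cuts, bg_total))  # k + 1 background chunk lengths
  out <- character(0)
  starts <- integer(k)
  for (i in seq_len(k)) {
    out <- c(out, sample_background(gaps[i]))
    starts[i] <- length(out) + 1L
    out <- c(out, segments[[i]])
  }
  out <- c(out, sample_background(gaps[k + 1L]))
  names(starts) <- names(segments)
  list(seq = out, starts = starts)
}

#' Generate a synthetic labeled dataset
#'
#' Negatives are i.i.d. uniform ACGU background. Positives start as
#' background and then, independently with probability `motif_strength`,
#' receive a motif sampled column-wise from the profile and, with
#' probability `structure_strength`, a perfect hairpin (random stem followed
#' after a random loop by its reverse complement) -- giving positives both a
#' sequence signal and a base-pair-probability-visible structural signal.
#' Finally each label flips with probability `label_noise`. The result is a
#' pure function of the configuration (byte-identical across runs).
#'
#' @param cfg A [synthetic_config()].
#' @param prefix Record-id prefix.
#' @return A labeled dataset whose records carry additional columns
#'   `motif_start` and `hp_start` (1-based insertion starts, `NA` when the
#'   insertion was not made; `hp_start` is the first base of the 5' stem
#'   arm).
#' @export
generate_dataset <- function(cfg, prefix = "syn") {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_pos + cfg$n_neg
    truth <- rep(c(1L, 0L), c(cfg$n_pos, cfg$n_neg))
    rows <- lapply(seq_len(n), function(i) {
      segments <- list()
      if (truth[i] == 1L) {
        if (runif(1) < cfg$motif_strength) {
          motif <- vapply(seq_len(ncol(cfg$motif)), function(j)
            sample(rownames(cfg$motif), 1L, prob = cfg$motif[, j]),
            character(1))
          segments$motif <- motif
        }
        if (runif(1) < cfg$structure_strength) {
          stem <- sample_background(cfg$stem_len)
          segments$hairpin <- c(stem, sample_background(cfg$loop_len),
                                reverse_complement(stem))
        }
      }
      comp <- compose_sequence(cfg$length, segments)
      data.frame(
        seq = paste(comp$seq, collapse = ""),
        motif_start = unname(comp$starts["motif"] %|NA|% NA_integer_),
        hp_start = unname(comp$starts["hairpin"] %|NA|% NA_integer_)
      )
    })
    df <- do.call(rbind, rows)
    label <- truth
    flip <- runif(n) < cfg$label_noise
    label[flip] <- 1L - label[flip]
    records <- data.frame(
      id = sprintf("%s_%s_%04d", prefix, ifelse(truth == 1L, "pos", "neg"),
                   seq_len(n)),
      raw_seq = df$seq, canon_seq = df$seq, label = label,
      motif_start = df$motif_start, hp_start = df$hp_start,
      stringsAsFactors = FALSE
    )
    out <- labeled_dataset(records)
    out$truth <- truth
    out$config <- cfg
    out
  })
}

`%|NA|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Planted hairpin pair indices of a synthetic record
#'
#' @param record One row of a [generate_dataset()] records data frame.
#' @param cfg The generating [synthetic_config()].
#' @return 2-column matrix of the stem's (i, j) index pairs, or `NULL` if no
#'   hairpin was inserted.
#' @export
hairpin_pairs <- function(record, cfg) {
  s <- record$hp_start
  if (is.na(s)) return(NULL)
  total <- 2L * cfg$stem_len + cfg$loop_len
  cbind(i = s + seq_len(cfg$stem_len) - 1L,
        j = s + total - seq_len(cfg$stem_len))
}

#' Composition summary of a labeled dataset
#'
#' @param data A labeled dataset.
#' @return A list with per-class counts, the sequence-length range, and
#'   per-class mononucleotide frequencies (including the combined A+U
#'   fraction).
#' @export
summarize_dataset <- function(data) {
  stopifnot(inherits(data, "ireseek_dataset"), nrow(data$records) > 0L)
  freqs <- function(rows) {
    chars <- strsplit(paste(rows$canon_seq, collapse = ""), "")[[1L]]
    tab <- table(factor(chars, levels = c("A", "C", "G", "U")))
    p <- as.numeric(tab) / length(chars)
    names(p) <- c("A", "C", "G", "U")
    c(p, AU = unname(p["A"] + p["U"]))
  }
  pos <- data$records[data$records$label == 1L, , drop = FALSE]
  neg <- data$records[data$records$label == 0L, , drop = FALSE]
  list(
    n_pos = data$n_pos, n_neg = data$n_neg,
    length_range = range(nchar(data$records$canon_seq)),
    freq_pos = if (nrow(pos)) freqs(pos) else NULL,
    freq_neg = if (nrow(neg)) freqs(neg) else NULL
  )
}

#' Write a dataset as FASTA + label TSV
#'
#' @param data A labeled dataset.
#' @param fasta_path,labels_path Output paths.
#' @export
write_dataset <- function(data, fasta_path, labels_path) {
  write_fasta(data$records, fasta_path)
  write_labels(data, labels_path)
  invisible(c(fasta_path, labels_path))
}

#' Verify a benchmark directory against the published split sizes
#'
#' Reads train/test FASTA and label files and checks the class counts and
#' the uniform sequence length against the published benchmark composition
#' (training 3949 positive / 9034 negative, test 582 / 582, all sequences
#' 174 nt). Works on the deposited benchmark after download, or on any
#' emulation of it.
#'
#' @param train_fasta,train_labels,test_fasta,test_labels File paths.
#' @param expected Named list of expected values.
#' @return A list with the observed counts, the expectation, and `ok`.
#' @export
verify_benchmark_dataset <- function(train_fasta, train_labels,
                                     test_fasta, test_labels,
                                     expected = list(train_pos = 3949L,
                                                     train_neg = 9034L,
                                                     test_pos = 582L,
                                                     test_neg = 582L,
                                                     length = 174L)) {
  train <- read_labels(train_labels, read_fasta(train_fasta))
  test <- read_labels(test_labels, read_fasta(test_fasta))
  lens <- unique(nchar(c(train$records$canon_seq, test$records$canon_seq)))
  observed <- list(train_pos = train$n_pos, train_neg = train$n_neg,
                   test_pos = test$n_pos, test_neg = test$n_neg,
                   length = if (length(lens) == 1L) lens else lens)
  ok <- length(lens) == 1L &&
    identical(as.integer(unlist(observed)), as.integer(unlist(expected)))
  list(observed = observed, expected = expected, ok = ok)
}
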