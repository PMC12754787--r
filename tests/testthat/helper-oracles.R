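# Independent oracles and small fixture builders used across the suite.

random_rna <- function(L) paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                                collapse = "")

# Independent structure-counting recursion (counts only, no enumeration):
# N(i, j) = N(i+1, j) + sum_k canonical(i,k) N(i+1, k-1) N(k+1, j).
count_structures_oracle <- function(seq, model = energy_model()) {
  chars <- strsplit(seq, "")[[1]]
  ml <- model$min_loop
  canonical <- function(a, b) paste0(min(a, b), max(a, b)) %in%
    c("CG", "AU", "GU")
  memo <- new.env()
  cnt <- function(i, j) {
    if (i > j) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    n <- cnt(i + 1, j)
    if (i + ml + 1 <= j)
      for (k in (i + ml + 1):j)
        if (canonical(chars[i], chars[k]))
          n <- n + cnt(i + 1, k - 1) * cnt(k + 1, j)
    memo[[key]] <- n
    n
  }
  cnt(1, length(chars))
}

# Pair probabilities from the enumeration listing (the brute-force oracle).
bpp_from_enumeration <- function(seq, model = energy_model()) {
  structs <- enumerate_structures(seq, model)
  L <- nchar(seq)
  z <- sum(vapply(structs, `[[`, numeric(1), "weight"))
  p <- matrix(0, L, L)
  for (s in structs) {
    if (!nrow(s$pairs)) next
    p[s$pairs] <- p[s$pairs] + s$weight
  }
  p <- p + t(p)
  p / z
}

# Exhaustive Mann-Whitney pair counting.
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# A small model state for network tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(d = 8L, n_blocks = 1L, n_heads = 2L, gcn_layers = 2L,
         mlp_hidden = 8L, dropout = 0, seed = 42L),
    list(...))
  do.call(model_config, args)
}

# Features for a set of sequences under a config (builtin structure).
features_for <- function(seqs, config, model = energy_model()) {
  records <- data.frame(id = paste0("s", seq_along(seqs)), raw_seq = seqs,
                        canon_seq = seqs, label = NA_integer_,
                        stringsAsFactors = FALSE)
  featurize_dataset(records, config, model)
}

# Labeled dataset straight from sequences and labels.
dataset_from <- function(seqs, labels) {
  labeled_dataset(data.frame(
    id = paste0("s", seq_along(seqs)), raw_seq = seqs, canon_seq = seqs,
    label = as.integer(labels), stringsAsFactors = FALSE))
}

write_tmp_fasta <- function(seqs, ids = paste0("s", seq_along(seqs)),
                            width = 70L) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(seq_along(seqs), function(i) {
    starts <- seq(1L, nchar(seqs[i]), by = width)
    c(paste0(">", ids[i]),
      substring(seqs[i], starts, pmin(starts + width - 1L, nchar(seqs[i]))))
  }))
  writeLines(lines, path)
  path
}

write_tmp_labels <- function(ids, labels) {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(ids, labels, sep = "\t"), path)
  path
}
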