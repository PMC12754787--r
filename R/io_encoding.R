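# Sequence input, canonicalization and one-hot encoding.

IRESEEK_ALPHABET <- c("A", "G", "C", "U")

#' Canonicalize a raw sequence to the RNA alphabet
#'
#' Uppercases the input, maps `T` to `U`, and maps every remaining character
#' outside `A/C/G/U` deterministically to `A`. Length is preserved, so
#' downstream position indices keep their meaning.
#'
#' @param raw Non-empty character scalar (arbitrary characters).
#' @return Character scalar over `A/C/G/U` of the same length as `raw`.
#' @examples
#' preprocess_sequence("acgt") # "ACGU"
#' preprocess_sequence("ANG")  # "AAG"
#' @export
preprocess_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L)
    stop("`raw` must be a non-empty character scalar")
  up <- chartr("T", "U", toupper(raw))
  gsub("[^ACGU]", "A", up)
}

# Number of characters preprocess_sequence would rewrite (for logging).
n_noncanonical <- function(raw) {
  up <- chartr("T", "U", toupper(raw))
  nchar(gsub("[ACGU]", "", up))
}

#' Read sequences from a FASTA file
#'
#' Headers are truncated at the first whitespace to form record ids; wrapped
#' sequence lines are concatenated. Each record's canonical form is produced
#' by [preprocess_sequence()]. Plain and gzip-compressed files are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `raw_seq`, `canon_seq` and `label`
#'   (all labels `NA` until [read_labels()] attaches them), one row per
#'   record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  first <- character(0)
  repeat {
    l <- readLines(con, n = 1L, warn = FALSE)
    if (!length(l)) break
    if (nzchar(trimws(l))) {
      first <- l
      break
    }
  }
  close(con)
  if (!length(first)) stop("FASTA file is empty: ", path)
  if (!startsWith(trimws(first), ">"))
    stop("not a FASTA file (first non-blank character is not '>'): ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  empty <- !nzchar(seqs) | is.na(seqs)
  if (any(empty))
    stop("FASTA entry with empty sequence: ", paste(ids[empty], collapse = ", "))
  n_sub <- vapply(seqs, n_noncanonical, numeric(1))
  if (any(n_sub > 0))
    message(sum(n_sub), " non-ACGUT character(s) mapped to A in record(s): ",
            paste(ids[n_sub > 0], collapse = ", "))
  data.frame(
    id = ids,
    raw_seq = unname(seqs),
    canon_seq = vapply(unname(seqs), preprocess_sequence, character(1),
                       USE.NAMES = FALSE),
    label = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Write records to a FASTA file
#'
#' @param records Data frame with `id` and `canon_seq` columns.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(setNames(records$canon_seq, records$id))
  atomic_write(path, function(tmp)
    Biostrings::writeXStringSet(set, tmp, width = width))
}

#' Attach binary labels to FASTA records
#'
#' Reads a two-column tab-separated file (`id<TAB>label`, label 0/1; an
#' optional `id<TAB>label` header row is tolerated) and joins it strictly onto
#' `records`: every record id must appear exactly once, and no extra ids may
#' be present.
#'
#' @param path Path to the label TSV.
#' @param records Data frame as returned by [read_fasta()].
#' @return A labeled dataset object (see [labeled_dataset()]).
#' @export
read_labels <- function(path, records) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character", col.names = c("id", "label"))
  if (nrow(tab) > 0L && tab$id[1L] == "id" && tab$label[1L] == "label")
    tab <- tab[-1L, , drop = FALSE]
  if (anyDuplicated(tab$id))
    stop("duplicate id(s) in label file: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  extra <- setdiff(tab$id, records$id)
  if (length(extra))
    stop("label file contains unknown id(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(records$id, tab$id)
  if (length(missing))
    stop("no label for record(s): ", paste(missing, collapse = ", "))
  bad <- !tab$label %in% c("0", "1")
  if (any(bad))
    stop("label outside {0,1} for id(s): ", paste(tab$id[bad], collapse = ", "))
  records$label <- as.integer(tab$label[match(records$id, tab$id)])
  labeled_dataset(records)
}

#' Construct a labeled dataset
#'
#' @param records Data frame with columns `id`, `canon_seq` and a complete
#'   binary `label` column (1 = IRES, 0 = non-IRES).
#' @return An object of class `ireseek_dataset`: a list with `records`,
#'   `n_pos` and `n_neg`.
#' @export
labeled_dataset <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "canon_seq", "label") %in%
                                          names(records)))
  if (anyNA(records$label)) stop("all records must carry a label")
  if (!all(records$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  structure(
    list(records = records,
         n_pos = sum(records$label == 1L),
         n_neg = sum(records$label == 0L)),
    class = "ireseek_dataset"
  )
}

#' @export
print.ireseek_dataset <- function(x, ...) {
  cat("ireseek dataset:", nrow(x$records), "records (",
      x$n_pos, "positive /", x$n_neg, "negative )\n")
  lens <- range(nchar(x$records$canon_seq))
  cat("sequence length:", if (lens[1] == lens[2]) lens[1]
      else paste(lens[1], "-", lens[2]), "nt\n")
  invisible(x)
}

#' Write a labeled dataset's labels to TSV
#'
#' @param data A labeled dataset.
#' @param path Output path (`id<TAB>label`, no header).
#' @export
write_labels <- function(data, path) {
  atomic_write(path, function(tmp)
    write.table(data$records[, c("id", "label")], tmp, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE))
}

#' One-hot encode a canonical RNA sequence
#'
#' Column order is fixed as (A, G, C, U): `A` maps to `(1,0,0,0)`, `G` to
#' `(0,1,0,0)`, `C` to `(0,0,1,0)` and `U` to `(0,0,0,1)`.
#'
#' @param canon_seq Character scalar over `A/C/G/U`
#'   (run [preprocess_sequence()] first for raw input).
#' @return An `L x 4` numeric 0/1 matrix with one row per nucleotide.
#' @export
one_hot_encode <- function(canon_seq) {
  stopifnot(is.character(canon_seq), length(canon_seq) == 1L,
            nchar(canon_seq) > 0L)
  chars <- strsplit(canon_seq, "", fixed = TRUE)[[1L]]
  idx <- match(chars, IRESEEK_ALPHABET)
  if (anyNA(idx))
    stop("character(s) outside A/C/G/U: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "),
         " (run preprocess_sequence first)")
  m <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, IRESEEK_ALPHABET))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}
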