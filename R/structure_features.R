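# Structural-guidance matrices: base-pair probability (BPP) from a built-in
# simplified partition function, and a stacking-aware base-pair motif energy
# (BPE) stand-in, plus adapters for externally computed matrices.

#' Simplified base-pairing energy model
#'
#' Additive per-pair free energies over canonical pairs (Watson-Crick plus GU
#' wobble, both strand orders), no loop terms, hairpin loops of at least
#' `min_loop` unpaired bases. This is the model behind [compute_bpp()] and
#' [compute_bpe_standin()]; externally computed matrices can be substituted
#' via [load_pair_matrix()].
#'
#' @param pair_energy Named energies in kcal/mol for `GC`, `AU`, `GU`
#'   (must be negative).
#' @param RT Thermal energy in kcal/mol (default 0.6163, i.e. 310.15 K).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(pair_energy = c(GC = -3.0, AU = -2.0, GU = -1.0),
                         RT = 0.6163, min_loop = 3L) {
  stopifnot(all(c("GC", "AU", "GU") %in% names(pair_energy)),
            all(pair_energy < 0), RT > 0, min_loop >= 3L)
  structure(list(pair_energy = pair_energy, RT = RT,
                 min_loop = as.integer(min_loop)),
            class = "energy_model")
}

# Energy of pairing bases a, b (vectors); NA for non-canonical combinations.
pair_energy_of <- function(model, a, b) {
  key <- paste0(pmin(a, b), pmax(a, b))  # order-free lookup
  lut <- c(CG = model$pair_energy[["GC"]], AU = model$pair_energy[["AU"]],
           GU = model$pair_energy[["GU"]])
  unname(lut[key])
}

#' Construct/validate a pair matrix
#'
#' An `L x L` symmetric matrix of per-pair structural scores: kind `BPP`
#' (base-pair probabilities in `[0,1]`, row sums at most 1) or kind `BPE`
#' (normalized base-pair motif energies in `[-1,1]`). The diagonal is zero.
#'
#' @param values Symmetric numeric matrix.
#' @param kind `"BPP"` or `"BPE"`.
#' @return The matrix with class `pair_matrix` and attribute `kind`.
#' @export
pair_matrix <- function(values, kind = c("BPP", "BPE")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-9) stop("pair matrix must be symmetric")
  if (any(diag(values) != 0)) stop("pair matrix diagonal must be zero")
  if (kind == "BPP") {
    if (min(values) < 0 || max(values) > 1 + 1e-9)
      stop("BPP entries must lie in [0, 1]")
    if (max(rowSums(values)) > 1 + 1e-9)
      stop("BPP row sums must not exceed 1")
  } else if (min(values) < -1 - 1e-9 || max(values) > 1 + 1e-9) {
    stop("BPE entries must lie in [-1, 1]")
  }
  structure(values, class = c("pair_matrix", "matrix"), kind = kind)
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("%s pair matrix, L = %d, %d nonzero upper-triangle entries\n",
              attr(x, "kind"), nrow(x), sum(x[upper.tri(x)] != 0)))
  invisible(x)
}

check_canon <- function(canon_seq) {
  if (!is.character(canon_seq) || length(canon_seq) != 1L ||
      nchar(canon_seq) == 0L || grepl("[^ACGU]", canon_seq))
    stop("`canon_seq` must be a non-empty string over A/C/G/U")
  strsplit(canon_seq, "", fixed = TRUE)[[1L]]
}

#' Enumerate all secondary structures of a short sequence
#'
#' Brute-force listing of every pseudoknot-free set of canonical pairs with
#' hairpin loops of at least `min_loop` unpaired bases, including the empty
#' structure, each with its Boltzmann weight `exp(-E/RT)` where `E` is the
#' sum of pair energies. Serves as an exact oracle for [compute_bpp()] on
#' short sequences.
#'
#' @param canon_seq Sequence over `A/C/G/U`, at most 14 nt (the structure
#'   count grows combinatorially).
#' @param model An [energy_model()].
#' @return A list of structures; each is a list with `pairs` (2-column
#'   matrix of 1-based index pairs, `i < j`), `energy` and `weight`.
#' @export
enumerate_structures <- function(canon_seq, model = energy_model()) {
  chars <- check_canon(canon_seq)
  L <- length(chars)
  if (L > 14L)
    stop("enumerate_structures is limited to L <= 14; use compute_bpp")
  ml <- model$min_loop
  empty <- matrix(integer(0), ncol = 2L)
  rec <- function(i, j) {
    if (i > j) return(list(empty))
    out <- rec(i + 1L, j)  # i unpaired
    ks <- if (i + ml + 1L <= j) seq.int(i + ml + 1L, j) else integer(0)
    for (k in ks) {
      if (is.na(pair_energy_of(model, chars[i], chars[k]))) next
      inner <- rec(i + 1L, k - 1L)
      outer <- rec(k + 1L, j)
      for (si in inner) for (so in outer)
        out[[length(out) + 1L]] <- rbind(matrix(c(i, k), ncol = 2L), si, so)
    }
    out
  }
  lapply(rec(1L, L), function(p) {
    e <- if (nrow(p)) sum(pair_energy_of(model, chars[p[, 1L]], chars[p[, 2L]]))
         else 0
    list(pairs = p, energy = e, weight = exp(-e / model$RT))
  })
}

#' Base-pair probability matrix by McCaskill-style recursions
#'
#' Computes, for every admissible canonical pair `(i, j)`, the Boltzmann
#' probability that the two bases pair, by inside-outside dynamic programming
#' over all pseudoknot-free structures under the simplified
#' [energy_model()]. Deterministic; agrees with [enumerate_structures()]
#' exactly (to numerical precision) on short sequences.
#'
#' @inheritParams enumerate_structures
#' @param canon_seq Sequence over `A/C/G/U` (any length; the unscaled
#'   recursion is intended for sequences up to a few hundred nt).
#' @return A [pair_matrix()] of kind `BPP`.
#' @export
compute_bpp <- function(canon_seq, model = energy_model()) {
  check_canon(canon_seq)
  vals <- cpp_bpp(canon_seq, model$pair_energy[["GC"]],
                  model$pair_energy[["AU"]], model$pair_energy[["GU"]],
                  model$RT, model$min_loop)
  pair_matrix(vals, "BPP")
}

#' Base-pair motif energy (BPE) stand-in
#'
#' A stacking-aware per-pair energy score: for each admissible canonical pair
#' `(i, j)` the raw score is its pair energy plus half the pair energy of
#' each immediately stacked neighbor pair (`(i+1, j-1)` inward, `(i-1, j+1)`
#' outward) when that neighbor is itself canonical and admissible. Raw scores
#' are normalized by 6 (the magnitude of the strongest attainable raw score)
#' and clipped into `[-1, 1]`; non-admissible entries are zero. The result
#' mimics the character of a trained base-pair motif energy: stronger,
#' stacked pairs score more negative.
#'
#' @inheritParams enumerate_structures
#' @param canon_seq Sequence over `A/C/G/U`.
#' @return A [pair_matrix()] of kind `BPE`.
#' @export
compute_bpe_standin <- function(canon_seq, model = energy_model()) {
  chars <- check_canon(canon_seq)
  L <- length(chars)
  E <- outer(chars, chars, function(a, b) pair_energy_of(model, a, b))
  span_ok <- abs(row(E) - col(E)) > model$min_loop
  adm <- !is.na(E) & span_ok
  M <- ifelse(adm, E, 0)
  inner <- matrix(0, L, L)
  if (L > 1L) inner[1:(L - 1L), 2:L] <- M[2:L, 1:(L - 1L)]
  outer_nb <- matrix(0, L, L)
  if (L > 1L) outer_nb[2:L, 1:(L - 1L)] <- M[1:(L - 1L), 2:L]
  raw <- M + 0.5 * inner + 0.5 * outer_nb
  raw[!adm] <- 0
  pair_matrix(pmin(pmax(raw / 6, -1), 1), "BPE")
}

#' Load a pair matrix computed by an external tool
#'
#' Accepts either a ViennaRNA dot-plot PostScript file (records
#' `i j v ubox`, where `v` is the square root of the pair probability) or a
#' plain whitespace-separated `L x L` numeric matrix. The result is
#' symmetrized by taking the elementwise maximum of the two triangles; values
#' outside the kind's range are clipped, with a warning when the violation
#' exceeds `1e-6`.
#'
#' @param path File to read.
#' @param kind `"BPP"` or `"BPE"`.
#' @param L_expected Expected sequence length; a mismatch is an error.
#' @return A [pair_matrix()].
#' @export
load_pair_matrix <- function(path, kind = c("BPP", "BPE"), L_expected) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("pair matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ubox <- grep("\\bubox\\b", lines, value = TRUE)
  ubox <- ubox[grepl("^\\s*\\d+\\s+\\d+\\s+[0-9.eE+-]+\\s+ubox", ubox)]
  if (length(ubox)) {
    m <- matrix(0, L_expected, L_expected)
    parts <- strsplit(trimws(ubox), "\\s+")
    for (p in parts) {
      i <- as.integer(p[1L]); j <- as.integer(p[2L]); v <- as.numeric(p[3L])
      if (is.na(i) || is.na(j) || is.na(v))
        stop("unparseable ubox record in ", path)
      if (i > L_expected || j > L_expected || i < 1L || j < 1L)
        stop("dot-plot index (", i, ", ", j, ") exceeds L_expected = ",
             L_expected)
      m[i, j] <- v^2  # dot plots store sqrt(p)
    }
  } else {
    toks <- scan(text = lines, quiet = TRUE)
    if (length(toks) != L_expected^2)
      stop("matrix in ", path, " has ", length(toks), " values; expected ",
           L_expected, "x", L_expected)
    m <- matrix(toks, nrow = L_expected, byrow = TRUE)
  }
  m <- pmax(m, t(m))
  diag(m) <- 0
  rng <- if (kind == "BPP") c(0, 1) else c(-1, 1)
  excess <- max(0, max(m) - rng[2L], rng[1L] - min(m))
  if (excess > 1e-6)
    warning("values outside the ", kind, " range by up to ",
            format(excess), "; clipping")
  m <- pmin(pmax(m, rng[1L]), rng[2L])
  pair_matrix(m, kind)
}

#' Write a pair matrix as plain text
#'
#' @param pm A [pair_matrix()].
#' @param path Output path (whitespace-separated `L x L` values, readable by
#'   [load_pair_matrix()]).
#' @export
write_pair_matrix <- function(pm, path) {
  atomic_write(path, function(tmp)
    write.table(unclass(pm), tmp, row.names = FALSE, col.names = FALSE))
}
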