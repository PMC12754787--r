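# Per-record feature construction: one-hot encodings and normalized
# base-pair adjacencies for the branches the configuration enables.

#' Compute model inputs for a set of records
#'
#' Builds, for every record, the `L x 4` one-hot encoding and -- for each
#' enabled structural branch -- the symmetrically normalized adjacency of
#' its base-pair graph. Structural matrices come either from the built-in
#' energy model ([compute_bpp()], [compute_bpe_standin()]) or from per-record
#' files produced by external tools (ViennaRNA dot plots or plain matrices;
#' see [load_pair_matrix()]).
#'
#' @param data A labeled dataset or a records data frame.
#' @param config A [model_config()]; only the enabled branches are computed.
#' @param model An [energy_model()] for the built-in computations.
#' @param structure `"builtin"` or `"files"`.
#' @param bpp_dir,bpe_dir Directories searched (in `files` mode) for
#'   `<id>_dp.ps`, `<id>.ps`, `<id>.txt` or `<id>.mat`.
#' @return A list with `ids`, `X` (list of one-hot matrices) and, when
#'   enabled, `Ap` / `Ae` (lists of normalized adjacency matrices).
#' @export
featurize_dataset <- function(data, config, model = energy_model(),
                              structure = c("builtin", "files"),
                              bpp_dir = NULL, bpe_dir = NULL) {
  structure <- match.arg(structure)
  records <- if (inherits(data, "ireseek_dataset")) data$records else data
  stopifnot(is.data.frame(records), inherits(config, "model_config"))
  seqs <- records$canon_seq
  out <- list(ids = records$id, X = lapply(seqs, one_hot_encode))
  get_pm <- function(id, L, kind, dir) {
    if (structure == "builtin") {
      seq <- seqs[match(id, records$id)]
      if (kind == "BPP") compute_bpp(seq, model)
      else compute_bpe_standin(seq, model)
    } else {
      if (is.null(dir)) stop("structure = 'files' requires the matrix dir")
      cand <- file.path(dir, paste0(id, c("_dp.ps", ".ps", ".txt", ".mat")))
      hit <- cand[file.exists(cand)]
      if (!length(hit)) stop("no ", kind, " matrix file found for record ", id)
      load_pair_matrix(hit[1L], kind, L)
    }
  }
  if (config$use_bpp)
    out$Ap <- lapply(seq_along(seqs), function(i)
      adjacency_from_pair_matrix(
        get_pm(records$id[i], nchar(seqs[i]), "BPP", bpp_dir)))
  if (config$use_bpe)
    out$Ae <- lapply(seq_along(seqs), function(i)
      adjacency_from_pair_matrix(
        get_pm(records$id[i], nchar(seqs[i]), "BPE", bpe_dir)))
  out
}

# Subset a feature list by record indices (used by the sampling plans).
subset_features <- function(features, idx) {
  out <- list(ids = features$ids[idx], X = features$X[idx])
  if (!is.null(features$Ap)) out$Ap <- features$Ap[idx]
  if (!is.null(features$Ae)) out$Ae <- features$Ae[idx]
  out
}
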