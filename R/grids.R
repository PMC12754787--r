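# Ablation and hyperparameter grids, plus run manifests.

#' Write / finalize a run manifest
#'
#' A manifest makes a run directory self-describing: the command, the full
#' configuration snapshot, seeds, package and R versions, input-file digests
#' and timestamps. It is written with status `"running"` before work starts
#' and finalized (status `"done"`, end timestamp, outputs) afterwards.
#'
#' @param dir Run directory (created if needed).
#' @param command Command name.
#' @param config Configuration snapshot (any list; serialized as JSON).
#' @param seed Seed(s) in use.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, command, config = list(), seed = NA,
                               inputs = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    command = command,
    status = "running",
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    package_version = as.character(utils::packageVersion("ireseek")),
    r_version = R.version.string,
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  )
  path <- file.path(dir, "manifest.json")
  atomic_write(path, function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE))
  invisible(path)
}

#' @rdname write_run_manifest
#' @param outputs Character vector of produced output paths.
#' @export
finalize_run_manifest <- function(dir, outputs = character()) {
  path <- file.path(dir, "manifest.json")
  manifest <- jsonlite::read_json(path)
  manifest$status <- "done"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$outputs <- as.list(outputs)
  atomic_write(path, function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE))
  invisible(path)
}

grid_eval <- function(train, test, config, train_cfg, train_features,
                      test_features, strategy) {
  ens <- train_ensemble(train, train_features, config, train_cfg, strategy)
  pred <- predict(ens, test_features)
  evaluate_scores(pred$prob, test$records$label)
}

#' Feature-ablation grid
#'
#' Trains the soft-voting ensemble once per feature configuration --
#' sequence plus both structural matrices, sequence plus one of them, and
#' sequence alone -- under shared seeds, and reports the test metrics of
#' each.
#'
#' @param train,test Labeled datasets.
#' @param config Base [model_config()] (its flags are overridden per row).
#' @param train_cfg A [train_config()] shared by all rows.
#' @param model An [energy_model()] for feature computation.
#' @param out_dir Optional run directory; written as TSV and JSON with a
#'   manifest.
#' @return Data frame with one row per configuration
#'   (`seq+BPE+BPP`, `seq+BPE`, `seq+BPP`, `seq`) and the metric columns.
#' @export
run_ablation_grid <- function(train, test, config = model_config(),
                              train_cfg = train_config(),
                              model = energy_model(), out_dir = NULL) {
  if (!is.null(out_dir))
    write_run_manifest(out_dir, "ablation",
                       list(model = unclass(config),
                            train = unclass(train_cfg)),
                       seed = train_cfg$seed)
  full_cfg <- modify_config(config, use_bpp = TRUE, use_bpe = TRUE)
  train_feats <- featurize_dataset(train, full_cfg, model)
  test_feats <- featurize_dataset(test, full_cfg, model)
  flags <- list(`seq+BPE+BPP` = c(TRUE, TRUE), `seq+BPE` = c(FALSE, TRUE),
                `seq+BPP` = c(TRUE, FALSE), seq = c(FALSE, FALSE))
  rows <- lapply(names(flags), function(lab) {
    fl <- flags[[lab]]
    cfg_i <- modify_config(config, use_bpp = fl[1L], use_bpe = fl[2L])
    rep <- grid_eval(train, test, cfg_i, train_cfg,
                     strip_features(train_feats, cfg_i),
                     strip_features(test_feats, cfg_i), "ensemble")
    cbind(data.frame(config = lab, use_bpp = fl[1L], use_bpe = fl[2L]),
          metrics_row(rep))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    tsv <- file.path(out_dir, "ablation.tsv")
    atomic_write(tsv, function(tmp)
      write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
    js <- file.path(out_dir, "ablation.json")
    atomic_write(js, function(tmp)
      jsonlite::write_json(out, tmp, digits = NA, pretty = TRUE))
    finalize_run_manifest(out_dir, c(tsv, js))
  }
  out
}

#' Hyperparameter grid: GCN depth x hidden dimension x sampling strategy
#'
#' Trains one model (or ensemble) per combination of GCN layers, hidden
#' dimension and sampling strategy, under shared seeds, and reports test
#' metrics.
#'
#' @inheritParams run_ablation_grid
#' @param layers GCN depths to scan.
#' @param dims Hidden dimensions to scan.
#' @param strategies Sampling strategies to scan.
#' @return Wide data frame (one row per combination, metric columns); when
#'   `out_dir` is given a long-format TSV
#'   (`layers`, `dim`, `strategy`, `metric`, `value`) is also written.
#' @export
run_hyperparameter_grid <- function(train, test, config = model_config(),
                                    train_cfg = train_config(),
                                    model = energy_model(),
                                    layers = c(2L, 4L, 8L),
                                    dims = c(16L, 32L, 64L),
                                    strategies = c("over", "under",
                                                   "ensemble"),
                                    out_dir = NULL) {
  if (!is.null(out_dir))
    write_run_manifest(out_dir, "hpgrid",
                       list(model = unclass(config),
                            train = unclass(train_cfg),
                            layers = layers, dims = dims,
                            strategies = strategies),
                       seed = train_cfg$seed)
  base_cfg <- modify_config(config, use_bpp = TRUE, use_bpe = TRUE)
  train_feats <- featurize_dataset(train, base_cfg, model)
  test_feats <- featurize_dataset(test, base_cfg, model)
  grid <- expand.grid(layers = layers, dim = dims, strategy = strategies,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- modify_config(config, d = grid$dim[i], n_heads = NULL,
                           gcn_layers = grid$layers[i])
    rep <- grid_eval(train, test, cfg_i, train_cfg,
                     strip_features(train_feats, cfg_i),
                     strip_features(test_feats, cfg_i), grid$strategy[i])
    cbind(grid[i, , drop = FALSE], metrics_row(rep))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    long <- do.call(rbind, lapply(c("ACC", "P", "R", "F1", "MCC", "AUROC"),
                                  function(m)
      data.frame(layers = out$layers, dim = out$dim, strategy = out$strategy,
                 metric = m, value = out[[m]])))
    tsv <- file.path(out_dir, "hpgrid_long.tsv")
    atomic_write(tsv, function(tmp)
      write.table(long, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
    finalize_run_manifest(out_dir, tsv)
  }
  out
}

# Rebuild a model_config with some fields replaced (re-validating).
modify_config <- function(config, ...) {
  args <- utils::modifyList(
    list(d = config$d, n_blocks = config$n_blocks, n_heads = config$n_heads,
         ffn_mult = config$ffn_mult, conv_kernels = config$conv_kernels,
         gcn_layers = config$gcn_layers, use_bpp = config$use_bpp,
         use_bpe = config$use_bpe, mlp_hidden = config$mlp_hidden,
         dropout = config$dropout, add_pos = config$add_pos,
         bn_momentum = config$bn_momentum, seed = config$seed),
    list(...), keep.null = TRUE)
  do.call(model_config, args)
}

# Drop structural features a configuration does not use.
strip_features <- function(features, config) {
  out <- features
  if (!config$use_bpp) out$Ap <- NULL
  if (!config$use_bpe) out$Ae <- NULL
  out
}
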