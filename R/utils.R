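# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Flatten a nested parameter list into one numeric vector (row-major over the
# list structure; matrices keep their column-major internal layout).
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

# Inverse of flatten_params given a skeleton with the same shapes.
relist_params <- function(flat, skeleton) {
  pos <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    out <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  out <- rec(skeleton)
  stopifnot(pos == length(flat))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write `lines`/object atomically: temp file in the same directory, then rename.
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file onto ", path)
  invisible(path)
}
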