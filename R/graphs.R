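# Base-pair graphs and the symmetrically normalized adjacency operator.

#' Build an undirected weighted graph from a pair matrix
#'
#' One node per nucleotide; an edge `(i, j, values[i, j])` for every `i < j`
#' whose absolute weight exceeds `edge_threshold`. By default BPP graphs use
#' a threshold of `1e-4` (bounding graph density against the many tiny
#' probabilities a partition function produces) and BPE graphs use 0 (every
#' nonzero energy entry becomes an edge).
#'
#' @param matrix A [pair_matrix()].
#' @param edge_threshold Nonnegative scalar; `NULL` picks the kind default.
#' @return An object of class `structure_graph`: a list with `n_nodes`,
#'   `edges` (data frame `i`, `j`, `w` with `i < j`) and `kind`.
#' @export
build_graph <- function(matrix, edge_threshold = NULL) {
  stopifnot(inherits(matrix, "pair_matrix"))
  kind <- attr(matrix, "kind")
  if (is.null(edge_threshold))
    edge_threshold <- if (kind == "BPP") 1e-4 else 0
  stopifnot(edge_threshold >= 0)
  m <- unclass(matrix)
  keep <- which(upper.tri(m) & abs(m) > edge_threshold, arr.ind = TRUE)
  structure(
    list(n_nodes = nrow(m),
         edges = data.frame(i = keep[, 1L], j = keep[, 2L],
                            w = m[keep]),
         kind = kind),
    class = "structure_graph"
  )
}

#' @export
print.structure_graph <- function(x, ...) {
  cat(sprintf("%s structure graph: %d nodes, %d edges\n", x$kind, x$n_nodes,
              nrow(x$edges)))
  invisible(x)
}

#' Symmetrically normalized adjacency operator
#'
#' Reconstructs the weight matrix `M` from the graph's edges and returns
#' `D^(-1/2) (M + I) D^(-1/2)`, the graph-convolution propagation operator.
#' Degrees use absolute values, `D_ii = sum_j |M_ij + I_ij|`, which reduces
#' to the usual definition for nonnegative weights and keeps degrees
#' positive for signed energy weights; the raw signed weights are retained
#' in the operator itself.
#'
#' @param graph A [build_graph()] result.
#' @return An `L x L` numeric matrix.
#' @export
normalized_adjacency <- function(graph) {
  stopifnot(inherits(graph, "structure_graph"))
  n <- graph$n_nodes
  m <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    m[cbind(graph$edges$i, graph$edges$j)] <- graph$edges$w
    m[cbind(graph$edges$j, graph$edges$i)] <- graph$edges$w
  }
  diag(m) <- diag(m) + 1
  dinv <- 1 / sqrt(rowSums(abs(m)))
  m * outer(dinv, dinv)
}

#' Export a graph's edge list as TSV
#'
#' @param graph A [build_graph()] result.
#' @param path Output path (`i<TAB>j<TAB>weight`, 1-based, with header).
#' @export
export_edges <- function(graph, path) {
  atomic_write(path, function(tmp)
    write.table(graph$edges, tmp, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = c("i", "j", "weight")))
}

# Convenience: pair matrix -> normalized adjacency in one step.
adjacency_from_pair_matrix <- function(pm, edge_threshold = NULL) {
  normalized_adjacency(build_graph(pm, edge_threshold))
}
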