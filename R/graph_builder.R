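#' Map features to domain nodes by name prefix
#'
#' Features follow the `<domain>__<feature>` convention; each feature is
#' assigned to the node named by its prefix. Unknown prefixes either raise an
#' error (`strict = TRUE`) or are pooled into an `other` node.
#'
#' @param feature_names Character vector of feature names.
#' @param nodes Node names; default: the distinct prefixes, in order of first
#'   appearance.
#' @param sep Prefix separator (default `"__"`).
#' @param strict Error on a prefix not in `nodes` (default `TRUE`); otherwise
#'   assign it to `other_node`.
#' @param other_node Name of the catch-all node used when `strict = FALSE`.
#' @return Named character vector: `feature -> node`.
#' @export
assign_nodes <- function(feature_names, nodes = NULL, sep = "__",
                         strict = TRUE, other_node = "other") {
  if (length(feature_names) == 0) stopf("empty feature list")
  pref <- vapply(strsplit(feature_names, sep, fixed = TRUE), `[[`, "", 1L)
  if (is.null(nodes)) nodes <- unique(pref)
  unknown <- !(pref %in% nodes)
  if (any(unknown)) {
    if (strict)
      stopf("unknown domain prefix(es): %s",
            paste(unique(pref[unknown]), collapse = ", "))
    pref[unknown] <- other_node
  }
  stats::setNames(pref, feature_names)
}

#' Per-row node-level summaries
#'
#' Reduces standardized features to the node scale: each node's value is the
#' mean of its assigned features; nodes with no assigned feature get 0.
#'
#' @param X Numeric matrix (rows x features), columns named.
#' @param map Feature-to-node map from [assign_nodes()].
#' @param nodes Node order for the output (default: unique map values).
#' @return Matrix rows x nodes.
#' @export
node_summaries <- function(X, map, nodes = unique(unname(map))) {
  X <- as.matrix(X)
  out <- matrix(0, nrow(X), length(nodes), dimnames = list(rownames(X), nodes))
  for (j in seq_along(nodes)) {
    cols <- names(map)[map == nodes[j]]
    cols <- intersect(cols, colnames(X))
    if (length(cols))
      out[, j] <- rowMeans(X[, cols, drop = FALSE])
  }
  out
}

#' Build a data-driven adjacency matrix over domain nodes
#'
#' Default construction: absolute Pearson correlation between node summaries
#' across training rows, thresholded at `tau`, with unit self-loops, then
#' row-normalized so each row sums to 1 — making message passing a convex
#' averaging operator. Zero-variance nodes get zero off-diagonal weight (a
#' warning is issued). `method = "full"` gives a fully connected uniform
#' graph and `method = "identity"` the no-mixing baseline.
#'
#' @param node_mat Training rows x nodes matrix of node summaries (ignored
#'   for `method = "identity"` except for dimensions).
#' @param tau Threshold below which correlations are zeroed (default 0.1).
#' @param method `"correlation"` (default), `"full"`, or `"identity"`.
#' @param row_normalize Row-normalize the final matrix (default `TRUE`).
#' @return A list of class `graph_spec`: `nodes`, `A`, `method`, `tau`.
#' @export
build_adjacency <- function(node_mat, tau = 0.1,
                            method = c("correlation", "full", "identity"),
                            row_normalize = TRUE) {
  method <- match.arg(method)
  node_mat <- as.matrix(node_mat)
  N <- ncol(node_mat)
  nodes <- colnames(node_mat) %||% sprintf("node%02d", seq_len(N))
  if (method == "correlation" && nrow(node_mat) < 2)
    stopf("need >= 2 training rows to estimate correlations")
  A <- switch(method,
    identity = diag(1, N),
    full = matrix(1, N, N),
    correlation = {
      sds <- apply(node_mat, 2, stats::sd)
      flat <- sds == 0 | !is.finite(sds)
      if (any(flat))
        warning(sprintf("zero-variance node(s): %s; off-diagonal weights set to 0",
                        paste(nodes[flat], collapse = ", ")), call. = FALSE)
      R <- suppressWarnings(abs(stats::cor(node_mat)))
      R[!is.finite(R)] <- 0
      R[R < tau] <- 0
      diag(R) <- 1
      R[flat, ] <- 0; R[, flat] <- 0
      diag(R) <- 1
      R
    })
  if (row_normalize) {
    rs <- rowSums(A)
    A <- A / ifelse(rs == 0, 1, rs)
  }
  dimnames(A) <- list(nodes, nodes)
  structure(list(nodes = nodes, A = A, method = method, tau = tau,
                 row_normalized = row_normalize),
            class = "graph_spec")
}

#' Construct a graph specification from a preprocessed training panel
#'
#' Convenience wrapper: assigns features to nodes by prefix, summarizes the
#' training rows at node level, and builds the adjacency matrix.
#'
#' @param panel Preprocessed (standardized) training panel.
#' @param feature_cols Feature columns.
#' @inheritParams build_adjacency
#' @return A `graph_spec` with the feature map attached (`$map`).
#' @export
build_graph <- function(panel, feature_cols = feature_columns(panel),
                        tau = 0.1, method = "correlation") {
  map <- assign_nodes(feature_cols)
  nm <- node_summaries(as.matrix(panel[feature_cols]), map)
  g <- build_adjacency(nm, tau = tau, method = method)
  g$map <- map
  g
}

#' @export
print.graph_spec <- function(x, ...) {
  cat(sprintf("Graph spec: %d nodes, %d off-diagonal edges (method '%s', tau %.2f)\n",
              length(x$nodes), sum(x$A[upper.tri(x$A)] > 0),
              x$method, x$tau %||% NA_real_))
  invisible(x)
}

#' One step of message passing
#'
#' Propagates node values through the graph: `x_graph = A x`. Accepts a
#' single node vector or a rows-x-nodes matrix (each row propagated).
#'
#' @param A Adjacency matrix or a `graph_spec`.
#' @param x Numeric vector of length N, or matrix with N columns.
#' @return Object of the same shape as `x`.
#' @export
message_pass <- function(A, x) {
  if (inherits(A, "graph_spec")) A <- A$A
  if (is.matrix(x)) {
    if (ncol(x) != ncol(A)) stopf("dimension mismatch: %d columns vs %d nodes",
                                  ncol(x), ncol(A))
    return(x %*% t(A))
  }
  if (length(x) != ncol(A))
    stopf("dimension mismatch: length %d vs %d nodes", length(x), ncol(A))
  as.numeric(A %*% x)
}

#' Serialize a graph specification to JSON / edge list
#'
#' @param graph A `graph_spec`.
#' @param path Output path.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "graph_spec"))
  obj <- list(nodes = graph$nodes, A = graph$A, method = graph$method,
              tau = graph$tau, row_normalized = graph$row_normalized,
              map = if (!is.null(graph$map)) as.list(graph$map))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- as.matrix(obj$A)
  dimnames(A) <- list(obj$nodes, obj$nodes)
  g <- structure(list(nodes = obj$nodes, A = A, method = obj$method,
                      tau = obj$tau, row_normalized = obj$row_normalized),
                 class = "graph_spec")
  if (!is.null(obj$map)) g$map <- unlist(obj$map)
  g
}

#' @rdname write_graph
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "graph_spec"))
  idx <- which(graph$A != 0, arr.ind = TRUE)
  df <- data.frame(node_i = graph$nodes[idx[, 1]],
                   node_j = graph$nodes[idx[, 2]],
                   weight = graph$A[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
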