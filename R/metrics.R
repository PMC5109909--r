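#' All-pairs shortest path lengths of a binary network
#'
#' Unweighted shortest-path distances between every pair of nodes, computed by
#' iterated boolean matrix products (distance k is the first power of the
#' adjacency matrix with a nonzero walk count). Unreachable pairs are `Inf`;
#' the diagonal is 0.
#'
#' @param net A [binary_network()] or plain 0/1 adjacency matrix.
#' @return N x N numeric matrix of distances.
#' @export
shortest_paths <- function(net) {
  a <- unclass(net)
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a > 0] <- 1
  walk <- a
  k <- 1L
  while (k < n) {
    walk <- (walk %*% a) > 0
    k <- k + 1L
    new <- walk & !is.finite(d)
    if (!any(new)) break
    d[new] <- k
    walk <- walk * 1
  }
  dimnames(d) <- dimnames(a)
  d
}

#' Clustering coefficient of one node
#'
#' `C_i = 2 t_i / (K_i (K_i - 1))` where `t_i` counts the edges among the
#' neighbours of node `i` and `K_i` is its degree; 0 by convention when
#' `K_i < 2`.
#'
#' @param net A [binary_network()].
#' @param i Node index (1-based).
#' @return Clustering coefficient in `[0, 1]`.
#' @export
node_clustering <- function(net, i) {
  a <- unclass(net)
  if (!(i >= 1 && i <= nrow(a) && i == round(i))) {
    stop("node index out of range", call. = FALSE)
  }
  nb <- which(a[i, ] == 1)
  k <- length(nb)
  if (k < 2) return(0)
  t_i <- sum(a[nb, nb]) / 2
  2 * t_i / (k * (k - 1))
}

#' Node-level network indicators
#'
#' Computes, for every node: degree `K_i`, neighbour-subgraph edge count
#' `t_i`, clustering coefficient `C_i`, average shortest path `L_i` (over
#' reachable partners only; `NA` for a node with none), nodal efficiency
#' `E_g_i = (1/(N-1)) * sum_j 1/d_ij` (with `1/Inf = 0`), and local efficiency
#' `E_loc_i`, the mean inverse distance within the subgraph induced by the
#' node's neighbours (0 when `K_i < 2`). Distances in the local-efficiency
#' subgraph are computed inside that subgraph only, not in the full network.
#'
#' @param net A [binary_network()].
#' @param distances Optional precomputed [shortest_paths()] matrix.
#' @return A tibble with columns `node`, `K`, `t`, `C`, `L`, `Eg`, `Eloc`.
#' @export
node_metrics <- function(net, distances = NULL) {
  a <- unclass(net)
  n <- nrow(a)
  if (n < 2) stop("network must have at least 2 nodes", call. = FALSE)
  K <- unname(rowSums(a))
  walk2 <- a %*% a
  t_i <- unname(rowSums(walk2 * a) / 2) # closed 3-walks / 2 = edges among neighbours
  C <- ifelse(K >= 2, 2 * t_i / (K * (K - 1)), 0)
  d <- if (is.null(distances)) shortest_paths(a) else distances
  off <- unname(d)
  diag(off) <- NA
  L <- apply(off, 1, function(x) {
    x <- x[!is.na(x)]
    fin <- x[is.finite(x)]
    if (length(fin) == 0) NA_real_ else mean(fin)
  })
  inv <- 1 / off
  inv[!is.finite(inv)] <- 0
  Eg <- rowSums(inv, na.rm = TRUE) / (n - 1)
  Eloc <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    dsub <- shortest_paths(a[nb, nb, drop = FALSE])
    isub <- 1 / dsub
    diag(isub) <- 0
    isub[!is.finite(isub)] <- 0
    sum(isub) / (k * (k - 1))
  }, numeric(1))
  tibble::tibble(node = if (!is.null(rownames(a))) rownames(a) else paste0("R", seq_len(n)),
                 K = as.numeric(K), t = as.numeric(t_i), C = C,
                 L = as.numeric(L), Eg = Eg, Eloc = Eloc)
}

#' Network-level indicators of a binary network
#'
#' The six network indicators, each the arithmetic mean of its node-level
#' counterpart over all `N` nodes: clustering coefficient `C_net`, average
#' path length `L_net` (nodes with no reachable partner are excluded from the
#' mean; `NA` for an empty graph), global efficiency `E_glob`, local
#' efficiency `E_loc`, and average node degree `K_net`. The `connected` flag
#' records whether every node pair was mutually reachable.
#'
#' @param net A [binary_network()].
#' @param distances Optional precomputed [shortest_paths()] matrix.
#' @return A `network_metrics` list with fields `C_net`, `L_net`, `E_glob`,
#'   `E_loc`, `K_net`, `n_nodes`, `connected`, and the per-node table `nodes`.
#' @examples
#' k4 <- generate_benchmark_graph("complete", n = 4)
#' network_metrics(k4) # C = L = E_glob = E_loc = 1, K_net = 3
#' @export
network_metrics <- function(net, distances = NULL) {
  a <- unclass(net)
  n <- nrow(a)
  if (n < 3) stop("network must have at least 3 nodes", call. = FALSE)
  d <- if (is.null(distances)) shortest_paths(a) else distances
  nodes <- node_metrics(net, distances = d)
  off <- d
  diag(off) <- NA
  L_vals <- nodes$L[!is.na(nodes$L)]
  structure(list(
    C_net = mean(nodes$C),
    L_net = if (length(L_vals) > 0) mean(L_vals) else NA_real_,
    E_glob = mean(nodes$Eg),
    E_loc = mean(nodes$Eloc),
    K_net = mean(nodes$K),
    n_nodes = n,
    connected = all(is.finite(off[upper.tri(off)])),
    nodes = nodes
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "network_metrics (N = %d%s): C_net = %.4f, L_net = %s, E_glob = %.4f, E_loc = %.4f, K_net = %.3f\n",
    x$n_nodes, if (x$connected) "" else ", disconnected",
    x$C_net, ifelse(is.na(x$L_net), "NA", sprintf("%.4f", x$L_net)),
    x$E_glob, x$E_loc, x$K_net))
  invisible(x)
}
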