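#' Construct a binary network from an adjacency matrix
#'
#' A `binary_network` is an undirected simple graph stored as a symmetric
#' 0/1 adjacency matrix with zero diagonal. It is the object every graph
#' indicator in the package consumes.
#'
#' @param adjacency Square numeric matrix containing only 0 and 1, symmetric,
#'   with zero diagonal.
#' @param region_ids Optional character vector of node labels; defaults to
#'   existing dimnames or `"R1"..."RN"`.
#' @return A `binary_network`: the validated adjacency matrix with node labels
#'   as dimnames.
#' @export
binary_network <- function(adjacency, region_ids = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  a <- adjacency
  storage.mode(a) <- "double"
  if (anyNA(a) || !all(a %in% c(0, 1))) {
    stop("adjacency values must be 0 or 1 with no missing entries", call. = FALSE)
  }
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero (no self-loops)", call. = FALSE)
  if (max(abs(a - t(a))) != 0) {
    stop("adjacency must be symmetric (undirected graph)", call. = FALSE)
  }
  n <- nrow(a)
  if (is.null(region_ids)) {
    region_ids <- if (!is.null(rownames(a))) rownames(a) else paste0("R", seq_len(n))
  }
  if (length(region_ids) != n) stop("region_ids length must match node count", call. = FALSE)
  dimnames(a) <- list(region_ids, region_ids)
  class(a) <- c("binary_network", "matrix", "array")
  a
}

#' @export
print.binary_network <- function(x, ...) {
  n <- nrow(x)
  e <- sum(x) / 2
  cat(sprintf("binary_network: %d nodes, %d edges, mean degree %.3f\n",
              n, e, 2 * e / n))
  invisible(x)
}

#' Number of nodes and edges of a binary network
#'
#' @param net A [binary_network()].
#' @return `n_nodes`: integer node count. `n_edges`: integer edge count.
#' @export
n_nodes <- function(net) nrow(net)

#' @rdname n_nodes
#' @export
n_edges <- function(net) as.integer(sum(unclass(net)) / 2)

#' Edge list of a binary network
#'
#' @param net A [binary_network()].
#' @param base Index origin for the output, 0 or 1.
#' @return Two-column integer matrix of edges `(i, j)` with `i < j`.
#' @export
edge_list <- function(net, base = 0L) {
  idx <- which(upper.tri(net) & unclass(net) == 1, arr.ind = TRUE)
  el <- cbind(i = idx[, 1], j = idx[, 2])
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  el + (base - 1L)
}

#' Generate benchmark graphs with known structure
#'
#' Deterministic and random reference graphs used to exercise and validate the
#' network indicators: ring lattices and Watts-Strogatz rewirings (the
#' canonical small-world construction), Erdos-Renyi random graphs (the
#' canonical non-small-world control), and the complete, star and cycle graphs
#' whose indicator values have closed forms.
#'
#' `watts_strogatz` starts from the even-degree ring lattice and rewires the
#' far endpoint of each lattice edge with probability `p`, skipping rewirings
#' that would create a self-loop or duplicate edge, so the edge count of the
#' lattice (`n*k/2`) is always preserved.
#'
#' @param kind One of `"ring_lattice"`, `"watts_strogatz"`, `"erdos_renyi"`,
#'   `"complete"`, `"star"`, `"cycle"`.
#' @param n Number of nodes (>= 3).
#' @param k Even neighbour count for the lattice kinds (each node connects to
#'   `k/2` neighbours on each side).
#' @param p Rewiring probability (`watts_strogatz`) or edge probability
#'   (`erdos_renyi`), in `[0, 1]`.
#' @param seed Optional integer seed; identical seeds give identical graphs.
#' @return A [binary_network()].
#' @examples
#' g <- generate_benchmark_graph("watts_strogatz", n = 90, k = 10, p = 0.1, seed = 7)
#' n_edges(g)  # 450, same as the k = 10 ring lattice
#' @export
generate_benchmark_graph <- function(kind = c("ring_lattice", "watts_strogatz",
                                              "erdos_renyi", "complete", "star",
                                              "cycle"),
                                     n, k = NULL, p = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || length(n) != 1 || n < 3 || n != round(n)) {
    stop("n must be an integer >= 3", call. = FALSE)
  }
  n <- as.integer(n)
  if (kind %in% c("ring_lattice", "watts_strogatz")) {
    if (is.null(k) || k != round(k) || k %% 2 != 0 || k <= 0 || k >= n) {
      stop("lattice kinds need an even neighbour count k with 0 < k < n",
           call. = FALSE)
    }
    k <- as.integer(k)
  }
  if (kind %in% c("watts_strogatz", "erdos_renyi")) {
    if (is.null(p) || p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  a <- matrix(0, n, n)
  if (kind == "complete") {
    a[] <- 1
    diag(a) <- 0
  } else if (kind == "star") {
    a[1, 2:n] <- 1
    a[2:n, 1] <- 1
  } else if (kind == "cycle") {
    for (i in seq_len(n)) {
      j <- i %% n + 1L
      a[i, j] <- a[j, i] <- 1
    }
  } else if (kind == "ring_lattice") {
    a <- ring_lattice_adj(n, k)
  } else if (kind == "erdos_renyi") {
    up <- which(upper.tri(a))
    a[up] <- as.numeric(stats::runif(length(up)) < p)
    a <- a + t(a)
  } else { # watts_strogatz
    a <- ring_lattice_adj(n, k)
    # Rewire the clockwise endpoint of each lattice edge, sweeping offsets
    # then nodes, as in the original construction.
    for (off in seq_len(k %/% 2)) {
      for (i in seq_len(n)) {
        if (stats::runif(1) >= p) next
        j <- (i - 1L + off) %% n + 1L
        if (a[i, j] == 0) next # already rewired away by an earlier step
        candidates <- which(a[i, ] == 0)
        candidates <- setdiff(candidates, i)
        if (length(candidates) == 0L) next
        jnew <- candidates[sample.int(length(candidates), 1L)]
        a[i, j] <- a[j, i] <- 0
        a[i, jnew] <- a[jnew, i] <- 1
      }
    }
  }
  binary_network(a)
}

ring_lattice_adj <- function(n, k) {
  a <- matrix(0, n, n)
  for (off in seq_len(k %/% 2)) {
    for (i in seq_len(n)) {
      j <- (i - 1L + off) %% n + 1L
      a[i, j] <- a[j, i] <- 1
    }
  }
  a
}
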