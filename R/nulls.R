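#' Propose one degree-preserving double-edge swap
#'
#' Selects two distinct edges `(i1, j1)` and `(i2, j2)` uniformly at random
#' and proposes replacing them with `(i1, j2)` and `(i2, j1)`, with the edge
#' orientations randomized so both crossed pairings are proposed with equal
#' probability (without this the chain is irreversible and its stationary
#' distribution visibly under-produces triangles). The proposal is aborted —
#' leaving the network unchanged — if either replacement would be a
#' self-loop, already exists, or the two replacements coincide. Every node's
#' degree is unchanged whether or not the swap succeeds, which is what makes
#' the resulting Markov chain sample degree-matched random graphs.
#'
#' @param net A [binary_network()] with at least 2 edges.
#' @return List with `net` (the possibly rewired network) and `success`
#'   (logical flag).
#' @export
rewire_swap <- function(net) {
  a <- unclass(net)
  el <- edge_list(net, base = 1L)
  if (nrow(el) < 2) stop("need at least 2 edges to propose a swap", call. = FALSE)
  idx <- sample.int(nrow(el), 2L)
  res <- propose_swap(a, el, idx[1], idx[2], flip = stats::runif(1) < 0.5)
  list(net = binary_network(res$a, region_ids = rownames(a)), success = res$success)
}

# core swap on raw adjacency + edge list; returns updated pieces and flag.
# `flip` selects which of the two crossed pairings is proposed.
propose_swap <- function(a, el, e1, e2, flip = FALSE) {
  i1 <- el[e1, 1]; j1 <- el[e1, 2]
  i2 <- el[e2, 1]; j2 <- el[e2, 2]
  if (flip) { tmp <- i2; i2 <- j2; j2 <- tmp }
  # abort: self-loop, coinciding replacements, or replacement already present
  if (i1 == j2 || i2 == j1 ||
      (i1 == i2 && j1 == j2) ||
      (i1 == j1 && i2 == j2) ||
      a[i1, j2] == 1 || a[i2, j1] == 1) {
    return(list(a = a, el = el, success = FALSE))
  }
  a[i1, j1] <- a[j1, i1] <- 0
  a[i2, j2] <- a[j2, i2] <- 0
  a[i1, j2] <- a[j2, i1] <- 1
  a[i2, j1] <- a[j1, i2] <- 1
  el[e1, ] <- c(min(i1, j2), max(i1, j2))
  el[e2, ] <- c(min(i2, j1), max(i2, j1))
  list(a = a, el = el, success = TRUE)
}

#' Randomize a network by repeated degree-preserving swaps
#'
#' Runs the double-edge-swap Markov chain until `target_swaps` proposals have
#' succeeded (or an attempt cap of `attempt_factor * target_swaps` is reached,
#' with a warning). The output has exactly the degree sequence of the input
#' and is always simple and symmetric.
#'
#' @param net A [binary_network()].
#' @param target_swaps Number of successful swaps to perform; a common choice
#'   is 10 per edge, see [ensemble_summary()].
#' @param seed Optional integer seed for reproducibility.
#' @param attempt_factor Attempt cap as a multiple of `target_swaps`.
#' @return A randomized [binary_network()].
#' @export
randomize_network <- function(net, target_swaps, seed = NULL,
                              attempt_factor = 100) {
  stopifnot(target_swaps >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (target_swaps == 0) return(net)
  a <- unclass(net)
  el <- edge_list(net, base = 1L)
  m <- nrow(el)
  if (m < 2) {
    warning("network too small to rewire; returning input unchanged")
    return(net)
  }
  cap <- ceiling(attempt_factor * target_swaps)
  successes <- 0L
  attempts <- 0L
  # buffered proposals: draw edge pairs and pairing choices in blocks to keep
  # the chain loop allocation-free
  chunk <- 2048L
  buf_pos <- chunk + 1L
  e1v <- e2v <- integer(0)
  flipv <- logical(0)
  while (successes < target_swaps && attempts < cap) {
    if (buf_pos > chunk) {
      e1v <- sample.int(m, chunk, replace = TRUE)
      e2v <- sample.int(m, chunk, replace = TRUE)
      flipv <- stats::runif(chunk) < 0.5
      buf_pos <- 1L
    }
    e1 <- e1v[buf_pos]; e2 <- e2v[buf_pos]; flip <- flipv[buf_pos]
    buf_pos <- buf_pos + 1L
    if (e1 == e2) next # same edge drawn twice: not a valid pair
    attempts <- attempts + 1L
    i1 <- el[e1, 1L]; j1 <- el[e1, 2L]
    if (flip) { i2 <- el[e2, 2L]; j2 <- el[e2, 1L] }
    else      { i2 <- el[e2, 1L]; j2 <- el[e2, 2L] }
    if (i1 == j2 || i2 == j1 || a[i1, j2] == 1 || a[i2, j1] == 1) next
    a[i1, j1] <- 0; a[j1, i1] <- 0
    a[i2, j2] <- 0; a[j2, i2] <- 0
    a[i1, j2] <- 1; a[j2, i1] <- 1
    a[i2, j1] <- 1; a[j1, i2] <- 1
    el[e1, 1L] <- min(i1, j2); el[e1, 2L] <- max(i1, j2)
    el[e2, 1L] <- min(i2, j1); el[e2, 2L] <- max(i2, j1)
    successes <- successes + 1L
  }
  if (successes == 0L) {
    warning("rewiring chain is rigid: no successful swap within the attempt cap; returning input unchanged")
    return(net)
  }
  if (successes < target_swaps) {
    warning(sprintf("attempt cap reached after %d of %d successful swaps",
                    successes, target_swaps))
  }
  binary_network(a, region_ids = rownames(a))
}

# clustering + path length only; the quantities an ensemble needs
cl_metrics <- function(a) {
  K <- rowSums(a)
  t_i <- rowSums((a %*% a) * a) / 2
  C <- ifelse(K >= 2, 2 * t_i / (K * (K - 1)), 0)
  d <- shortest_paths(a)
  diag(d) <- NA
  L_i <- apply(d, 1, function(x) {
    fin <- x[is.finite(x) & !is.na(x)]
    if (length(fin) == 0) NA_real_ else mean(fin)
  })
  L_vals <- L_i[!is.na(L_i)]
  list(C = mean(C),
       L = if (length(L_vals) > 0) mean(L_vals) else NA_real_,
       connected = all(is.finite(d[upper.tri(d)])))
}

#' Degree-matched random-network ensemble summary
#'
#' Generates `n_random` independent randomizations of `net` (each a fresh
#' chain of `target_swaps_per_edge * n_edges` successful double-edge swaps)
#' and records each null's clustering coefficient and average path length.
#' The ensemble means are the reference values `C_random` and `L_random`
#' against which the small-world indices are formed. Each null runs on its
#' own seed drawn once from `seed`, so the ensemble is reproducible.
#'
#' @param net A [binary_network()].
#' @param n_random Ensemble size (default 100).
#' @param target_swaps_per_edge Successful swaps per edge per null network.
#' @param seed Integer seed for the ensemble.
#' @return A `null_ensemble` list: `C_random`, `L_random`, `n_random`,
#'   `per_network` (tibble of per-null `C`, `L`, `connected`), `seed`,
#'   `any_disconnected`.
#' @export
ensemble_summary <- function(net, n_random = 100, target_swaps_per_edge = 10,
                             seed = 1L) {
  stopifnot(n_random >= 1)
  m <- n_edges(net)
  target <- ceiling(target_swaps_per_edge * m)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_random)
  per <- lapply(seq_len(n_random), function(r) {
    nullnet <- randomize_network(net, target_swaps = target, seed = sub_seeds[r])
    cl_metrics(unclass(nullnet))
  })
  tab <- tibble::tibble(C = vapply(per, `[[`, numeric(1), "C"),
                        L = vapply(per, `[[`, numeric(1), "L"),
                        connected = vapply(per, `[[`, logical(1), "connected"))
  structure(list(C_random = mean(tab$C),
                 L_random = mean(tab$L[!is.na(tab$L)]),
                 n_random = n_random,
                 per_network = tab,
                 seed = as.integer(seed),
                 any_disconnected = any(!tab$connected)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: n = %d, C_random = %.4f, L_random = %.4f%s\n",
              x$n_random, x$C_random, x$L_random,
              if (x$any_disconnected) " (some nulls disconnected)" else ""))
  invisible(x)
}

#' Small-world indices gamma, lambda, sigma
#'
#' `gamma = C_net / C_random`, `lambda = L_net / L_random`,
#' `sigma = gamma / lambda`. A network is considered small-world when
#' `sigma > 1`: clustering well above its degree-matched random graphs with a
#' path length close to theirs.
#'
#' @param C_net,L_net Clustering coefficient and average path length of the
#'   observed network.
#' @param C_random,L_random Ensemble means from [ensemble_summary()].
#' @return A `small_world_indices` list with `gamma`, `lam`, `sigma`.
#' @export
small_world_index <- function(C_net, C_random, L_net, L_random) {
  vals <- c(C_net = C_net, C_random = C_random, L_net = L_net,
            L_random = L_random)
  if (anyNA(vals) || any(vals <= 0)) {
    stop("all of C_net, C_random, L_net, L_random must be positive", call. = FALSE)
  }
  gamma <- C_net / C_random
  lam <- L_net / L_random
  structure(list(gamma = gamma, lam = lam, sigma = gamma / lam),
            class = "small_world_indices")
}

#' @export
print.small_world_indices <- function(x, ...) {
  cat(sprintf("gamma = %.4f, lambda = %.4f, sigma = %.4f\n",
              x$gamma, x$lam, x$sigma))
  invisible(x)
}
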