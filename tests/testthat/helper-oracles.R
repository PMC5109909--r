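# Independent brute-force oracles for the graph indicators. These deliberately
# use the slowest, most literal formulations (Floyd-Warshall over all triples,
# explicit neighbour-pair enumeration) so they share no code path with the
# package implementation.

oracle_floyd_warshall <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_node_metrics <- function(a) {
  n <- nrow(a)
  d <- oracle_floyd_warshall(a)
  out <- data.frame(K = numeric(n), t = numeric(n), C = numeric(n),
                    L = numeric(n), Eg = numeric(n), Eloc = numeric(n))
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    t_i <- 0
    if (k >= 2) {
      for (x in seq_len(k - 1)) {
        for (y in (x + 1):k) {
          if (a[nb[x], nb[y]] == 1) t_i <- t_i + 1
        }
      }
    }
    di <- d[i, -i]
    fin <- di[is.finite(di)]
    eg <- sum(ifelse(is.finite(di), 1 / di, 0)) / (n - 1)
    eloc <- 0
    if (k >= 2) {
      dsub <- oracle_floyd_warshall(a[nb, nb, drop = FALSE])
      s <- 0
      for (x in seq_len(k)) {
        for (y in seq_len(k)) {
          if (x != y && is.finite(dsub[x, y])) s <- s + 1 / dsub[x, y]
        }
      }
      eloc <- s / (k * (k - 1))
    }
    out$K[i] <- k
    out$t[i] <- t_i
    out$C[i] <- if (k >= 2) 2 * t_i / (k * (k - 1)) else 0
    out$L[i] <- if (length(fin) > 0) mean(fin) else NA_real_
    out$Eg[i] <- eg
    out$Eloc[i] <- eloc
  }
  out
}

oracle_network_metrics <- function(a) {
  nm <- oracle_node_metrics(a)
  list(C_net = mean(nm$C),
       L_net = mean(nm$L[!is.na(nm$L)]),
       E_glob = mean(nm$Eg),
       E_loc = mean(nm$Eloc),
       K_net = mean(nm$K))
}

random_adjacency <- function(n, p) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.numeric(runif(length(up)) < p)
  a + t(a)
}

degree_sequence <- function(net) sort(rowSums(unclass(net)))

# small graph used across metric tests: edges (1,2),(1,3),(2,3),(2,4)
paw_graph <- function() {
  a <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(2, 4))) {
    a[e[1], e[2]] <- a[e[2], e[1]] <- 1
  }
  binary_network(a)
}
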