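# Exhaustive-enumeration oracle for directed-graph statistics on small
# graphs. Independent of the package implementation: plain BFS distances
# plus recursive enumeration of every shortest path.

random_adjacency <- function(n, p) {
  adj <- matrix(stats::runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  dimnames(adj) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  adj
}

graph_from_adjacency <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj * 1, mode = "directed")
}

oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in which(adj[v, ])) {
        if (is.infinite(D[s, w])) { D[s, w] <- D[s, v] + 1; nxt <- c(nxt, w) }
      }
      frontier <- unique(nxt)
    }
  }
  D
}

# every shortest path from s to t as a list of node-index vectors
enumerate_shortest_paths <- function(adj, D, s, t) {
  if (is.infinite(D[s, t])) return(list())
  recurse <- function(u) {
    if (u == t) return(list(t))
    out <- list()
    for (w in which(adj[u, ])) {
      if (is.finite(D[w, t]) && D[w, t] == D[u, t] - 1) {
        for (sub in recurse(w)) out[[length(out) + 1L]] <- c(u, sub)
      }
    }
    out
  }
  recurse(s)
}

oracle_pair_connectivity <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  diag(D) <- Inf
  sum(is.finite(D)) / (n * (n - 1))
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  B <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || is.infinite(D[s, t])) next
    paths <- enumerate_shortest_paths(adj, D, s, t)
    for (v in setdiff(seq_len(n), c(s, t))) {
      hit <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      B[v] <- B[v] + hit / length(paths)
    }
  }
  stats::setNames(B / ((n - 1) * (n - 2)), rownames(adj))
}

oracle_path_through <- function(adj, x, mode) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  num <- 0; den <- 0
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || s == x || t == x || is.infinite(D[s, t])) next
    den <- den + 1
    paths <- enumerate_shortest_paths(adj, D, s, t)
    hit <- sum(vapply(paths, function(p) x %in% p, logical(1)))
    if (mode == "pair") num <- num + (hit > 0)
    else num <- num + hit / length(paths)
  }
  if (den == 0) return(NA_real_)
  num / den
}
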