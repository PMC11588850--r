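#' Build the directed TF-TF graph from a regulon table
#'
#' Nodes are all genes that appear as a regulator anywhere in the table;
#' a directed edge u -> v exists whenever u regulates v and v is itself a
#' regulator. Self-regulation records are dropped and parallel records
#' (activation/repression/dual, duplicates) collapse to a single edge —
#' effect signs play no role in the graph statistics.
#'
#' @param regulon Regulon data.frame (`regulator`, `target`, `effect`).
#' @return An [igraph::igraph] directed graph.
#' @export
build_tf_graph <- function(regulon) {
  if (is.null(regulon) || !nrow(regulon))
    stop("cannot build a TF graph from an empty regulon table", call. = FALSE)
  tfs <- sort(unique(regulon$regulator))
  e <- regulon[regulon$target %in% tfs & regulon$regulator != regulon$target,
               c("regulator", "target")]
  e <- unique(e)
  igraph::graph_from_data_frame(e, directed = TRUE,
                                vertices = data.frame(name = tfs))
}

#' Fraction of regulators in the largest weakly connected component
#'
#' @param g TF graph from [build_tf_graph()].
#' @return A fraction in `[0, 1]`.
#' @export
component_fraction <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph", call. = FALSE)
  max(igraph::components(g, mode = "weak")$csize) / n
}

#' Fraction of ordered TF pairs connected through regulation
#'
#' The fraction of ordered pairs (u, v), u != v, over all regulator nodes
#' for which a directed path u -> ... -> v exists.
#'
#' @param g TF graph.
#' @return A fraction in `[0, 1]`.
#' @export
pair_connectivity <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  sum(is.finite(d)) / (n * (n - 1))
}

#' Pair-connectivity impact of removing one regulator
#'
#' Deletes the node (with its incident edges), recomputes
#' [pair_connectivity()] over the remaining nodes, and reports both the
#' new fraction ("drops to") and the relative drop in percent ("drops
#' by"), `100 (f0 - f1) / f0`. When the original connectivity is zero the
#' relative drop is undefined and returned as `NA` with a warning.
#'
#' @param g TF graph.
#' @param node Regulator id to remove.
#' @return A list with `new_fraction` and `relative_drop_percent`.
#' @export
removal_impact <- function(g, node) {
  if (!node %in% igraph::V(g)$name)
    stop("node '", node, "' is not in the graph", call. = FALSE)
  if (igraph::vcount(g) < 3)
    stop("graph minus node must retain at least 2 nodes", call. = FALSE)
  f0 <- pair_connectivity(g)
  f1 <- pair_connectivity(igraph::delete_vertices(g, node))
  if (f0 == 0) {
    warning("baseline pair connectivity is zero; relative drop undefined")
    return(list(new_fraction = f1, relative_drop_percent = NA_real_))
  }
  list(new_fraction = f1, relative_drop_percent = 100 * (f0 - f1) / f0)
}

#' Normalized directed betweenness centrality of every regulator
#'
#' Standard shortest-path betweenness on the directed TF graph, divided by
#' `(n - 1)(n - 2)` so values lie in `[0, 1]`.
#'
#' @param g TF graph with at least 3 nodes.
#' @return Named numeric vector over nodes.
#' @export
tf_betweenness <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3) stop("need at least 3 nodes", call. = FALSE)
  igraph::betweenness(g, directed = TRUE, normalized = FALSE) /
    ((n - 1) * (n - 2))
}

# shortest-path counts from one source via BFS (unweighted Brandes
# forward pass); returns distances and path counts sigma
.bfs_sigma <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n); sigma <- numeric(n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

#' Fraction of regulator shortest paths passing through a node
#'
#' For `mode = "pair"` (default): among ordered pairs (s, t) with
#' s, t distinct from `node` and a directed s -> t path, the fraction of
#' pairs for which `node` lies on at least one shortest path. For
#' `mode = "path"`: the per-pair fraction of shortest paths containing
#' `node` (path counts with multiplicity), averaged over the same
#' eligible pairs — so the value times the number of eligible pairs
#' equals the node's unnormalized betweenness numerator.
#'
#' @param g TF graph.
#' @param node Regulator id.
#' @param mode `"pair"` or `"path"`.
#' @return A fraction in `[0, 1]`.
#' @export
path_through_fraction <- function(g, node, mode = c("pair", "path")) {
  mode <- match.arg(mode)
  names <- igraph::V(g)$name
  if (!node %in% names)
    stop("node '", node, "' is not in the graph", call. = FALSE)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(adj)
  x <- match(node, names)
  fwd <- lapply(seq_len(n), function(s) .bfs_sigma(adj, s))
  dists <- do.call(rbind, lapply(fwd, `[[`, "dist"))
  sig <- do.call(rbind, lapply(fwd, `[[`, "sigma"))
  num <- 0; den <- 0
  for (s in seq_len(n)) {
    if (s == x) next
    for (t in seq_len(n)) {
      if (t == s || t == x || is.infinite(dists[s, t])) next
      den <- den + 1
      on_path <- is.finite(dists[s, x]) && is.finite(dists[x, t]) &&
        dists[s, x] + dists[x, t] == dists[s, t]
      if (!on_path) next
      if (mode == "pair") num <- num + 1
      else num <- num + sig[s, x] * sig[x, t] / sig[s, t]
    }
  }
  if (den == 0)
    stop("no connected ordered pairs avoid the node; fraction undefined",
         call. = FALSE)
  num / den
}

#' Degree-distribution skewness of a regulator's regulon subnetwork
#'
#' Builds the subnetwork induced by the TF together with its targets,
#' using every regulon record among those genes (collapsed to single
#' directed edges, self-records dropped), and returns the Fisher-Pearson
#' skewness of the total degree (in + out) distribution. High skew marks
#' hub-dominated, complex regulon neighbourhoods.
#'
#' @param regulon Regulon data.frame.
#' @param tf Regulator id with at least 3 targets.
#' @param adjusted Use the bias-adjusted (sample) skewness G1 instead of
#'   the population g1.
#' @return Skewness (numeric); `NA` with a warning when the degree
#'   variance is zero.
#' @export
regulon_subnetwork_skewness <- function(regulon, tf, adjusted = FALSE) {
  targets <- unique(regulon$target[regulon$regulator == tf])
  nodes <- union(tf, targets)
  if (length(nodes) < 3 || length(targets) < 3)
    stop("regulator must regulate at least 3 genes", call. = FALSE)
  sub <- regulon[regulon$regulator %in% nodes & regulon$target %in% nodes &
                   regulon$regulator != regulon$target,
                 c("regulator", "target")]
  sub <- unique(sub)
  deg <- table(factor(c(sub$regulator, sub$target), levels = nodes))
  deg <- as.numeric(deg)
  m2 <- mean((deg - mean(deg))^2)
  if (m2 == 0) {
    warning("degree distribution has zero variance; skewness undefined")
    return(NA_real_)
  }
  g1 <- mean((deg - mean(deg))^3) / m2^1.5
  if (adjusted) {
    n <- length(deg)
    g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  }
  g1
}
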