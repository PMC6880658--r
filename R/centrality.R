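# Weighted centrality on the signed partial-correlation network. Distances
# follow the weighted-network convention: edge length = 1 / |weight|, so
# strong edges are short. Shortest-path quantities are delegated to igraph
# (Dijkstra / Brandes with fractional credit for tied paths).

net_graph <- function(net) {
  W <- abs(net$weights)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Node strength
#'
#' Sum of absolute incident edge weights per node.
#'
#' @param net A `symptom_network`.
#' @return Named numeric vector.
#' @export
node_strength <- function(net) {
  setNames(rowSums(abs(net$weights)), net$labels)
}

#' Closeness and betweenness on the weighted network
#'
#' Edge lengths are `1/|w|`. Closeness of a node is the inverse of its summed
#' shortest-path distance to all reachable nodes (0 for isolated nodes).
#' Betweenness counts, for every ordered pair of other nodes, the fraction of
#' shortest paths passing through the node (tied paths split credit).
#'
#' @param net A `symptom_network`.
#' @return List with named numeric vectors `closeness` and `betweenness`.
#' @export
distance_centralities <- function(net) {
  p <- length(net$labels)
  g <- net_graph(net)
  if (igraph::ecount(g) == 0) {
    z <- setNames(rep(0, p), net$labels)
    return(list(closeness = z, betweenness = z))
  }
  d <- igraph::distances(g, weights = igraph::E(g)$length)
  closeness <- vapply(seq_len(p), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0) 0 else 1 / sum(di)
  }, numeric(1))
  btw <- igraph::betweenness(g, directed = FALSE,
                             weights = igraph::E(g)$length)
  list(closeness = setNames(closeness, net$labels),
       betweenness = setNames(as.numeric(btw), net$labels))
}

#' Centrality table
#'
#' Strength, closeness and betweenness for every node of the network.
#'
#' @param net A `symptom_network`.
#' @return A data frame with columns `node`, `cluster`, `strength`,
#'   `closeness`, `betweenness`.
#' @export
centrality_table <- function(net) {
  dc <- distance_centralities(net)
  data.frame(node = net$labels,
             cluster = if (is.null(net$cluster_tags)) NA_character_
                       else net$cluster_tags,
             strength = as.numeric(node_strength(net)),
             closeness = as.numeric(dc$closeness),
             betweenness = as.numeric(dc$betweenness),
             stringsAsFactors = FALSE)
}
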