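#' Global topology summary of an undirected network
#'
#' Five node-averaged statistics with the conventions of common network
#' analyzers:
#' \describe{
#'   \item{avg_shortest_path}{mean unweighted shortest-path length over
#'     all ordered node pairs within the same connected component
#'     (cross-component pairs excluded).}
#'   \item{avg_betweenness}{per-node shortest-path betweenness computed
#'     inside each component and normalized by `(n-1)(n-2)/2` for the
#'     component's node count n (0 for components with < 3 nodes),
#'     averaged over all nodes.}
#'   \item{avg_closeness}{per node, the reciprocal of the mean distance
#'     to the other nodes of its component (0 for isolated nodes),
#'     averaged over all nodes.}
#'   \item{avg_clustering_coefficient}{per-node triangle density (local
#'     transitivity; 0 for nodes of degree < 2), averaged over all
#'     nodes.}
#'   \item{avg_degree}{`2 |E| / |V|`.}
#' }
#'
#' @param graph non-empty simple undirected igraph graph.
#' @return one-row data.frame with the five statistics (column order:
#'   avg_shortest_path, avg_betweenness, avg_closeness,
#'   avg_clustering_coefficient, avg_degree).
#' @export
global_topology <- function(graph) {
  if (inherits(graph, "synergy_network")) graph <- graph$graph
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  comps <- igraph::components(graph)
  btw <- numeric(n)
  cls <- numeric(n)
  for (cid in seq_len(comps$no)) {
    vids <- which(comps$membership == cid)
    nc <- length(vids)
    if (nc < 2) next
    sub <- igraph::induced_subgraph(graph, vids)
    if (nc >= 3)
      btw[vids] <- igraph::betweenness(sub, directed = FALSE,
                                       normalized = TRUE)
    d <- igraph::distances(sub)
    cls[vids] <- (nc - 1) / rowSums(d)
  }
  asp <- igraph::mean_distance(graph, directed = FALSE, unconnected = TRUE)
  cc <- igraph::transitivity(graph, type = "localundirected",
                             isolates = "zero")
  data.frame(avg_shortest_path = asp,
             avg_betweenness = mean(btw),
             avg_closeness = mean(cls),
             avg_clustering_coefficient = mean(cc),
             avg_degree = 2 * igraph::ecount(graph) / n)
}

#' Write the topology summary as a one-row TSV
#' @param summary data.frame from [global_topology()].
#' @param path output path.
#' @export
write_topology <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
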