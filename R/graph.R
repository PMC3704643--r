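#' Build the directed MPA graph
#'
#' Nodes are MPAs; a directed edge j -> i exists whenever \code{c(i, j) > 0}
#' and \code{i != j}. Self-loops (local retention) are recorded as node flags
#' but excluded from the edge set used for neighborhoods, clusters and
#' shortest paths.
#'
#' @param cm a \code{\link{connectivity_matrix}} or plain probability matrix
#'   (rows destination, columns source).
#' @return an object of class \code{mpa_graph}: list with the \pkg{igraph}
#'   object \code{g}, \code{self_loop} flags and edge probabilities.
#' @export
build_graph <- function(cm) {
  m <- if (inherits(cm, "connectivity_matrix")) cm$c else as.matrix(cm)
  n <- nrow(m)
  self_loop <- diag(m) > 0
  adj <- t(m)                 # adjacency[j, i]: edge j -> i
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed",
                                           weighted = TRUE)
  igraph::V(g)$name <- rownames(m) %||% as.character(seq_len(n))
  structure(list(g = g, n = n, self_loop = self_loop,
                 ids = as.integer(igraph::V(g)$name)),
            class = "mpa_graph")
}

#' @export
print.mpa_graph <- function(x, ...) {
  cat(sprintf("mpa_graph: %d nodes, %d directed edges, %d self-loops\n",
              x$n, igraph::ecount(x$g), sum(x$self_loop)))
  invisible(x)
}

#' Upstream and downstream neighborhood sizes
#'
#' Downstream neighborhood size = out-degree (MPAs receiving larvae from this
#' one through direct links); upstream = in-degree (MPAs sending larvae to
#' it). Self-loops are excluded. Also classifies nodes: isolated (both 0),
#' pure source (no upstream), pure sink (no downstream).
#'
#' @param graph an \code{\link{build_graph}} result.
#' @return data.frame with \code{mpa}, \code{downstream}, \code{upstream},
#'   \code{class}.
#' @export
neighborhood_sizes <- function(graph) {
  dn <- igraph::degree(graph$g, mode = "out")
  up <- igraph::degree(graph$g, mode = "in")
  cls <- ifelse(dn == 0 & up == 0, "isolated",
         ifelse(up == 0, "pure_source",
         ifelse(dn == 0, "pure_sink", "connected")))
  data.frame(mpa = graph$ids, downstream = as.integer(dn),
             upstream = as.integer(up), class = cls, row.names = NULL)
}

#' Strongly connected clusters
#'
#' Partition of the MPAs into strongly connected components: nodes in a
#' cluster are mutually reachable through directed larval paths. Every pure
#' source, pure sink and isolated MPA forms a singleton cluster.
#'
#' @param graph an \code{\link{build_graph}} result.
#' @return list with \code{membership} (integer vector named by MPA id) and
#'   \code{n_clusters}.
#' @export
strong_clusters <- function(graph) {
  comp <- igraph::components(graph$g, mode = "strong")
  list(membership = stats::setNames(as.integer(comp$membership), graph$ids),
       n_clusters = comp$no)
}

#' Weakly connected clusters
#'
#' Connected components after forgetting edge direction. Always at most as
#' many clusters as the strong criterion gives: every weak cluster is a
#' union of strong clusters.
#'
#' @param graph an \code{\link{build_graph}} result.
#' @return list with \code{membership} and \code{n_clusters}.
#' @export
weak_clusters <- function(graph) {
  comp <- igraph::components(graph$g, mode = "weak")
  list(membership = stats::setNames(as.integer(comp$membership), graph$ids),
       n_clusters = comp$no)
}

#' Betweenness centrality of MPAs
#'
#' \code{b(i) = sum over ordered pairs (k, l), k != i != l, of
#' sigma_kl(i) / sigma_kl}, where \code{sigma_kl} counts hop-count shortest
#' directed paths from k to l and \code{sigma_kl(i)} those passing through i.
#' Paths are unweighted ("minimum number of nodes regardless of the
#' distance"); unreachable pairs contribute nothing. Both the raw sum and a
#' normalized variant (divided by \code{(n-1)(n-2)}, the number of ordered
#' pairs) are returned.
#'
#' @param graph an \code{\link{build_graph}} result.
#' @return data.frame with \code{mpa}, \code{betweenness},
#'   \code{betweenness_norm}.
#' @export
betweenness_centrality <- function(graph) {
  b <- igraph::betweenness(graph$g, directed = TRUE, weights = NA,
                           normalized = FALSE)
  n <- graph$n
  norm <- if (n > 2) b / ((n - 1) * (n - 2)) else b * 0
  data.frame(mpa = graph$ids, betweenness = as.numeric(b),
             betweenness_norm = as.numeric(norm), row.names = NULL)
}

#' Rank MPAs by betweenness centrality
#'
#' Nodes sorted by decreasing betweenness (ties broken by id), with degrees
#' and cluster labels: the table identifies gateway MPAs whose loss would
#' fragment multigenerational connectivity.
#'
#' @param graph an \code{\link{build_graph}} result.
#' @return data.frame with \code{rank}, \code{mpa}, \code{betweenness},
#'   \code{betweenness_norm}, \code{downstream}, \code{upstream},
#'   \code{strong_cluster}, \code{weak_cluster}, \code{class}.
#' @export
rank_nodes <- function(graph) {
  b <- betweenness_centrality(graph)
  nb <- neighborhood_sizes(graph)
  sc <- strong_clusters(graph)$membership
  wc <- weak_clusters(graph)$membership
  out <- data.frame(mpa = b$mpa, betweenness = b$betweenness,
                    betweenness_norm = b$betweenness_norm,
                    downstream = nb$downstream, upstream = nb$upstream,
                    strong_cluster = as.integer(sc),
                    weak_cluster = as.integer(wc), class = nb$class)
  out <- out[order(-out$betweenness, out$mpa), ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Export the MPA graph as edge-list and node-metrics CSV
#'
#' @param graph an \code{\link{build_graph}} result.
#' @param edges_path,nodes_path output CSV paths (NULL to skip either).
#' @return invisible list of the two tables.
#' @export
write_graph_csv <- function(graph, edges_path = NULL, nodes_path = NULL) {
  el <- igraph::as_data_frame(graph$g, what = "edges")
  names(el) <- c("source", "destination", "c")
  nodes <- rank_nodes(graph)
  if (!is.null(edges_path)) utils::write.csv(el, edges_path, row.names = FALSE)
  if (!is.null(nodes_path)) utils::write.csv(nodes, nodes_path, row.names = FALSE)
  invisible(list(edges = el, nodes = nodes))
}
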