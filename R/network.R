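# internal constructor shared by build_network() and simulate_random_graph()
new_coexpr_network <- function(nodes, edges, threshold,
                               node_profile = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = nodes))
  if (nrow(edges) > 0) igraph::E(g)$r <- edges$r
  if (!is.null(node_profile)) igraph::V(g)$profile <- node_profile
  structure(list(graph = g,
                 nodes = data.frame(gene = nodes,
                                    profile = if (is.null(node_profile))
                                      NA_integer_ else node_profile),
                 edges = edges, threshold = threshold),
            class = "coexpr_network")
}

#' Build a gene co-expression network by correlation thresholding
#'
#' Pearson correlation of log2 signals is computed across all samples (all
#' conditions jointly — the condition dynamics are part of the signal) for
#' every gene pair; an edge connects two genes when `|r| >= threshold`. Edge
#' weights keep the signed correlation. Genes with constant signal are
#' excluded with a warning (their correlation is undefined).
#'
#' @param em an [expr_matrix()], typically restricted to the genes of the
#'   trend profiles of interest via [subset_genes()]
#' @param threshold absolute-correlation cutoff in (0, 1] (default 0.8)
#' @param node_profile optional integer vector (parallel to the matrix genes)
#'   labelling each node with its trend profile
#' @return object of class `coexpr_network`: `graph` (igraph), `nodes`
#'   (data.frame gene/profile), `edges` (data.frame from/to/r), `threshold`
#' @export
build_network <- function(em, threshold = 0.8, node_profile = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (nrow(em$values) < 2) stop("need at least 2 genes")
  if (ncol(em$values) < 3) stop("need at least 3 samples for correlation")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  L <- log2_values(em)
  sds <- apply(L, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped from the network: ",
            paste(utils::head(rownames(L)[sds == 0], 5), collapse = ", "))
    if (!is.null(node_profile)) node_profile <- node_profile[sds > 0]
    L <- L[sds > 0, , drop = FALSE]
  }
  if (nrow(L) < 2) stop("fewer than 2 non-constant genes")
  C <- stats::cor(t(L))
  hit <- which(abs(C) >= threshold & upper.tri(C), arr.ind = TRUE)
  edges <- data.frame(from = rownames(L)[hit[, 1]],
                      to = rownames(L)[hit[, 2]],
                      r = C[hit])
  new_coexpr_network(rownames(L), edges, threshold, node_profile)
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat("Co-expression network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges")
  if (!is.na(x$threshold)) cat(" (|r| >=", x$threshold, ")")
  cat("\n")
  invisible(x)
}

#' Plot a co-expression network
#' @param x a `coexpr_network`
#' @param ... passed to `igraph::plot.igraph`; node size scales with degree
#' @export
plot.coexpr_network <- function(x, ...) {
  deg <- igraph::degree(x$graph)
  igraph::plot.igraph(x$graph, vertex.size = 3 + 12 * deg / max(deg, 1),
                      vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Per-node network metrics: degree, clustering coefficient, k-core
#'
#' Degree is the neighbor count; the local clustering coefficient is
#' `2 e_i / (k_i (k_i - 1))` with `e_i` the number of edges among the node's
#' neighbors (0 by convention for degree < 2); the k-core index is the
#' largest `k` such that the node survives iterative removal of all nodes of
#' degree < `k`.
#'
#' @param network a `coexpr_network`
#' @return data.frame with `gene`, `profile`, `degree`, `clustering`,
#'   `kcore`, in node order
#' @export
node_metrics <- function(network) {
  stopifnot(inherits(network, "coexpr_network"))
  g <- network$graph
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[deg < 2] <- 0
  core <- igraph::coreness(g)
  data.frame(gene = igraph::V(g)$name, profile = network$nodes$profile,
             degree = as.integer(deg), clustering = cc,
             kcore = as.integer(core), row.names = NULL)
}

#' Rank hub genes
#'
#' Hubs are the most connected genes: nodes sorted by degree descending,
#' ties broken by clustering coefficient descending, then gene id.
#'
#' @param metrics a metrics data.frame from [node_metrics()] (or a
#'   `coexpr_network`, in which case metrics are computed)
#' @param top_k number of hubs to return (> 0; capped at the node count)
#' @return the top `top_k` rows of the metrics table, ranked
#' @export
rank_hubs <- function(metrics, top_k = 21) {
  if (inherits(metrics, "coexpr_network")) metrics <- node_metrics(metrics)
  if (top_k <= 0) stop("top_k must be > 0")
  ord <- order(-metrics$degree, -metrics$clustering, metrics$gene)
  out <- metrics[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Write the edge list of a network as TSV
#' @param network a `coexpr_network`
#' @param path output path
#' @export
write_edge_list <- function(network, path) {
  write_tsv(data.frame(gene_i = network$edges$from,
                       gene_j = network$edges$to,
                       r = network$edges$r), path)
}

#' Write a network as GraphML
#' @param network a `coexpr_network`
#' @param path output path
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
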