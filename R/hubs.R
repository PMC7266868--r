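#' Degree centrality and pivotal-hub identification
#'
#' Degree is the count of distinct neighbour nodes (a mixed-sign family
#' edge counts once). Nodes are ranked by degree descending with ties
#' sharing the smallest applicable rank; rows are ordered by degree
#' descending then label ascending. All maximal-degree nodes carry
#' \code{is_pivotal = TRUE}.
#'
#' @param net a \code{dn_network}, \code{dn_common}, or plain edge table
#'   with columns \code{node_a}/\code{node_b} (or
#'   \code{family_a}/\code{family_b}).
#' @return data.frame with columns node, degree, rank, is_pivotal.
#' @export
degree_centrality <- function(net) {
  edges <- network_edge_table(net)
  nodes <- if (inherits(net, "dn_network")) net$nodes$node else
    sort(unique(c(edges$node_a, edges$node_b)))
  if (!length(nodes))
    return(data.frame(node = character(), degree = integer(),
                      rank = integer(), is_pivotal = logical(),
                      stringsAsFactors = FALSE))
  deg <- vapply(nodes, function(n) {
    length(unique(c(edges$node_b[edges$node_a == n],
                    edges$node_a[edges$node_b == n])))
  }, integer(1))
  out <- data.frame(node = nodes, degree = deg, stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  out$rank <- as.integer(rank(-out$degree, ties.method = "min"))
  out$is_pivotal <- out$degree == max(out$degree)
  rownames(out) <- NULL
  out
}

#' Summarize the pivotal hub(s) of a network
#'
#' @param report output of [degree_centrality()].
#' @param net the network the report was computed from (for the incident
#'   edge sign breakdown).
#' @param pathways optional pathway table to annotate gene hubs.
#' @return list with \code{pivotal} (per-hub node, pathway, degree and
#'   sign counts) and \code{n_nodes}/\code{n_edges}; empty networks give a
#'   summary stating no hub.
#' @export
hub_summary <- function(report, net = NULL, pathways = NULL) {
  edges <- if (!is.null(net)) network_edge_table(net) else NULL
  if (!nrow(report))
    return(list(pivotal = list(), n_nodes = 0L, n_edges = 0L,
                message = "empty network: no hub"))
  piv <- report$node[report$is_pivotal]
  pivotal <- lapply(piv, function(n) {
    signs <- if (!is.null(edges))
      edges$sign[edges$node_a == n | edges$node_b == n] else character()
    fam_path <- if (!is.null(pathways)) {
      i <- match(n, pathways$gene_id)
      j <- if (is.na(i)) match(n, pathways$family) else i
      if (!is.na(j)) pathways$pathway[j] else NA_character_
    } else NA_character_
    list(node = n, pathway = fam_path,
         degree = report$degree[report$node == n],
         n_pos = sum(signs == "+"), n_neg = sum(signs == "-"),
         n_mixed = sum(signs == "mixed"))
  })
  list(pivotal = pivotal, n_nodes = nrow(report),
       n_edges = if (!is.null(edges)) nrow(edges) else NA_integer_)
}
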