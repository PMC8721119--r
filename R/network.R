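#' Build the dynamical residue network
#'
#' Nodes are residues; an edge joins exactly the residue pairs that are
#' persistent contacts in `contacts`, weighted by
#' \eqn{d_{ij} = -\ln|Corr_{ij}|} (see [edge_weight()]).  The sign of the
#' correlation is kept as an edge attribute for reporting.  Pairs with zero
#' correlation (infinite weight) are dropped from the edge set with a message.
#'
#' @param corr A [correlation_matrix()].
#' @param contacts A [contact_map()] over the same residues in the same order.
#' @return An object of class `dynamic_network` wrapping an igraph graph, with
#'   a tidy edge table (`res_i`, `res_j`, `corr`, `weight`).
#' @export
build_network <- function(corr, contacts) {
  stopifnot(inherits(corr, "correlation_matrix"), inherits(contacts, "contact_map"))
  keys <- rownames(corr)
  if (!identical(keys, rownames(contacts$probability))) {
    abort_allopath(
      "Correlation matrix and contact map do not share the same residue order.",
      "consistency_error"
    )
  }
  ut <- upper.tri(contacts$contact)
  sel <- which(contacts$contact & ut, arr.ind = TRUE)
  cvals <- corr[sel]
  w <- edge_weight(cvals)
  inf <- is.infinite(w)
  if (any(inf)) {
    rlang::inform(sprintf(
      "Dropping %d edge(s) with zero correlation (infinite weight).", sum(inf)
    ))
    sel <- sel[!inf, , drop = FALSE]
    cvals <- cvals[!inf]
    w <- w[!inf]
  }
  edges <- tibble::tibble(
    res_i = keys[sel[, 1L]],
    res_j = keys[sel[, 2L]],
    corr = cvals,
    weight = w
  )
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$res_i, to = edges$res_j,
               weight = edges$weight, corr = edges$corr),
    directed = FALSE,
    vertices = data.frame(name = keys)
  )
  structure(
    list(
      graph = g,
      edges = edges,
      residues = keys,
      settings = list(cutoff = contacts$cutoff, occupancy = contacts$occupancy)
    ),
    class = "dynamic_network"
  )
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat(sprintf(
    "<dynamic_network> %d residues, %d edges (contact cutoff %.1f A, occupancy >= %.2f)\n",
    length(x$residues), nrow(x$edges), x$settings$cutoff, x$settings$occupancy
  ))
  invisible(x)
}

#' Export a dynamical network
#'
#' @param net A [build_network()] result.
#' @param graphml,edges Optional output paths for GraphML and an edge-list TSV
#'   (`res_i`, `res_j`, `corr`, `weight`).
#' @return `net`, invisibly.
#' @export
write_network <- function(net, graphml = NULL, edges = NULL) {
  stopifnot(inherits(net, "dynamic_network"))
  if (!is.null(graphml)) igraph::write_graph(net$graph, graphml, format = "graphml")
  if (!is.null(edges)) readr::write_tsv(net$edges, edges)
  invisible(net)
}
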