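#' Typed weighted network
#'
#' Undirected network whose nodes carry a role (`otu`, `sample`,
#' `genotype-bin`, `property`) and whose edges carry a weight and an
#' optional sign. Bipartite networks (OTU-sample presence, enrichment
#' hypergraphs) set `bipartite = TRUE`, in which case every edge must span
#' two distinct roles. Node and edge tables are kept in deterministic
#' (lexicographic) order so exports are byte-reproducible.
#'
#' @param nodes data.frame with columns `id`, `role` and optional attribute
#'   columns.
#' @param edges data.frame with columns `from`, `to`, `weight` and optional
#'   `sign` (`"+"`, `"-"`, `"none"`) plus extra attribute columns.
#' @param bipartite Logical bipartite flag.
#' @return Object of class `rhizo_network`.
#' @export
rhizo_network <- function(nodes, edges = NULL, bipartite = FALSE) {
  nodes <- as.data.frame(nodes)
  if (!all(c("id", "role") %in% colnames(nodes)))
    stop("nodes need id and role columns")
  nodes$id <- as.character(nodes$id)
  nodes$role <- as.character(nodes$role)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(nodes$role %in% c("otu", "sample", "genotype-bin", "property")))
    stop("unknown node role")
  if (is.null(edges) || !nrow(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), sign = character())
  edges <- as.data.frame(edges)
  if (!all(c("from", "to") %in% colnames(edges)))
    stop("edges need from and to columns")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$weight)) edges$weight <- 1
  if (is.null(edges$sign)) edges$sign <- "none"
  bad <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad)) stop("edge endpoint(s) not in node set: ",
                        paste(unique(bad), collapse = ", "))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  # canonical endpoint order for an undirected edge, then sort
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  if (anyDuplicated(paste(edges$from, edges$to, sep = "\r")))
    stop("duplicate edges")
  if (bipartite && nrow(edges)) {
    role <- stats::setNames(nodes$role, nodes$id)
    if (any(role[edges$from] == role[edges$to]))
      stop("bipartite network has an edge within one role")
  }
  nodes <- nodes[order(nodes$role, nodes$id, method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, directed = FALSE,
                 bipartite = bipartite),
            class = "rhizo_network")
}

#' @export
print.rhizo_network <- function(x, ...) {
  cat(sprintf("rhizo_network: %d nodes, %d edges%s\n", nrow(x$nodes),
              nrow(x$edges), if (x$bipartite) " (bipartite)" else ""))
  invisible(x)
}

#' Node degrees of a network
#'
#' @param net A [rhizo_network()].
#' @return Named integer vector over all nodes (zero for isolated nodes).
#' @export
network_degree <- function(net) {
  deg <- stats::setNames(integer(nrow(net$nodes)), net$nodes$id)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$from, net$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Convert to an igraph object
#'
#' @param net A [rhizo_network()].
#' @param weighted Attach `weight` edge attribute.
#' @return An [igraph::graph] with node `role` and edge `sign` attributes.
#' @export
as_igraph <- function(net, weighted = TRUE) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  if (!weighted && "weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  g
}

#' Export a network to a standard graph format
#'
#' Deterministic exports for external graph viewers: `graphml` (node role /
#' attribute columns and edge weight/sign preserved), `edge-tsv`
#' (`source`, `target`, `weight`, `sign`), or `sif-like`
#' (`source  interaction  target`).
#'
#' @param net A [rhizo_network()].
#' @param path Destination file.
#' @param format One of `"graphml"`, `"edge-tsv"`, `"sif-like"`.
#' @export
export_network <- function(net, path, format = c("graphml", "edge-tsv",
                                                 "sif-like")) {
  if (length(format) != 1L || !format %in% c("graphml", "edge-tsv", "sif-like"))
    stop("unsupported format; supported: graphml, edge-tsv, sif-like")
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "edge-tsv") {
    df <- net$edges
    colnames(df)[colnames(df) == "from"] <- "source"
    colnames(df)[colnames(df) == "to"] <- "target"
    write_tsv_plain(df, path)
  } else {
    lines <- paste(net$edges$from, "cc", net$edges$to, sep = "\t")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Re-import a GraphML export
#'
#' @param path GraphML file written by [export_network()].
#' @return A [rhizo_network()].
#' @export
import_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- as.data.frame(igraph::vertex_attr(g))
  colnames(nodes)[colnames(nodes) == "name"] <- "id"
  ed <- igraph::as_data_frame(g, what = "edges")
  rhizo_network(nodes, ed, bipartite = FALSE)
}
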