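#' OTU co-occurrence correlation network
#'
#' Drops OTUs observed in fewer than `min_nonzero` samples, computes the
#' Pearson correlation between every remaining pair of OTU abundance
#' profiles across all samples, and connects pairs whose absolute
#' correlation reaches the threshold. Edge weight is `|r|`; the sign of `r`
#' is retained as edge metadata. Correlations are computed on the
#' Hellinger-scale table by default (pass `transform = FALSE` to correlate
#' the table as given).
#'
#' @param table An [otu_table()]; if on the counts scale and
#'   `transform = TRUE` it is Hellinger-transformed first.
#' @param threshold Absolute-correlation threshold (the study uses 0.6).
#' @param min_nonzero Rare-OTU filter (default 3 positive samples).
#' @param transform Apply [hellinger_transform()] to counts input.
#' @return A [rhizo_network()] over the retained OTUs.
#' @export
correlation_network <- function(table, threshold = 0.6, min_nonzero = 3L,
                                transform = TRUE) {
  if (ncol(table) < 3L) stop("need at least 3 samples")
  tab <- filter_min_occurrence(table, min_nonzero)
  if (transform && otu_scale(tab) %in% c("counts", "relative"))
    tab <- hellinger_transform(tab)
  nodes <- data.frame(id = otu_ids(tab), role = "otu")
  if (nrow(tab) < 2L)
    return(rhizo_network(nodes))
  r <- suppressWarnings(pearson_similarity_matrix(tab, axis = "otus"))
  hit <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = rownames(r)[hit[, 1L]],
                      to = rownames(r)[hit[, 2L]],
                      weight = abs(r[hit]),
                      sign = ifelse(r[hit] < 0, "-", "+"))
  rhizo_network(nodes, edges)
}

#' Node-level topology measures
#'
#' Degree, local clustering coefficient, topological coefficient, and
#' (unnormalised) betweenness centrality for every node of an undirected
#' network. Degree and clustering follow the usual definitions
#' (`cc = 2 * edges-among-neighbours / (k * (k - 1))`, 0 when `k < 2`).
#' The topological coefficient of node `n` is the mean of `J(n, m) / k(n)`
#' over all nodes `m != n` sharing at least one neighbour with `n`, where
#' `J(n, m)` counts shared neighbours plus 1 if `n` and `m` are adjacent;
#' it is 0 when `k < 2`. Betweenness counts shortest-path pairs through a
#' node with even splitting over equal-length paths. Degree, clustering and
#' betweenness are delegated to igraph; the topological coefficient is
#' computed directly from the adjacency matrix.
#'
#' @param net A [rhizo_network()].
#' @return data.frame of class `topology_report` with columns `id`,
#'   `degree`, `clustering_coefficient`, `topological_coefficient`,
#'   `betweenness`.
#' @export
topology_measures <- function(net) {
  g <- as_igraph(net, weighted = FALSE)
  ids <- net$nodes$id
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, ids); j <- match(net$edges$to, ids)
    adj[cbind(i, j)] <- 1; adj[cbind(j, i)] <- 1
  }
  shared <- adj %*% adj            # shared-neighbour counts
  jmat <- shared + adj             # +1 when adjacent
  tc <- vapply(seq_along(ids), function(v) {
    k <- sum(adj[v, ])
    if (k < 2) return(0)
    others <- which(shared[v, ] > 0)
    others <- setdiff(others, v)
    if (!length(others)) return(0)
    mean(jmat[v, others]) / k
  }, 0)
  out <- data.frame(id = ids,
                    degree = as.integer(deg[ids]),
                    clustering_coefficient = as.numeric(cc[ids]),
                    topological_coefficient = tc,
                    betweenness = as.numeric(btw[ids]))
  # isolated nodes: all coefficients defined as 0
  iso <- out$degree == 0
  out$clustering_coefficient[iso] <- 0
  out$topological_coefficient[iso] <- 0
  class(out) <- c("topology_report", "data.frame")
  out
}

#' Fungal/bacterial composition of communities
#'
#' Summarises each community of a partition by size and by how many members
#' are fungal vs bacterial, classifying it as `mixed`, `fungal-only` or
#' `bacterial-only`.
#'
#' @param partition A `community_partition` from [mcl_cluster()], or a named
#'   membership vector.
#' @param taxonomy A [taxonomy_table()] tagging every clustered OTU.
#' @return List with `communities` (data.frame: community, size, n_fungal,
#'   n_bacterial, class) and `tally` (named counts of the three classes,
#'   summing to the number of communities).
#' @export
community_composition <- function(partition, taxonomy) {
  membership <- if (inherits(partition, "community_partition"))
    partition$membership else partition
  dom <- otu_domain(taxonomy, names(membership))
  comm <- sort(unique(membership))
  rows <- lapply(comm, function(k) {
    d <- dom[membership == k]
    nf <- sum(d == "fungal"); nb <- sum(d == "bacterial")
    data.frame(community = k, size = nf + nb, n_fungal = nf,
               n_bacterial = nb,
               class = if (nf > 0 && nb > 0) "mixed"
                       else if (nf > 0) "fungal-only" else "bacterial-only")
  })
  communities <- do.call(rbind, rows)
  tally <- c(mixed = sum(communities$class == "mixed"),
             `fungal-only` = sum(communities$class == "fungal-only"),
             `bacterial-only` = sum(communities$class == "bacterial-only"))
  list(communities = communities, tally = tally)
}
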