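#' Pairwise Pearson similarity matrix
#'
#' Pearson correlation between all pairs of samples (columns) or OTUs
#' (rows). Computed on whatever scale the table holds; the workflow applies
#' it to Hellinger-transformed abundances, matching the normalisation used
#' before all multivariate analyses. Constant vectors would make `r`
#' undefined; their correlations are set to 0 (conservative, keeps spanning
#' trees connected) and the affected labels are recorded in the
#' `"constant"` attribute.
#'
#' @param table An [otu_table()] or plain numeric matrix.
#' @param axis `"samples"` (correlate columns) or `"otus"` (correlate rows).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_similarity_matrix <- function(table, axis = c("samples", "otus")) {
  axis <- match.arg(axis)
  v <- unclass(table)
  m <- if (axis == "samples") v else t(v)
  if (ncol(m) < 2L) stop("need at least 2 vectors to correlate")
  if (nrow(m) < 3L) stop("need vectors of length >= 3")
  sds <- apply(m, 2L, stats::sd)
  const <- colnames(m)[sds == 0]
  if (length(const))
    warning("constant vector(s), correlations set to 0: ",
            paste(const, collapse = ", "))
  r <- suppressWarnings(stats::cor(m))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  attr(r, "constant") <- const
  r
}

#' Proportional similarity matrix
#'
#' Renyi/Colwell proportional similarity between sample composition
#' profiles: columns are renormalised to proportions and
#' `PS(p, q) = sum_i min(p_i, q_i) = 1 - 0.5 * sum_i |p_i - q_i|`.
#' `PS = 1` iff two profiles are identical, `0` iff they share no OTUs.
#' All-zero samples get `PS = 0` against every other sample and are listed
#' in the `"empty"` attribute.
#'
#' @param table An [otu_table()] or numeric matrix (columns = samples).
#' @return Symmetric matrix in `[0, 1]` with unit diagonal (except all-zero
#'   samples, flagged).
#' @export
proportional_similarity_matrix <- function(table) {
  v <- unclass(table)
  cs <- colSums(v)
  empty <- colnames(v)[cs == 0]
  cs[cs == 0] <- 1
  p <- sweep(v, 2L, cs, "/")
  n <- ncol(p)
  ps <- matrix(1, n, n, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ps[i, j] <- ps[j, i] <- sum(pmin(p[, i], p[, j]))
  }
  if (length(empty)) {
    ps[colnames(v) %in% empty, ] <- 0
    ps[, colnames(v) %in% empty] <- 0
    diag(ps)[colnames(v) %in% empty] <- 1
    warning("all-zero sample(s), PS set to 0: ", paste(empty, collapse = ", "))
  }
  attr(ps, "empty") <- empty
  ps
}

#' Maximum spanning tree of a similarity matrix
#'
#' Converts similarities to distances `d = 1 - s` and finds the spanning
#' tree of minimum total distance (equivalently maximum total similarity)
#' by Kruskal's algorithm. Edges are considered in increasing distance with
#' ties broken by lexicographic `(u, v)` label order, so the tree is
#' bit-reproducible. With non-finite similarities the result is a spanning
#' forest (one tree per connected component).
#'
#' @param similarity Square symmetric similarity matrix.
#' @param labels Node labels (defaults to matrix dimnames).
#' @param role Node role recorded in the output network.
#' @return A [rhizo_network()] whose edge weights are the similarities.
#' @export
maximum_spanning_tree <- function(similarity, labels = NULL, role = "sample") {
  s <- as.matrix(similarity)
  n <- nrow(s)
  if (n < 2L) stop("need at least 2 nodes for a spanning tree")
  if (ncol(s) != n) stop("similarity matrix must be square")
  if (is.null(labels)) labels <- rownames(s)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  iu <- which(upper.tri(s))
  i <- ((iu - 1L) %% n) + 1L
  j <- ((iu - 1L) %/% n) + 1L
  keep <- is.finite(s[iu])
  i <- i[keep]; j <- j[keep]
  sim <- s[iu][keep]
  u <- pmin(labels[i], labels[j])
  v <- pmax(labels[i], labels[j])
  ord <- order(1 - sim, u, v, method = "radix")
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  pick <- logical(length(ord))
  for (k in ord) {
    ri <- find(i[k]); rj <- find(j[k])
    if (ri != rj) { parent[ri] <- rj; pick[k] <- TRUE }
  }
  nodes <- data.frame(id = labels, role = role)
  edges <- data.frame(from = u[pick], to = v[pick], weight = sim[pick],
                      sign = ifelse(sim[pick] < 0, "-", "+"))
  rhizo_network(nodes, edges)
}

#' Bipartite OTU-sample presence network
#'
#' Connects an OTU node to a sample node whenever the OTU was observed in
#' that sample (abundance > 0); edge weight is the abundance. Presence is
#' invariant to the Hellinger transform.
#'
#' @param table An [otu_table()].
#' @return A bipartite [rhizo_network()] with roles `otu` and `sample`.
#' @export
bipartite_presence_network <- function(table) {
  v <- unclass(table)
  idx <- which(v > 0, arr.ind = TRUE)
  nodes <- data.frame(id = c(rownames(v), colnames(v)),
                      role = rep(c("otu", "sample"),
                                 c(nrow(v), ncol(v))))
  edges <- data.frame(from = rownames(v)[idx[, 1L]],
                      to = colnames(v)[idx[, 2L]],
                      weight = v[idx], sign = rep("none", nrow(idx)))
  rhizo_network(nodes, edges, bipartite = TRUE)
}
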