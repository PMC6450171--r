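# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and, where the implementation delegates to a
# library, that library's routine as well).

# exact hypergeometric tail probabilities from binomial coefficients
oracle_fisher <- function(a, b, c, d, alternative = "greater") {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0, k - m2); hi <- min(k, m1)
  supp <- lo:hi
  dens <- choose(m1, supp) * choose(m2, k - supp) / choose(m1 + m2, k)
  if (alternative == "greater") {
    sum(dens[supp >= a])
  } else {
    obs <- dens[supp == a]
    sum(dens[dens <= obs * (1 + 1e-7)])
  }
}

# decode a Pruefer sequence into a tree edge list (nodes 1..n)
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  ptr <- 0L
  for (s in seq) {
    leaf <- which(degree == 1L)[1L]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(leaf, s)
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- last
  edges
}

# maximum total similarity over every spanning tree of K_n (Cayley)
oracle_max_spanning_total <- function(s) {
  n <- nrow(s)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_decode(seqs[r, ], n)
    tot <- sum(s[ed])
    if (tot > best) best <- tot
  }
  best
}

# betweenness by exhaustive simple-path enumeration (small graphs only)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(visited))
    out <- list()
    for (nb in which(adj[from, ] > 0)) {
      if (!nb %in% visited)
        out <- c(out, all_paths(nb, to, c(visited, nb)))
    }
    out
  }
  for (s in seq_len(n - 1L)) for (t in seq.int(s + 1L, n)) {
    paths <- all_paths(s, t, s)
    if (!length(paths)) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      inner <- setdiff(p, c(s, t))
      btw[inner] <- btw[inner] + 1 / length(shortest)
    }
  }
  btw
}

# plain-loop reference MCL, written independently of mcl_cluster(): no
# pruning, limit interpreted as weakly connected components of the support
reference_mcl_membership <- function(adj, inflation = 2.5, expansion = 2L,
                                     max_iter = 200L, tol = 1e-8) {
  n <- nrow(adj)
  diag(adj) <- diag(adj) + 1
  m <- adj
  for (j in seq_len(n)) m[, j] <- m[, j] / sum(m[, j])
  for (it in seq_len(max_iter)) {
    prev <- m
    ex <- m
    for (e in seq_len(expansion - 1L)) ex <- ex %*% m
    infl <- ex^inflation
    for (j in seq_len(n)) {
      cs <- sum(infl[, j])
      if (cs > 0) infl[, j] <- infl[, j] / cs
    }
    m <- infl
    if (max(abs(m - prev)) < tol) break
  }
  supp <- (m > 1e-5) | (t(m) > 1e-5)
  g <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected")
  igraph::components(g)$membership
}

# fraction of node pairs on which two partitions agree (same/split)
pair_agreement <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# tiny deterministic counts table used by several format/transform tests
toy_counts <- function() {
  otu_table(matrix(c(3, 0, 2, 1, 2, 0, 0, 5, 1, 4, 0, 3), nrow = 4,
                   dimnames = list(paste0("otu", 1:4), paste0("s", 1:3))),
            marker = "ITS", scale = "counts")
}

# small metadata frame matching toy layouts: k soils x r samples (+controls)
toy_frame <- function(soils = c("NC1", "NC2"), per_soil = 3L,
                      genotypes = NULL, controls = 0L) {
  reps <- if (is.null(genotypes)) per_soil else per_soil * length(genotypes)
  soil_col <- rep(soils, each = reps)
  geno_col <- if (is.null(genotypes)) rep("G1", length(soil_col)) else
    rep(rep(genotypes, each = per_soil), times = length(soils))
  ids <- paste0("s", seq_along(soil_col))
  samples <- data.frame(sample_id = c(ids, if (controls)
                          paste0("ctl", seq_len(controls))),
                        soil_id = c(soil_col, rep("control", controls)),
                        genotype_id = c(geno_col, rep("G1", controls)),
                        is_control = c(rep(FALSE, length(ids)),
                                       rep(TRUE, controls)),
                        experiment_id = "toy")
  soils_df <- data.frame(soil_id = soils, Ca_ppm = seq(300, by = 50,
                                                       length.out = length(soils)),
                         pH = seq(5.5, by = 0.3, length.out = length(soils)))
  sample_frame(samples, soils_df)
}
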