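test_that("correlation network thresholds |r| and drops sparse OTUs", {
  v <- rbind(a = c(1, 2, 3, 4, 5, 6),
             b = c(2, 4, 6, 8, 10, 12),       # proportional to a
             c = c(6, 5, 4, 3, 2, 1),         # anti-correlated with a
             d = c(0, 3, 0, 0, 0, 0))         # present in 1 sample
  colnames(v) <- paste0("s", 1:6)
  tab <- otu_table(v, scale = "counts")
  net <- correlation_network(tab, threshold = 0.6, min_nonzero = 3L,
                             transform = FALSE)
  expect_false("d" %in% net$nodes$id)
  ab <- net$edges[net$edges$from == "a" & net$edges$to == "b", ]
  expect_equal(ab$weight, 1)
  expect_equal(ab$sign, "+")
  ac <- net$edges[net$edges$from == "a" & net$edges$to == "c", ]
  expect_equal(ac$sign, "-")
  expect_error(correlation_network(tab[, 1:2]), "at least 3")
  # independent rows at n = 30: |r| >= 0.6 edges are rare
  set.seed(14)
  hits <- 0; pairs <- 0
  for (i in 1:20) {
    m <- matrix(rnorm(50 * 30), 50, 30)
    r <- cor(t(m))
    hits <- hits + sum(abs(r[upper.tri(r)]) >= 0.6)
    pairs <- pairs + sum(upper.tri(r))
  }
  expect_lt(hits / pairs, 0.01)
})

test_that("MCL recovers disjoint cliques exactly", {
  for (k in 3:6) {
    n <- 2L * k
    adj <- matrix(0, n, n)
    adj[1:k, 1:k] <- 1
    adj[(k + 1):n, (k + 1):n] <- 1
    diag(adj) <- 0
    dimnames(adj) <- list(paste0("v", 1:n), paste0("v", 1:n))
    part <- mcl_cluster(adj, inflation = 2.5)
    expect_equal(part$n_communities, 2L)
    expect_equal(length(unique(part$membership[1:k])), 1L)
    expect_equal(length(unique(part$membership[(k + 1):n])), 1L)
    expect_false(part$membership[1] == part$membership[n])
  }
  # single-edge graph is one community of two
  e <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("x", "y"),
                                                   c("x", "y")))
  p2 <- mcl_cluster(e)
  expect_equal(p2$n_communities, 1L)
  # empty graph
  p0 <- mcl_cluster(rhizo_network(data.frame(id = character(),
                                             role = character())))
  expect_equal(p0$n_communities, 0L)
  # negative weights rejected
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(mcl_cluster(neg), "non-negative")
})

test_that("MCL is idempotent and cluster counts fall with inflation", {
  set.seed(15)
  make_modular <- function(n_block = 3L, size = 6L, p_in = 0.7,
                           p_out = 0.05) {
    n <- n_block * size
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      same <- ((i - 1) %/% size) == ((j - 1) %/% size)
      if (runif(1) < (if (same) p_in else p_out)) adj[i, j] <- adj[j, i] <- 1
    }
    dimnames(adj) <- list(paste0("v", 1:n), paste0("v", 1:n))
    adj
  }
  trend <- matrix(0, 20, 4)
  for (g in 1:20) {
    adj <- make_modular()
    trend[g, ] <- vapply(c(1.5, 2.0, 2.5, 4.0), function(infl)
      mcl_cluster(adj, inflation = infl)$n_communities, 0L)
  }
  means <- colMeans(trend)
  expect_true(all(diff(means) >= 0))  # more inflation, finer partitions
  # idempotence: clustering the blocks again changes nothing
  adj <- make_modular()
  p1 <- mcl_cluster(adj)
  block_adj <- matrix(0, nrow(adj), nrow(adj), dimnames = dimnames(adj))
  for (cc in unique(p1$membership)) {
    mem <- which(p1$membership == cc)
    block_adj[mem, mem] <- 1
  }
  diag(block_adj) <- 0
  p2 <- mcl_cluster(block_adj)
  expect_equal(pair_agreement(p1$membership, p2$membership), 1)
})

test_that("topology measures match their definitions on small graphs", {
  tri <- rhizo_network(data.frame(id = c("a", "b", "c"), role = "otu"),
                       data.frame(from = c("a", "a", "b"),
                                  to = c("b", "c", "c")))
  tt <- topology_measures(tri)
  expect_equal(tt$degree, rep(2L, 3))
  expect_equal(tt$clustering_coefficient, rep(1, 3))
  expect_equal(tt$topological_coefficient, rep(1, 3))
  expect_equal(tt$betweenness, rep(0, 3))
  path <- rhizo_network(data.frame(id = c("a", "b", "c"), role = "otu"),
                        data.frame(from = c("a", "b"), to = c("b", "c")))
  tp <- topology_measures(path)
  expect_equal(tp$betweenness[tp$id == "b"], 1)
  expect_equal(tp$clustering_coefficient, rep(0, 3))
  # isolated node has all coefficients zero
  iso <- rhizo_network(data.frame(id = c("a", "b", "c"), role = "otu"),
                       data.frame(from = "a", to = "b"))
  ti <- topology_measures(iso)
  expect_equal(ti[ti$id == "c", c("degree", "clustering_coefficient",
                                  "topological_coefficient", "betweenness")],
               data.frame(degree = 0L, clustering_coefficient = 0,
                          topological_coefficient = 0, betweenness = 0),
               ignore_attr = TRUE)
})

test_that("betweenness matches exhaustive enumeration on graphs up to 7 nodes", {
  set.seed(16)
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.45) adj[i, j] <- adj[j, i] <- 1
    dimnames(adj) <- list(paste0("v", 1:n), paste0("v", 1:n))
    idx <- which(adj > 0 & upper.tri(adj), arr.ind = TRUE)
    if (!nrow(idx)) next
    net <- rhizo_network(data.frame(id = rownames(adj), role = "otu"),
                         data.frame(from = rownames(adj)[idx[, 1]],
                                    to = colnames(adj)[idx[, 2]]))
    got <- topology_measures(net)
    want <- oracle_betweenness(adj)
    expect_equal(got$betweenness[match(rownames(adj), got$id)], want,
                 tolerance = 1e-9)
  }
})

test_that("community composition tallies fungi and bacteria per community", {
  taxonomy <- taxonomy_table(data.frame(
    otu_id = c("f1", "f2", "b1", "b2"),
    kingdom = c("Fungi", "Fungi", "Bacteria", "Bacteria"),
    phylum = "", class = "", order = "", family = "", genus = "",
    species = "", domain = c("fungal", "fungal", "bacterial", "bacterial")))
  membership <- c(f1 = 1L, b1 = 1L, f2 = 2L, b2 = 3L)
  comp <- community_composition(membership, taxonomy)
  expect_equal(comp$communities$class,
               c("mixed", "fungal-only", "bacterial-only"))
  expect_equal(sum(comp$tally), 3L)
  expect_equal(comp$communities$size,
               comp$communities$n_fungal + comp$communities$n_bacterial)
  expect_error(community_composition(c(zz = 1L), taxonomy), "missing")
})
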