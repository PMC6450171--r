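test_that("bray-curtis handles identical, disjoint and partial overlap", {
  v <- cbind(a = c(2, 0), b = c(1, 1), c = c(2, 0), d = c(0, 3))
  tab <- otu_table(v, scale = "counts")
  d <- as.matrix(bray_curtis_matrix(tab))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], 1)
  expect_equal(d["a", "b"], 0.5)
  expect_true(all(d >= 0 & d <= 1))
  # all-zero pair defined as 0 and flagged
  z <- otu_table(cbind(a = c(1, 0), b = c(0, 0), c = c(0, 0)),
                 scale = "counts")
  dz <- bray_curtis_matrix(z)
  expect_setequal(attr(dz, "empty"), c("b", "c"))
  expect_equal(as.matrix(dz)["b", "c"], 0)
})

test_that("pcoa reconstructs planted coordinates and agrees with cmdscale", {
  pts <- cbind(c(0, 3, 7, 10), c(0, 0, 0, 0))
  d <- dist(pts)
  out <- pcoa(d, k = 1L)
  rec <- dist(out$coordinates[, 1])
  expect_equal(as.numeric(rec), as.numeric(d), tolerance = 1e-9)
  # agreement with classical scaling up to sign
  set.seed(41)
  x <- matrix(rnorm(24), 8, 3)
  dd <- dist(x)
  mine <- pcoa(dd, k = 3L)$coordinates
  ref <- cmdscale(dd, k = 3)
  for (j in 1:3)
    expect_equal(abs(mine[, j]), abs(ref[, j]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  # axis sign convention: largest-magnitude loading positive
  expect_true(all(apply(mine, 2, function(cl) cl[which.max(abs(cl))] > 0)))
  # zero matrix and euclidean eigenvalue bound
  zero <- matrix(0, 3, 3)
  expect_warning(z <- pcoa(zero, k = 2L), "positive eigenvalue")
  expect_equal(ncol(z$coordinates), 0L)
  expect_true(all(pcoa(dd, k = 2L)$eigenvalues > -1e-9 * max(abs(dd))))
})

test_that("permanova matches brute-force sums of squares", {
  set.seed(42)
  x <- matrix(abs(rnorm(18 * 10)), 18, 10)
  d <- vegan::vegdist(x, "bray")
  g <- rep(c("a", "b", "c"), each = 6)
  res <- permanova(d, g, n_permutations = 99L, seed = 1L)
  m <- as.matrix(d)
  n <- nrow(m); k <- 3
  ss_total <- sum(m[upper.tri(m)]^2) / n
  ss_within <- sum(vapply(unique(g), function(gg) {
    sub <- m[g == gg, g == gg]
    sum(sub[upper.tri(sub)]^2) / sum(g == gg)
  }, 0))
  ss_between <- ss_total - ss_within
  f_oracle <- (ss_between / (k - 1)) / (ss_within / (n - k))
  expect_equal(res$pseudo_F, f_oracle, tolerance = 1e-10)
  expect_equal(res$R_squared, ss_between / ss_total, tolerance = 1e-10)
  # R^2 + residual fraction = 1
  expect_equal(res$R_squared + ss_within / ss_total, 1, tolerance = 1e-10)
  expect_error(permanova(d, c("a", rep("b", 17))), "single member")
  # identical seed, identical p
  p1 <- permanova(d, g, n_permutations = 199L, seed = 5L)$p_value
  p2 <- permanova(d, g, n_permutations = 199L, seed = 5L)$p_value
  expect_identical(p1, p2)
})

test_that("well-separated groups saturate the permutation p-value", {
  set.seed(43)
  x <- rbind(matrix(rnorm(8 * 4, 0), 8, 4), matrix(rnorm(8 * 4, 30), 8, 4))
  d <- dist(x)
  g <- rep(c("lo", "hi"), each = 8)
  res <- permanova(d, g, n_permutations = 199L, seed = 2L)
  expect_lte(res$p_value, 2 / 200)
})

test_that("permdisp reproduces betadisper distances and the anova F", {
  set.seed(44)
  x <- matrix(abs(rnorm(16 * 12)), 16, 12)
  d <- vegan::vegdist(x, "bray")
  g <- factor(rep(c("a", "b", "c", "d"), each = 4))
  mine <- permdisp(d, g, n_permutations = 99L, seed = 1L)
  ref <- vegan::betadisper(d, g, type = "centroid")
  expect_equal(unname(mine$distances), unname(ref$distances),
               tolerance = 1e-10)
  expect_equal(mine$F, anova(ref)$`F value`[1], tolerance = 1e-10)
  # duplicated points at the centroid have zero dispersion
  y <- rbind(matrix(rep(c(1, 2), each = 4), 4, 2), matrix(rnorm(8), 4, 2))
  dy <- dist(y)
  gy <- rep(c("dup", "spread"), each = 4)
  md <- permdisp(dy, gy, n_permutations = 99L, seed = 1L)
  expect_equal(unname(md$group_dispersion["dup"]), 0, tolerance = 1e-10)
})

test_that("indicator statistic hits its boundary cases", {
  v <- rbind(perfect = c(4, 5, 6, 0, 0, 0),
             uniform = c(2, 2, 2, 2, 2, 2),
             other = c(1, 0, 2, 3, 1, 2))
  colnames(v) <- paste0("s", 1:6)
  g <- rep(c("g1", "g2"), each = 3)
  res <- indicator_analysis(v, g, allow_combinations = FALSE,
                            n_permutations = 99L, seed = 1L)
  perfect <- res[res$otu_id == "perfect", ]
  expect_equal(perfect$stat, 1)
  expect_equal(perfect$best_target, "g1")
  expect_equal(res$A[res$otu_id == "uniform"], 0.5)  # 1/k for k = 2
  # scale invariance of the statistic
  res10 <- indicator_analysis(v * 10, g, allow_combinations = FALSE,
                              n_permutations = 99L, seed = 1L)
  expect_equal(res10$stat, res$stat, tolerance = 1e-12)
})

test_that("indicator group unions beat single groups for shared taxa", {
  set.seed(45)
  v <- rbind(pair = c(5, 6, 5, 6, 5, 6, 0, 0, 0, 0, 0, 0),
             noise = abs(rnorm(12)))
  colnames(v) <- paste0("s", 1:12)
  g <- rep(c("g1", "g2", "g3", "g4"), each = 3)
  res <- indicator_analysis(v, g, allow_combinations = TRUE,
                            n_permutations = 199L, seed = 1L)
  expect_equal(res$best_target[res$otu_id == "pair"], "g1+g2")
  expect_equal(res$stat[res$otu_id == "pair"], 1, tolerance = 1e-12)
})

test_that("chi-square detection matches the formula oracle", {
  u <- matrix(10, 2, 2)
  res <- chi_square_detection(u)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  set.seed(46)
  for (i in 1:10) {
    m <- matrix(rpois(6, 30) + 5, 2, 3)
    got <- chi_square_detection(m)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(got$statistic, sum((m - e)^2 / e), tolerance = 1e-12)
  }
  # 1 x k reduces to uniform goodness of fit
  g1 <- chi_square_detection(matrix(c(10, 20, 30), 1, 3))
  ref <- suppressWarnings(chisq.test(c(10, 20, 30)))
  expect_equal(g1$statistic, unname(ref$statistic))
  expect_warning(chi_square_detection(matrix(c(1, 0, 0, 1), 2, 2)),
                 "expected")
})

test_that("detection counts feed the contingency", {
  tab <- toy_counts()
  dc <- detection_counts(tab, c("g1", "g1", "g2"))
  expect_equal(unname(dc["g1"]), sum(rowSums(unclass(tab)[, 1:2]) > 0))
  expect_equal(unname(dc["g2"]), sum(unclass(tab)[, 3] > 0))
})
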