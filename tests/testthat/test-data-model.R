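test_that("otu_table validates ids, signs and scale invariants", {
  tab <- toy_counts()
  expect_equal(dim(tab), c(4L, 3L))
  expect_equal(otu_scale(tab), "counts")
  expect_error(otu_table(matrix(1, 2, 2), otu_ids = c("a", "a")),
               "duplicate OTU")
  expect_error(otu_table(matrix(-1, 1, 1)), "negative")
  expect_error(otu_table(matrix(2, 2, 2), scale = "relative"), "sum to 1")
})

test_that("dense and sparse dialects round-trip bit-identically", {
  tab <- toy_counts()
  for (dialect in c("tsv-dense", "triplet-sparse")) {
    f <- withr::local_tempfile(fileext = ".tsv")
    write_otu_table(tab, f, dialect = dialect)
    back <- read_otu_table(f, dialect = dialect)
    expect_equal(unclass(back)[otu_ids(tab), sample_ids(tab)],
                 unclass(tab), ignore_attr = TRUE)
    # byte-identical on rewrite
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_otu_table(back[otu_ids(tab), sample_ids(tab)], f2,
                    dialect = dialect)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("triplet reader fills absent cells with zero", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tsample_id\tcount", "otu1\ts1\t3"), f)
  tab <- read_otu_table(f, dialect = "triplet-sparse")
  expect_equal(as.numeric(unclass(tab)), 3)
})

test_that("malformed tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1\ts1", "otu1\t1\t2"), f)
  expect_error(read_otu_table(f), "duplicate sample")
  writeLines(c("otu_id\ts1", "otu1\tfrog"), f)
  expect_error(read_otu_table(f), "non-numeric.*otu1")
  writeLines(c("otu_id\ts1", "otu1\t-2"), f)
  expect_error(read_otu_table(f), "negative")
})

test_that("metadata joins samples to soils and rejects unknown soils", {
  frame <- toy_frame()
  expect_equal(sample_property(frame, c("s1", "s4"), "Ca_ppm"), c(300, 350))
  samples <- frame$samples
  samples$soil_id[1] <- "XX"
  expect_error(sample_frame(samples, frame$soils), "undefined soil.*XX")
  # control samples need no soil properties
  frame2 <- toy_frame(controls = 2L)
  expect_true(all(is.na(sample_property(frame2, c("ctl1", "ctl2"), "pH"))))
  expect_error(sample_frame(frame$samples[, -2], frame$soils),
               "missing sample metadata")
})

test_that("metadata and taxonomy round-trip through TSV", {
  frame <- toy_frame(controls = 1L)
  fs <- withr::local_tempfile(fileext = ".tsv")
  fo <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(frame, fs, fo)
  back <- read_metadata(fs, fo)
  expect_equal(back$samples, frame$samples)
  expect_equal(back$soils, frame$soils)
})

test_that("hellinger transform yields unit-norm columns, zeros preserved", {
  tab <- otu_table(matrix(c(1, 4, 0, 0, 7, 0), nrow = 2), scale = "counts")
  h <- hellinger_transform(tab)
  expect_equal(unclass(h)[, 1], c(otu1 = 0.4472, otu2 = 0.8944),
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(unclass(h)[, 2], c(0, 0), ignore_attr = TRUE)
  expect_equal(unclass(h)[, 3], c(1, 0), ignore_attr = TRUE)
  expect_equal(otu_scale(h), "hellinger")
  # property: unit Euclidean norm of nonzero columns on random tables
  set.seed(1)
  for (i in 1:20) {
    v <- matrix(rpois(60, 3), nrow = 6)
    hh <- unclass(hellinger_transform(otu_table(v, scale = "counts")))
    nz <- colSums(v) > 0
    expect_true(all(abs(sqrt(colSums(hh[, nz, drop = FALSE]^2)) - 1) < 1e-12))
  }
})

test_that("rank abundance orders by mean relative abundance with id ties", {
  tab <- otu_table(matrix(c(2, 8), nrow = 2,
                          dimnames = list(c("otu1", "otu2"), "s1")),
                   scale = "counts")
  r <- relative_and_rank_abundance(tab)
  expect_equal(r$otu_id, c("otu2", "otu1"))
  expect_equal(r$mean_relative_abundance, c(0.8, 0.2))
  tie <- otu_table(matrix(c(5, 5), nrow = 2,
                          dimnames = list(c("b", "a"), "s1")),
                   scale = "counts")
  expect_equal(relative_and_rank_abundance(tie)$otu_id, c("a", "b"))
  two <- otu_table(matrix(c(1, 0, 0, 1), nrow = 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))),
                   scale = "counts")
  r2 <- relative_and_rank_abundance(two)
  expect_equal(r2$mean_relative_abundance, c(0.5, 0.5))
  expect_equal(r2$otu_id, c("a", "b"))
  expect_error(relative_and_rank_abundance(two, groups = c("g1", "g1")),
               NA)
})

test_that("minimum-occurrence filter keeps the boundary and is idempotent", {
  v <- matrix(c(1, 1, 0, 0, 0,
                2, 0, 1, 1, 0,
                1, 1, 1, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("two", "three", "alsothree"), paste0("s", 1:5)))
  tab <- otu_table(v, scale = "counts")
  f3 <- filter_min_occurrence(tab, 3L)
  expect_setequal(otu_ids(f3), c("three", "alsothree"))
  expect_equal(sample_ids(f3), paste0("s", 1:5))
  expect_equal(unclass(filter_min_occurrence(f3, 3L)), unclass(f3))
  expect_equal(unclass(filter_min_occurrence(tab, 1L)), unclass(tab))
  # commutes with sample-column permutation
  perm <- c(3, 1, 5, 2, 4)
  a <- unclass(filter_min_occurrence(tab[, perm], 2L))
  b <- unclass(filter_min_occurrence(tab, 2L)[, perm])
  expect_equal(a, b)
})

test_that("rarefaction expectation matches closed form and Monte Carlo", {
  expect_equal(rarefaction_expected_richness(c(5, 5), 1L), 1.0)
  expect_equal(rarefaction_expected_richness(c(5, 5), 10L), 2.0)
  expect_equal(rarefaction_expected_richness(10, c(1L, 5L)), c(1, 1))
  expect_error(rarefaction_expected_richness(c(2, 2), 5L), "exceeds")
  counts <- c(6, 3, 1, 0, 2)
  depths <- c(1L, 4L, 8L)
  ex <- rarefaction_expected_richness(counts, depths)
  expect_true(all(diff(ex) >= 0))
  # Monte-Carlo oracle: subsample reads without replacement
  set.seed(42)
  reads <- rep(seq_along(counts), counts)
  for (j in seq_along(depths)) {
    sims <- replicate(10000, length(unique(sample(reads, depths[j]))))
    se <- sd(sims) / sqrt(length(sims))
    expect_lt(abs(mean(sims) - ex[j]), 3 * se + 1e-9)
  }
})
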