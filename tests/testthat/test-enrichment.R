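test_that("contingency cells partition the grand total", {
  tab <- otu_table(matrix(c(3, 1, 0, 2), 2, 2,
                          dimnames = list(c("otu1", "otu2"), c("s1", "s2"))),
                   scale = "counts")
  cells <- sample_contingency(tab, "otu1", "s1")
  expect_equal(cells, c(a = 3, b = 0, c = 1, d = 2))
  expect_equal(sum(cells), sum(unclass(tab)))
  # absent OTU
  tab2 <- otu_table(rbind(unclass(tab), none = c(0, 0)), scale = "counts")
  cells2 <- sample_contingency(tab2, "none", "s1")
  expect_equal(unname(cells2[c("a", "b")]), c(0, 0))
  expect_equal(fisher_exact_test(cells2["a"], cells2["b"], cells2["c"],
                                 cells2["d"]), 1)
  expect_error(sample_contingency(tab / 2, "otu1", "s1"), "integer")
})

test_that("fisher exact matches hypergeometric enumeration on examples", {
  expect_equal(fisher_exact_test(3, 0, 0, 3, "greater"), 1 / 20)
  expect_equal(fisher_exact_test(2, 0, 0, 2, "greater"), 1 / 6)
  expect_equal(fisher_exact_test(1, 1, 1, 1, "two.sided"), 1)
  expect_equal(fisher_exact_test(0, 5, 5, 0, "greater"), 1)
  # zero margins
  expect_equal(fisher_exact_test(0, 0, 3, 4), 1)
  expect_equal(fisher_exact_test(3, 4, 0, 0), 1)
  # spot agreement with stats::fisher.test on moderate tables
  set.seed(6)
  for (i in 1:25) {
    cells <- rpois(4, 6) + 1
    ft <- stats::fisher.test(matrix(cells, 2, 2), alternative = "greater")
    expect_equal(fisher_exact_test(cells[1], cells[3], cells[2], cells[4],
                                   "greater"), ft$p.value, tolerance = 1e-9)
    ft2 <- stats::fisher.test(matrix(cells, 2, 2))
    expect_equal(fisher_exact_test(cells[1], cells[3], cells[2], cells[4],
                                   "two.sided"), ft2$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH step-up adjusts and flags per the closed form", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), level = 0.05)
  expect_equal(out$adjusted_p, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(out$discovery, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), 0.01)$discovery, rep(FALSE, 5))
  expect_true(bh_fdr(0.005, 0.01)$discovery)
  expect_equal(bh_fdr(numeric(), 0.01)$adjusted_p, numeric())
  # discovery set shrinks as the level drops
  set.seed(1)
  p <- runif(40)^2
  lv <- c(0.2, 0.1, 0.05, 0.01)
  ns <- vapply(lv, function(l) sum(bh_fdr(p, l)$discovery), 0L)
  expect_true(all(diff(ns) <= 0))
})

test_that("per-sample enrichment finds a concentrated OTU end to end", {
  set.seed(12)
  v <- matrix(rpois(60, 5), 10, 6,
              dimnames = list(paste0("o", 1:10), paste0("s", 1:6)))
  v["o1", ] <- c(60, 0, 0, 0, 0, 0)  # concentrated in s1
  tab <- otu_table(v, scale = "counts")
  frame <- toy_frame(per_soil = 3L)
  enr <- build_enrichment_network(tab, frame, mode = "per-sample",
                                  level = 0.01)
  hits <- enr$results[enr$results$enriched, ]
  expect_true(any(hits$otu_id == "o1" & hits$unit_id == "s1"))
  # oracle: manual fisher + BH over the same family
  fam <- enr$results
  manual_p <- mapply(oracle_fisher, fam$a, fam$b, fam$c, fam$d)
  expect_equal(fam$raw_p, unname(manual_p), tolerance = 1e-12)
  expect_equal(fam$adjusted_p, p.adjust(fam$raw_p, "BH"))
  # a uniform table has no enrichment anywhere
  u <- otu_table(matrix(5, 8, 6, dimnames = list(paste0("o", 1:8),
                                                 paste0("s", 1:6))),
                 scale = "counts")
  enr_u <- build_enrichment_network(u, frame, mode = "per-sample")
  expect_equal(nrow(enr_u$network$edges), 0)
})

test_that("control samples form their own enrichment family", {
  frame <- toy_frame(per_soil = 2L, controls = 2L)
  set.seed(3)
  v <- matrix(rpois(6 * 10, 4), 10, 6,
              dimnames = list(paste0("o", 1:10),
                              frame$samples$sample_id))
  v["o9", 5:6] <- c(80, 0)   # concentrated within the control family
  tab <- otu_table(v, scale = "counts")
  enr <- build_enrichment_network(tab, frame, mode = "per-sample")
  ctl_units <- frame$samples$sample_id[frame$samples$is_control]
  ctl_rows <- enr$results[enr$results$unit_id %in% ctl_units, ]
  # control family's cells only involve control-sample totals
  expect_equal(unique(ctl_rows$a + ctl_rows$c),
               unname(colSums(v[, ctl_units]))[match(unique(ctl_rows$unit_id),
                                                     ctl_units)])
  expect_true(any(ctl_rows$enriched[ctl_rows$otu_id == "o9"]))
})

test_that("binned mode bins by genotype and corrects FDR per soil", {
  frame <- toy_frame(per_soil = 2L, genotypes = c("G1", "G2"))
  # identical sub-matrices in the two soils must give identical edge sets
  block <- matrix(c(20, 0, 0, 0, 18, 2, 2, 2,
                    1, 8, 1, 7, 2, 2, 2, 2), 4, 4, byrow = TRUE)
  v <- cbind(block, block)
  dimnames(v) <- list(paste0("o", 1:4), frame$samples$sample_id)
  tab <- otu_table(v, scale = "counts")
  enr <- build_enrichment_network(tab, frame, mode = "binned-by-genotype",
                                  level = 0.05)
  res <- enr$results
  expect_setequal(unique(res$soil_id), c("NC1", "NC2"))
  per_soil <- split(res[, c("otu_id", "a", "b", "c", "d", "raw_p",
                            "adjusted_p", "enriched")],
                    res$soil_id)
  rownames(per_soil$NC1) <- rownames(per_soil$NC2) <- NULL
  expect_equal(per_soil$NC1, per_soil$NC2)
  # genotype bins sum the member samples
  expect_equal(res$a[res$otu_id == "o1" & res$unit_id == "NC1|G1"],
               sum(v["o1", 1:2]))
  # single-genotype soil is skipped with a warning
  frame1 <- toy_frame(per_soil = 3L)
  w <- capture_warnings(
    b1 <- build_enrichment_network(tab[, 1:6], frame1,
                                   mode = "binned-by-genotype"))
  expect_match(w, "single genotype", all = TRUE)
  expect_equal(nrow(b1$results), 0L)
})

test_that("quotient rule selects genotype-specific OTUs", {
  frame <- toy_frame(per_soil = 3L, genotypes = c("G1", "G2", "G3", "G4"))
  frame$samples$soil_id <- "NC1"
  frame$samples <- frame$samples[1:12, ]
  # build an enrichment network by hand: edges otu -> samples
  edges <- data.frame(
    from = c("q4", "q4", "q4", "q4",  # degree 4 across 2 genotypes
             "q3", "q3", "q3",       # degree 3 across 3 genotypes
             "q2", "q2"),            # degree 2 within 1 genotype
    to = c("s1", "s2", "s4", "s5", "s1", "s4", "s7", "s10", "s11"))
  nodes <- data.frame(id = c("q4", "q3", "q2", paste0("s", 1:12)),
                      role = rep(c("otu", "sample"), c(3, 12)))
  net <- rhizo_network(nodes, edges, bipartite = TRUE)
  sel <- genotype_quotient_selection(net, frame)
  expect_equal(sel$quotient[sel$otu_id == "q4"], 2.0)
  expect_true(sel$selected[sel$otu_id == "q4"])
  expect_equal(sel$quotient[sel$otu_id == "q3"], 1.0)
  expect_false(sel$selected[sel$otu_id == "q3"])
  expect_equal(sel$quotient[sel$otu_id == "q2"], 2.0)
  expect_true(sel$selected[sel$otu_id == "q2"])
  # degree-0 OTUs are absent from the result
  expect_setequal(sel$otu_id, c("q2", "q3", "q4"))
})
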