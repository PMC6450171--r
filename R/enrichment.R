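#' Contingency table for OTU-in-unit enrichment
#'
#' Partitions the grand read total of an integer count matrix into the four
#' cells used by the enrichment test: `a` = reads of the OTU in the unit,
#' `b` = reads of the OTU in all other units, `c` = reads of all other OTUs
#' in the unit, `d` = reads of all other OTUs elsewhere. The cells always
#' conserve the grand total.
#'
#' @param table Integer count matrix or [otu_table()] (rows OTUs, columns
#'   analysis units: samples or genotype bins).
#' @param otu OTU row id.
#' @param unit Unit column id.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
sample_contingency <- function(table, otu, unit) {
  v <- unclass(table)
  if (any(v != round(v)))
    stop("contingency tables need raw integer counts; use the counts-scale table")
  if (!otu %in% rownames(v)) stop("unknown OTU: ", otu)
  if (!unit %in% colnames(v)) stop("unknown unit: ", unit)
  a <- v[otu, unit]
  b <- sum(v[otu, ]) - a
  cc <- sum(v[, unit]) - a
  d <- sum(v) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric tail probability at fixed margins.
#' `alternative = "greater"` sums `P(X >= a)` (enrichment);
#' `"two.sided"` sums the probabilities of all tables whose point
#' probability does not exceed that of the observed table. Any zero margin
#' means no association is testable and returns `p = 1` by convention.
#' Vectorised over `a`, `b`, `c`, `d`.
#'
#' @param a,b,c,d Non-negative integer cells (recycled to common length).
#' @param alternative `"greater"` or `"two.sided"`.
#' @return Numeric vector of p-values.
#' @export
fisher_exact_test <- function(a, b, c, d,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(cbind(a, b, c, d) < 0) || any(cbind(a, b, c, d) != round(cbind(a, b, c, d))))
    stop("cells must be non-negative integers")
  m1 <- a + b          # OTU reads (white balls)
  m2 <- c + d          # other reads
  k <- a + c           # reads drawn into the unit
  p <- numeric(n)
  zero_margin <- (m1 == 0) | (m2 == 0) | (k == 0) | (b + d == 0)
  p[zero_margin] <- 1
  todo <- which(!zero_margin)
  if (alternative == "greater") {
    p[todo] <- stats::phyper(a[todo] - 1, m1[todo], m2[todo], k[todo],
                             lower.tail = FALSE)
  } else {
    for (t in todo) {
      lo <- max(0, k[t] - m2[t]); hi <- min(k[t], m1[t])
      supp <- lo:hi
      dens <- stats::dhyper(supp, m1[t], m2[t], k[t])
      obs <- stats::dhyper(a[t], m1[t], m2[t], k[t])
      p[t] <- sum(dens[dens <= obs * (1 + 1e-7)])
    }
  }
  pmin(p, 1)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) and discovery flags
#' at a target FDR level.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param level Target FDR (the enrichment networks use 0.01).
#' @return List with `adjusted_p` and logical `discovery`.
#' @export
bh_fdr <- function(p, level = 0.01) {
  if (!length(p)) return(list(adjusted_p = numeric(), discovery = logical()))
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted_p = adj, discovery = adj <= level)
}

#' OTU-sample / genotype-binned enrichment hypergraph
#'
#' Bipartite network connecting an OTU to an analysis unit whenever it is
#' significantly over-represented there by a one-sided Fisher exact test
#' after BH FDR control.
#'
#' In `per-sample` mode the analysis matrix is restricted to non-control
#' samples; control samples are analysed as their own separate family, as in
#' the study design. In `binned-by-genotype` mode the columns are summed per
#' genotype within each soil and enrichment + FDR correction run
#' independently per soil; bin node ids are `"<soil>|<genotype>"`. Each mode
#' invocation forms one FDR family per analysed matrix.
#'
#' @param table Counts-scale [otu_table()].
#' @param frame A [sample_frame()] resolving every sample.
#' @param mode `"per-sample"` or `"binned-by-genotype"`.
#' @param level FDR level (default 0.01).
#' @param alternative Passed to [fisher_exact_test()].
#' @return List with `network` (bipartite [rhizo_network()]) and `results`
#'   (data.frame: otu_id, unit_id, soil_id, a, b, c, d, raw_p, adjusted_p,
#'   enriched).
#' @export
build_enrichment_network <- function(table, frame,
                                     mode = c("per-sample",
                                              "binned-by-genotype"),
                                     level = 0.01,
                                     alternative = "greater") {
  mode <- match.arg(mode)
  if (otu_scale(table) != "counts")
    stop("enrichment requires the raw counts table")
  meta <- frame$samples[match(sample_ids(table), frame$samples$sample_id), ]
  if (anyNA(meta$sample_id))
    stop("sample(s) missing from metadata: ",
         paste(sample_ids(table)[is.na(meta$sample_id)], collapse = ", "))
  res_list <- list()
  if (mode == "per-sample") {
    for (ctl in unique(meta$is_control)) {
      sub <- table[, meta$is_control == ctl]
      if (!ncol(sub)) next
      fam <- enrich_family(unclass(sub), alternative, level)
      fam$soil_id <- NA_character_
      res_list[[length(res_list) + 1L]] <- fam
    }
    unit_role <- "sample"
  } else {
    for (soil in unique(meta$soil_id)) {
      cols <- which(meta$soil_id == soil)
      geno <- meta$genotype_id[cols]
      if (length(unique(geno)) < 2L) {
        warning("soil '", soil, "' has a single genotype bin; skipped")
        next
      }
      sub <- unclass(table)[, cols, drop = FALSE]
      binned <- vapply(unique(geno), function(g)
        rowSums(sub[, geno == g, drop = FALSE]), numeric(nrow(sub)))
      binned <- matrix(binned, nrow = nrow(sub),
                       dimnames = list(rownames(sub),
                                       paste(soil, unique(geno), sep = "|")))
      fam <- enrich_family(binned, alternative, level)
      fam$soil_id <- soil
      res_list[[length(res_list) + 1L]] <- fam
    }
    unit_role <- "genotype-bin"
  }
  results <- if (length(res_list)) do.call(rbind, res_list) else
    data.frame(otu_id = character(), unit_id = character(), a = numeric(),
               b = numeric(), c = numeric(), d = numeric(),
               raw_p = numeric(), adjusted_p = numeric(),
               enriched = logical(), soil_id = character())
  units <- unique(results$unit_id)
  nodes <- data.frame(id = c(otu_ids(table), units),
                      role = rep(c("otu", unit_role),
                                 c(nrow(table), length(units))))
  hits <- results[results$enriched, , drop = FALSE]
  edges <- data.frame(from = hits$otu_id, to = hits$unit_id,
                      weight = 1 - hits$adjusted_p,
                      sign = rep("none", nrow(hits)))
  list(network = rhizo_network(nodes, edges, bipartite = TRUE),
       results = results)
}

# One FDR family: every OTU x unit pair of one analysis matrix.
enrich_family <- function(mat, alternative, level) {
  grid <- expand.grid(otu = seq_len(nrow(mat)), unit = seq_len(ncol(mat)))
  a <- mat[cbind(grid$otu, grid$unit)]
  rs <- rowSums(mat); cs <- colSums(mat); tot <- sum(mat)
  b <- rs[grid$otu] - a
  cc <- cs[grid$unit] - a
  d <- tot - a - b - cc
  raw_p <- fisher_exact_test(a, b, cc, d, alternative = alternative)
  fdr <- bh_fdr(raw_p, level)
  data.frame(otu_id = rownames(mat)[grid$otu],
             unit_id = colnames(mat)[grid$unit],
             a = a, b = b, c = cc, d = d, raw_p = raw_p,
             adjusted_p = fdr$adjusted_p, enriched = fdr$discovery,
             row.names = NULL)
}

#' Genotype-specificity quotient selection
#'
#' For every OTU in a per-sample enrichment network, the quotient is its
#' enrichment degree divided by the number of distinct host genotypes its
#' enriched samples span. An OTU is selected as genotype-specific when it is
#' enriched in at most `max_genotypes` genotypes and its quotient is at
#' least `min_quotient` (the study rule: <= 2 genotypes, quotient >= 2).
#' OTUs with no enrichment edges have an undefined quotient and are
#' excluded.
#'
#' @param enrichment_net Per-sample enrichment [rhizo_network()].
#' @param frame A [sample_frame()] mapping samples to genotypes.
#' @param max_genotypes Maximum genotypes spanned (default 2).
#' @param min_quotient Minimum quotient (default 2).
#' @return data.frame: otu_id, degree, n_genotypes, quotient, selected.
#' @export
genotype_quotient_selection <- function(enrichment_net, frame,
                                        max_genotypes = 2L,
                                        min_quotient = 2.0) {
  ed <- enrichment_net$edges
  role <- stats::setNames(enrichment_net$nodes$role, enrichment_net$nodes$id)
  if (!nrow(ed))
    return(data.frame(otu_id = character(), degree = integer(),
                      n_genotypes = integer(), quotient = numeric(),
                      selected = logical()))
  otu <- ifelse(role[ed$from] == "otu", ed$from, ed$to)
  smp <- ifelse(role[ed$from] == "otu", ed$to, ed$from)
  geno <- frame$samples$genotype_id[match(smp, frame$samples$sample_id)]
  if (anyNA(geno)) stop("enriched sample(s) missing from metadata")
  out <- do.call(rbind, lapply(split(seq_along(otu), otu), function(ii) {
    data.frame(otu_id = otu[ii[1L]], degree = length(ii),
               n_genotypes = length(unique(geno[ii])))
  }))
  out$quotient <- out$degree / out$n_genotypes
  out$selected <- out$n_genotypes <= max_genotypes &
    out$quotient >= min_quotient
  out <- out[order(out$otu_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}
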