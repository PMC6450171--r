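#' Hellinger transformation
#'
#' Square root of per-sample relative abundances: each cell becomes
#' `sqrt(x / colsum)`, so every nonzero sample column has unit Euclidean
#' norm. This is the normalisation applied before all multivariate analyses
#' (ordination, PERMANOVA, correlation networks). All-zero columns (failed
#' samples) stay all-zero rather than propagating division by zero.
#'
#' @param table An [otu_table()] with scale `counts` or `relative`.
#' @return An [otu_table()] with `scale = "hellinger"`.
#' @export
hellinger_transform <- function(table) {
  if (!otu_scale(table) %in% c("counts", "relative"))
    stop("hellinger_transform expects counts or relative scale")
  v <- unclass(table)
  cs <- colSums(v)
  cs[cs == 0] <- 1  # all-zero columns stay all-zero
  out <- sqrt(sweep(v, 2L, cs, "/"))
  otu_table(out, marker = otu_marker(table), scale = "hellinger")
}

#' Per-sample relative abundances
#'
#' @param table An [otu_table()] on the counts scale.
#' @return An [otu_table()] with `scale = "relative"`; all-zero columns stay
#'   all-zero.
#' @export
relative_abundance <- function(table) {
  if (otu_scale(table) != "counts")
    stop("relative_abundance expects counts scale")
  v <- unclass(table)
  cs <- colSums(v)
  cs[cs == 0] <- 1
  otu_table(sweep(v, 2L, cs, "/"), marker = otu_marker(table),
            scale = "relative")
}

#' Rank-abundance summary
#'
#' Mean relative abundance of each OTU within sample groups, sorted in
#' decreasing order. Ties are broken by `otu_id` lexicographic order so the
#' ranking is deterministic.
#'
#' @param table An [otu_table()] on the counts scale.
#' @param groups Factor/character grouping of the samples (one entry per
#'   sample column); default puts all samples in one group.
#' @return data.frame with columns `group`, `rank`, `otu_id`,
#'   `mean_relative_abundance`.
#' @export
relative_and_rank_abundance <- function(table, groups = NULL) {
  if (otu_scale(table) != "counts")
    stop("relative_and_rank_abundance expects counts scale")
  if (is.null(groups)) groups <- rep("all", ncol(table))
  groups <- as.character(groups)
  if (length(groups) != ncol(table))
    stop("groups length must match sample count")
  rel <- unclass(relative_abundance(table))
  out <- lapply(unique(groups), function(g) {
    cols <- which(groups == g)
    if (!length(cols)) stop("empty group: ", g)
    m <- rowMeans(rel[, cols, drop = FALSE])
    ord <- order(-m, rownames(rel), method = "radix")
    data.frame(group = g, rank = seq_along(ord), otu_id = rownames(rel)[ord],
               mean_relative_abundance = m[ord], row.names = NULL)
  })
  do.call(rbind, out)
}

#' Drop sparse OTUs
#'
#' Retains exactly the OTUs observed (value > 0) in at least `min_nonzero`
#' samples; the rare-OTU filter applied before co-occurrence network
#' construction. Sample columns are untouched.
#'
#' @param table An [otu_table()].
#' @param min_nonzero Minimum number of samples with a positive value
#'   (default 3).
#' @return Filtered [otu_table()]; may have zero rows.
#' @export
filter_min_occurrence <- function(table, min_nonzero = 3L) {
  if (min_nonzero < 1L) stop("min_nonzero must be >= 1")
  keep <- rowSums(unclass(table) > 0) >= min_nonzero
  table[keep, ]
}

#' Expected rarefaction richness
#'
#' Analytic expectation of the number of OTUs observed in a random
#' subsample of `d` reads drawn without replacement from one sample:
#' `E[S(d)] = sum_i (1 - choose(N - n_i, d) / choose(N, d))`. Delegates to
#' [vegan::rarefy()].
#'
#' @param counts Integer read counts of one sample (one OTU table column).
#' @param depths Integer subsampling depths, each at most `sum(counts)`.
#' @return Numeric vector of expected richness per depth (monotone
#'   non-decreasing).
#' @export
rarefaction_expected_richness <- function(counts, depths) {
  counts <- as.numeric(counts)
  if (any(counts != round(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  depths <- as.numeric(depths)
  if (any(depths < 0) || any(depths != round(depths)))
    stop("depths must be non-negative integers")
  if (any(depths > sum(counts)))
    stop("depth exceeds sample total (", sum(counts), ")")
  out <- vapply(depths, function(d) {
    if (d == 0) return(0)
    as.numeric(suppressWarnings(
      vegan::rarefy(matrix(counts, nrow = 1L), sample = d)))
  }, 0)
  out
}
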