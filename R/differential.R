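#' Variance-stabilising transform for differential analysis
#'
#' Drops OTUs observed in fewer than `min_samples` samples (bias control
#' for rare OTUs), then applies `log2(x + 1)`; the unit pseudocount is
#' needed because OTU tables contain zeros. Order of values within each OTU
#' is preserved.
#'
#' @param table Counts-scale [otu_table()].
#' @param min_samples Minimum positive samples per OTU (default 3).
#' @return Plain numeric matrix of log2 abundances.
#' @export
variance_stabilize <- function(table, min_samples = 3L) {
  if (otu_scale(table) != "counts")
    stop("variance_stabilize expects counts scale")
  kept <- filter_min_occurrence(table, min_samples)
  log2(unclass(kept) + 1)
}

#' Quantile normalisation
#'
#' Forces every sample column onto a common reference distribution (the
#' mean of the per-column order statistics); ties receive the average of
#' their reference span. Delegates to [limma::normalizeQuantiles()]. After
#' normalisation all columns share identical sorted values, removing
#' between-replicate noise while keeping within-sample ranking.
#'
#' @param m Numeric matrix (rows OTUs, columns samples), >= 2 columns.
#' @return Normalised matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) {
    warning("single column: quantile normalisation is the identity")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Fold-change rank-order statistic (FCROS)
#'
#' Differential relative abundance between two sample classes. For each of
#' the `n_a * n_b` cross-class sample pairs the per-OTU fold change
#' (difference on the log scale) is computed and OTUs are ranked within the
#' pair (ascending, average ranks for ties). Ranks are normalised to (0, 1)
#' by dividing by `m + 1` (m = number of OTUs) and averaged per OTU with a
#' trimmed mean (the published statistic trims the extreme pair ranks,
#' which robustifies against single aberrant replicates); the
#' f-value is the standard normal CDF of the standardised average rank, an
#' estimate of the probability of over-abundance in class B relative to
#' class A. The two-sided p-value is `2 * min(f, 1 - f)`.
#'
#' @param m Numeric matrix of normalised log abundances (rows OTUs).
#' @param class_a,class_b Column ids or indices of the two classes (>= 2
#'   samples each).
#' @param trim Fraction of pair ranks trimmed from each tail before
#'   averaging (default 0.25; 0 gives the plain mean).
#' @return data.frame of class `differential_result`: otu_id, ri (average
#'   normalised rank), f_value, p_value, median_log_fc.
#' @export
fcros_statistic <- function(m, class_a, class_b, trim = 0.25) {
  m <- as.matrix(m)
  if (nrow(m) < 5L) stop("rank statistic degenerate below 5 OTUs")
  a <- if (is.character(class_a)) match(class_a, colnames(m)) else class_a
  b <- if (is.character(class_b)) match(class_b, colnames(m)) else class_b
  if (anyNA(a) || anyNA(b)) stop("unknown class sample(s)")
  if (length(a) < 2L || length(b) < 2L)
    stop("both classes need at least 2 samples")
  n_otu <- nrow(m)
  pairs <- expand.grid(a = a, b = b)
  rk <- matrix(0, n_otu, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    fc <- m[, pairs$b[p]] - m[, pairs$a[p]]
    rk[, p] <- rank(fc, ties.method = "average")
  }
  ri <- apply(rk, 1L, mean, trim = trim) / (n_otu + 1)
  # robust normal approximation: centre and scale from the bulk of the
  # average-rank distribution so genuinely changed OTUs do not inflate the
  # null scale estimate
  sc <- stats::mad(ri)
  if (sc == 0) sc <- stats::sd(ri)
  zz <- (ri - stats::median(ri)) / sc
  f <- stats::pnorm(zz)
  medfc <- apply(m[, b, drop = FALSE], 1L, stats::median) -
    apply(m[, a, drop = FALSE], 1L, stats::median)
  out <- data.frame(otu_id = rownames(m) %||% paste0("otu", seq_len(n_otu)),
                    ri = ri, f_value = f,
                    p_value = 2 * pmin(f, 1 - f),
                    median_log_fc = medfc, row.names = NULL)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Select differentially abundant OTUs
#'
#' Flags an OTU as over-abundant (in class B) when `p <= alpha` and
#' `f >= f_threshold`, and under-abundant when `p <= alpha` and
#' `f <= 1 - f_threshold` (the symmetric reading of the study's
#' "probability of over/under abundance greater than 0.9").
#'
#' @param results A `differential_result` from [fcros_statistic()].
#' @param alpha p-value threshold (default 0.05).
#' @param f_threshold f-value threshold (default 0.9).
#' @return The input with a `flagged` column (`"over"`, `"under"`,
#'   `"none"`).
#' @export
select_differential <- function(results, alpha = 0.05, f_threshold = 0.9) {
  flagged <- rep("none", nrow(results))
  flagged[results$p_value <= alpha & results$f_value >= f_threshold] <- "over"
  flagged[results$p_value <= alpha &
            results$f_value <= 1 - f_threshold] <- "under"
  results$flagged <- flagged
  results
}

#' Full differential-abundance pipeline between two classes
#'
#' Rare-OTU filter, log2 transform, quantile normalisation, FCROS and
#' thresholding in one call.
#'
#' @inheritParams fcros_statistic
#' @param table Counts-scale [otu_table()].
#' @param min_samples Rare-OTU filter (default 3).
#' @param alpha,f_threshold Selection thresholds (defaults 0.05, 0.9).
#' @return A flagged `differential_result`.
#' @export
differential_abundance <- function(table, class_a, class_b, min_samples = 3L,
                                   alpha = 0.05, f_threshold = 0.9) {
  vs <- variance_stabilize(table, min_samples)
  qn <- quantile_normalize(vs[, c(class_a, class_b), drop = FALSE])
  res <- fcros_statistic(qn, class_a, class_b)
  select_differential(res, alpha = alpha, f_threshold = f_threshold)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
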