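#' Bray-Curtis dissimilarity between samples
#'
#' `BC(p, q) = sum |p_i - q_i| / sum (p_i + q_i)` over OTUs, computed with
#' [vegan::vegdist()]. A pair of all-zero samples has no shared material;
#' their distance is defined as 0 and flagged in the `"empty"` attribute.
#'
#' @param table An [otu_table()] (typically Hellinger-transformed).
#' @return A `dist` object over the samples.
#' @export
bray_curtis_matrix <- function(table) {
  v <- t(unclass(table))
  empty <- rownames(v)[rowSums(v) == 0]
  d <- suppressWarnings(vegan::vegdist(v, method = "bray"))
  m <- as.matrix(d)
  if (length(empty)) {
    m[!is.finite(m)] <- 0
    ee <- rownames(v) %in% empty
    m[ee, ee] <- 0
    m[ee, !ee] <- 1
    m[!ee, ee] <- 1
    diag(m) <- 0
  }
  out <- stats::as.dist(m)
  attr(out, "empty") <- empty
  out
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of the squared distance matrix followed by
#' eigendecomposition. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; negative eigenvalues are reported
#' but their axes dropped. Axis orientation is made deterministic by
#' flipping each axis so its largest-magnitude loading is positive.
#'
#' @param d A `dist` or symmetric zero-diagonal matrix.
#' @param k Number of axes requested (truncated with a warning if fewer
#'   positive eigenvalues exist).
#' @return List with `coordinates` (n x k' matrix), `eigenvalues` (all n),
#'   `relative_eig` (share of the positive eigenvalue total).
#' @export
pcoa <- function(d, k = 2L) {
  m <- as.matrix(d)
  n <- nrow(m)
  a <- -0.5 * m^2
  g <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
  eig <- eigen(g, symmetric = TRUE)
  pos <- eig$values > 1e-9 * max(abs(eig$values), 1)
  npos <- sum(pos)
  if (k > npos) {
    warning("only ", npos, " positive eigenvalue(s); truncating axes")
    k <- npos
  }
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k, k)
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(m)
  colnames(coords) <- if (k) paste0("PCo", seq_len(k)) else character()
  list(coordinates = coords, eigenvalues = eig$values,
       relative_eig = if (npos) eig$values[seq_len(npos)] /
         sum(eig$values[pos]) else numeric())
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (pseudo-F from distance-based sums of squares, permutation p-value),
#' computed with [vegan::adonis2()]. Only single-factor designs are
#' exposed; the study tested factors separately after finding no
#' significant interactions.
#'
#' @param d A `dist` over samples.
#' @param groups Grouping vector (>= 2 groups, each >= 2 members).
#' @param n_permutations Number of label permutations (the study uses
#'   9999).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `permanova_result`: `pseudo_F`, `R_squared`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 9999L, seed = 1L) {
  groups <- as.factor(groups)
  check_groups(groups)
  df <- data.frame(g = groups)
  set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(d) ~ g, data = df,
                        permutations = n_permutations)
  structure(list(pseudo_F = fit$F[1L], R_squared = fit$R2[1L],
                 p_value = fit$`Pr(>F)`[1L],
                 n_permutations = n_permutations, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Distances of samples to their group centroid in principal-coordinate
#' space (contributions of negative axes subtracted from the squared
#' distances, as in Anderson's dispersion test), followed by a one-way
#' ANOVA F on those distances. The p-value permutes the group labels and
#' recomputes centroids and distances in full for every permutation, which
#' makes the test exact under exchangeability; schemes that only permute
#' the observed residual distances are anticonservative at the small group
#' sizes typical of trap-plant designs. Observed distances agree with
#' [vegan::betadisper()] (`type = "centroid"`).
#'
#' @inheritParams permanova
#' @return List of class `permdisp_result`: `F`, `p_value`,
#'   `group_dispersion` (named mean distance-to-centroid), `distances`,
#'   plus the permutation settings.
#' @export
permdisp <- function(d, groups, n_permutations = 999L, seed = 1L) {
  groups <- as.factor(groups)
  check_groups(groups)
  m <- as.matrix(d)
  n <- nrow(m)
  a <- -0.5 * m^2
  g <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
  eig <- eigen(g, symmetric = TRUE)
  keep <- abs(eig$values) > 1e-10 * max(abs(eig$values), 1)
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(abs(eig$values[keep])), sum(keep))
  axis_sign <- sign(eig$values[keep])
  dispersion_F <- function(gi) {
    dd <- permdisp_distances(coords, axis_sign, gi)
    grand <- mean(dd)
    k <- length(unique(gi))
    ssb <- sum(tapply(dd, gi, function(x) length(x) * (mean(x) - grand)^2))
    ssw <- sum((dd - stats::ave(dd, gi))^2)
    list(F = (ssb / (k - 1)) / (ssw / (n - k)), distances = dd)
  }
  obs <- dispersion_F(groups)
  set.seed(seed)
  exceed <- 1L
  for (b in seq_len(n_permutations)) {
    pf <- dispersion_F(sample(groups))$F
    if (pf >= obs$F - 1e-12) exceed <- exceed + 1L
  }
  structure(list(F = obs$F, p_value = exceed / (n_permutations + 1),
                 group_dispersion = tapply(obs$distances, groups, mean),
                 distances = stats::setNames(obs$distances, rownames(m)),
                 n_permutations = n_permutations, seed = seed),
            class = "permdisp_result")
}

# distance to group centroid with imaginary (negative-eigenvalue) axes:
# squared real-part distance minus squared imaginary-part distance
permdisp_distances <- function(coords, axis_sign, gi) {
  cent <- apply(coords, 2L, function(col) stats::ave(col, gi))
  dev2 <- (coords - cent)^2
  sq <- as.numeric(dev2 %*% axis_sign)
  sqrt(pmax(sq, 0))
}

check_groups <- function(groups) {
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("group(s) with a single member: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  invisible(TRUE)
}

#' Indicator-species analysis with site-group combinations
#'
#' IndVal-style association of each OTU with each group of samples and,
#' when `allow_combinations` is on, each non-trivial union of groups.
#' Specificity `A` is the summed mean abundance over the target's member
#' groups divided by the sum over all base groups of the group mean
#' abundance (for a singleton target this is the usual group-mean share);
#' fidelity `B` is
#' the fraction of target samples where the OTU is present; the statistic
#' is `sqrt(A * B)`, maximised over candidate targets. Significance comes
#' from permuting sample group labels and counting permuted best statistics
#' at least as large as the observed one, followed by BH FDR correction
#' across OTUs.
#'
#' @param table An [otu_table()] or abundance matrix (rows OTUs).
#' @param groups Grouping vector over samples.
#' @param allow_combinations Also score unions of groups (up to
#'   `max_order` groups per union).
#' @param max_order Largest union size considered (default `k - 1`).
#' @param n_permutations Label permutations (default 999).
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return data.frame of class `indicator_result`: otu_id, best_target,
#'   A, B, stat, p_value, adjusted_p, significant. OTUs absent everywhere
#'   are skipped.
#' @export
indicator_analysis <- function(table, groups, allow_combinations = TRUE,
                               max_order = NULL, n_permutations = 999L,
                               alpha = 0.05, seed = 1L) {
  v <- unclass(table)
  groups <- as.character(groups)
  if (length(groups) != ncol(v)) stop("groups length must match sample count")
  keep <- rowSums(v) > 0
  v <- v[keep, , drop = FALSE]
  if (!nrow(v))
    stop("no OTU present anywhere")
  glev <- sort(unique(groups))
  k <- length(glev)
  if (k < 2L) stop("need at least 2 groups")
  if (is.null(max_order)) max_order <- if (allow_combinations) k - 1L else 1L
  combos <- indicator_combinations(glev, allow_combinations, max_order)
  cmat <- vapply(combos, function(cc) glev %in% cc, logical(k))  # k x C
  obs <- indval_stats(v, groups, glev, cmat)
  best <- max.col(obs, ties.method = "first")
  obs_best <- obs[cbind(seq_len(nrow(v)), best)]
  set.seed(seed)
  exceed <- rep(1L, nrow(v))
  for (b in seq_len(n_permutations)) {
    pg <- sample(groups)
    pstat <- indval_stats(v, pg, glev, cmat)
    pbest <- pstat[cbind(seq_len(nrow(v)), max.col(pstat, ties.method = "first"))]
    exceed <- exceed + (pbest >= obs_best - 1e-12)
  }
  p <- exceed / (n_permutations + 1)
  ab <- indval_components(v, groups, glev, cmat)
  adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(otu_id = rownames(v) %||% paste0("otu", seq_len(nrow(v))),
                    best_target = vapply(combos[best], paste, "",
                                         collapse = "+"),
                    A = ab$A[cbind(seq_len(nrow(v)), best)],
                    B = ab$B[cbind(seq_len(nrow(v)), best)],
                    stat = obs_best, p_value = p, adjusted_p = adj,
                    significant = adj <= alpha, row.names = NULL)
  class(out) <- c("indicator_result", "data.frame")
  out
}

indicator_combinations <- function(glev, allow_combinations, max_order) {
  if (!allow_combinations) return(as.list(glev))
  out <- list()
  for (ord in seq_len(min(max_order, length(glev) - 1L)))
    out <- c(out, utils::combn(glev, ord, simplify = FALSE))
  out
}

# stat matrix (OTUs x combos); vectorised: group means via matrix product.
# A(T) = sum_{g in T} mean_g / sum_all mean_g; B(T) = presence fraction in T.
indval_stats <- function(v, groups, glev, cmat) {
  ab <- indval_components(v, groups, glev, cmat)
  sqrt(pmax(ab$A, 0) * ab$B)
}

indval_components <- function(v, groups, glev, cmat) {
  gi <- match(groups, glev)
  ind <- matrix(0, ncol(v), length(glev))
  ind[cbind(seq_len(ncol(v)), gi)] <- 1
  nper <- colSums(ind)
  gmean <- (v %*% ind) / rep(nper, each = nrow(v))      # OTUs x k
  gpres <- ((v > 0) %*% ind)                            # presence counts
  target_n <- as.numeric(nper %*% cmat)                 # samples per combo
  # specificity numerator: sum of member-group means (IndVal convention for
  # group unions; reduces to the group mean for singleton targets)
  denom <- rowSums(gmean)
  a <- sweep(gmean %*% cmat, 1L, ifelse(denom > 0, denom, 1), "/")
  b <- sweep(gpres %*% cmat, 2L, target_n, "/")
  list(A = a, B = b)
}

#' Chi-square test of OTU detection counts
#'
#' Pearson chi-square on a contingency table of the number of OTUs detected
#' per group (e.g., per genotype or per soil), via [stats::chisq.test()]
#' without continuity correction. A single-row table is tested as goodness
#' of fit against a uniform distribution. Warns when any expected cell is
#' below 1 (an exact test would be preferable there).
#'
#' @param counts Matrix or vector of detection counts.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_detection <- function(counts) {
  m <- as.matrix(counts)
  if (nrow(m) == 1L || ncol(m) == 1L) {
    x <- as.numeric(m)
    fit <- suppressWarnings(stats::chisq.test(x))
  } else {
    fit <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  }
  if (any(fit$expected < 1))
    warning("expected count(s) below 1; consider an exact test")
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value, expected = fit$expected)
}

#' Count OTUs detected per sample group
#'
#' Helper building the detection contingency for
#' [chi_square_detection()]: number of distinct OTUs with a positive value
#' in each group.
#'
#' @param table An [otu_table()].
#' @param groups Grouping vector over samples.
#' @return Named integer vector of detected-OTU counts.
#' @export
detection_counts <- function(table, groups) {
  v <- unclass(table)
  groups <- as.character(groups)
  vapply(sort(unique(groups)), function(g)
    sum(rowSums(v[, groups == g, drop = FALSE] > 0) > 0), 0L)
}
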