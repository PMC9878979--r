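# Label-free differential-abundance engine: lower-tail imputation of
# left-censored intensities, log2 + quantile normalization, per-feature
# two-group Gaussian linear model with an ANOVA contrast against the null
# model, Benjamini-Hochberg correction and volcano-style significance calls.
# The same engine is applied to log-scale transcriptomic matrices.

#' Impute missing intensities from the lower tail
#'
#' Missing cells are assumed left-censored (too faint to be observed): each is
#' replaced by a uniformly random draw from the multiset of observed
#' intensities at or below the pooled 5th percentile of the whole matrix —
#' the "overall distribution of protein intensities in all samples", not a
#' per-sample pool. Observed cells are untouched. Features with no observed
#' value at all receive fully imputed rows and are flagged in the
#' `all_missing` attribute.
#'
#' @param mat numeric matrix of raw intensities, NA = missing.
#' @param impute_quantile pooled quantile bounding the donor pool (default
#'   0.05, the bottom five percentiles).
#' @param seed integer seed for the random draws.
#' @return the completed matrix, with attributes `imputed` (logical mask) and
#'   `all_missing` (character vector of fully imputed feature ids).
#' @export
impute_lower_tail <- function(mat, impute_quantile = 0.05, seed = 1L) {
  stopifnot(is.matrix(mat), length(mat) > 0)
  obs <- mat[!is.na(mat)]
  if (length(obs) == 0) stop("matrix has no observed values")
  miss <- is.na(mat)
  if (!any(miss)) {
    attr(mat, "imputed") <- miss
    attr(mat, "all_missing") <- character(0)
    return(mat)
  }
  cutoff <- stats::quantile(obs, impute_quantile, names = FALSE, type = 7)
  pool <- obs[obs <= cutoff]
  out <- mat
  out[miss] <- with_seed(seed, pool[sample.int(length(pool), sum(miss),
                                               replace = TRUE)])
  attr(out, "imputed") <- miss
  attr(out, "all_missing") <- rownames(mat)[rowSums(!miss) == 0] %||% character(0)
  out
}

#' Log2 transform and quantile normalize
#'
#' Applies `log2` to every cell, then classical quantile normalization: the
#' value of rank r in each sample is replaced by the across-sample mean of
#' the rank-r values, so every column shares one empirical distribution. Tied
#' values within a column receive the mean of the reference values at the
#' positions they jointly occupy.
#'
#' @param mat complete positive numeric matrix (post-imputation).
#' @return the normalized log2 matrix.
#' @export
log2_quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) stop("matrix must be complete (impute first)")
  if (any(mat <= 0)) stop("non-positive intensity encountered")
  quantile_normalize(log2(mat))
}

# classical quantile normalization of a complete matrix; ties within a column
# receive the mean of the reference values at their joint positions
quantile_normalize <- function(l) {
  ref <- rowMeans(apply(l, 2, sort))
  out <- l
  for (j in seq_len(ncol(l))) {
    o <- order(l[, j])
    xs <- l[o, j]
    grp <- cumsum(c(TRUE, diff(xs) != 0))
    out[o, j] <- stats::ave(ref, grp)
  }
  out
}

#' Per-feature two-group differential expression
#'
#' For each feature, fits the Gaussian linear model with a group mean per
#' level and the intercept-only null model; the ANOVA contrast between the
#' two yields an F statistic on (1, n - 2) degrees of freedom (identically
#' the squared pooled-variance t statistic in the two-group case). The log2
#' fold change is the second group's mean minus the first's, on the
#' normalized log2 scale.
#'
#' @param mat normalized log2 matrix (features x samples).
#' @param groups factor or vector of two group labels, one per column; the
#'   first level is the reference.
#' @return data.frame with `feature`, `log2fc`, `F`, `p_raw`; features with
#'   zero residual variance get `p_raw = NA` and are listed in the
#'   `zero_variance` attribute.
#' @export
fit_de <- function(mat, groups) {
  stopifnot(is.matrix(mat), ncol(mat) == length(groups))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2); n <- n1 + n2
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  ss1 <- rowSums((mat[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, g2, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / (n - 2)                     # pooled residual variance
  fstat <- (m2 - m1)^2 / (s2 * (1 / n1 + 1 / n2)) # = t^2
  p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  zero <- s2 <= 0
  fstat[zero & (m2 == m1)] <- 0
  p[zero] <- NA_real_
  p[zero & (m2 == m1)] <- 1   # flat feature: no evidence either way
  res <- data.frame(feature = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                    log2fc = unname(m2 - m1), F = unname(fstat),
                    p_raw = unname(p), stringsAsFactors = FALSE)
  attr(res, "zero_variance") <- res$feature[zero]
  attr(res, "contrast") <- paste(levels(groups)[2], "vs", levels(groups)[1])
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p values (capped at 1,
#' monotone in the sorted order). NA p values are preserved.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return the adjusted p values.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Flag significant features
#'
#' A feature is significant iff its BH-adjusted p value is strictly below
#' `alpha` and its absolute log2 fold change strictly exceeds `lfc`.
#'
#' @param de data.frame with `log2fc` and `p_adj` (or `p_raw` to adjust here).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 1).
#' @return `de` with columns `p_adj` and `significant`.
#' @export
call_significant <- function(de, alpha = 0.05, lfc = 1) {
  if (is.null(de$p_adj)) de$p_adj <- adjust_bh(de$p_raw)
  de$significant <- !is.na(de$p_adj) & de$p_adj < alpha & abs(de$log2fc) > lfc
  de
}

#' Run the full differential-abundance pipeline
#'
#' Imputation (optional) -> log2 + quantile normalization -> per-feature
#' Gaussian linear model -> BH adjustment -> significance calls. Set
#' `log_transform = FALSE` for matrices already on the log scale (e.g. a
#' transcriptomic log2 abundance matrix), in which case imputation is skipped
#' and quantile normalization is applied directly.
#'
#' @param mat raw intensity matrix (NA = missing), or a log-scale matrix with
#'   `log_transform = FALSE`.
#' @param groups two-group labels, one per column.
#' @param alpha,lfc significance thresholds (see [call_significant()]).
#' @param impute_quantile donor-pool quantile for [impute_lower_tail()].
#' @param seed seed for the imputation draws.
#' @param log_transform if FALSE, `mat` is taken as already log scale.
#' @return data.frame of per-feature results: `feature`, `log2fc`, `F`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
run_de <- function(mat, groups, alpha = 0.05, lfc = 1,
                   impute_quantile = 0.05, seed = 1L, log_transform = TRUE) {
  if (log_transform) {
    full <- impute_lower_tail(mat, impute_quantile, seed)
    norm <- log2_quantile_normalize(full)
  } else {
    if (anyNA(mat)) stop("log-scale input must be complete")
    norm <- quantile_normalize(mat)
  }
  de <- fit_de(norm, groups)
  call_significant(de, alpha = alpha, lfc = lfc)
}
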