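# Spectral-count comparison of immunoglobulin heavy/light-chain families
# between two groups: presence filtering on unique peptides, Poisson and
# quasi-Poisson (quasi-likelihood) tests with per-sample total-spectra
# offsets, and dual-FDR reporting.

#' Filter chain families by peptide-level presence
#'
#' A family is "present" in a sample when it has at least
#' `min_unique_peptides` unique peptide identifications there. Families
#' present in no sample are dropped; families present in only one group are
#' flagged `exclusive_to_group` and reported descriptively rather than
#' tested.
#'
#' @param counts families x samples integer matrix of spectral counts.
#' @param unique_peptides matrix of the same shape with unique-peptide counts.
#' @param groups two-group labels, one per sample.
#' @param min_unique_peptides presence threshold (>= 1).
#' @return list with `counts` (retained rows), `exclusive_to_group` (named
#'   character: family -> group label, for one-group families).
#' @export
filter_present <- function(counts, unique_peptides, groups,
                           min_unique_peptides = 2L) {
  stopifnot(identical(dim(counts), dim(unique_peptides)))
  if (min_unique_peptides < 1) stop("presence threshold must be >= 1")
  groups <- droplevels(as.factor(groups))
  present <- unique_peptides >= min_unique_peptides
  keep <- rowSums(present) > 0
  counts <- counts[keep, , drop = FALSE]
  present <- present[keep, , drop = FALSE]
  lv <- levels(groups)
  in1 <- rowSums(present[, groups == lv[1], drop = FALSE]) > 0
  in2 <- rowSums(present[, groups == lv[2], drop = FALSE]) > 0
  excl <- c(stats::setNames(rep(lv[1], sum(in1 & !in2)), rownames(counts)[in1 & !in2]),
            stats::setNames(rep(lv[2], sum(!in1 & in2)), rownames(counts)[!in1 & in2]))
  list(counts = counts, exclusive_to_group = excl)
}

# per-family GLM fits shared by both tracks; returns coefficient (log rate
# ratio group2 vs group1), LR statistic, and Pearson dispersion of the group
# model
fit_count_models <- function(y, totals, groups) {
  g <- droplevels(as.factor(groups))
  off <- log(totals)
  fit1 <- stats::glm(y ~ g + offset(off), family = stats::poisson())
  fit0 <- stats::glm(y ~ 1 + offset(off), family = stats::poisson())
  phi <- sum(stats::residuals(fit1, type = "pearson")^2) / fit1$df.residual
  list(lr = fit0$deviance - fit1$deviance,
       coef = unname(stats::coef(fit1)[2]),
       phi = phi, df_resid = fit1$df.residual)
}

#' Poisson test of group effect on spectral counts
#'
#' Per family, a Poisson log-linear model of counts with a log(total spectra)
#' offset and a group term is compared to the intercept-only model by a
#' likelihood-ratio chi-square test on 1 degree of freedom.
#'
#' @param counts families x samples integer matrix.
#' @param totals per-sample total matched spectra (offset).
#' @param groups two-group labels.
#' @return data.frame `family`, `log2_ratio` (group2 vs group1 normalized
#'   rates), `p_poisson`; all-zero families get `p = 1` and `log2_ratio = NA`.
#' @export
poisson_test <- function(counts, totals, groups) {
  stopifnot(ncol(counts) == length(totals), ncol(counts) == length(groups))
  if (any(totals <= 0)) stop("totals must be positive")
  res <- t(apply(counts, 1, function(y) {
    if (sum(y) == 0) return(c(NA_real_, 1))
    f <- fit_count_models(y, totals, groups)
    c(f$coef / log(2), stats::pchisq(max(f$lr, 0), 1, lower.tail = FALSE))
  }))
  data.frame(family = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             log2_ratio = res[, 1], p_poisson = res[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quasi-likelihood test of group effect on spectral counts
#'
#' The same mean model as [poisson_test()], but under a quasi-Poisson working
#' model: the deviance drop of the group term is scaled by the
#' Pearson-residual dispersion and referred to an F distribution. Per-family
#' dispersions estimated on n - 2 residual degrees of freedom are noisy, so
#' by default they are moderated across families by empirical-Bayes
#' squeezing (`limma::squeezeVar`), the approach of quasi-likelihood F-tests
#' for count data; the F denominator degrees of freedom are the residual
#' plus prior degrees of freedom. With dispersion near 1 the two tracks
#' agree; with real overdispersion the quasi track is the more stringent one.
#'
#' @inheritParams poisson_test
#' @param moderate moderate per-family dispersions across families
#'   (recommended; requires >= 3 testable families to take effect).
#' @return data.frame `family`, `log2_ratio`, `p_quasi`, `dispersion` (the
#'   moderated dispersion actually used).
#' @export
quasi_likelihood_test <- function(counts, totals, groups, moderate = TRUE) {
  g <- droplevels(as.factor(groups))
  if (any(table(g) < 2)) stop("need >= 2 samples per group to estimate dispersion")
  df_resid <- length(g) - 2L
  if (df_resid <= 0) stop("no residual degrees of freedom")
  n <- nrow(counts)
  lr <- coef <- phi <- rep(NA_real_, n)
  nonzero <- rowSums(counts) > 0
  for (i in which(nonzero)) {
    f <- fit_count_models(counts[i, ], totals, g)
    lr[i] <- max(f$lr, 0); coef[i] <- f$coef; phi[i] <- f$phi
  }
  phi_use <- phi
  df_den <- rep(as.numeric(df_resid), n)
  ok <- nonzero & is.finite(phi) & phi > 0
  if (moderate && sum(ok) >= 3) {
    sq <- limma::squeezeVar(phi[ok], df = df_resid)
    phi_use[ok] <- sq$var.post
    df_prior <- if (is.finite(sq$df.prior)) sq$df.prior else Inf
    df_den[ok] <- df_resid + df_prior
    # families without an estimable dispersion borrow the prior
    borrow <- nonzero & !ok
    phi_use[borrow] <- if (is.finite(sq$var.prior)) sq$var.prior else mean(phi[ok])
    df_den[borrow] <- df_resid + df_prior
  }
  p <- rep(NA_real_, n)
  p[rowSums(counts) == 0] <- 1
  for (i in which(nonzero)) {
    if (lr[i] <= 1e-12) { p[i] <- 1; next }
    if (!is.finite(phi_use[i]) || phi_use[i] <= 0) next
    p[i] <- stats::pf(lr[i] / phi_use[i], 1, df_den[i], lower.tail = FALSE)
  }
  data.frame(family = rownames(counts) %||% as.character(seq_len(n)),
             log2_ratio = coef / log(2), p_quasi = p, dispersion = phi_use,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Immunoglobulin spectral-count summary with dual FDR tracks
#'
#' Runs presence filtering, then the Poisson and quasi-likelihood tests on
#' families present in both groups; BH-adjusts each track separately. A
#' family is called differentially expressed when its quasi-track adjusted p
#' is below `alpha`; families passing only the Poisson track are reported as
#' `poisson_only` (the trend-level calls). One-group families carry their
#' `exclusive_to_group` label with no test.
#'
#' @param counts families x samples integer matrix.
#' @param totals per-sample total matched spectra.
#' @param groups two-group labels.
#' @param unique_peptides optional presence matrix; if NULL every family with
#'   a positive count is considered present.
#' @param alpha adjusted-p threshold.
#' @param min_unique_peptides presence threshold.
#' @return data.frame: `family`, `log2_ratio`, `p_poisson`, `p_quasi`,
#'   `fdr_poisson`, `fdr_quasi`, `exclusive_to_group`, `poisson_only`,
#'   `differential`.
#' @export
summarize_ig <- function(counts, totals, groups, unique_peptides = NULL,
                         alpha = 0.05, min_unique_peptides = 2L) {
  if (is.null(unique_peptides))
    unique_peptides <- matrix(2L * (counts > 0), nrow(counts),
                              dimnames = dimnames(counts))
  flt <- filter_present(counts, unique_peptides, groups, min_unique_peptides)
  counts <- flt$counts
  if (nrow(counts) == 0)
    return(data.frame(family = character(0), log2_ratio = numeric(0),
                      p_poisson = numeric(0), p_quasi = numeric(0),
                      fdr_poisson = numeric(0), fdr_quasi = numeric(0),
                      exclusive_to_group = character(0),
                      poisson_only = logical(0), differential = logical(0)))
  fam <- rownames(counts)
  excl <- flt$exclusive_to_group
  testable <- !(fam %in% names(excl))
  pois <- poisson_test(counts[testable, , drop = FALSE], totals, groups)
  quasi <- quasi_likelihood_test(counts[testable, , drop = FALSE], totals, groups)
  out <- data.frame(family = fam,
                    log2_ratio = NA_real_, p_poisson = NA_real_,
                    p_quasi = NA_real_, fdr_poisson = NA_real_,
                    fdr_quasi = NA_real_,
                    exclusive_to_group = unname(excl[fam]),
                    stringsAsFactors = FALSE)
  idx <- match(pois$family, out$family)
  out$log2_ratio[idx] <- pois$log2_ratio
  out$p_poisson[idx] <- pois$p_poisson
  out$p_quasi[idx] <- quasi$p_quasi
  out$fdr_poisson[idx] <- adjust_bh(pois$p_poisson)
  out$fdr_quasi[idx] <- adjust_bh(quasi$p_quasi)
  out$poisson_only <- !is.na(out$fdr_poisson) & out$fdr_poisson < alpha &
    (is.na(out$fdr_quasi) | out$fdr_quasi >= alpha)
  out$differential <- !is.na(out$fdr_quasi) & out$fdr_quasi < alpha
  out
}
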