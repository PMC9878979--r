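#' Parameters for synthetic omics datasets
#'
#' Settings for the intensity-matrix, count-table and paired proteome /
#' transcriptome generators. The intensity model is log-normal: each feature
#' has a baseline log2 mean drawn from `Normal(base_log2_mean, base_log2_sd)`,
#' cells add `Normal(0, noise_sd)` replicate noise, and a planted fraction of
#' features is shifted by `effect_log2fc` (random sign) in the second group.
#' Missingness is intensity-dependent (left-censored / MNAR): a cell goes
#' missing with probability `plogis((t - x) / censor_scale)` where the
#' threshold `t` is solved so the expected missing fraction equals
#' `censor_quantile`. Counts are negative-binomial with per-sample total
#' offsets and variance `dispersion * mean` (`dispersion = 1` is Poisson).
#'
#' @param n_features number of proteins / genes / chain families.
#' @param n_per_group samples per group (two groups).
#' @param frac_affected fraction of features with a planted effect, in \[0,1\].
#' @param effect_log2fc planted absolute log2 fold change.
#' @param base_log2_mean,base_log2_sd mean and SD of feature baseline log2
#'   intensities.
#' @param noise_sd within-feature (replicate) SD on the log2 scale.
#' @param censor_quantile target overall missing fraction in \[0,1); 0 disables
#'   censoring.
#' @param censor_scale softness of the logistic censoring curve, log2 units.
#' @param dispersion count variance inflation, >= 1.
#' @param total_counts_per_sample expected total matched spectra per sample.
#' @param group_labels length-2 character; effects are planted in the second.
#' @param seed integer seed.
#' @return an object of class `omics_params`.
#' @export
omics_params <- function(n_features = 2000L, n_per_group = 10L,
                         frac_affected = 0.05, effect_log2fc = 2,
                         base_log2_mean = 20, base_log2_sd = 2,
                         noise_sd = 0.5,
                         censor_quantile = 0.1, censor_scale = 0.5,
                         dispersion = 3, total_counts_per_sample = 50000L,
                         group_labels = c("iNM", "SLONM"),
                         seed = 1L) {
  stopifnot(n_features >= 1, n_per_group >= 1,
            frac_affected >= 0, frac_affected <= 1,
            censor_quantile >= 0, censor_quantile < 1,
            censor_scale > 0, dispersion >= 1,
            total_counts_per_sample > 0,
            length(group_labels) == 2, !anyDuplicated(group_labels))
  structure(list(n_features = as.integer(n_features),
                 n_per_group = as.integer(n_per_group),
                 frac_affected = frac_affected, effect_log2fc = effect_log2fc,
                 base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
                 noise_sd = noise_sd,
                 censor_quantile = censor_quantile, censor_scale = censor_scale,
                 dispersion = dispersion,
                 total_counts_per_sample = as.integer(total_counts_per_sample),
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "omics_params")
}

feature_ids <- function(n, prefix = "FEAT") sprintf("%s%05d", prefix, seq_len(n))

omics_groups <- function(params) {
  g <- factor(rep(params$group_labels, each = params$n_per_group),
              levels = params$group_labels)
  names(g) <- sprintf("%s_%02d", as.character(g),
                      rep(seq_len(params$n_per_group), times = 2))
  g
}

# features eligible for effect planting: the detectable mid-range of the
# abundance distribution. The lower bound (twice the censoring quantile)
# excludes features unobservable in every sample — an effect on a protein the
# instrument never sees is not expressed in the measured data. The upper
# bound excludes the top abundance decile: the few most abundant proteins are
# not plausible strongly-regulated targets, and rank-based normalization is
# unstable at the sparse extreme tail.
plantable_ids <- function(ids, mu, censor_quantile) {
  lo <- if (censor_quantile > 0)
    stats::quantile(mu, min(0.5, 2 * censor_quantile)) else -Inf
  hi <- stats::quantile(mu, 0.9)
  ids[mu >= lo & mu <= hi]
}

# latent complete log2 matrix + planted truth; `planted` overrides the random
# choice of affected features (data.frame feature, true_log2fc); `mu`
# overrides the baseline draw
latent_log2_matrix <- function(params, ids, planted = NULL, mu = NULL) {
  n <- params$n_features
  groups <- omics_groups(params)
  if (is.null(mu)) mu <- stats::rnorm(n, params$base_log2_mean, params$base_log2_sd)
  if (is.null(planted)) {
    k <- round(params$frac_affected * n)
    cand <- plantable_ids(ids, mu, params$censor_quantile)
    aff <- if (k > 0) sample(cand, k) else character(0)
    sgn <- if (k > 0) sample(c(-1, 1), k, replace = TRUE) else numeric(0)
    planted <- data.frame(feature = aff,
                          true_log2fc = sgn * params$effect_log2fc,
                          stringsAsFactors = FALSE)
  }
  x <- matrix(stats::rnorm(n * length(groups), 0, params$noise_sd),
              nrow = n, dimnames = list(ids, names(groups)))
  x <- x + mu
  if (nrow(planted)) {
    idx <- match(planted$feature, ids)
    x[idx, groups == params$group_labels[2]] <-
      x[idx, groups == params$group_labels[2]] + planted$true_log2fc
  }
  list(latent = x, groups = groups, truth = planted)
}

# logistic left-censoring mask calibrated so the mean missing probability over
# the realised latent values equals q exactly
censor_mask <- function(latent, q, scale) {
  if (q <= 0) return(matrix(FALSE, nrow(latent), ncol(latent),
                            dimnames = dimnames(latent)))
  x <- as.vector(latent)
  f <- function(t) mean(stats::plogis((t - x) / scale)) - q
  t_star <- stats::uniroot(f, range(x) + c(-20, 20) * scale, tol = 1e-10)$root
  p_miss <- stats::plogis((t_star - latent) / scale)
  mask <- matrix(stats::runif(length(latent)) < p_miss, nrow(latent),
                 dimnames = dimnames(latent))
  mask
}

#' Generate a raw protein-intensity matrix with planted effects
#'
#' Produces a proteins x samples matrix of raw-scale intensities with
#' intensity-dependent missing cells (left-censoring, the missingness regime
#' typical of label-free MS) and a ground-truth table of planted log2 fold
#' changes in the second group.
#'
#' @param params an [omics_params()] object.
#' @param seed seed override (defaults to `params$seed`).
#' @return an object of class `omics_sim`: list with `intensities` (raw scale,
#'   NA = missing), `latent` (complete log2 matrix, for diagnostics),
#'   `groups` (named factor), `truth` (feature, true_log2fc).
#' @export
generate_intensity_matrix <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "omics_params"))
  if (params$n_per_group < 2)
    stop("n_per_group must be >= 2 (group comparison undefined otherwise)")
  with_seed(seed, {
    ids <- feature_ids(params$n_features, "PROT")
    lat <- latent_log2_matrix(params, ids)
    mask <- censor_mask(lat$latent, params$censor_quantile, params$censor_scale)
    raw <- 2^lat$latent
    raw[mask] <- NA_real_
    structure(list(intensities = raw, latent = lat$latent,
                   groups = lat$groups, truth = lat$truth),
              class = "omics_sim")
  })
}

#' Generate an immunoglobulin-style spectral-count table with planted effects
#'
#' Counts are negative-binomial with mean `rate_family * total_sample` and
#' variance `dispersion * mean`; planted families are multiplied by
#' `2^effect_log2fc` in the second group. A crude per-cell unique-peptide
#' count accompanies the table so presence filtering can be exercised.
#'
#' @param params an [omics_params()] object (uses `n_features` families,
#'   `dispersion`, `total_counts_per_sample`, `effect_log2fc`,
#'   `frac_affected`).
#' @param seed seed override.
#' @return an object of class `count_sim`: list with `counts` (families x
#'   samples integer matrix), `totals` (per-sample total matched spectra),
#'   `unique_peptides` (same shape as counts), `groups`, `truth`.
#' @export
generate_count_table <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "omics_params"))
  if (params$dispersion < 1) stop("dispersion must be >= 1")
  if (params$total_counts_per_sample <= 0) stop("totals must be positive")
  with_seed(seed, {
    n <- params$n_features
    ids <- feature_ids(n, "IG")
    groups <- omics_groups(params)
    m <- length(groups)
    totals <- round(params$total_counts_per_sample * stats::runif(m, 0.8, 1.2))
    names(totals) <- names(groups)
    # family relative rates: lognormal around ~2e-4 of total spectra
    rate <- exp(stats::rnorm(n, log(2e-4), 0.8))
    # as in the intensity generator, effects are planted on detectable
    # families: the lowest-rate fifth sits at the presence-filter floor
    cand <- if (n >= 5) ids[rate >= stats::quantile(rate, 0.2)] else ids
    k <- round(params$frac_affected * n)
    aff <- if (k > 0) sample(cand, k) else character(0)
    sgn <- if (k > 0) sample(c(-1, 1), k, replace = TRUE) else numeric(0)
    truth <- data.frame(feature = aff, true_log2fc = sgn * params$effect_log2fc,
                        stringsAsFactors = FALSE)
    mu <- outer(rate, totals)
    if (k > 0) {
      idx <- match(aff, ids)
      mu[idx, groups == params$group_labels[2]] <-
        mu[idx, groups == params$group_labels[2]] * 2^(sgn * params$effect_log2fc)
    }
    d <- params$dispersion
    counts <- if (d == 1) {
      matrix(stats::rpois(n * m, mu), n)
    } else {
      matrix(stats::rnbinom(n * m, mu = mu, size = as.vector(mu) / (d - 1)), n)
    }
    dimnames(counts) <- list(ids, names(groups))
    up <- matrix(0L, n, m, dimnames = dimnames(counts))
    pos <- counts > 0
    up[pos] <- 1L + stats::rpois(sum(pos), pmax(0, counts[pos] / 5))
    structure(list(counts = counts, totals = totals, unique_peptides = up,
                   groups = groups, truth = truth),
              class = "count_sim")
  })
}

#' Generate a paired proteome / transcriptome with shared planted targets
#'
#' Builds a protein-intensity dataset (with left-censoring) and a complete
#' log2 expression matrix over one gene universe whose planted-effect sets
#' intersect in exactly `n_shared_targets` features, with the same effect
#' direction in both arms — the ground truth the cross-omic overlap step is
#' expected to recover.
#'
#' @param params an [omics_params()] object; `frac_affected` features are
#'   planted in each arm.
#' @param n_shared_targets number of concordant shared targets; must not
#'   exceed the planted set size of either arm.
#' @param seed seed override.
#' @return list with `proteomics` (an `omics_sim`), `rna` (list `log2`,
#'   `groups`), `truth` (feature, arm, true_log2fc), `shared` (character).
#' @export
generate_paired_omics <- function(params, n_shared_targets = 3L,
                                  seed = params$seed) {
  stopifnot(inherits(params, "omics_params"))
  k <- round(params$frac_affected * params$n_features)
  if (n_shared_targets > k)
    stop("n_shared_targets exceeds the planted set size (", k, ") of an arm")
  if (2 * k - n_shared_targets > params$n_features)
    stop("feature universe too small for disjoint arm-specific planted sets")
  with_seed(seed, {
    ids <- feature_ids(params$n_features, "GENE")
    mu_prot <- stats::rnorm(params$n_features, params$base_log2_mean,
                            params$base_log2_sd)
    cand <- plantable_ids(ids, mu_prot, params$censor_quantile)
    if (length(cand) < 2 * k - n_shared_targets)
      stop("feature universe too small for disjoint planted sets after the detectability restriction")
    pool <- sample(cand, 2 * k - n_shared_targets)
    shared <- pool[seq_len(n_shared_targets)]
    prot_only <- pool[seq_len(k - n_shared_targets) + n_shared_targets]
    rna_only <- setdiff(pool, c(shared, prot_only))
    sgn_shared <- sample(c(-1, 1), n_shared_targets, replace = TRUE)
    plant <- function(extra, sgn_extra) data.frame(
      feature = c(shared, extra),
      true_log2fc = c(sgn_shared, sgn_extra) * params$effect_log2fc,
      stringsAsFactors = FALSE)
    planted_prot <- plant(prot_only, sample(c(-1, 1), length(prot_only), TRUE))
    planted_rna <- plant(rna_only, sample(c(-1, 1), length(rna_only), TRUE))

    lat_p <- latent_log2_matrix(params, ids, planted_prot, mu = mu_prot)
    mask <- censor_mask(lat_p$latent, params$censor_quantile, params$censor_scale)
    raw <- 2^lat_p$latent
    raw[mask] <- NA_real_
    prot <- structure(list(intensities = raw, latent = lat_p$latent,
                           groups = lat_p$groups, truth = planted_prot),
                      class = "omics_sim")
    lat_r <- latent_log2_matrix(params, ids, planted_rna)
    truth <- rbind(cbind(planted_prot, arm = "protein"),
                   cbind(planted_rna, arm = "rna"))
    list(proteomics = prot,
         rna = list(log2 = lat_r$latent, groups = lat_r$groups),
         truth = truth[, c("feature", "arm", "true_log2fc")],
         shared = shared)
  })
}
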