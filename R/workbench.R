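# Orchestration: one declarative YAML config drives generate -> morphometry
# -> protein DE -> enrichment -> immunoglobulin counts -> integration, with
# all randomness derived from a single global seed and a manifest of output
# checksums.

#' Default run configuration
#'
#' Returns the demo configuration used by [run_all()]: small problem sizes
#' chosen so the full pipeline runs in seconds while exercising every stage.
#' Any block can be overridden in the YAML file.
#'
#' @return nested list of parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    cohort = list(
      n_samples_per_group = 3L,
      section_um = c(1600, 1600),
      fiber_pitch_um = 70,
      rod_prevalence_by_group = list(iNM = 0.53, SLONM = 0.11),
      size_ratio_by_group = list(iNM = 1.12, SLONM = 0.60)),
    omics = list(
      n_features = 800L, n_per_group = 8L,
      frac_affected = 0.05, effect_log2fc = 3,
      base_log2_mean = 20, base_log2_sd = 2, noise_sd = 0.5,
      censor_quantile = 0.10,
      dispersion = 3, total_counts_per_sample = 50000L,
      n_ig_families = 30L, ig_frac_affected = 0.1, ig_effect_log2fc = 2),
    thresholds = list(alpha = 0.05, lfc = 1),
    gsea = list(n_perm = 200L, weight = 1, n_random_sets = 10L, set_size = 20L),
    ig = list(min_unique_peptides = 2L, alpha = 0.05),
    integration = list(n_shared_targets = 3L))
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file; missing blocks fall back to [default_config()].
#' @return validated config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Every stage's parameters are checked before any stage runs, so an invalid
#' probability or size aborts the run up front.
#'
#' @param cfg config list.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  ch <- cfg$cohort
  prev <- unlist(ch$rod_prevalence_by_group)
  if (any(prev < 0 | prev > 1)) stop("config: rod prevalence outside [0, 1]")
  if (any(unlist(ch$size_ratio_by_group) <= 0)) stop("config: size ratio must be positive")
  if (ch$n_samples_per_group < 1) stop("config: n_samples_per_group must be >= 1")
  om <- cfg$omics
  if (om$frac_affected < 0 || om$frac_affected > 1)
    stop("config: frac_affected outside [0, 1]")
  if (om$censor_quantile < 0 || om$censor_quantile >= 1)
    stop("config: censor_quantile outside [0, 1)")
  if (om$dispersion < 1) stop("config: dispersion must be >= 1")
  if (om$n_per_group < 2) stop("config: n_per_group must be >= 2")
  th <- cfg$thresholds
  if (th$alpha <= 0 || th$alpha >= 1) stop("config: alpha outside (0, 1)")
  if (cfg$gsea$n_perm < 100) stop("config: gsea n_perm must be >= 100")
  if (cfg$ig$min_unique_peptides < 1) stop("config: min_unique_peptides must be >= 1")
  invisible(cfg)
}

config_cohort_params <- function(cfg) {
  ch <- cfg$cohort
  base <- cohort_params(seed = cfg$seed)
  cohort_params(
    n_samples_per_group = ch$n_samples_per_group,
    rod_prevalence_by_group = unlist(ch$rod_prevalence_by_group),
    size_ratio_by_group = unlist(ch$size_ratio_by_group),
    distribution_mix_by_group = base$distribution_mix_by_group[names(unlist(ch$rod_prevalence_by_group))],
    lesion_rates = base$lesion_rates[names(unlist(ch$rod_prevalence_by_group))],
    seed = cfg$seed)
}

config_omics_params <- function(cfg, dispersion = NULL, frac = NULL, effect = NULL,
                                n_features = NULL) {
  om <- cfg$omics
  omics_params(
    n_features = n_features %||% om$n_features,
    n_per_group = om$n_per_group,
    frac_affected = frac %||% om$frac_affected,
    effect_log2fc = effect %||% om$effect_log2fc,
    base_log2_mean = om$base_log2_mean, base_log2_sd = om$base_log2_sd,
    noise_sd = om$noise_sd,
    censor_quantile = om$censor_quantile,
    dispersion = dispersion %||% om$dispersion,
    total_counts_per_sample = om$total_counts_per_sample,
    seed = cfg$seed)
}

#' Run the whole pipeline on one configuration
#'
#' Executes generate -> morphometry -> protein differential abundance ->
#' preranked enrichment -> immunoglobulin counts -> integration, writing
#' every intermediate as plain text under `out_dir` and finishing with a JSON
#' manifest of outputs, seeds and md5 checksums. All randomness is derived
#' from `cfg$seed` by [child_seed()], so two runs of the same config produce
#' byte-identical outputs.
#'
#' @param cfg a config list (see [default_config()]) or a YAML file path.
#' @param out_dir output directory (created if absent).
#' @param quiet suppress progress messages.
#' @return path of the manifest file, invisibly.
#' @export
run_all <- function(cfg = default_config(), out_dir, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }

  # -- generate ---------------------------------------------------------------
  say("stage: generate")
  cp <- config_cohort_params(cfg)
  groups <- names(cp$rod_prevalence_by_group)
  maps <- list()
  for (g in groups) for (i in seq_len(cp$n_samples_per_group)) {
    m <- generate_section(cp, g, seed = child_seed(cfg$seed, paste0("fiber_map/", g, "/", i)),
                          section_um = unlist(cfg$cohort$section_um),
                          fiber_pitch_um = cfg$cohort$fiber_pitch_um)
    id <- sprintf("%s_%02d", g, i)
    maps[[id]] <- m
    emit(write_fiber_map(m, file.path(out_dir, paste0("fiber_map_", id, ".geojson"))))
  }
  paired <- generate_paired_omics(config_omics_params(cfg),
                                  n_shared_targets = cfg$integration$n_shared_targets,
                                  seed = child_seed(cfg$seed, "paired_omics"))
  prot <- paired$proteomics
  emit(write_matrix_tsv(prot$intensities, file.path(out_dir, "protein_intensities.tsv")))
  emit(write_design_tsv(prot$groups, file.path(out_dir, "design.tsv")))
  emit(write_matrix_tsv(paired$rna$log2, file.path(out_dir, "rna_log2.tsv")))
  emit(write_table_tsv(paired$truth, file.path(out_dir, "truth_omics.tsv")))
  igp <- config_omics_params(cfg, n_features = cfg$omics$n_ig_families,
                             frac = cfg$omics$ig_frac_affected,
                             effect = cfg$omics$ig_effect_log2fc)
  igs <- generate_count_table(igp, seed = child_seed(cfg$seed, "ig_counts"))
  emit(write_matrix_tsv(igs$counts, file.path(out_dir, "ig_counts.tsv")))
  emit(write_table_tsv(data.frame(sample = names(igs$totals), total = unname(igs$totals)),
                       file.path(out_dir, "ig_totals.tsv")))

  # -- morphometry ------------------------------------------------------------
  say("stage: morphometry")
  summaries <- lapply(names(maps), function(id) {
    m <- maps[[id]]
    plan <- plan_sampling(m, seed = child_seed(cfg$seed, paste0("plan/", id)))
    summarize_sample(sample_fibers(m, plan))
  })
  names(summaries) <- names(maps)
  per_sample <- do.call(rbind, lapply(summaries, summary_row))
  per_sample <- cbind(sample = names(summaries),
                      group = sub("_[0-9]+$", "", names(summaries)), per_sample)
  emit(write_table_tsv(per_sample, file.path(out_dir, "morphometry_per_sample.tsv")))
  ga <- summaries[grep(paste0("^", groups[1]), names(summaries))]
  gb <- summaries[grep(paste0("^", groups[2]), names(summaries))]
  cmp <- compare_groups(ga, gb, labels = groups, alpha = cfg$thresholds$alpha)
  emit(write_table_tsv(cmp, file.path(out_dir, "morphometry_group_comparison.tsv")))

  # -- protein DE -------------------------------------------------------------
  say("stage: protein differential abundance")
  de_prot <- run_de(prot$intensities, prot$groups,
                    alpha = cfg$thresholds$alpha, lfc = cfg$thresholds$lfc,
                    seed = child_seed(cfg$seed, "impute"))
  emit(write_table_tsv(de_prot, file.path(out_dir, "de_proteins.tsv")))

  # -- enrichment -------------------------------------------------------------
  say("stage: enrichment")
  ranked <- compute_rank_scores(de_prot)
  sets <- with_seed(child_seed(cfg$seed, "gmt"), {
    universe <- ranked$gene
    s <- lapply(seq_len(cfg$gsea$n_random_sets), function(i)
      sample(universe, cfg$gsea$set_size))
    names(s) <- sprintf("RANDOM_SET_%02d", seq_along(s))
    s$PLANTED_UP <- unique(c(paired$truth$feature[paired$truth$arm == "protein" &
                                                    paired$truth$true_log2fc > 0]))
    s[vapply(s, length, integer(1)) >= 2]
  })
  gmt_path <- emit(write_gmt(sets, file.path(out_dir, "gene_sets.gmt")))
  gsea <- preranked_gsea(ranked, sets, n_perm = cfg$gsea$n_perm,
                         seed = child_seed(cfg$seed, "gsea"),
                         weight = cfg$gsea$weight)
  emit(write_table_tsv(gsea, file.path(out_dir, "gsea_results.tsv")))

  # -- immunoglobulin counts --------------------------------------------------
  say("stage: immunoglobulin counts")
  ig_res <- summarize_ig(igs$counts, igs$totals, igs$groups, igs$unique_peptides,
                         alpha = cfg$ig$alpha,
                         min_unique_peptides = cfg$ig$min_unique_peptides)
  emit(write_table_tsv(ig_res, file.path(out_dir, "ig_results.tsv")))

  # -- integration ------------------------------------------------------------
  say("stage: integration")
  de_rna <- run_de(paired$rna$log2, paired$rna$groups,
                   alpha = cfg$thresholds$alpha, lfc = cfg$thresholds$lfc,
                   log_transform = FALSE)
  emit(write_table_tsv(de_rna, file.path(out_dir, "de_genes.tsv")))
  ov <- overlap_targets(de_prot, de_rna)
  emit(write_table_tsv(ov$common, file.path(out_dir, "overlap_common.tsv")))
  emit(write_table_tsv(
    data.frame(n_common = ov$n_common, n_protein_only = ov$n_protein_only,
               n_rna_only = ov$n_rna_only, n_unmapped = ov$n_unmapped),
    file.path(out_dir, "overlap_counts.tsv")))

  # -- manifest ---------------------------------------------------------------
  outputs <- unique(outputs)
  manifest <- list(
    seed = cfg$seed,
    config = cfg,
    outputs = lapply(outputs, function(p) list(
      file = basename(p), md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             manifest_path)
  say("done: ", manifest_path)
  invisible(manifest_path)
}
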