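#' Pipeline thresholds
#'
#' Houses every tunable threshold of the preprocessing and signature
#' pipeline, with the defaults used throughout: spot intensity-over-background
#' ratio > 1.5 (strict, either channel), spot pixel correlation > 0.6
#' (strict), gene presence fraction >= 0.8 (inclusive), per-gene SD >= 0.7
#' (inclusive), differential fold change > 1.5-fold (strict),
#' cell-type-specific induction >= 4-fold (inclusive), 10 imputation
#' neighbours, 100 label permutations, and FDR targets of 1% (multiclass /
#' two-class) and 0.8% (block-permutation design).
#'
#' @param intensity_ratio_min Foreground-mean over background-median ratio a
#'   spot must exceed in at least one channel.
#' @param pixel_corr_min Pixel regression correlation a spot must exceed.
#' @param presence_min_fraction Minimum fraction of non-missing measurements
#'   for a gene to be retained (inclusive).
#' @param sd_min Minimum per-gene standard deviation (inclusive).
#' @param fold_select_min Fold-change cutoff for induced/repressed calls
#'   (strict).
#' @param cell_specific_fold_min Fold-change cutoff for cell-type-specific
#'   induction (inclusive).
#' @param cell_specific_margin_fold Other cell types must respond below this
#'   fold change (strict) for a gene to count as type-specific.
#' @param knn_k Number of imputation neighbours.
#' @param n_permutations Label permutations for the significance analysis.
#' @param fdr_target Target false discovery rate for two-class/multiclass
#'   analyses.
#' @param fdr_target_blocked Target FDR for the block-permutation design.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(intensity_ratio_min = 1.5,
                            pixel_corr_min = 0.6,
                            presence_min_fraction = 0.8,
                            sd_min = 0.7,
                            fold_select_min = 1.5,
                            cell_specific_fold_min = 4,
                            cell_specific_margin_fold = 1.5,
                            knn_k = 10,
                            n_permutations = 100,
                            fdr_target = 0.01,
                            fdr_target_blocked = 0.008) {
  cfg <- list(
    intensity_ratio_min = intensity_ratio_min,
    pixel_corr_min = pixel_corr_min,
    presence_min_fraction = presence_min_fraction,
    sd_min = sd_min,
    fold_select_min = fold_select_min,
    cell_specific_fold_min = cell_specific_fold_min,
    cell_specific_margin_fold = cell_specific_margin_fold,
    knn_k = knn_k,
    n_permutations = n_permutations,
    fdr_target = fdr_target,
    fdr_target_blocked = fdr_target_blocked
  )
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                logical(1))
  if (!all(num)) {
    abort(paste0("pipeline_config: non-positive or non-scalar field(s): ",
                 paste(names(cfg)[!num], collapse = ", ")),
          class = "stromasig_config_error")
  }
  if (presence_min_fraction > 1 || fdr_target > 1 || fdr_target_blocked > 1) {
    abort("pipeline_config: fractions must lie in (0, 1]",
          class = "stromasig_config_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Simulation configuration
#'
#' Describes a synthetic stimulation study and tumour cohort with planted
#' ground truth. The defaults emulate the profiled study design: duplicate
#' mock and stimulated samples for three cell types, a fibroblast-like
#' target cell type carrying specific induction (log2 effect 2.5 +/- 0.3),
#' a small shared-response gene set, replicate noise of 0.3 log2 units,
#' and ~5% missing measurements.
#'
#' @param n_genes Number of genes.
#' @param n_cell_types Number of cell types; the first is the target.
#' @param stimuli Stimulus labels, containing exactly one `"mock"`.
#' @param n_replicates Biological replicates per condition (duplicates by
#'   default).
#' @param frac_signature Fraction of genes with planted target-specific
#'   induction.
#' @param planted_log2_effect Length-2 vector `c(mean, sd)` of the planted
#'   log2 fold change.
#' @param shared_effect_frac Fraction of genes responding in all cell types.
#' @param noise_sd Replicate noise SD (log2 units).
#' @param missing_rate Fraction of entries masked completely at random.
#' @param frac_bad_intensity,frac_bad_corr,frac_flagged Fractions of
#'   simulated spots violating each spot-quality rule.
#' @param cohort_n Patients in the simulated tumour cohort.
#' @param beta Log hazard ratio of the high-activation group.
#' @param baseline_hazard Baseline exponential event rate (per month).
#' @param censor_rate Independent exponential censoring rate (per month).
#' @param activation_sep Separation of the bimodal patient activation
#'   mixture (log2 units).
#' @param activation_sd Within-mode SD of patient activation.
#' @param hazard_covariate `"group"` (default): the hazard acts on the binary
#'   latent activation class; `"score"`: on the continuous activation.
#' @param other_cause_frac Fraction of deaths attributed to causes other than
#'   the disease.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_cell_types = 3,
                       stimuli = c("mock", "BMP2"),
                       n_replicates = 2,
                       frac_signature = 0.05,
                       planted_log2_effect = c(2.5, 0.3),
                       shared_effect_frac = 0.02,
                       noise_sd = 0.3,
                       missing_rate = 0.05,
                       frac_bad_intensity = 0.05,
                       frac_bad_corr = 0.05,
                       frac_flagged = 0.02,
                       cohort_n = 500,
                       beta = log(2),
                       baseline_hazard = 0.02,
                       censor_rate = 0.01,
                       activation_sep = 2,
                       activation_sd = 0.3,
                       hazard_covariate = c("group", "score"),
                       other_cause_frac = 0,
                       seed = 1L) {
  hazard_covariate <- match.arg(hazard_covariate)
  cfg <- list(
    n_genes = n_genes, n_cell_types = n_cell_types, stimuli = stimuli,
    n_replicates = n_replicates, frac_signature = frac_signature,
    planted_log2_effect = planted_log2_effect,
    shared_effect_frac = shared_effect_frac, noise_sd = noise_sd,
    missing_rate = missing_rate, frac_bad_intensity = frac_bad_intensity,
    frac_bad_corr = frac_bad_corr, frac_flagged = frac_flagged,
    cohort_n = cohort_n, beta = beta, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, activation_sep = activation_sep,
    activation_sd = activation_sd, hazard_covariate = hazard_covariate,
    other_cause_frac = other_cause_frac, seed = as.integer(seed)
  )
  counts <- c("n_genes", "n_cell_types", "n_replicates", "cohort_n")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]])) {
      abort(paste0("sim_config: `", f, "` must be a count >= 1"),
            class = "stromasig_config_error")
    }
  }
  fracs <- c("frac_signature", "shared_effect_frac", "missing_rate",
             "frac_bad_intensity", "frac_bad_corr", "frac_flagged",
             "other_cause_frac")
  for (f in fracs) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("sim_config: `", f, "` must be a fraction in [0, 1]"),
            class = "stromasig_config_error")
    }
  }
  for (f in c("noise_sd", "baseline_hazard", "censor_rate", "activation_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      abort(paste0("sim_config: `", f, "` must be >= 0"),
            class = "stromasig_config_error")
    }
  }
  if (sum(cfg$stimuli == "mock") != 1) {
    abort("sim_config: `stimuli` must contain exactly one \"mock\" label",
          class = "stromasig_config_error")
  }
  if (length(cfg$planted_log2_effect) != 2 || cfg$planted_log2_effect[2] < 0) {
    abort("sim_config: `planted_log2_effect` must be c(mean, sd) with sd >= 0",
          class = "stromasig_config_error")
  }
  structure(cfg, class = "sim_config")
}
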