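#' Simulate a stimulation study with planted differential expression
#'
#' Generates a gene x sample log2-ratio table for a multi-cell-type
#' stimulation experiment with replicate structure, planted
#' target-cell-type-specific induction, a shared (all-cell-type) response
#' set, additive Gaussian replicate noise on the log2 scale, and
#' completely-at-random missingness. The first cell type is the target.
#'
#' @param config A [sim_config()].
#' @return A list with
#'   \describe{
#'     \item{expr}{wide expression tibble (`gene_id` + one column per
#'       sample),}
#'     \item{samples}{sample annotation tibble (`sample_id`, `cell_type`,
#'       `stimulus`, `replicate`, `is_mock`),}
#'     \item{truth}{planted truth: `specific_gene_ids`, `shared_gene_ids`,
#'       `per_gene_log2_effect` (named vector), `target_cell_type`.}
#'   }
#' @export
simulate_expression_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(g))
  cell_types <- paste0("cell", LETTERS[seq_len(config$n_cell_types)])
  target <- cell_types[1]

  samples <- tidyr::expand_grid(
    cell_type = cell_types,
    stimulus = config$stimuli,
    replicate = seq_len(config$n_replicates)
  ) %>%
    mutate(
      is_mock = .data$stimulus == "mock",
      sample_id = paste(.data$cell_type, .data$stimulus, .data$replicate,
                        sep = "_")
    ) %>%
    select("sample_id", "cell_type", "stimulus", "replicate", "is_mock")

  n_specific <- round(config$frac_signature * g)
  n_shared <- round(config$shared_effect_frac * g)
  picked <- sample.int(g, n_specific + n_shared)
  specific_idx <- picked[seq_len(n_specific)]
  shared_idx <- setdiff(picked, specific_idx)

  effect <- numeric(g)
  planted <- c(specific_idx, shared_idx)
  effect[planted] <- rnorm(length(planted),
                           config$planted_log2_effect[1],
                           config$planted_log2_effect[2])

  m <- matrix(rnorm(g * nrow(samples), 0, config$noise_sd),
              nrow = g, dimnames = list(gene_ids, samples$sample_id))
  stim_cols <- which(!samples$is_mock)
  target_stim_cols <- which(!samples$is_mock & samples$cell_type == target)
  m[specific_idx, target_stim_cols] <-
    m[specific_idx, target_stim_cols] + effect[specific_idx]
  m[shared_idx, stim_cols] <- m[shared_idx, stim_cols] + effect[shared_idx]

  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(m)) < config$missing_rate, nrow = g)
    m[mask] <- NA_real_
  }

  truth <- list(
    specific_gene_ids = gene_ids[specific_idx],
    shared_gene_ids = gene_ids[shared_idx],
    per_gene_log2_effect = setNames(effect[planted], gene_ids[planted]),
    target_cell_type = target
  )
  list(expr = as_expr_tibble(m), samples = samples, truth = truth)
}

#' Simulate a tumour cohort whose hazard depends on a planted signature
#'
#' Patients carry a latent bimodal signature activation (low/high mixture);
#' the named signature genes are expressed at the patient's activation level
#' plus noise, other genes are standard-normal background. Event times are
#' exponential under proportional hazards; by default the log hazard is
#' `beta` for the high-activation class (so `exp(beta)` is the true hazard
#' ratio of the planted high group). Censoring is independent exponential.
#'
#' @param config A [sim_config()]; uses `cohort_n`, `beta`,
#'   `baseline_hazard`, `censor_rate`, `activation_sep`, `activation_sd`,
#'   `noise_sd`, `missing_rate`, `hazard_covariate`, `other_cause_frac`,
#'   `seed`.
#' @param signature_genes Non-empty character vector of signature gene ids;
#'   ids not of the simulated `G#####` form are added to the gene roster.
#' @return A list with `expr` (genes x patients, carries `unigene_id` and
#'   `symbol` annotations), `clinical` (tibble: `sample_id`, `time` in
#'   months, `event`, `cause`, `stage`), and `truth` (`activation_class`,
#'   `activation`, `true_beta`).
#' @export
simulate_survival_cohort <- function(config = sim_config(),
                                     signature_genes) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(signature_genes) || length(signature_genes) == 0) {
    abort("simulate_survival_cohort: `signature_genes` must be non-empty",
          class = "stromasig_input_error")
  }
  set.seed(config$seed + 1L)
  n <- config$cohort_n
  gene_ids <- union(sprintf("G%05d", seq_len(config$n_genes)),
                    signature_genes)
  g <- length(gene_ids)
  patient_ids <- sprintf("P%04d", seq_len(n))

  z <- rbinom(n, 1, 0.5)
  activation <- z * config$activation_sep + rnorm(n, 0, config$activation_sd)

  m <- matrix(rnorm(g * n), nrow = g, dimnames = list(gene_ids, patient_ids))
  sig_rows <- match(signature_genes, gene_ids)
  # signature genes are log-ratios against a pooled reference, so the cohort
  # is roughly symmetric around zero: low mode near -sep/2, high near +sep/2
  m[sig_rows, ] <- rep(activation - config$activation_sep / 2,
                       each = length(sig_rows)) +
    rnorm(length(sig_rows) * n, 0, config$noise_sd)
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(m)) < config$missing_rate, nrow = g)
    m[mask] <- NA_real_
  }

  x <- if (config$hazard_covariate == "group") z else activation
  rate <- config$baseline_hazard * exp(config$beta * x)
  t_event <- rexp(n, rate)
  t_cens <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else
    rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  cause <- ifelse(event == 1,
                  ifelse(runif(n) < config$other_cause_frac,
                         "other", "disease"),
                  NA_character_)

  annot <- tibble(gene_id = gene_ids,
                  unigene_id = paste0("Hs.", seq_along(gene_ids)),
                  symbol = gene_ids)
  clinical <- tibble(
    sample_id = patient_ids,
    time = time,
    event = event,
    cause = cause,
    stage = "I"
  )
  truth <- list(activation_class = setNames(z, patient_ids),
                activation = setNames(activation, patient_ids),
                true_beta = config$beta)
  list(expr = as_expr_tibble(m, annot), clinical = clinical, truth = truth)
}

#' Simulate a spot-level two-channel array table
#'
#' Emits per-spot Cy5/Cy3 foreground means, background medians, and the
#' within-spot pixel regression correlation for every gene on each array,
#' with configured fractions of spots violating each quality rule
#' (intensity-over-background, pixel correlation, manual flag). The truth of
#' each violation is recorded in `bad_intensity`, `bad_corr` and `flagged`
#' columns. Good spots encode a planted log2 ratio of zero plus noise.
#'
#' @param config A [sim_config()]; uses `n_genes`, `noise_sd`,
#'   `frac_bad_intensity`, `frac_bad_corr`, `frac_flagged`, `seed`.
#' @param sample_ids Array/sample identifiers, one array per sample.
#' @return A spot tibble: `spot_id`, `gene_id`, `sample_id`, `cy5_fg_mean`,
#'   `cy5_bg_median`, `cy3_fg_mean`, `cy3_bg_median`, `pixel_corr`,
#'   `flagged`, plus the truth columns.
#' @export
simulate_spot_table <- function(config = sim_config(),
                                sample_ids = c("S1", "S2")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  spots <- tidyr::expand_grid(
    gene_id = sprintf("G%05d", seq_len(config$n_genes)),
    sample_id = sample_ids
  )
  ns <- nrow(spots)
  bg <- 100
  ref_net <- 2^runif(ns, 8, 12)                      # reference channel net
  log_ratio <- rnorm(ns, 0, config$noise_sd)         # planted true ratio 0
  spots <- spots %>%
    mutate(
      spot_id = sprintf("spot%06d", dplyr::row_number()),
      bad_intensity = runif(ns) < config$frac_bad_intensity,
      bad_corr = runif(ns) < config$frac_bad_corr,
      flagged = runif(ns) < config$frac_flagged,
      cy3_bg_median = bg,
      cy5_bg_median = bg,
      cy3_fg_mean = bg + ref_net,
      cy5_fg_mean = bg + ref_net * 2^log_ratio,
      pixel_corr = runif(ns, 0.75, 0.99)
    )
  # violations: drive both channels under the 1.5 ratio, or the correlation
  # under 0.6
  low <- runif(ns, 0.5, 1.5)
  spots$cy3_fg_mean[spots$bad_intensity] <- bg * low[spots$bad_intensity]
  spots$cy5_fg_mean[spots$bad_intensity] <- bg * low[spots$bad_intensity]
  spots$pixel_corr[spots$bad_corr] <- runif(sum(spots$bad_corr), 0.1, 0.6)
  spots %>%
    select("spot_id", "gene_id", "sample_id", "cy5_fg_mean", "cy5_bg_median",
           "cy3_fg_mean", "cy3_bg_median", "pixel_corr", "flagged",
           "bad_intensity", "bad_corr")
}
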