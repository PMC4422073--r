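#' Simulate a study to disk
#'
#' Writes the synthetic stimulation study (PCL matrix, sample table, spot
#' table), the planted truth, the survival cohort, and a run manifest into
#' `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the list of files written.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_expression_study(config)
  spots <- simulate_spot_table(config)
  cohort <- simulate_survival_cohort(
    config, signature_genes = study$truth$specific_gene_ids)
  p <- function(f) file.path(out_dir, f)
  write_pcl(study$expr, p("study.pcl"))
  readr::write_tsv(study$samples, p("samples.tsv"))
  readr::write_tsv(spots, p("spots.tsv"))
  write_pcl(cohort$expr, p("cohort.pcl"))
  readr::write_tsv(cohort$clinical, p("clinical.tsv"))
  jsonlite::write_json(
    list(specific_gene_ids = study$truth$specific_gene_ids,
         shared_gene_ids = study$truth$shared_gene_ids,
         true_beta = cohort$truth$true_beta,
         target_cell_type = study$truth$target_cell_type),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(p("manifest.json"), stage = "simulate",
                 config = unclass(config), seeds = config$seed,
                 inputs = character(0),
                 outputs = c("study.pcl", "samples.tsv", "spots.tsv",
                             "cohort.pcl", "clinical.tsv", "truth.json"))
  invisible(list.files(out_dir, full.names = TRUE))
}

#' Derive a cell-type-specific signature from a stimulation study
#'
#' The discovery path: presence and variability filters, 10-NN imputation,
#' block-permutation significance analysis (mock vs stimulated, blocks =
#' cell types) reporting the common-response sets, per-cell-type
#' zero-transformation, and the inclusive 4-fold target-specific selection
#' with the non-response margin. The signature itself is the fold-rule set;
#' the significance analysis and gene dendrogram are reported alongside.
#'
#' @param expr Wide expression tibble of log2 ratios (may contain missing
#'   values).
#' @param samples Sample annotation tibble (`sample_id`, `cell_type`,
#'   `stimulus`, `is_mock`).
#' @param target_type Cell type defining specificity (default: first).
#' @param cfg A [pipeline_config()].
#' @param seed Seed for the permutation null.
#' @return A list: `signature`, `sam`, `responses`, `filtered`, `zeroed`,
#'   `dendrogram`, `reports`.
#' @export
run_derive_signature <- function(expr, samples,
                                 target_type = samples$cell_type[1],
                                 cfg = pipeline_config(), seed = 1L) {
  f1 <- presence_filter(expr, cfg)
  f2 <- variability_filter(f1, cfg)
  if (nrow(f2) == 0) {
    return(list(signature = NULL, sam = NULL,
                reports = list(presence = filter_report(f1),
                               variability = filter_report(f2)),
                empty = TRUE))
  }
  imp <- knn_impute(f2, k = cfg$knn_k)
  samples <- samples[match(sample_ids(imp), samples$sample_id), ]
  design <- sam_design("two_class_blocked",
                       labels = ifelse(samples$is_mock, "mock", "stimulated"),
                       blocks = samples$cell_type,
                       n_permutations = cfg$n_permutations,
                       seed = seed, target_fdr = cfg$fdr_target_blocked)
  sam <- run_sam(imp, design)

  # per-cell-type zero-transformation: each cell type referenced to its own
  # mock duplicates
  m <- expr_matrix(imp)
  zeroed <- m
  for (ct in unique(samples$cell_type)) {
    ids <- samples$sample_id[samples$cell_type == ct]
    mock_ids <- samples$sample_id[samples$cell_type == ct & samples$is_mock]
    zeroed[, ids] <- m[, ids] -
      rowMeans(m[, mock_ids, drop = FALSE], na.rm = TRUE)
  }
  zeroed_tbl <- set_expr_values(imp, zeroed)
  responses <- cell_type_responses(zeroed_tbl, samples)
  signature <- cell_type_specific_set(
    responses, target_type,
    min_fold = cfg$cell_specific_fold_min,
    margin_fold = cfg$cell_specific_margin_fold)
  dend <- if (nrow(signature) >= 2) {
    average_linkage(uncentered_pearson_distance(
      zeroed_tbl[zeroed_tbl$gene_id %in% signature$gene_id, ]))
  } else NULL
  list(signature = signature, sam = sam, responses = responses,
       filtered = f2, zeroed = zeroed_tbl, dendrogram = dend,
       reports = list(presence = filter_report(f1),
                      variability = filter_report(f2),
                      imputed_fraction = attr(imp, "imputed_fraction")),
       empty = FALSE)
}

#' Validate a signature against a tumour cohort
#'
#' Maps the signature onto the cohort platform (Unigene averaging, >80%
#' presence), then stratifies by both methods (dendrogram root cut and
#' centroid median split) and reports Kaplan-Meier curves, survival at the
#' requested horizons, and univariate Cox fits.
#'
#' @param sig A `gene_signature`.
#' @param expr Cohort expression tibble.
#' @param clinical Clinical tibble aligned by `sample_id`.
#' @param horizons Months for survival read-offs.
#' @param endpoint Passed to [make_endpoint()] when a `cause` column is
#'   present.
#' @return A list: `mapping`, `median_score`, `cluster_split`.
#' @export
run_validate_signature <- function(sig, expr, clinical,
                                   horizons = c(12, 24, 60),
                                   endpoint = "overall") {
  mp <- map_signature(sig, expr)
  cl <- if ("cause" %in% names(clinical))
    make_endpoint(clinical, endpoint) else clinical
  list(mapping = mp$report,
       n_matched = mp$n_matched,
       median_score = stratified_analysis(mp$mapped, cl,
                                          method = "median_score",
                                          horizons = horizons),
       cluster_split = stratified_analysis(mp$mapped, cl,
                                           method = "cluster_split",
                                           horizons = horizons))
}

write_manifest <- function(path, stage, config, seeds, inputs, outputs) {
  jsonlite::write_json(
    list(stage = stage,
         package_version = as.character(utils::packageVersion("stromasig")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC"),
         seeds = seeds,
         config = config,
         inputs = inputs,
         outputs = outputs),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
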