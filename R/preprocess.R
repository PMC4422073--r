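#' Spot quality filter
#'
#' Retains spots whose mean foreground intensity over median background
#' intensity exceeds the threshold in at least one channel (Cy3 or Cy5,
#' strict `>`), whose within-spot pixel regression correlation exceeds its
#' threshold (strict `>`), and which were not manually flagged. A removal
#' report is attached (see [filter_report()]).
#'
#' @param spots Spot tibble with columns `spot_id`, `cy5_fg_mean`,
#'   `cy5_bg_median`, `cy3_fg_mean`, `cy3_bg_median`, `pixel_corr`,
#'   `flagged`.
#' @param cfg A [pipeline_config()].
#' @return The retained spots, with a `filter_report` attribute.
#' @export
spot_quality_filter <- function(spots, cfg = pipeline_config()) {
  if (nrow(spots) == 0) {
    abort("spot_quality_filter: empty spot table",
          class = "stromasig_input_error")
  }
  evaluated <- !spots$flagged
  bad_bg <- evaluated &
    (spots$cy3_bg_median <= 0 | spots$cy5_bg_median <= 0)
  if (any(bad_bg)) {
    abort(paste0("spot_quality_filter: background median of 0 on spot(s) ",
                 paste(head(spots$spot_id[bad_bg], 5), collapse = ", ")),
          class = "stromasig_data_error")
  }
  ratio_ok <- spots$cy3_fg_mean / spots$cy3_bg_median > cfg$intensity_ratio_min |
    spots$cy5_fg_mean / spots$cy5_bg_median > cfg$intensity_ratio_min
  corr_ok <- spots$pixel_corr > cfg$pixel_corr_min
  keep <- ratio_ok & corr_ok & evaluated
  removed <- list(
    flagged = sum(spots$flagged),
    low_intensity_ratio = sum(evaluated & !ratio_ok),
    low_pixel_corr = sum(evaluated & ratio_ok & !corr_ok)
  )
  with_filter_report(
    spots[keep, , drop = FALSE],
    make_filter_report(nrow(spots), removed, sum(keep))
  )
}

#' Log2 ratio formation from quality-filtered spots
#'
#' For each spot, forms log2 of the background-subtracted sample-channel
#' (Cy5) intensity over the background-subtracted reference-channel (Cy3)
#' intensity. Non-positive net intensity in either channel yields a missing
#' value (never a clamped ratio) and is counted in the attached report.
#' Replicate spots of the same gene on one array are averaged after the log
#' transform. (Gene, sample) pairs absent from the table are missing.
#'
#' @param spots Quality-filtered spot tibble.
#' @return A wide expression tibble with a `filter_report` attribute
#'   counting spots lost to non-positive net intensity.
#' @export
compute_log_ratios <- function(spots) {
  net5 <- spots$cy5_fg_mean - spots$cy5_bg_median
  net3 <- spots$cy3_fg_mean - spots$cy3_bg_median
  ok <- net5 > 0 & net3 > 0
  lr <- rep(NA_real_, length(ok))
  lr[ok] <- log2(net5[ok] / net3[ok])
  long <- tibble(gene_id = spots$gene_id, sample_id = spots$sample_id,
                 value = lr) %>%
    group_by(.data$gene_id, .data$sample_id) %>%
    summarise(value = if (all(is.na(.data$value))) NA_real_ else
      mean(.data$value, na.rm = TRUE), .groups = "drop")
  wide <- tidyr::pivot_wider(long, names_from = "sample_id",
                             values_from = "value") %>%
    arrange(.data$gene_id)
  report <- make_filter_report(
    nrow(spots),
    list(nonpositive_net_intensity = sum(!ok)),
    sum(ok)
  )
  with_filter_report(as_tibble(wide), report)
}

#' Presence filter
#'
#' Keeps genes measured (non-missing) in at least
#' `cfg$presence_min_fraction` of the samples (inclusive: a gene observed in
#' exactly 80% of samples is retained at the default).
#'
#' @inheritParams spot_quality_filter
#' @param expr Wide expression tibble.
#' @return Filtered tibble with a `filter_report` attribute.
#' @export
presence_filter <- function(expr, cfg = pipeline_config()) {
  m <- expr_matrix(expr)
  if (ncol(m) < 1) abort("presence_filter: matrix has no samples",
                         class = "stromasig_input_error")
  frac <- rowMeans(!is.na(m))
  keep <- frac >= cfg$presence_min_fraction
  with_filter_report(
    expr[keep, , drop = FALSE],
    make_filter_report(nrow(expr), list(low_presence = sum(!keep)),
                       sum(keep))
  )
}

#' Variability filter
#'
#' Keeps genes whose sample standard deviation over non-missing values is at
#' least `cfg$sd_min` (inclusive). Genes with fewer than two observed values
#' have no defined SD and are removed (counted separately).
#'
#' @inheritParams presence_filter
#' @return Filtered tibble with a `filter_report` attribute.
#' @export
variability_filter <- function(expr, cfg = pipeline_config()) {
  m <- expr_matrix(expr)
  n_obs <- rowSums(!is.na(m))
  sds <- apply(m, 1, sd, na.rm = TRUE)
  too_few <- n_obs < 2
  keep <- !too_few & sds >= cfg$sd_min
  with_filter_report(
    expr[keep, , drop = FALSE],
    make_filter_report(nrow(expr),
                       list(under_two_observations = sum(too_few),
                            low_sd = sum(!too_few & !keep)),
                       sum(keep))
  )
}

#' Zero-transformation against mock samples
#'
#' Subtracts from every value of a gene the mean of that gene's mock
#' (non-stimulated) measurements, so all values express change relative to
#' the unstimulated state. The mock mean is taken over non-missing mock
#' entries; genes with no observed mock value are set fully missing and
#' counted in the attached report.
#'
#' @param expr Wide expression tibble.
#' @param mock_sample_ids Character vector of mock sample columns.
#' @return Zero-transformed tibble with a `filter_report` attribute counting
#'   rows lost to all-missing mock values.
#' @export
zero_transform <- function(expr, mock_sample_ids) {
  if (length(mock_sample_ids) == 0) {
    abort("zero_transform: `mock_sample_ids` is empty",
          class = "stromasig_input_error")
  }
  missing_cols <- setdiff(mock_sample_ids, sample_ids(expr))
  if (length(missing_cols) > 0) {
    abort(paste0("zero_transform: mock sample(s) not in matrix: ",
                 paste(missing_cols, collapse = ", ")),
          class = "stromasig_input_error")
  }
  m <- expr_matrix(expr)
  mock_mean <- rowMeans(m[, mock_sample_ids, drop = FALSE], na.rm = TRUE)
  all_missing <- !is.finite(mock_mean)
  out <- m - mock_mean
  out[all_missing, ] <- NA_real_
  report <- make_filter_report(nrow(m),
                               list(no_mock_value = sum(all_missing)),
                               sum(!all_missing))
  with_filter_report(set_expr_values(expr, out), report)
}

#' Time-course normalisation against mock and the time-zero profile
#'
#' For a stimulation time course with a matched mock series, expresses each
#' stimulated profile relative to the time-dependent mock changes and the
#' time-zero state: `out(g, t) = (stim(g, t) - mock(g, t)) -
#' (stim(g, t0) - mock(g, t0))`. The mock-corrected time-zero reference
#' makes the result invariant to any constant offset applied to all
#' samples, and zero whenever the stimulated series equals the mock series.
#'
#' @param expr Wide expression tibble.
#' @param stim_sample_ids,mock_sample_ids Equal-length vectors pairing each
#'   stimulated timepoint with its matched mock timepoint (same order).
#' @param t0_index Position (in the paired series) of the time-zero sample.
#' @return Tibble of normalised stimulated profiles, columns named as the
#'   stimulated samples.
#' @export
time_course_normalize <- function(expr, stim_sample_ids, mock_sample_ids,
                                  t0_index = 1L) {
  if (length(stim_sample_ids) != length(mock_sample_ids)) {
    abort("time_course_normalize: each stimulated timepoint needs a matched mock timepoint",
          class = "stromasig_config_error")
  }
  cols <- sample_ids(expr)
  missing_cols <- setdiff(c(stim_sample_ids, mock_sample_ids), cols)
  if (length(missing_cols) > 0) {
    abort(paste0("time_course_normalize: sample(s) not in matrix: ",
                 paste(missing_cols, collapse = ", ")),
          class = "stromasig_config_error")
  }
  if (t0_index < 1 || t0_index > length(stim_sample_ids)) {
    abort("time_course_normalize: `t0_index` outside the series",
          class = "stromasig_config_error")
  }
  m <- expr_matrix(expr)
  diff <- m[, stim_sample_ids, drop = FALSE] -
    m[, mock_sample_ids, drop = FALSE]
  out <- diff - diff[, t0_index]
  colnames(out) <- stim_sample_ids
  dplyr::bind_cols(expr_annotation(expr), as_tibble(as.data.frame(out)))
}
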