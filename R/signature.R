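#' Fold-change selection of induced and repressed genes
#'
#' On a zero-transformed matrix, computes each gene's mean log2 response
#' over the stimulated samples and calls genes induced (or repressed) when
#' the response exceeds `log2(min_fold)` (strict `>` by default; the
#' inclusive `>=` semantics are used for the cell-type-specific 4-fold
#' rule). Reports the mean and SD of the linear fold changes per set.
#'
#' @param expr_zeroed Zero-transformed wide expression tibble.
#' @param stim_sample_ids Stimulated sample columns to average.
#' @param min_fold Linear fold-change cutoff (> 1).
#' @param inclusive Use `>=` instead of `>` at the cutoff.
#' @return A tibble (`gene_id`, `mean_log2`, `fold_change`, `direction`)
#'   of selected genes, with a `fold_summary` attribute (per-direction mean
#'   and SD of linear fold change).
#' @export
fold_change_select <- function(expr_zeroed, stim_sample_ids,
                               min_fold = 1.5, inclusive = FALSE) {
  if (min_fold <= 1) {
    abort("fold_change_select: `min_fold` must exceed 1",
          class = "stromasig_config_error")
  }
  m <- expr_matrix(expr_zeroed)
  resp <- rowMeans(m[, stim_sample_ids, drop = FALSE], na.rm = TRUE)
  cut <- log2(min_fold)
  up <- if (inclusive) resp >= cut else resp > cut
  dn <- if (inclusive) resp <= -cut else resp < -cut
  up[is.na(up)] <- FALSE
  dn[is.na(dn)] <- FALSE
  out <- tibble(gene_id = rownames(m), mean_log2 = unname(resp)) %>%
    mutate(fold_change = 2^abs(.data$mean_log2),
           direction = case_when(up ~ "induced", dn ~ "repressed",
                                 TRUE ~ NA_character_)) %>%
    filter(!is.na(.data$direction))
  summary <- out %>%
    group_by(.data$direction) %>%
    summarise(n = dplyr::n(), mean_fold = mean(.data$fold_change),
              sd_fold = sd(.data$fold_change), .groups = "drop")
  attr(out, "fold_summary") <- summary
  out
}

#' Per-cell-type mean responses
#'
#' Convenience: from a zero-transformed matrix and sample annotations,
#' returns the gene x cell-type matrix of mean stimulated responses.
#'
#' @param expr_zeroed Zero-transformed wide expression tibble.
#' @param samples Sample annotation tibble (`sample_id`, `cell_type`,
#'   `is_mock`).
#' @param stimulus Optional stimulus to restrict to.
#' @return Genes x cell types numeric matrix.
#' @export
cell_type_responses <- function(expr_zeroed, samples, stimulus = NULL) {
  m <- expr_matrix(expr_zeroed)
  stim <- samples %>% filter(!.data$is_mock)
  if (!is.null(stimulus)) stim <- filter(stim, .data$stimulus == !!stimulus)
  types <- unique(stim$cell_type)
  resp <- vapply(types, function(ct) {
    ids <- stim$sample_id[stim$cell_type == ct]
    rowMeans(m[, ids, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  colnames(resp) <- types
  resp
}

#' Cell-type-specific induced gene set
#'
#' Selects genes induced at least `min_fold`-fold (inclusive, log2 >= 2 at
#' the default 4-fold) in the target cell type while staying below a
#' non-response margin (strict, default < 1.5-fold) in every other cell
#' type. The margin rule is the deterministic analog of delimiting a
#' target-specific cluster by inspection.
#'
#' @param responses Genes x cell types response matrix (see
#'   [cell_type_responses()]).
#' @param target_type Column of `responses` defining specificity.
#' @param min_fold Inclusive induction cutoff in the target type.
#' @param margin_fold Strict non-response margin for the other types.
#' @param name Signature name recorded in the result.
#' @return A `gene_signature`: tibble (`gene_id`, `direction`, response
#'   columns) with `name` and `provenance` attributes.
#' @export
cell_type_specific_set <- function(responses, target_type, min_fold = 4,
                                   margin_fold = 1.5,
                                   name = paste0(target_type,
                                                 "_specific_induced")) {
  if (!target_type %in% colnames(responses)) {
    abort(paste0("cell_type_specific_set: target type `", target_type,
                 "` absent from responses"),
          class = "stromasig_input_error")
  }
  if (ncol(responses) < 2) {
    abort("cell_type_specific_set: need >= 2 cell types",
          class = "stromasig_input_error")
  }
  others <- setdiff(colnames(responses), target_type)
  tgt <- responses[, target_type]
  ok_target <- !is.na(tgt) & tgt >= log2(min_fold)
  oth <- responses[, others, drop = FALSE]
  ok_margin <- rowSums(is.na(oth) | oth >= log2(margin_fold)) == 0
  keep <- ok_target & ok_margin
  out <- tibble(gene_id = rownames(responses)[keep],
                direction = "induced") %>%
    dplyr::bind_cols(as_tibble(as.data.frame(
      responses[keep, , drop = FALSE])))
  attr(out, "name") <- name
  attr(out, "provenance") <- list(target_type = target_type,
                                  min_fold = min_fold,
                                  margin_fold = margin_fold,
                                  other_types = others)
  class(out) <- c("gene_signature", class(out))
  out
}

#' Correlation of response profiles between two stimuli
#'
#' Standard centered Pearson correlation over co-observed genes with a
#' two-sided p-value from the t transform, plus the paired values for
#' scatter export.
#'
#' @param response_a,response_b Named per-gene response vectors.
#' @return A list: `r`, `p`, `n`, `pairs` (tibble of co-observed values).
#' @export
response_correlation <- function(response_a, response_b) {
  common <- intersect(names(response_a), names(response_b))
  a <- response_a[common]
  b <- response_b[common]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) {
    abort("response_correlation: fewer than 3 co-observed genes",
          class = "stromasig_input_error")
  }
  ct <- stats::cor.test(a[ok], b[ok], method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       pairs = tibble(gene_id = common[ok], response_a = unname(a[ok]),
                      response_b = unname(b[ok])))
}

#' Map a signature onto another expression platform
#'
#' Probes sharing a Unigene cluster are averaged per sample (so clusters
#' matched by several probes are not over-weighted), signature genes absent
#' from the platform are dropped and listed, and genes observed in no more
#' than 80% of samples (strict `> 0.8` required) are dropped.
#'
#' @param sig A `gene_signature` (needs a `unigene_id` or `symbol` column;
#'   `gene_id` is used as the match key when the target lacks annotations).
#' @param target Wide expression tibble of the target cohort, carrying
#'   `unigene_id` (preferred) or `symbol` annotations.
#' @param min_present_fraction Strict lower bound on the observed fraction.
#' @return A list: `mapped` (wide tibble, one row per mapped signature
#'   gene), `report` (tibble per signature gene: matched, n_probes,
#'   fraction observed, retained).
#' @export
map_signature <- function(sig, target, min_present_fraction = 0.8) {
  key <- if ("unigene_id" %in% names(target) &&
             "unigene_id" %in% names(sig)) "unigene_id"
  else if ("symbol" %in% names(target) && "symbol" %in% names(sig)) "symbol"
  else "gene_id"
  ids <- sample_ids(target)
  collapsed <- target %>%
    filter(!is.na(.data[[key]])) %>%
    group_by(.data[[key]]) %>%
    summarise(n_probes = dplyr::n(),
              across(all_of(ids), ~ {
                v <- .x
                if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
              }),
              .groups = "drop")
  sig_keys <- unique(sig[[key]])
  hit <- collapsed %>% filter(.data[[key]] %in% sig_keys)
  frac <- rowMeans(!is.na(as.matrix(hit[, ids, drop = FALSE])))
  retained <- frac > min_present_fraction
  report <- tibble(!!key := sig_keys) %>%
    left_join(hit %>%
                mutate(fraction_observed = frac, retained = retained) %>%
                select(all_of(key), "n_probes", "fraction_observed",
                       "retained"),
              by = key) %>%
    mutate(matched = !is.na(.data$n_probes),
           retained = !is.na(.data$retained) & .data$retained)
  mapped <- hit[retained, , drop = FALSE] %>%
    rename(gene_id = all_of(key)) %>%
    select(-"n_probes")
  if (nrow(mapped) == 0) {
    abort("map_signature: no signature gene matched the target platform",
          class = "stromasig_input_error")
  }
  list(mapped = as_tibble(mapped), report = report,
       n_matched = sum(report$matched), n_retained = sum(report$retained))
}

#' Centroid score of a signature
#'
#' The per-sample mean log2 expression over the mapped signature genes
#' (missing entries ignored per sample). Samples with no observed
#' signature value are flagged and excluded from any later split.
#'
#' @param mapped Wide expression tibble restricted to signature genes (the
#'   `mapped` element of [map_signature()]), or any expression tibble if
#'   `sig` is given.
#' @param sig Optional `gene_signature` to subset `mapped` by `gene_id`.
#' @return A tibble (`sample_id`, `score`, `n_genes_observed`,
#'   `all_missing`).
#' @export
centroid_score <- function(mapped, sig = NULL) {
  m <- expr_matrix(mapped)
  if (!is.null(sig)) m <- m[rownames(m) %in% sig$gene_id, , drop = FALSE]
  if (nrow(m) == 0) {
    abort("centroid_score: no signature genes in matrix",
          class = "stromasig_input_error")
  }
  tibble(sample_id = colnames(m),
         score = unname(colMeans(m, na.rm = TRUE)),
         n_genes_observed = unname(colSums(!is.na(m)))) %>%
    mutate(score = ifelse(.data$n_genes_observed == 0, NA_real_,
                          .data$score),
           all_missing = .data$n_genes_observed == 0)
}

#' Median split of centroid scores
#'
#' Samples with a score strictly above the cohort median are labelled
#' `"high"`, the rest `"low"` (ties at the median deterministically go to
#' the low group). Samples with no score are left ungrouped.
#'
#' @param scores A [centroid_score()] tibble.
#' @return The tibble with a `group` column.
#' @export
median_split <- function(scores) {
  ok <- !is.na(scores$score)
  if (sum(ok) < 2) {
    abort("median_split: need >= 2 scored samples",
          class = "stromasig_input_error")
  }
  med <- median(scores$score[ok])
  if (all(scores$score[ok] == med)) {
    warn("median_split: all scores identical; every sample labelled low")
  }
  scores %>%
    mutate(group = case_when(
      is.na(.data$score) ~ NA_character_,
      .data$score > med ~ "high",
      TRUE ~ "low"
    ))
}

#' Write a signature as a two-column table
#'
#' @param sig A `gene_signature`.
#' @param path TSV path; a header comment declares the identifier type.
#' @export
write_signature <- function(sig, path) {
  writeLines(c("# identifier_type: gene_id",
               "gene_id\tdirection",
               paste(sig$gene_id, sig$direction, sep = "\t")),
             path)
  invisible(path)
}
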