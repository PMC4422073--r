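test_that("fold-change selection honours strict and inclusive boundaries", {
  m <- rbind(
    exact4 = c(2, 2),       # log2 = 2.0, exactly 4-fold
    near15 = c(0.58, 0.58), # just under log2(1.5) = 0.585
    at15 = c(log2(1.5), log2(1.5)),
    up = c(1, 1),
    down = c(-1.2, -1.2)
  )
  colnames(m) <- c("s1", "s2")
  e <- as_expr_tibble(m)
  # strict 1.5-fold: the value exactly at log2(1.5) is excluded
  strict <- fold_change_select(e, c("s1", "s2"), min_fold = 1.5,
                               inclusive = FALSE)
  expect_false("at15" %in% strict$gene_id)
  expect_false("near15" %in% strict$gene_id)
  expect_setequal(strict$gene_id[strict$direction == "induced"],
                  c("exact4", "up"))
  expect_equal(strict$gene_id[strict$direction == "repressed"], "down")
  # inclusive 4-fold: log2 = 2.0 is included
  incl <- fold_change_select(e, c("s1", "s2"), min_fold = 4,
                             inclusive = TRUE)
  expect_equal(incl$gene_id, "exact4")
  # summary reports linear fold changes
  smry <- attr(strict, "fold_summary")
  expect_equal(smry$mean_fold[smry$direction == "repressed"], 2^1.2)
  expect_error(fold_change_select(e, c("s1", "s2"), min_fold = 1),
               class = "stromasig_config_error")
})

test_that("fold selection on a planted study recovers genes above threshold", {
  cfg <- sim_config(n_genes = 800, noise_sd = 0, missing_rate = 0,
                    shared_effect_frac = 0, seed = 44)
  s <- simulate_expression_study(cfg)
  mocks <- s$samples$sample_id[s$samples$is_mock &
                                 s$samples$cell_type == "cellA"]
  stim <- s$samples$sample_id[!s$samples$is_mock &
                                s$samples$cell_type == "cellA"]
  z <- zero_transform(s$expr, mocks)
  sel <- fold_change_select(z, stim, min_fold = 4, inclusive = TRUE)
  planted_above <- names(which(
    s$truth$per_gene_log2_effect[s$truth$specific_gene_ids] >= 2))
  expect_setequal(sel$gene_id[sel$direction == "induced"], planted_above)
})

test_that("cell-type-specific selection excludes shared responders", {
  resp <- rbind(
    spec = c(2.5, 0.1, 0.2),     # target only -> included
    shared = c(2.5, 2.5, 2.5),   # everywhere -> excluded
    margin = c(2.5, 0.7, 0.1),   # other type above 1.5-fold -> excluded
    weak = c(1.9, 0, 0),         # below 4-fold -> excluded
    at4 = c(2, 0, 0)             # exactly 4-fold -> included (inclusive)
  )
  colnames(resp) <- c("cellA", "cellB", "cellC")
  sig <- cell_type_specific_set(resp, "cellA")
  expect_setequal(sig$gene_id, c("spec", "at4"))
  expect_error(cell_type_specific_set(resp, "cellX"),
               class = "stromasig_input_error")
})

test_that("specific and shared planted genes separate in a synthetic study", {
  cfg <- sim_config(n_genes = 1500, noise_sd = 0.1, missing_rate = 0,
                    frac_signature = 0.04, shared_effect_frac = 0.02,
                    planted_log2_effect = c(3, 0.2), seed = 8)
  s <- simulate_expression_study(cfg)
  m <- expr_matrix(s$expr)
  zeroed <- m
  for (ct in unique(s$samples$cell_type)) {
    ids <- s$samples$sample_id[s$samples$cell_type == ct]
    mock <- s$samples$sample_id[s$samples$cell_type == ct &
                                  s$samples$is_mock]
    zeroed[, ids] <- m[, ids] - rowMeans(m[, mock, drop = FALSE])
  }
  resp <- cell_type_responses(set_expr_values <- as_expr_tibble(zeroed),
                              s$samples)
  sig <- cell_type_specific_set(resp, "cellA")
  # effect 3 +/- 0.2 with noise 0.1: all planted specific genes recovered
  expect_setequal(sig$gene_id, s$truth$specific_gene_ids)
  expect_length(intersect(sig$gene_id, s$truth$shared_gene_ids), 0)
})

test_that("response correlation matches a direct transcription", {
  set.seed(21)
  a <- setNames(rnorm(50), paste0("g", 1:50))
  b <- 0.6 * a + rnorm(50, 0, 0.5)
  names(b) <- names(a)
  rc <- response_correlation(a, b)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  tstat <- r_direct * sqrt(48 / (1 - r_direct^2))
  expect_equal(rc$r, r_direct, tolerance = 1e-12)
  expect_equal(rc$p, 2 * pt(-abs(tstat), 48), tolerance = 1e-12)
  expect_equal(response_correlation(a, a)$r, 1)
  expect_equal(response_correlation(a, -a)$r, -1)
  expect_error(response_correlation(a[1:2], b[1:2]),
               class = "stromasig_input_error")
})

test_that("signature mapping averages Unigene probes and applies presence rule", {
  target <- tibble::tibble(
    gene_id = paste0("probe", 1:5),
    unigene_id = c("Hs.1", "Hs.1", "Hs.2", "Hs.3", "Hs.4"),
    p1 = c(1, 3, 5, 1, NA), p2 = c(2, 4, 6, NA, NA),
    p3 = c(0, 2, 7, 2, 1), p4 = c(1, 1, 8, 3, 1),
    p5 = c(1, 1, 9, 4, 1)
  )
  sig <- tibble::tibble(gene_id = c("a", "b", "c"),
                        unigene_id = c("Hs.1", "Hs.4", "Hs.9"))
  class(sig) <- c("gene_signature", class(sig))
  mp <- map_signature(sig, target)
  # two probes of Hs.1 averaged: (1+3)/2 = 2 in p1
  expect_equal(mp$mapped$p1[mp$mapped$gene_id == "Hs.1"], 2)
  # Hs.4 observed in 3/5 = 60% <= 80% -> dropped
  expect_false("Hs.4" %in% mp$mapped$gene_id)
  # Hs.9 absent from platform -> dropped, in report
  rep <- mp$report
  expect_false(rep$matched[rep$unigene_id == "Hs.9"])
  expect_equal(mp$n_matched, 2)
  expect_equal(mp$n_retained, 1)

  # a gene observed in exactly 80% of samples is dropped (strict > 80%)
  target2 <- tibble::tibble(gene_id = "p", unigene_id = "Hs.1",
                            s1 = 1, s2 = 1, s3 = 1, s4 = 1, s5 = NA)
  sig2 <- tibble::tibble(gene_id = "a", unigene_id = "Hs.1")
  expect_error(map_signature(sig2, target2),
               class = "stromasig_input_error")
})

test_that("signature mapping is idempotent on an averaged matrix", {
  set.seed(3)
  target <- tibble::tibble(
    gene_id = paste0("probe", 1:6),
    unigene_id = paste0("Hs.", c(1, 1, 2, 2, 3, 4)),
    s1 = rnorm(6), s2 = rnorm(6), s3 = rnorm(6)
  )
  sig <- tibble::tibble(gene_id = paste0("Hs.", 1:4),
                        unigene_id = paste0("Hs.", 1:4))
  m1 <- map_signature(sig, target)$mapped
  m2 <- map_signature(sig, m1 %>%
                        dplyr::mutate(unigene_id = gene_id))$mapped
  expect_equal(m2, m1)
})

test_that("centroid score is the row-subset column mean with linear shifts", {
  set.seed(5)
  m <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  e <- as_expr_tibble(m)
  sig <- tibble::tibble(gene_id = paste0("g", c(2, 4, 6)))
  sc <- centroid_score(e, sig)
  expect_equal(sc$score, unname(colMeans(m[c(2, 4, 6), ])),
               tolerance = 1e-12)
  # single-gene signature: score equals that gene's values
  sc1 <- centroid_score(e, tibble::tibble(gene_id = "g3"))
  expect_equal(sc1$score, unname(m[3, ]))
  # adding c to one sample's signature genes raises its score by c
  m2 <- m
  m2[c(2, 4, 6), 2] <- m2[c(2, 4, 6), 2] + 1.5
  sc2 <- centroid_score(as_expr_tibble(m2), sig)
  expect_equal(sc2$score[2] - sc$score[2], 1.5, tolerance = 1e-12)
  # gene order is irrelevant
  perm <- sample(8)
  expect_equal(centroid_score(as_expr_tibble(m[perm, ]), sig)$score,
               sc$score, tolerance = 1e-12)
})

test_that("median split sends ties to the low group", {
  s4 <- tibble::tibble(sample_id = paste0("p", 1:4), score = c(1, 2, 3, 4))
  g4 <- median_split(s4)
  expect_equal(g4$group, c("low", "low", "high", "high"))
  s3 <- tibble::tibble(sample_id = paste0("p", 1:3), score = c(1, 2, 3))
  g3 <- median_split(s3)
  expect_equal(g3$group, c("low", "low", "high"))
  sc <- tibble::tibble(sample_id = paste0("p", 1:3), score = c(2, 2, 2))
  expect_warning(gc_ <- median_split(sc), "identical")
  expect_true(all(gc_$group == "low"))
})

test_that("median split recovers a planted bimodal activation", {
  cfg <- sim_config(cohort_n = 300, activation_sep = 2,
                    activation_sd = 0.3, noise_sd = 0.3,
                    missing_rate = 0, seed = 61)
  sig_genes <- sprintf("G%05d", 1:50)
  cohort <- simulate_survival_cohort(cfg, sig_genes)
  sc <- centroid_score(cohort$expr,
                       tibble::tibble(gene_id = sig_genes))
  grouped <- median_split(sc)
  truth_high <- names(cohort$truth$activation_class)[
    cohort$truth$activation_class == 1]
  agree <- mean((grouped$sample_id %in% truth_high) ==
                  (grouped$group == "high"))
  # separation 2 with mode SD ~0.3: misclassification essentially nil;
  # the median itself can displace at most a few boundary patients
  expect_gte(agree, 0.97)
})
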