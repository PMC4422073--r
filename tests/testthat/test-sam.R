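two_class_design <- function(n1 = 3, n2 = 3, ...) {
  sam_design("two_class_unpaired",
             labels = c(rep("A", n1), rep("B", n2)), ...)
}

rand_matrix <- function(g, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(g * n), g, n,
         dimnames = list(sprintf("g%03d", seq_len(g)),
                         sprintf("s%d", seq_len(n))))
}

test_that("two-class statistic matches an independent formula transcription", {
  m <- rand_matrix(30, 6, seed = 8)
  des <- two_class_design()
  for (s0 in c(0, 0.2, 1)) {
    expect_equal(unname(sam_statistic(m, des, s0)),
                 unname(oracle_two_class_d(m, des$labels, s0)),
                 tolerance = 1e-12)
  }
  # hand example: {0,0} vs {1,1}, s0 = 0.5 -> d = 2
  mm <- matrix(c(0, 0, 1, 1), 1, 4,
               dimnames = list("g1", paste0("s", 1:4)))
  d4 <- sam_design("two_class_unpaired", labels = c("A", "A", "B", "B"))
  expect_equal(unname(sam_statistic(mm, d4, 0.5)), 2)
  # identical group means -> d = 0 for any s0
  m0 <- matrix(c(1, 2, 1, 2), 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  expect_equal(unname(sam_statistic(m0, d4, 0.3)), 0)
})

test_that("multiclass statistic matches its oracle and ranks shifted genes first", {
  set.seed(14)
  m <- rand_matrix(40, 6, seed = 14)
  labels <- rep(c("A", "B", "C"), each = 2)
  des <- sam_design("multiclass", labels = labels)
  expect_equal(unname(sam_statistic(m, des, 0.1)),
               unname(oracle_multiclass_d(m, labels, 0.1)),
               tolerance = 1e-12)
  # shift one class strongly for 5 genes -> those genes rank on top
  m[1:5, labels == "B"] <- m[1:5, labels == "B"] + 6
  d <- sam_statistic(m, des, 0.1)
  expect_setequal(names(sort(d, decreasing = TRUE))[1:5],
                  sprintf("g%03d", 1:5))
})

test_that("two-class statistic is antisymmetric under label swap", {
  m <- rand_matrix(25, 6, seed = 3)
  lab <- c("A", "B", "A", "B", "A", "B")
  swap <- ifelse(lab == "A", "B", "A")
  d1 <- sam_statistic(m, sam_design("two_class_unpaired", labels = lab), 0.2)
  d2 <- sam_statistic(m, sam_design("two_class_unpaired", labels = swap),
                      0.2)
  expect_equal(d1, -d2, tolerance = 1e-12)
})

test_that("fudge factor follows the grid-search oracle and its tie rules", {
  m <- rand_matrix(300, 6, seed = 19)
  m[1:30, 4:6] <- m[1:30, 4:6] + 2
  des <- two_class_design()
  s0 <- estimate_s0(m, des)
  # exhaustive oracle over the same candidate grid
  p_r <- rowMeans(m[, 4:6]) - rowMeans(m[, 1:3])
  ss <- rowSums((m[, 1:3] - rowMeans(m[, 1:3]))^2) +
    rowSums((m[, 4:6] - rowMeans(m[, 4:6]))^2)
  p_s <- sqrt((1 / 3 + 1 / 3) / 4 * ss)
  alphas <- seq(0, 1, by = 0.05)
  cands <- quantile(p_s, alphas, names = FALSE)
  brks <- unique(quantile(p_s, seq(0, 1, length.out = 101), names = FALSE))
  grp <- cut(p_s, brks, include.lowest = TRUE)
  cv <- sapply(cands, function(c0) {
    mads <- tapply(p_r / (p_s + c0), grp, mad)
    sd(mads) / mean(mads)
  })
  expect_equal(s0, cands[which.min(cv)], tolerance = 1e-12)

  # gene-order permutation invariance
  perm <- sample(nrow(m))
  expect_equal(estimate_s0(m[perm, ], des), s0, tolerance = 1e-12)

  # all s_i equal -> smallest candidate percentile = that common value
  meq <- matrix(rep(c(0, 1, 2, 3, 4, 5), each = 120), 120, 6,
                dimnames = list(sprintf("g%03d", 1:120),
                                sprintf("s%d", 1:6)))
  common_s <- unname(sqrt(
    (2 / 3) / 4 * (rowSums((meq[, 1:3] - rowMeans(meq[, 1:3]))^2) +
                     rowSums((meq[, 4:6] - rowMeans(meq[, 4:6]))^2)))[1])
  expect_equal(estimate_s0(meq, des), common_s)
})

test_that("3v3 permutation null is enumerated exhaustively and matches the exact mean", {
  m <- rand_matrix(30, 6, seed = 25)
  des <- two_class_design(n_permutations = 100, seed = 2)
  s0 <- 0.2
  nn <- permutation_null(m, des, s0)
  expect_equal(nn$n_effective_permutations, 20)   # C(6,3)
  expect_true(nn$exhaustive)

  # independent exhaustive oracle over label assignments
  combos <- combn(6, 3)
  d_exp <- matrix(0, 30, ncol(combos))
  for (j in seq_len(ncol(combos))) {
    lab <- rep("B", 6)
    lab[combos[, j]] <- "A"
    d_exp[, j] <- sort(oracle_two_class_d(m, lab, s0))
  }
  expect_equal(nn$d_expected, rowMeans(d_exp), tolerance = 1e-12)
})

test_that("sampled permutations are seeded, identity-free and reproducible", {
  m <- rand_matrix(50, 10, seed = 30)
  des <- two_class_design(5, 5, n_permutations = 60, seed = 11)
  nn1 <- permutation_null(m, des, 0.1)
  nn2 <- permutation_null(m, des, 0.1)
  expect_false(nn1$exhaustive)       # C(10,5) = 252 > 60
  expect_identical(nn1$null_d_sorted, nn2$null_d_sorted)
  perms <- stromasig:::sam_permutations(des)$perms
  expect_false(any(apply(perms, 1, identical, des$labels)))
})

test_that("sampled null agrees with exhaustive null within Monte-Carlo error", {
  m <- rand_matrix(60, 8, seed = 41)
  des_ex <- two_class_design(4, 4, n_permutations = 100, seed = 1)
  nn_ex <- permutation_null(m, des_ex, 0.2)       # C(8,4) = 70, exhaustive
  expect_true(nn_ex$exhaustive)
  des_s <- two_class_design(4, 4, n_permutations = 69, seed = 1)
  nn_s <- permutation_null(m, des_s, 0.2)         # forced sampling
  expect_false(nn_s$exhaustive)
  mc_se <- apply(nn_ex$null_d_sorted, 1, sd) / sqrt(69)
  expect_true(all(abs(nn_s$d_expected - nn_ex$d_expected) <
                    4 * mc_se + 0.05))
})

test_that("blocked permutations stay within blocks with the right count", {
  labels <- rep(c("mock", "stim"), 3)
  blocks <- rep(c("b1", "b2", "b3"), each = 2)
  des <- sam_design("two_class_blocked", labels = labels, blocks = blocks,
                    n_permutations = 100)
  pp <- stromasig:::sam_permutations(des)
  expect_equal(nrow(pp$perms), 8)     # 2^3 within-block arrangements
  expect_true(pp$exhaustive)
  for (i in seq_len(nrow(pp$perms))) {
    for (b in unique(blocks)) {
      expect_setequal(pp$perms[i, blocks == b], c("mock", "stim"))
    }
  }
  # a block missing one class is a design error
  expect_error(sam_design("two_class_blocked",
                          labels = c("mock", "mock", "stim", "stim"),
                          blocks = c("b1", "b1", "b2", "b2")),
               class = "stromasig_design_error")
})

test_that("delta selection is monotone and honours the FDR target machinery", {
  set.seed(55)
  m <- rand_matrix(500, 8, seed = 55)
  m[1:40, 5:8] <- m[1:40, 5:8] + 3
  des <- two_class_design(4, 4, target_fdr = 0.05)
  fit <- run_sam(m, des)
  tab <- fit$selection$fdr_table
  # raising delta never adds a called gene
  expect_true(all(diff(tab$n_called) <= 0))
  # the largest delta calls nothing
  expect_equal(tab$n_called[nrow(tab)], 0)
  # significant sets are disjoint and reproducible
  expect_length(intersect(fit$selection$significant_up,
                          fit$selection$significant_down), 0)
  fit2 <- run_sam(m, des)
  expect_identical(fit$selection$significant_up,
                   fit2$selection$significant_up)
  # most planted genes are recovered at a liberal target
  expect_gte(length(intersect(fit$selection$significant_up,
                              sprintf("g%03d", 1:40))), 35)
})

test_that("null data produce a symmetric observed-vs-expected picture", {
  m <- rand_matrix(400, 6, seed = 60)
  des <- two_class_design()
  s0 <- estimate_s0(m, des)
  d <- sam_statistic(m, des, s0)
  nn <- permutation_null(m, des, s0)
  expect_lt(abs(mean(sort(d) - nn$d_expected)), 0.1)
})

test_that("planted two-class signal is recovered at FDR 1% with high recall", {
  set.seed(70)
  # 12 vs 12 so a 2-SD shift is detectable at a 1% FDR
  m <- rand_matrix(2000, 24, seed = 70)
  m[1:100, 13:24] <- m[1:100, 13:24] + 2    # 100 genes shifted 2 SD
  des <- two_class_design(12, 12, target_fdr = 0.01)
  fit <- run_sam(m, des)
  called <- c(fit$selection$significant_up, fit$selection$significant_down)
  recall <- mean(sprintf("g%03d", 1:100) %in% called)
  expect_gte(recall, 0.9)
})

test_that("tidy and glance expose the fit in broom shape", {
  m <- rand_matrix(150, 6, seed = 80)
  fit <- run_sam(m, two_class_design())
  td <- tidy(fit)
  expect_equal(nrow(td), 150)
  expect_named(td, c("gene_id", "d", "d_expected", "called", "direction"))
  # d_expected column carries the expected order statistic at each rank
  expect_equal(sort(td$d_expected), fit$d_expected)
  gl <- glance(fit)
  expect_equal(gl$n_genes, 150)
  expect_equal(gl$n_permutations, 20)
})
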