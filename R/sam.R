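#' Describe a significance-analysis design
#'
#' Three designs are supported: `two_class_unpaired` (relative-difference
#' statistic between two groups), `multiclass` (F-like statistic of
#' between-class over within-class variation), and `two_class_blocked`
#' (two-class statistic with label permutations restricted to within-block
#' swaps, e.g. blocks = cell lines).
#'
#' @param mode One of `"two_class_unpaired"`, `"multiclass"`,
#'   `"two_class_blocked"`.
#' @param labels Per-sample class labels.
#' @param blocks Per-sample block ids (required iff blocked mode).
#' @param n_permutations Label permutations for the null (all distinct
#'   permutations are enumerated exhaustively when there are no more than
#'   this many).
#' @param seed Integer seed for sampled permutations.
#' @param target_fdr Target false discovery rate for gene selection.
#' @return A `sam_design` object.
#' @export
sam_design <- function(mode = c("two_class_unpaired", "multiclass",
                                "two_class_blocked"),
                       labels, blocks = NULL, n_permutations = 100,
                       seed = 1L, target_fdr = 0.01) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  tab <- table(labels)
  if (mode %in% c("two_class_unpaired", "two_class_blocked")) {
    if (length(classes) != 2 || any(tab < 2)) {
      abort("sam_design: two-class modes need exactly 2 classes with >= 2 samples each",
            class = "stromasig_design_error")
    }
  } else if (length(classes) < 2 || any(tab < 2)) {
    abort("sam_design: multiclass needs >= 2 classes with >= 2 samples each",
          class = "stromasig_design_error")
  }
  if (mode == "two_class_blocked") {
    if (is.null(blocks) || length(blocks) != length(labels)) {
      abort("sam_design: blocked mode needs per-sample `blocks`",
            class = "stromasig_design_error")
    }
    for (b in unique(blocks)) {
      if (length(unique(labels[blocks == b])) != 2) {
        abort(paste0("sam_design: block `", b,
                     "` does not contain both classes"),
              class = "stromasig_design_error")
      }
    }
  } else {
    blocks <- NULL
  }
  structure(list(mode = mode, labels = labels, classes = classes,
                 blocks = blocks, n_permutations = n_permutations,
                 seed = as.integer(seed), target_fdr = target_fdr),
            class = "sam_design")
}

# numerator r_i and standard error s_i of the statistic for given labels
sam_parts <- function(m, labels, classes, mode) {
  if (mode == "multiclass") {
    ks <- classes
    n_k <- vapply(ks, function(k) sum(labels == k), numeric(1))
    n <- sum(n_k)
    means <- vapply(ks, function(k)
      rowMeans(m[, labels == k, drop = FALSE]), numeric(nrow(m)))
    grand <- rowMeans(m)
    between <- rowSums(sweep((means - grand)^2, 2, n_k, `*`))
    r <- sqrt((n / prod(n_k)) * between)
    ss_within <- rowSums(vapply(seq_along(ks), function(j) {
      x <- m[, labels == ks[j], drop = FALSE]
      rowSums((x - means[, j])^2)
    }, numeric(nrow(m))))
    s <- sqrt(sum(1 / n_k) / (n - length(ks)) * ss_within)
  } else {
    i1 <- labels == classes[1]
    i2 <- labels == classes[2]
    n1 <- sum(i1)
    n2 <- sum(i2)
    m1 <- rowMeans(m[, i1, drop = FALSE])
    m2 <- rowMeans(m[, i2, drop = FALSE])
    ss <- rowSums((m[, i1, drop = FALSE] - m1)^2) +
      rowSums((m[, i2, drop = FALSE] - m2)^2)
    r <- m2 - m1
    s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * ss)
  }
  list(r = r, s = s)
}

#' Per-gene modified statistic
#'
#' Two-class: `d = (mean2 - mean1) / (s + s0)` with `s` the pooled standard
#' error (class 2 is the lexically larger label). Multiclass: square root of
#' the between-class sum of squares scaled by the class sizes over the
#' pooled within-class standard error, again stabilised by `s0`.
#'
#' @param expr Wide expression tibble (or numeric matrix), complete
#'   (imputed).
#' @param design A [sam_design()].
#' @param s0 Fudge factor added to each gene's standard error.
#' @return Named numeric vector of per-gene statistics.
#' @export
sam_statistic <- function(expr, design, s0) {
  m <- if (is.matrix(expr)) expr else expr_matrix(expr)
  if (anyNA(m)) {
    abort("sam_statistic: matrix contains missing values; impute first",
          class = "stromasig_input_error")
  }
  if (length(design$labels) != ncol(m)) {
    abort("sam_statistic: labels do not match the number of samples",
          class = "stromasig_design_error")
  }
  p <- sam_parts(m, design$labels, design$classes, design$mode)
  setNames(p$r / (p$s + s0), rownames(m))
}

#' Estimate the fudge factor
#'
#' Follows the exchangeability-factor convention of the cited significance
#' analysis: candidate values are the percentiles (0, 5, ..., 100) of the
#' per-gene standard errors `s_i`; the candidate minimising the coefficient
#' of variation of the median-absolute-deviation of the modified statistic
#' across `s_i`-quantile windows is chosen. Ties (including the degenerate
#' all-equal-`s_i` case) resolve to the smallest candidate percentile.
#'
#' @inheritParams sam_statistic
#' @return The estimated `s0` (>= 0).
#' @export
estimate_s0 <- function(expr, design) {
  m <- if (is.matrix(expr)) expr else expr_matrix(expr)
  if (nrow(m) < 100) {
    warn("estimate_s0: fewer than 100 genes; the fudge factor is unstable")
  }
  p <- sam_parts(m, design$labels, design$classes, design$mode)
  alphas <- seq(0, 1, by = 0.05)
  cands <- quantile(p$s, alphas, names = FALSE, type = 7)
  brks <- unique(quantile(p$s, seq(0, 1, length.out = 101), names = FALSE))
  grp <- if (length(brks) > 1) {
    cut(p$s, breaks = brks, include.lowest = TRUE)
  } else {
    factor(rep(1, length(p$s)))
  }
  cvs <- vapply(cands, function(s0c) {
    d <- p$r / (p$s + s0c)
    mads <- tapply(d, grp, mad)
    mads <- mads[!is.na(mads)]
    if (length(mads) < 2 || mean(mads) == 0) return(Inf)
    sd(mads) / mean(mads)
  }, numeric(1))
  cvs[!is.finite(cvs)] <- Inf
  cands[which.min(cvs)]
}

# ---- permutation machinery ----------------------------------------------

# all distinct permutations of a label multiset (call only when few)
multiset_perms <- function(labels) {
  if (length(labels) <= 1) return(list(labels))
  out <- list()
  for (u in unique(labels)) {
    rest <- labels[-match(u, labels)]
    for (p in multiset_perms(rest)) out <- c(out, list(c(u, p)))
  }
  out
}

n_distinct_perms <- function(labels) {
  tab <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
}

# label matrix (one row per permutation) for a design
sam_permutations <- function(design) {
  labels <- design$labels
  n <- length(labels)
  B <- design$n_permutations
  if (design$mode == "two_class_blocked") {
    blocks <- design$blocks
    ub <- unique(blocks)
    total <- prod(vapply(ub, function(b)
      n_distinct_perms(labels[blocks == b]), numeric(1)))
    if (total <= B) {
      per_block <- lapply(ub, function(b)
        do.call(rbind, multiset_perms(labels[blocks == b])))
      grid <- expand.grid(lapply(per_block, function(p) seq_len(nrow(p))))
      perms <- t(apply(grid, 1, function(row) {
        lab <- labels
        for (j in seq_along(ub)) {
          lab[blocks == ub[j]] <- per_block[[j]][row[j], ]
        }
        lab
      }))
      return(list(perms = perms, exhaustive = TRUE))
    }
    set.seed(design$seed)
    perms <- matrix(NA_character_, B, n)
    for (i in seq_len(B)) {
      repeat {
        lab <- labels
        for (b in ub) {
          idx <- which(blocks == b)
          lab[idx] <- sample(lab[idx])
        }
        if (!identical(lab, labels)) break
      }
      perms[i, ] <- lab
    }
    return(list(perms = perms, exhaustive = FALSE))
  }
  total <- n_distinct_perms(labels)
  if (total <= B + 0.5) {
    perms <- do.call(rbind, multiset_perms(labels))
    return(list(perms = perms, exhaustive = TRUE))
  }
  set.seed(design$seed)
  perms <- matrix(NA_character_, B, n)
  for (i in seq_len(B)) {
    repeat {
      lab <- sample(labels)
      if (!identical(lab, labels)) break
    }
    perms[i, ] <- lab
  }
  list(perms = perms, exhaustive = FALSE)
}

#' Permutation null of the ordered statistics
#'
#' Recomputes the per-gene statistic under permutations of the class labels
#' (within blocks for the blocked design), sorts each permuted statistic
#' vector, and averages order statistics across permutations to obtain the
#' expected ordered statistics. When the number of distinct label
#' permutations does not exceed `n_permutations` they are enumerated
#' exhaustively (the identity included); otherwise permutations are sampled
#' with the design seed, excluding the identity.
#'
#' @inheritParams sam_statistic
#' @param s0 Fudge factor used for all permuted statistics.
#' @return A list: `d_expected` (ascending expected order statistics),
#'   `null_d_sorted` (genes x permutations matrix of sorted null
#'   statistics), `n_effective_permutations`, `exhaustive`.
#' @export
permutation_null <- function(expr, design, s0) {
  m <- if (is.matrix(expr)) expr else expr_matrix(expr)
  pp <- sam_permutations(design)
  B <- nrow(pp$perms)
  null_sorted <- matrix(NA_real_, nrow(m), B)
  for (i in seq_len(B)) {
    p <- sam_parts(m, pp$perms[i, ], design$classes, design$mode)
    null_sorted[, i] <- sort(p$r / (p$s + s0))
  }
  list(d_expected = rowMeans(null_sorted),
       null_d_sorted = null_sorted,
       n_effective_permutations = B,
       exhaustive = pp$exhaustive)
}

#' Delta selection against a target false discovery rate
#'
#' Scans a grid of `delta` thresholds. For each, the ordered observed
#' statistics are compared with the expected order statistics from the
#' origin outwards; the first rank whose departure exceeds `delta` sets an
#' asymmetric up (and down) cutoff, and all genes beyond the cutoffs are
#' called. The estimated FDR is the permutation false-positive count
#' (median by default, 90th percentile selectable) scaled by the estimated
#' true-null proportion over the number of calls. The reported gene sets
#' belong to the largest set whose estimated FDR does not exceed
#' `target_fdr`.
#'
#' @param d_observed Named per-gene statistics.
#' @param d_expected Expected order statistics (ascending).
#' @param null_d_sorted Sorted null statistic matrix from
#'   [permutation_null()].
#' @param target_fdr Target FDR.
#' @param pi0 `"iqr"` estimates the true-null proportion from the fraction
#'   of observed statistics inside the permutation interquartile range;
#'   `"one"` uses the conservative value 1.
#' @param fp_summary `"median"` (default) or `"p90"` summary of permutation
#'   false-positive counts.
#' @param n_delta Grid resolution.
#' @return A list with `delta`, `cut_up`, `cut_low`, `significant_up`,
#'   `significant_down`, `pi0`, and the full `fdr_table` tibble.
#' @export
select_significant <- function(d_observed, d_expected, null_d_sorted,
                               target_fdr = 0.01, pi0 = c("iqr", "one"),
                               fp_summary = c("median", "p90"),
                               n_delta = 200) {
  pi0 <- match.arg(pi0)
  fp_summary <- match.arg(fp_summary)
  g <- length(d_observed)
  ord <- order(d_observed)
  ds <- d_observed[ord]
  de <- d_expected
  stopifnot(length(de) == g)

  null_all <- as.vector(null_d_sorted)
  q <- quantile(null_all, c(0.25, 0.75), names = FALSE)
  pi0_hat <- if (pi0 == "iqr") {
    min(1, sum(d_observed > q[1] & d_observed < q[2]) / (0.5 * g))
  } else 1

  i_up0 <- which(de >= 0)[1]
  i_dn0 <- if (any(de <= 0)) max(which(de <= 0)) else NA_integer_
  dmax <- max(abs(ds - de))
  deltas <- seq(0, dmax, length.out = n_delta)

  cuts <- vapply(deltas, function(delta) {
    cu <- Inf
    if (!is.na(i_up0)) {
      idx <- which(ds - de > delta)
      idx <- idx[idx >= i_up0]
      if (length(idx) > 0) cu <- ds[min(idx)]
    }
    cl <- -Inf
    if (!is.na(i_dn0)) {
      idx <- which(de - ds > delta)
      idx <- idx[idx <= i_dn0]
      if (length(idx) > 0) cl <- ds[max(idx)]
    }
    c(cu, cl)
  }, numeric(2))

  fp_fun <- if (fp_summary == "median") median else
    function(x) quantile(x, 0.9, names = FALSE)
  tab <- purrr::map_dfr(seq_along(deltas), function(j) {
    cu <- cuts[1, j]
    cl <- cuts[2, j]
    n_up <- sum(d_observed >= cu)
    n_dn <- sum(d_observed <= cl)
    n_called <- n_up + n_dn
    fp <- fp_fun(colSums(null_d_sorted >= cu) + colSums(null_d_sorted <= cl))
    tibble(delta = deltas[j], cut_up = cu, cut_low = cl,
           n_called_up = n_up, n_called_down = n_dn, n_called = n_called,
           false_positives = fp,
           fdr = ifelse(n_called == 0, 0, pi0_hat * fp / n_called))
  })

  ok <- which(tab$fdr <= target_fdr)
  if (length(ok) == 0) {
    chosen <- tab[nrow(tab), ]
    sig_up <- character(0)
    sig_dn <- character(0)
  } else {
    chosen <- tab[ok[which.max(tab$n_called[ok])], ]
    sig_up <- names(d_observed)[d_observed >= chosen$cut_up]
    sig_dn <- names(d_observed)[d_observed <= chosen$cut_low]
  }
  list(delta = chosen$delta, cut_up = chosen$cut_up,
       cut_low = chosen$cut_low, significant_up = sig_up,
       significant_down = sig_dn, pi0 = pi0_hat, fdr = chosen$fdr,
       fdr_table = tab)
}

#' Run the full significance analysis
#'
#' Orchestrates fudge-factor estimation, the observed statistic, the
#' permutation null, and delta/FDR selection, and records every tuning
#' value in the returned fit.
#'
#' @inheritParams sam_statistic
#' @param pi0,fp_summary Passed to [select_significant()].
#' @return A `sam_fit` object; see [tidy.sam_fit()] and
#'   [glance.sam_fit()].
#' @export
run_sam <- function(expr, design, pi0 = "iqr", fp_summary = "median") {
  m <- if (is.matrix(expr)) expr else expr_matrix(expr)
  s0 <- estimate_s0(m, design)
  d <- sam_statistic(m, design, s0)
  nn <- permutation_null(m, design, s0)
  sel <- select_significant(d, nn$d_expected, nn$null_d_sorted,
                            target_fdr = design$target_fdr, pi0 = pi0,
                            fp_summary = fp_summary)
  structure(list(design = design, s0 = s0, d_observed = d,
                 d_expected = nn$d_expected,
                 null_d_sorted = nn$null_d_sorted,
                 n_effective_permutations = nn$n_effective_permutations,
                 exhaustive = nn$exhaustive, selection = sel),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("Significance analysis (", x$design$mode, ")\n", sep = "")
  cat("  genes:", length(x$d_observed),
      " permutations:", x$n_effective_permutations,
      if (x$exhaustive) "(exhaustive)" else "(sampled)", "\n")
  cat("  s0:", signif(x$s0, 4), " delta:", signif(x$selection$delta, 4),
      " est. FDR:", signif(x$selection$fdr, 3), "\n")
  cat("  significant: ", length(x$selection$significant_up), " up, ",
      length(x$selection$significant_down), " down\n", sep = "")
  invisible(x)
}

#' Tidy a significance-analysis fit
#'
#' @param x A `sam_fit`.
#' @param ... Unused.
#' @return One row per gene: `gene_id`, `d`, `d_expected` (expected order
#'   statistic at the gene's rank), `called`, `direction`.
#' @method tidy sam_fit
#' @export
tidy.sam_fit <- function(x, ...) {
  ord <- order(x$d_observed)
  de <- numeric(length(ord))
  de[ord] <- x$d_expected
  tibble(
    gene_id = names(x$d_observed),
    d = unname(x$d_observed),
    d_expected = de,
    called = names(x$d_observed) %in%
      c(x$selection$significant_up, x$selection$significant_down),
    direction = case_when(
      names(x$d_observed) %in% x$selection$significant_up ~ "up",
      names(x$d_observed) %in% x$selection$significant_down ~ "down",
      TRUE ~ NA_character_
    )
  )
}

#' @rdname tidy.sam_fit
#' @method glance sam_fit
#' @export
glance.sam_fit <- function(x, ...) {
  tibble(mode = x$design$mode, n_genes = length(x$d_observed),
         s0 = x$s0, delta = x$selection$delta, pi0 = x$selection$pi0,
         fdr = x$selection$fdr, target_fdr = x$design$target_fdr,
         n_significant_up = length(x$selection$significant_up),
         n_significant_down = length(x$selection$significant_down),
         n_permutations = x$n_effective_permutations,
         exhaustive = x$exhaustive)
}

#' Export a fit as a per-gene table plus a tuning sidecar
#'
#' Writes the tidy per-gene table as TSV and the tuning values (s0, delta,
#' seed, FDR table) as JSON next to it.
#'
#' @param x A `sam_fit`.
#' @param path TSV path; the JSON sidecar replaces the extension with
#'   `.json`.
#' @export
write_sam <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  side <- sub("\\.tsv$", "", path)
  jsonlite::write_json(
    list(mode = x$design$mode, s0 = x$s0, delta = x$selection$delta,
         seed = x$design$seed, pi0 = x$selection$pi0,
         target_fdr = x$design$target_fdr,
         n_permutations = x$n_effective_permutations,
         fdr_table = x$selection$fdr_table),
    paste0(side, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
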