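# shared fixture builders

# small wide expression tibble from a matrix given by rows
expr_fixture <- function(values, gene_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(gene_ids, sample_ids)
  as_expr_tibble(m)
}

# one-row spot table with overridable fields
spot_fixture <- function(n = 1, ...) {
  base <- tibble::tibble(
    spot_id = sprintf("sp%02d", seq_len(n)),
    gene_id = sprintf("g%02d", seq_len(n)),
    sample_id = "s1",
    cy5_fg_mean = 500, cy5_bg_median = 100,
    cy3_fg_mean = 500, cy3_bg_median = 100,
    pixel_corr = 0.9, flagged = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# independent transcription of the two-class statistic (oracle)
oracle_two_class_d <- function(m, labels, s0) {
  classes <- sort(unique(labels))
  apply(m, 1, function(x) {
    x1 <- x[labels == classes[1]]
    x2 <- x[labels == classes[2]]
    n1 <- length(x1); n2 <- length(x2)
    sp <- sqrt(((1 / n1 + 1 / n2) / (n1 + n2 - 2)) *
                 (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)))
    (mean(x2) - mean(x1)) / (sp + s0)
  })
}

# independent transcription of the multiclass statistic (oracle)
oracle_multiclass_d <- function(m, labels, s0) {
  classes <- sort(unique(labels))
  apply(m, 1, function(x) {
    n_k <- sapply(classes, function(k) sum(labels == k))
    n <- length(x)
    mk <- sapply(classes, function(k) mean(x[labels == k]))
    r <- sqrt(n / prod(n_k) * sum(n_k * (mk - mean(x))^2))
    ss <- sum(sapply(classes, function(k)
      sum((x[labels == k] - mean(x[labels == k]))^2)))
    s <- sqrt(sum(1 / n_k) / (n - length(classes)) * ss)
    r / (s + s0)
  })
}

# brute-force KNN imputation oracle: exhaustive neighbour search, same
# root-mean-square distance and inverse-distance weighting
oracle_knn_impute <- function(m, k) {
  out <- m
  gm <- rowMeans(m, na.rm = TRUE)
  for (i in seq_len(nrow(m))) {
    for (j in which(is.na(m[i, ]))) {
      d <- sapply(seq_len(nrow(m)), function(l) {
        if (l == i) return(Inf)
        co <- !is.na(m[i, ]) & !is.na(m[l, ])
        if (!any(co)) return(Inf)
        sqrt(mean((m[i, co] - m[l, co])^2))
      })
      donors <- order(d)
      donors <- donors[is.finite(d[donors]) & !is.na(m[donors, j])]
      donors <- donors[seq_len(min(k, length(donors)))]
      if (length(donors) == 0) {
        out[i, j] <- gm[i]
      } else {
        w <- 1 / (d[donors] + 1e-6)
        out[i, j] <- sum(w * m[donors, j]) / sum(w)
      }
    }
  }
  out
}

# naive UPGMA oracle: recompute average inter-cluster distance from the raw
# pairwise matrix at every step
oracle_upgma <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), function(i)
    list(id = -i, members = i, minleaf = i))
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- NULL; best_d <- Inf
    k <- length(clusters)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      avg <- mean(d[clusters[[i]]$members, clusters[[j]]$members])
      tie <- abs(avg - best_d) <= 1e-12
      better <- avg < best_d - 1e-12
      if (tie && !is.null(best)) {
        cand <- sort(c(clusters[[i]]$minleaf, clusters[[j]]$minleaf))
        cur <- sort(c(clusters[[best[1]]]$minleaf,
                      clusters[[best[2]]]$minleaf))
        better <- cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])
      }
      if (better) { best <- c(i, j); best_d <- avg }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(clusters[[i]]$id, clusters[[j]]$id))
    height[step] <- best_d
    newc <- list(id = step,
                 members = c(clusters[[i]]$members, clusters[[j]]$members),
                 minleaf = min(clusters[[i]]$minleaf,
                               clusters[[j]]$minleaf))
    clusters <- c(clusters[-c(i, j)], list(newc))
  }
  list(merge = merge, height = height)
}
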