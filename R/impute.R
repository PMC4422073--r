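#' K-nearest-neighbour imputation of missing log ratios
#'
#' Replaces each missing value by the inverse-distance-weighted mean of the
#' `k` nearest genes (by Euclidean distance over co-observed samples, scaled
#' by the number of co-observed samples so genes with different missingness
#' are comparable) that carry an observed value at the target sample.
#' Neighbours lacking a value there are skipped in favour of the next
#' nearest; when no donor exists at all the gene's own mean is used and
#' counted. Weighting is `1 / (distance + 1e-6)`, so identical neighbours
#' dominate.
#'
#' @param expr Wide expression tibble; every gene must have at least one
#'   observed value.
#' @param k Number of neighbours (default 10).
#' @return The completed tibble with attributes `imputed_fraction` (fraction
#'   of matrix entries imputed) and `n_gene_mean_fallback`.
#' @export
knn_impute <- function(expr, k = 10) {
  m <- expr_matrix(expr)
  g <- nrow(m)
  if (g < k + 1) {
    abort("knn_impute: need at least k + 1 genes",
          class = "stromasig_input_error")
  }
  n_obs <- rowSums(!is.na(m))
  if (any(n_obs == 0)) {
    abort(paste0("knn_impute: gene(s) with zero observed values: ",
                 paste(head(rownames(m)[n_obs == 0], 5), collapse = ", ")),
          class = "stromasig_input_error")
  }
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss) == 0) {
    out <- expr
    attr(out, "imputed_fraction") <- 0
    attr(out, "n_gene_mean_fallback") <- 0L
    return(out)
  }

  # root-mean-square difference over co-observed samples, all gene pairs
  W <- !is.na(m)
  X0 <- m
  X0[!W] <- 0
  Wn <- W * 1
  sq <- (X0^2) %*% t(Wn)
  cross <- X0 %*% t(X0)
  nco <- Wn %*% t(Wn)
  ss <- sq + t(sq) - 2 * cross
  ss[ss < 0] <- 0                       # numerical guard
  D <- sqrt(ss / nco)                   # NaN where no co-observed samples
  D[!is.finite(D)] <- Inf
  diag(D) <- Inf

  out <- m
  fallback <- 0L
  gene_mean <- rowMeans(m, na.rm = TRUE)
  eps <- 1e-6
  for (gi in unique(miss[, 1])) {
    ord <- order(D[gi, ])
    ord <- ord[is.finite(D[gi, ord])]
    for (ci in miss[miss[, 1] == gi, 2]) {
      donors <- ord[W[ord, ci]]
      donors <- donors[seq_len(min(k, length(donors)))]
      if (length(donors) == 0) {
        out[gi, ci] <- gene_mean[gi]
        fallback <- fallback + 1L
      } else {
        w <- 1 / (D[gi, donors] + eps)
        out[gi, ci] <- sum(w * m[donors, ci]) / sum(w)
      }
    }
  }
  res <- set_expr_values(expr, out)
  attr(res, "imputed_fraction") <- nrow(miss) / length(m)
  attr(res, "n_gene_mean_fallback") <- fallback
  res
}
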