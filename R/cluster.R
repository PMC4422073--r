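#' Uncentered Pearson distance
#'
#' The "non-centered metric" of the Eisen clustering convention:
#' `r_u(x, y) = sum(x*y) / sqrt(sum(x^2) * sum(y^2))` computed over
#' co-observed entries (pairwise deletion), with distance `1 - r_u`. A
#' vector that is all zeros (or has no co-observed entries with its
#' partner) has an undefined norm; its distance to every other vector is
#' defined as 1 and counted in the `n_undefined` attribute.
#'
#' @param expr Wide expression tibble or numeric matrix.
#' @param axis `"genes"` clusters rows, `"samples"` clusters columns.
#' @return Symmetric distance matrix with zero diagonal, labelled by gene
#'   ids or sample ids.
#' @export
uncentered_pearson_distance <- function(expr, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  m <- if (is.matrix(expr)) expr else expr_matrix(expr)
  if (axis == "samples") m <- t(m)
  W <- (!is.na(m)) * 1
  X0 <- m
  X0[is.na(m)] <- 0
  cross <- X0 %*% t(X0)           # sum x_i y_i over co-observed
  sq <- (X0^2) %*% t(W)           # sum x_i^2 over entries co-observed with y
  denom <- sqrt(sq * t(sq))
  r <- cross / denom
  undefined <- !is.finite(r)
  r[undefined] <- 0               # distance 1
  d <- 1 - r
  diag(d) <- 0
  d <- (d + t(d)) / 2
  attr(d, "n_undefined") <- sum(undefined[upper.tri(undefined)])
  d
}

#' Average-linkage hierarchical clustering
#'
#' Classic UPGMA: the distance between two clusters is the unweighted mean
#' of all inter-cluster pairwise distances. Merges are deterministic: among
#' pairs at the minimal distance, the pair whose clusters contain the
#' smallest leaf indices is merged first. Returns an `hclust`-compatible
#' structure (usable with [stats::cutree()]).
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @return An object of class `c("stromasig_dendrogram", "hclust")` with
#'   `merge`, `height`, `order`, `labels`.
#' @export
average_linkage <- function(d) {
  if (!is.matrix(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-10))) {
    abort("average_linkage: distance matrix must be symmetric",
          class = "stromasig_input_error")
  }
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active clusters: id (negative leaf, positive internal node), members,
  # min leaf index for tie-breaks
  active <- lapply(seq_len(n), function(i)
    list(id = -i, members = i, minleaf = i))
  dm <- d
  diag(dm) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  sizes <- rep(1, n)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    # find minimal pair with deterministic tie-break
    best <- NULL
    best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- dm[i, j]
        if (dij < best_d - 1e-12) {
          best_d <- dij
          best <- c(i, j)
        } else if (abs(dij - best_d) <= 1e-12 && !is.null(best)) {
          cand <- sort(c(active[[i]]$minleaf, active[[j]]$minleaf))
          cur <- sort(c(active[[best[1]]]$minleaf, active[[best[2]]]$minleaf))
          if (cand[1] < cur[1] ||
              (cand[1] == cur[1] && cand[2] < cur[2])) {
            best_d <- dij
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]
    j <- best[2]
    a <- active[[i]]
    b <- active[[j]]
    merge[step, ] <- sort(c(a$id, b$id))        # hclust convention
    height[step] <- best_d
    new <- list(id = step, members = c(a$members, b$members),
                minleaf = min(a$minleaf, b$minleaf))
    na_ <- length(a$members)
    nb_ <- length(b$members)
    # Lance-Williams update for UPGMA
    newrow <- (na_ * dm[i, ] + nb_ * dm[j, ]) / (na_ + nb_)
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- dm[keep, keep, drop = FALSE]
    newrow <- newrow[keep]
    dm <- rbind(cbind(dm, newrow), c(newrow, Inf))
    active <- c(active[keep], list(new))
  }
  # leaf order by recursive traversal of the merge tree
  order_of <- function(node) {
    if (node < 0) return(-node)
    c(order_of(merge[node, 1]), order_of(merge[node, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = order_of(n - 1), labels = labels,
                 method = "average", dist.method = "uncentered_pearson",
                 call = match.call()),
            class = c("stromasig_dendrogram", "hclust"))
}

#' Cut a dendrogram into its two root subtrees
#'
#' Removes the root merge and labels the two resulting subtrees; group 1 is
#' the subtree containing the smallest leaf index, making labels invariant
#' to input row reordering.
#'
#' @param dend An [average_linkage()] result.
#' @return Named integer vector (1 or 2) per leaf label.
#' @export
cut_two_groups <- function(dend) {
  n <- length(dend$labels)
  if (n < 2) abort("cut_two_groups: need >= 2 leaves",
                   class = "stromasig_input_error")
  grp <- stats::cutree(dend, k = 2)
  # group 1 = group of the smallest leaf index
  if (grp[1] != 1) grp <- 3L - grp
  setNames(as.integer(grp), dend$labels)
}

#' Write clustered output for tree viewers
#'
#' Emits the CDT/GTR/ATR trio understood by TreeView-style software: the
#' reordered data table with GID/AID links, and gene/array tree files whose
#' node scores are `1 - merge height` (a correlation-like similarity).
#'
#' @param expr Wide expression tibble.
#' @param gene_dend Optional gene dendrogram from [average_linkage()].
#' @param sample_dend Optional sample dendrogram.
#' @param basename Output path without extension.
#' @return Invisibly, the paths written.
#' @export
write_cdt <- function(expr, gene_dend = NULL, sample_dend = NULL,
                      basename) {
  m <- expr_matrix(expr)
  gorder <- if (!is.null(gene_dend)) gene_dend$order else seq_len(nrow(m))
  sorder <- if (!is.null(sample_dend)) sample_dend$order else
    seq_len(ncol(m))
  gid <- sprintf("GENE%dX", seq_len(nrow(m)))
  aid <- sprintf("ARRY%dX", seq_len(ncol(m)))
  paths <- character(0)

  write_tree <- function(dend, ids, path, prefix) {
    n <- length(ids)
    rows <- purrr::map_chr(seq_len(n - 1), function(i) {
      node <- function(x) if (x < 0) ids[-x] else
        sprintf("%s%dX", prefix, x)
      paste(sprintf("%s%dX", prefix, i),
            node(dend$merge[i, 1]), node(dend$merge[i, 2]),
            format(1 - dend$height[i], digits = 10), sep = "\t")
    })
    writeLines(rows, path)
    path
  }
  if (!is.null(gene_dend)) {
    paths <- c(paths, write_tree(gene_dend, gid,
                                 paste0(basename, ".gtr"), "NODE"))
  }
  if (!is.null(sample_dend)) {
    paths <- c(paths, write_tree(sample_dend, aid,
                                 paste0(basename, ".atr"), "NODE"))
  }

  cdt <- paste0(basename, ".cdt")
  con <- file(cdt, "w")
  on.exit(close(con))
  name <- if ("symbol" %in% names(expr)) expr$symbol else expr$gene_id
  header <- c("GID", "ID", "NAME", "GWEIGHT", colnames(m)[sorder])
  writeLines(paste(header, collapse = "\t"), con)
  if (!is.null(sample_dend)) {
    writeLines(paste(c("AID", "", "", "", aid[sorder]), collapse = "\t"),
               con)
  }
  writeLines(paste(c("EWEIGHT", "", "", "",
                     rep("1", ncol(m))), collapse = "\t"), con)
  for (i in gorder) {
    vals <- m[i, sorder]
    vals <- ifelse(is.na(vals), "", format(vals, digits = 10))
    writeLines(paste(c(gid[i], rownames(m)[i], name[i], "1", vals),
                     collapse = "\t"), con)
  }
  invisible(c(paths, cdt))
}
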