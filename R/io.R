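#' Read and write PCL-style expression matrices
#'
#' The PCL layout is tab-delimited text: first column the unique identifier
#' (`ID`), second a display name (`NAME`), an optional `GWEIGHT` column, one
#' column per sample, and an optional second header row of `EWEIGHT`s.
#' Missing values are empty fields.
#'
#' @param path File path.
#' @return `read_pcl()`: a wide expression tibble (`gene_id`, `symbol`,
#'   sample columns).
#' @export
read_pcl <- function(path) {
  header <- strsplit(readr::read_lines(path, n_max = 2), "\t")
  cols <- header[[1]]
  skip <- if (length(header) > 1 && header[[2]][1] == "EWEIGHT") 2L else 1L
  raw <- readr::read_tsv(path, skip = skip, col_names = cols,
                         na = c("", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  has_gweight <- "GWEIGHT" %in% cols
  out <- raw %>%
    rename(gene_id = 1, symbol = 2) %>%
    select(-dplyr::any_of("GWEIGHT"))
  as_tibble(out)
}

#' @rdname read_pcl
#' @param expr Wide expression tibble.
#' @param gweight,eweight Emit unit gene/array weight rows.
#' @export
write_pcl <- function(expr, path, gweight = TRUE, eweight = TRUE) {
  ids <- sample_ids(expr)
  name <- if ("symbol" %in% names(expr)) expr$symbol else expr$gene_id
  out <- tibble(ID = expr$gene_id, NAME = name)
  if (gweight) out$GWEIGHT <- 1
  out <- dplyr::bind_cols(out, expr[, ids, drop = FALSE])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (eweight) {
    ew <- c("EWEIGHT", "", if (gweight) "", rep("1", length(ids)))
    writeLines(paste(ew, collapse = "\t"), con)
  }
  body <- apply(out, 1, function(r) {
    r[is.na(r)] <- ""
    paste(r, collapse = "\t")
  })
  writeLines(body, con)
  invisible(path)
}

# GenePix-results-compatible column aliases for spot tables
.spot_col_map <- c(
  spot_id = "spot_id", gene_id = "gene_id", sample_id = "sample_id",
  cy5_fg_mean = "cy5_fg_mean", cy5_bg_median = "cy5_bg_median",
  cy3_fg_mean = "cy3_fg_mean", cy3_bg_median = "cy3_bg_median",
  pixel_corr = "pixel_corr", flagged = "flagged",
  "F635 Mean" = "cy5_fg_mean", "B635 Median" = "cy5_bg_median",
  "F532 Mean" = "cy3_fg_mean", "B532 Median" = "cy3_bg_median",
  "Rgn R2" = "pixel_corr", "Flags" = "flagged", "ID" = "gene_id",
  "Name" = "spot_id"
)

#' Read a spot-level table
#'
#' Tab-delimited spot tables are accepted with either the package's own
#' column names or GenePix-results-style names (`F635 Mean`, `B635 Median`,
#' `F532 Mean`, `B532 Median`, `Rgn R2`, `Flags`); a GenePix `Flags` column
#' of negative values is interpreted as flagged.
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping file columns to
#'   canonical names, overriding the built-in aliases.
#' @return A spot tibble.
#' @export
read_spot_table <- function(path, column_map = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  map <- .spot_col_map
  if (!is.null(column_map)) map <- c(column_map, map)
  hits <- intersect(names(raw), names(map))
  names(raw)[match(hits, names(raw))] <- unname(map[hits])
  if (is.numeric(raw$flagged)) raw$flagged <- raw$flagged < 0
  need <- c("spot_id", "gene_id", "sample_id", "cy5_fg_mean",
            "cy5_bg_median", "cy3_fg_mean", "cy3_bg_median", "pixel_corr",
            "flagged")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("read_spot_table: missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "stromasig_input_error")
  }
  as_tibble(raw[, union(need, names(raw))])
}

#' Read a clinical survival table
#'
#' Expects tab-delimited columns `sample_id`, `time`, `event`, optional
#' `cause` and `stage`.
#'
#' @param path File path.
#' @return A clinical tibble.
#' @export
read_clinical <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("read_clinical: missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "stromasig_input_error")
  }
  as_tibble(raw)
}
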