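#' Read a DepMap-style cell line x gene matrix CSV
#'
#' First column holds cell-line identifiers; remaining columns are genes.
#' Column headers in the `"SYMBOL (entrezid)"` dialect are stripped to the
#' plain symbol; symbols are trimmed and uppercased.
#'
#' @param path CSV file path.
#' @return Numeric matrix with cell-line rownames and gene colnames.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- normalize_symbol(sub("\\s*\\(.*\\)$", "", colnames(m)))
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_csv
#' @export
read_expression_csv <- read_matrix_csv

#' Write a cell line x gene matrix as CSV
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(cell_line = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mutation table
#'
#' Default dialect: columns `cell_line`, `gene`, `is_silent`,
#' `is_deleterious`, `is_hotspot` with `true`/`false` flags. Other
#' dialects (e.g. DepMap mutation exports) are supported through
#' `column_map`, a named list mapping these five canonical names to the
#' file's column names.
#'
#' @param path CSV file path.
#' @param column_map Optional named list, e.g.
#'   `list(cell_line = "DepMap_ID", gene = "Hugo_Symbol", ...)`.
#' @return Data frame with the five canonical columns; flags logical,
#'   gene symbols normalized.
#' @export
read_mutation_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  wanted <- c("cell_line", "gene", "is_silent", "is_deleterious",
              "is_hotspot")
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      names(df)[names(df) == column_map[[nm]]] <- nm
    }
  }
  missing <- setdiff(wanted, names(df))
  if (length(missing) > 0L) {
    stop("mutation table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- df[, wanted]
  for (fl in c("is_silent", "is_deleterious", "is_hotspot")) {
    out[[fl]] <- as.logical(out[[fl]])
  }
  out$gene <- normalize_symbol(out$gene)
  bad <- out$is_hotspot & out$is_silent
  if (any(bad)) {
    stop(sum(bad), " record(s) flagged both hotspot and silent",
         call. = FALSE)
  }
  out
}
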