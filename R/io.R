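#' Read a samples x proteins intensity table
#'
#' The first column holds sample identifiers; the header row holds gene
#' symbols. Values must be numeric and non-negative; the missingness sentinel
#' 0.0099 is preserved verbatim (no NA conversion).
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Numeric matrix with sample ids as row names and gene symbols as
#'   column names, in input order.
#' @export
read_intensity_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2) stop("intensity table needs sample ids plus >= 1 protein")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate sample identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  syms <- colnames(df)[-1]
  if (anyDuplicated(syms))
    stop("duplicate protein symbol(s): ",
         paste(unique(syms[duplicated(syms)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at row ", bad[1], " (sample ", ids[bad[1]],
         "), column ", syms[bad[2]])
  }
  if (any(num < 0)) stop("negative intensity values are not allowed")
  dimnames(num) <- list(ids, syms)
  num
}

#' Write a samples x proteins intensity table
#'
#' Numbers are formatted with 17 significant digits so that a write/read
#' round trip reproduces the doubles bit-exactly.
#'
#' @param matrix Numeric matrix with row and column names.
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_intensity_table <- function(matrix, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  chr <- apply(matrix, 2, function(x) formatC(x, digits = 17, format = "g"))
  lines <- c(
    paste(c("sample_id", colnames(matrix)), collapse = sep),
    paste(rownames(matrix), apply(chr, 1, paste, collapse = sep), sep = sep)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' @param path Two-column TSV/CSV with header `sample_id`, `group`.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Data frame with columns sample_id, group, class (0/1).
#' @export
read_annotation <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(ann)))
    stop("annotation needs columns sample_id and group")
  ann$class <- binarize_labels(ann$group)
  ann
}

#' Write a generic results table as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
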