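## Feature grammar over protein columns
##
## expression := operand ( '/' operand | '*' operand )?
## operand    := SYMBOL | sum | '(' sum ')'
## sum        := SYMBOL ('+' SYMBOL)+
##
## 'A/B' is a ratio, 'A*B' a product, 'A+B+C' a family sum, a bare symbol a
## raw level. Sums may appear as ratio/product operands when parenthesized.

#' Parse a chaperone-network feature expression
#'
#' @param text Expression string over gene symbols with `/`, `*`, `+` and
#'   parentheses, e.g. `"HSP90AA1/TRAP1"`, `"HSPB1*HSPA9"`,
#'   `"(CCT1+CCT2+CCT5)/HSP90AA1"`.
#' @return A `feature_expr`: list with `name` (the canonical rendering),
#'   `kind` (raw / ratio / product / sum) and `operands` (list of one or two
#'   symbol vectors).
#' @export
parse_feature_expr <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub(" ", "", text)
  if (!nzchar(s)) stop("empty feature expression")
  bad <- regexpr("[^A-Za-z0-9_+*/()]", s)
  if (bad > 0)
    stop("invalid character '", substr(s, bad, bad), "' at position ", bad,
         " in '", text, "'")
  op_pos <- find_toplevel_op(s)
  if (is.null(op_pos)) {
    members <- parse_sum(s, text)
    if (length(members) == 1)
      return(new_feature_expr("raw", list(members)))
    return(new_feature_expr("sum", list(members)))
  }
  op <- substr(s, op_pos, op_pos)
  lhs <- substr(s, 1, op_pos - 1)
  rhs <- substr(s, op_pos + 1, nchar(s))
  if (!nzchar(lhs) || !nzchar(rhs))
    stop("missing operand for '", op, "' at position ", op_pos,
         " in '", text, "'")
  operands <- list(parse_sum(strip_parens(lhs), text),
                   parse_sum(strip_parens(rhs), text))
  new_feature_expr(if (op == "/") "ratio" else "product", operands)
}

## locate a single top-level '/' or '*' (outside parentheses)
find_toplevel_op <- function(s) {
  depth <- 0L
  pos <- NULL
  for (i in seq_len(nchar(s))) {
    ch <- substr(s, i, i)
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0) stop("unbalanced ')' at position ", i, " in '", s, "'")
    } else if (depth == 0L && ch %in% c("/", "*")) {
      if (!is.null(pos))
        stop("more than one top-level operator in '", s,
             "' (second at position ", i, ")")
      pos <- i
    }
  }
  if (depth != 0L) stop("unbalanced '(' in '", s, "'")
  pos
}

strip_parens <- function(s) {
  if (startsWith(s, "(") && endsWith(s, ")")) substr(s, 2, nchar(s) - 1)
  else s
}

parse_sum <- function(s, context) {
  if (grepl("[()]", s))
    stop("nested parentheses are not supported in '", context, "'")
  parts <- strsplit(s, "+", fixed = TRUE)[[1]]
  if (!length(parts) || any(!nzchar(parts)))
    stop("malformed sum '", s, "' in '", context, "'")
  ok <- grepl("^[A-Za-z][A-Za-z0-9_]*$", parts)
  if (!all(ok))
    stop("invalid symbol '", parts[!ok][1], "' in '", context, "'")
  canonicalize_symbols(parts)
}

new_feature_expr <- function(kind, operands) {
  structure(list(name = render_operands(kind, operands), kind = kind,
                 operands = operands), class = "feature_expr")
}

render_operands <- function(kind, operands) {
  wrap <- function(v) if (length(v) > 1)
    paste0("(", paste(v, collapse = "+"), ")") else v
  switch(kind,
    raw = operands[[1]],
    sum = paste(operands[[1]], collapse = "+"),
    ratio = paste0(wrap(operands[[1]]), "/", wrap(operands[[2]])),
    product = paste0(wrap(operands[[1]]), "*", wrap(operands[[2]])))
}

#' Render a feature expression to its canonical string
#'
#' Inverse of [parse_feature_expr()] on canonical strings.
#'
#' @param expr A `feature_expr`.
#' @return Character scalar.
#' @export
render_feature_expr <- function(expr) expr$name

#' @export
print.feature_expr <- function(x, ...) {
  cat("<feature_expr ", x$kind, "> ", x$name, "\n", sep = "")
  invisible(x)
}

#' All gene symbols referenced by a list of feature expressions
#' @param features List of `feature_expr`.
#' @return Character vector of unique symbols.
#' @export
feature_symbols <- function(features)
  unique(unlist(lapply(features, function(f)
    unlist(f$operands, use.names = FALSE))))

#' Evaluate feature expressions over an intensity matrix
#'
#' Sums are evaluated first; ratios divide the numerator by the denominator
#' floored at `epsilon` (the missingness sentinel by default), so division
#' never hits a true zero while a sentinel-over-sentinel ratio evaluates to
#' 1. Sentinel-valued entries enter the arithmetic at their literal value
#' (no imputation).
#'
#' @param matrix Samples x proteins intensity matrix.
#' @param features List of `feature_expr` (or strings, parsed on the fly).
#' @param epsilon Denominator floor (default [MISSING_SENTINEL]).
#' @return Samples x features numeric matrix, feature names as column names,
#'   row order identical to `matrix`.
#' @export
evaluate_feature_set <- function(matrix, features,
                                 epsilon = MISSING_SENTINEL) {
  stopifnot(is.matrix(matrix))
  features <- lapply(features, function(f)
    if (is.character(f)) parse_feature_expr(f) else f)
  missing <- setdiff(feature_symbols(features), colnames(matrix))
  if (length(missing))
    stop("feature(s) reference symbol(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  evl <- function(v) {  # operand value: sum of member columns
    rowSums(matrix[, v, drop = FALSE])
  }
  cols <- lapply(features, function(f) {
    switch(f$kind,
      raw = ,
      sum = evl(f$operands[[1]]),
      ratio = evl(f$operands[[1]]) / pmax(evl(f$operands[[2]]), epsilon),
      product = evl(f$operands[[1]]) * evl(f$operands[[2]]))
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(rownames(matrix),
                        vapply(features, `[[`, "", "name"))
  out
}

#' Default chaperone-network feature set
#'
#' The raw level of every panel protein plus the engineered relationships
#' that encode how the chaperone machinery operates: cytosolic-to-
#' mitochondrial HSP90 ratios (HSP90AA1/TRAP1, HSP90AB1/TRAP1), constitutive
#' to stress-inducible HSP90 (HSP90AB1/HSP90AA1), cochaperone-to-chaperone
#' ratios (FKBP4/HSP90AA1, ST13 to the DNAJ family sum), chaperonin and
#' HSP70 couplings (CCT2/HSP90AB1, HSPA6/TRAP1, HSPB1*HSPA9, HSPA9*TRAP1,
#' CCTs/HSP90AA1) and the HSP70-family-to-DNAJ balance.
#'
#' Features whose symbols are missing from the panel are dropped with a
#' warning.
#'
#' @param panel A `panel_definition` (default [default_panel()]).
#' @return List of `feature_expr`.
#' @export
default_feature_set <- function(panel = default_panel()) {
  dnaj <- "(DNAJA1+DNAJA2+DNAJC11+DNAJB1+DNAJC5+DNAJC13)"
  hsp70 <- "(HSPA2+HSPA6+HSPA8+HSPA12+HSPA5)"
  engineered <- c(
    "HSP90AA1/TRAP1", "HSP90AB1/TRAP1", "HSP90AB1/HSP90AA1",
    "FKBP4/HSP90AA1", "HSPA6/TRAP1", "CCT2/HSP90AB1",
    "HSPB1*HSPA9", "HSPA9*TRAP1",
    "(CCT1+CCT2+CCT5)/HSP90AA1",
    paste0("ST13/", dnaj),
    paste0(hsp70, "/", dnaj)
  )
  exprs <- c(lapply(panel$symbols, function(s) parse_feature_expr(s)),
             lapply(engineered, parse_feature_expr))
  keep <- vapply(exprs, function(f)
    all(unlist(f$operands) %in% panel$symbols), logical(1))
  if (!all(keep))
    warning("dropping feature(s) with symbols outside the panel: ",
            paste(vapply(exprs[!keep], `[[`, "", "name"), collapse = ", "))
  exprs[keep]
}

#' Read feature definitions from a plain-text file
#'
#' One expression per line; `#` starts a comment; blank lines ignored.
#'
#' @param path File path.
#' @return List of `feature_expr`.
#' @export
read_feature_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lapply(lines[nzchar(lines)], parse_feature_expr)
}
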