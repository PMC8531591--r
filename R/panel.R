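## Donor group labels and the binary class split used throughout the pipeline.
.CANCER_GROUPS <- c("GC", "EC", "LC", "BC", "CCA", "CRC")
.NONCANCER_GROUPS <- c("COPD", "PM", "CTL")
.ALL_GROUPS <- c(.CANCER_GROUPS, .NONCANCER_GROUPS)

#' Sentinel value encoding a non-detected protein
#'
#' Urine iFOT tables encode missing (non-detected) protein intensities as the
#' literal constant 0.0099 rather than as NA. Missingness is detected by exact
#' equality to this value.
#'
#' @export
MISSING_SENTINEL <- 0.0099

#' Gene-symbol aliases
#'
#' A small alias table mapping alternative chaperone gene symbols to the
#' canonical symbols used by this package (e.g. TCP1 -> CCT1, CRYAB -> HSPB5,
#' HSP27 -> HSPB1).
#'
#' @return Named character vector: names are aliases, values canonical symbols.
#' @export
symbol_aliases <- function() {
  c(TCP1 = "CCT1", CRYAB = "HSPB5", HSP27 = "HSPB1", HSPB2 = "HSPB1")
}

#' Canonicalize gene symbols through the alias table
#'
#' @param symbols Character vector of gene symbols.
#' @return Character vector with known aliases replaced by canonical symbols.
#' @export
canonicalize_symbols <- function(symbols) {
  al <- symbol_aliases()
  hit <- symbols %in% names(al)
  symbols[hit] <- unname(al[symbols[hit]])
  symbols
}

#' Default HSP / cochaperone panel
#'
#' The default analysis panel: 25 heat-shock proteins and cochaperones
#' spanning the HSP90, HSP70, HSP40/DNAJ, HSPB, HSP110 and chaperonin
#' families plus the cochaperones ST13 (Hip) and FKBP4. Each symbol belongs
#' to exactly one family.
#'
#' @return An object of class `panel_definition`: a list with `symbols`
#'   (character vector) and `families` (named list of member symbol vectors).
#' @export
#' @examples
#' p <- default_panel()
#' length(p$symbols)
default_panel <- function() {
  families <- list(
    HSP90      = c("HSP90AA1", "HSP90AB1", "TRAP1"),
    HSP70      = c("HSPA2", "HSPA4", "HSPA5", "HSPA6", "HSPA8", "HSPA9",
                   "HSPA12"),
    `HSP40/DNAJ` = c("DNAJA1", "DNAJA2", "DNAJB1", "DNAJC5", "DNAJC11",
                     "DNAJC13"),
    HSPB       = c("HSPB1", "HSPB5"),
    HSP110     = c("HSPH1"),
    chaperonin = c("HSPD1", "CCT1", "CCT2", "CCT5"),
    cochaperone = c("ST13", "FKBP4")
  )
  panel_definition(unname(unlist(families)), families)
}

#' Construct a panel definition
#'
#' @param symbols Character vector of gene symbols.
#' @param families Named list mapping family name to member symbols. Every
#'   symbol must belong to exactly one family.
#' @return A `panel_definition` object.
#' @export
panel_definition <- function(symbols, families) {
  symbols <- canonicalize_symbols(symbols)
  families <- lapply(families, canonicalize_symbols)
  members <- unlist(families, use.names = FALSE)
  if (anyDuplicated(members))
    stop("panel families overlap: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  if (!setequal(members, symbols))
    stop("panel families must partition the symbol list")
  structure(list(symbols = symbols, families = families),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("<panel_definition> ", length(x$symbols), " proteins, ",
      length(x$families), " families\n", sep = "")
  for (f in names(x$families))
    cat("  ", f, ": ", paste(x$families[[f]], collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Subset an intensity matrix to a protein panel
#'
#' Returns the panel columns in panel order. Panel symbols absent from the
#' matrix are reported with a warning (not fatal); matrix column names are
#' canonicalized through the alias table before matching.
#'
#' @param matrix Numeric samples x proteins matrix with gene-symbol column
#'   names and sample-id row names.
#' @param panel A `panel_definition` (default [default_panel()]).
#' @return The subset matrix; sample order unchanged.
#' @export
select_panel <- function(matrix, panel = default_panel()) {
  stopifnot(is.matrix(matrix))
  colnames(matrix) <- canonicalize_symbols(colnames(matrix))
  present <- panel$symbols %in% colnames(matrix)
  if (!any(present))
    stop("no panel symbol present in the intensity matrix")
  if (!all(present))
    warning("panel symbols absent from matrix: ",
            paste(panel$symbols[!present], collapse = ", "))
  matrix[, panel$symbols[present], drop = FALSE]
}

#' Exclude proteins with too much sentinel-coded missingness
#'
#' Drops every protein whose fraction of sentinel-valued entries is strictly
#' greater than `max_missing_fraction`; a protein at exactly the threshold is
#' retained. Samples are never removed.
#'
#' @param matrix Numeric samples x proteins matrix.
#' @param sentinel Missingness sentinel value (default [MISSING_SENTINEL]).
#' @param max_missing_fraction Exclusion threshold in `[0, 1]` (default 0.30).
#' @return The filtered matrix, with a `filter_report` attribute: a data frame
#'   of protein, missing_fraction and kept.
#' @export
filter_low_detection <- function(matrix, sentinel = MISSING_SENTINEL,
                                 max_missing_fraction = 0.30) {
  stopifnot(is.matrix(matrix), nrow(matrix) > 0, ncol(matrix) > 0)
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- colMeans(matrix == sentinel)
  keep <- frac <= max_missing_fraction
  out <- matrix[, keep, drop = FALSE]
  attr(out, "filter_report") <- data.frame(
    protein = colnames(matrix),
    missing_fraction = unname(frac),
    kept = unname(keep),
    stringsAsFactors = FALSE
  )
  out
}

#' Map donor groups to the binary cancer / non-cancer classes
#'
#' Cancer groups (GC, EC, LC, BC, CCA, CRC) map to the positive class 1;
#' benign lung disease (COPD, PM) and healthy controls (CTL) map to 0.
#'
#' @param groups Character vector of group labels.
#' @return Integer vector of 0/1 class labels, same length.
#' @export
binarize_labels <- function(groups) {
  unknown <- setdiff(unique(groups), .ALL_GROUPS)
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  as.integer(groups %in% .CANCER_GROUPS)
}
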