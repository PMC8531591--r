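#' Exact tree Shapley attributions for a boosted model
#'
#' Per-sample, per-feature Shapley contributions on the model's margin
#' (log-odds) scale, computed exactly from the tree paths, plus the base
#' value (expected margin). With the default `orientation = "noncancer"`
#' the non-cancer-class margin is attributed, so a negative value pushes
#' the prediction toward cancer — the reading convention of the summary
#' reports; `orientation = "cancer"` attributes the positive-class margin
#' directly.
#'
#' @param model An `xgb.Booster` trained on `features`' columns.
#' @param features Samples x features matrix with matching column names.
#' @param orientation `"noncancer"` (default) or `"cancer"`.
#' @return An `attribution_matrix`: list with `values` (samples x features),
#'   `base_value`, `margin` (per-sample oriented margin) and `orientation`.
#'   For every sample, `base_value + rowSums(values)` equals the oriented
#'   margin.
#' @export
shapley_attributions <- function(model, features,
                                 orientation = c("noncancer", "cancer")) {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(features))
  ts <- tree_shap(model, features)
  sgn <- if (orientation == "noncancer") -1 else 1
  structure(list(values = sgn * ts$phi, base_value = sgn * ts$base,
                 margin = sgn * ts$margin, orientation = orientation,
                 sample_ids = rownames(features)),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat("<attribution_matrix> ", nrow(x$values), " samples x ",
      ncol(x$values), " features (", x$orientation, " orientation)\n",
      sep = "")
  invisible(x)
}

#' Aggregate attributions into chaperone families
#'
#' Sums member-feature attributions per sample into one family column
#' (e.g. HSPA2+HSPA6+HSPA8+HSPA12+HSPA5 as "HSP70", the DNAJ members as
#' "DNAJ"); features not listed in any family pass through unchanged.
#' Additivity preserves Shapley efficiency.
#'
#' @param attributions An `attribution_matrix`.
#' @param families Named list mapping family name to member feature names;
#'   members must be disjoint.
#' @return An `attribution_matrix` over family + passthrough columns.
#' @export
aggregate_families <- function(attributions, families) {
  v <- attributions$values
  members <- unlist(families, use.names = FALSE)
  if (anyDuplicated(members))
    stop("overlapping families: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  families <- lapply(families, intersect, colnames(v))
  families <- families[lengths(families) > 0]
  agg <- vapply(families, function(m)
    rowSums(v[, m, drop = FALSE]), numeric(nrow(v)))
  if (nrow(v) == 1) agg <- matrix(agg, nrow = 1,
                                  dimnames = list(NULL, names(families)))
  rest <- v[, setdiff(colnames(v), unlist(families)), drop = FALSE]
  out <- attributions
  out$values <- cbind(agg, rest)
  out
}

#' Mean-absolute-attribution feature ranking
#'
#' The tabular form of a Shapley summary ("beeswarm") plot: per feature,
#' the mean absolute attribution over samples, sorted descending.
#'
#' @param attributions An `attribution_matrix`.
#' @return Data frame with columns feature, mean_abs_shap.
#' @export
shap_summary <- function(attributions) {
  m <- colMeans(abs(attributions$values))
  data.frame(feature = names(m)[order(-m)],
             mean_abs_shap = unname(sort(m, decreasing = TRUE)),
             stringsAsFactors = FALSE)
}

#' Clipped z-score matrix for expression heatmaps
#'
#' Standardizes each protein across samples (zero-variance proteins map to
#' all-zero z), then clips every z value to the `lo_pct` and `hi_pct`
#' percentiles of the pooled z distribution to limit the influence of
#' outliers.
#'
#' @param matrix Samples x proteins intensity matrix (>= 2 samples).
#' @param lo_pct Lower clip percentile (default 1).
#' @param hi_pct Upper clip percentile (default 97).
#' @return A `heatmap_matrix`: list with `z_values`, `clip_lo`, `clip_hi`
#'   (the percentile bounds as values) and `lo_pct`, `hi_pct`.
#' @export
zscore_clipped <- function(matrix, lo_pct = 1, hi_pct = 97) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2, lo_pct < hi_pct)
  z <- apply(matrix, 2, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  dimnames(z) <- dimnames(matrix)
  bounds <- stats::quantile(z, c(lo_pct, hi_pct) / 100, names = FALSE)
  zc <- pmin(pmax(z, bounds[1]), bounds[2])
  structure(list(z_values = zc, clip_lo = bounds[1], clip_hi = bounds[2],
                 lo_pct = lo_pct, hi_pct = hi_pct),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf(
    "<heatmap_matrix> %d x %d; z clipped to [%.3f, %.3f] (pct %g/%g)\n",
    nrow(x$z_values), ncol(x$z_values), x$clip_lo, x$clip_hi,
    x$lo_pct, x$hi_pct))
  invisible(x)
}
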