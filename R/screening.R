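#' Kruskal-Wallis rank test across groups
#'
#' H is computed on midranks with the standard tie correction and compared to
#' a chi-square distribution with (number of groups - 1) degrees of freedom.
#' The degenerate case where every value is identical across all groups (the
#' tie-correction divisor vanishes) is defined as H = 0, p = 1.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List with elements `H` and `p`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!lengths(groups))) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Dunn's post-hoc test against a reference group
#'
#' Pooled-rank z statistics for every group against a designated reference
#' (the healthy-control group in the screening pipeline). For group i with
#' mean pooled rank Rbar_i,
#' `z = (Rbar_i - Rbar_ref) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_ref))`, with the tie sum running over tied value groups in
#' the pooled sample. Two-sided p-values come from the standard normal.
#'
#' @param values Numeric vector, all groups pooled.
#' @param groups Group label per value.
#' @param reference Reference group label (must be present).
#' @return Data frame with columns group, z, p_raw; one row per non-reference
#'   group, in first-appearance order.
#' @export
dunn_vs_reference <- function(values, groups, reference) {
  stopifnot(length(values) == length(groups))
  if (!reference %in% groups) stop("reference group absent: ", reference)
  if (length(values) < 2) stop("need at least two pooled observations")
  n <- table(groups)[unique(groups)]
  if (any(n == 0)) stop("every group must be non-empty")
  N <- length(values)
  r <- rank(values)  # midranks
  tie <- tabulate(match(values, unique(values)))  # exact-equality tie groups
  tie_sum <- sum(tie^3 - tie)
  var_term <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  others <- setdiff(unique(groups), reference)
  z <- vapply(others, function(gr) {
    denom <- sqrt(var_term * (1 / n[[gr]] + 1 / n[[reference]]))
    if (denom == 0) 0 else (rbar[[gr]] - rbar[[reference]]) / denom
  }, numeric(1))
  data.frame(group = others, z = unname(z),
             p_raw = 2 * stats::pnorm(-abs(unname(z))),
             stringsAsFactors = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.30))
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Two-stage nonparametric differential-abundance screen
#'
#' For every protein: a Kruskal-Wallis test across the healthy-control (CTL)
#' and six cancer groups, then Dunn's test of each cancer group against CTL
#' on the pooled ranks of those seven groups, with Holm-Bonferroni
#' adjustment. Benign lung disease samples (COPD, PM) are not part of the
#' screen. Sentinel-valued entries participate in ranking at their literal
#' value (they tie at the minimum); ranks are insensitive to the sentinel's
#' magnitude.
#'
#' @param matrix Filtered samples x proteins intensity matrix.
#' @param groups Per-sample group label vector aligned with the matrix rows.
#' @param alpha Significance level recorded in the table (default 0.05).
#' @param family Holm adjustment family: `"protein"` (default; the six
#'   contrasts within one protein) or `"global"` (all proteins x contrasts).
#' @param kw_gate Optional Kruskal-Wallis p-value gate: contrasts for
#'   proteins with KW p above the gate are reported with p_adj = 1. Default
#'   `NULL` (no gating; the KW stage is reported but does not gate).
#' @return A `screening_table`: data frame with columns protein, contrast,
#'   kw_H, kw_p, dunn_z, p_raw, p_adj, significant; attribute `alpha`.
#' @export
screen_panel <- function(matrix, groups, alpha = 0.05,
                         family = c("protein", "global"), kw_gate = NULL) {
  family <- match.arg(family)
  stopifnot(is.matrix(matrix), nrow(matrix) == length(groups))
  screen_groups <- c("CTL", .CANCER_GROUPS)
  if (!"CTL" %in% groups) stop("reference group CTL is missing")
  absent <- setdiff(screen_groups, unique(groups))
  if (length(absent))
    stop("screening needs CTL plus the six cancer groups; missing: ",
         paste(absent, collapse = ", "))
  keep <- groups %in% screen_groups
  m <- matrix[keep, , drop = FALSE]
  g <- groups[keep]
  recs <- lapply(colnames(m), function(pr) {
    x <- m[, pr]
    kw <- kruskal_wallis(split(x, g))
    dn <- dunn_vs_reference(x, g, reference = "CTL")
    dn <- dn[match(.CANCER_GROUPS, dn$group), ]
    data.frame(protein = pr, contrast = dn$group, kw_H = kw$H, kw_p = kw$p,
               dunn_z = dn$z, p_raw = dn$p_raw, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, recs)
  if (family == "protein") {
    tab$p_adj <- stats::ave(tab$p_raw, tab$protein, FUN = holm_adjust)
  } else {
    tab$p_adj <- holm_adjust(tab$p_raw)
  }
  if (!is.null(kw_gate)) tab$p_adj[tab$kw_p > kw_gate] <- 1
  tab$significant <- tab$p_adj < alpha
  attr(tab, "alpha") <- alpha
  class(tab) <- c("screening_table", "data.frame")
  tab
}

#' Reshape a screening table into the wide per-cancer-type layout
#'
#' One row per cancer contrast; per protein two columns, the signed Dunn
#' statistic and the Holm-adjusted p-value.
#'
#' @param table A `screening_table` from [screen_panel()].
#' @return Wide data frame (contrast, then `<protein>_z` / `<protein>_p`
#'   column pairs).
#' @export
screening_wide <- function(table) {
  prot <- unique(table$protein)
  out <- data.frame(cancer_type = .CANCER_GROUPS, stringsAsFactors = FALSE)
  for (pr in prot) {
    sub <- table[table$protein == pr, ]
    i <- match(out$cancer_type, sub$contrast)
    out[[paste0(pr, "_z")]] <- sub$dunn_z[i]
    out[[paste0(pr, "_p")]] <- sub$p_adj[i]
  }
  out
}
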