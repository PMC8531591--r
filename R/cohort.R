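#' Default synthetic cohort configuration
#'
#' Builds the configuration for the default synthetic urine-proteome cohort:
#' nine donor groups totalling 231 donors (GC 47, EC 14, LC 33, BC 17,
#' CCA 25, CRC 22, COPD 17, PM 23, CTL 33), the default 25-protein HSP /
#' cochaperone panel, log-normal baseline intensities on the iFOT display
#' scale, a uniform dropout probability, and a group-specific effect map
#' whose signs follow the differential-expression pattern seen in urine
#' cohorts: chaperonin subunits (CCT1, CCT5) and the cochaperone FKBP4
#' down in most cancers, mitochondrial chaperones HSPA9 and TRAP1 up,
#' HSPB5 up only in cervical cancer, HSP90AB1 down in gastric and
#' colorectal cancer.
#'
#' Effect magnitudes default to 1.0 on the natural-log scale for every
#' affected (protein, group) cell and 0 elsewhere.
#'
#' @param effect_size Absolute log-scale shift applied to each affected
#'   cell (default 1.0).
#' @param dropout Missingness (sentinel replacement) probability applied to
#'   every protein (default 0.1).
#' @param scale Intensity scale: `"display"` (iFOT x 1e5, the default) or
#'   `"fraction"` (raw fractions, values divided by 1e5).
#' @param seed Integer seed driving the generator stream (default 1).
#' @return An object of class `cohort_config`: list with `groups` (data frame
#'   of name, n, class), `panel`, `baseline` (data frame of protein, meanlog,
#'   sdlog), `effects` (matrix protein x group of log shifts), `dropout`
#'   (named vector), `sentinel`, `scale_factor`, `seed`.
#' @export
#' @examples
#' cfg <- default_cohort_config()
#' sum(cfg$groups$n)  # 231 donors
default_cohort_config <- function(effect_size = 1.0, dropout = 0.1,
                                  scale = c("display", "fraction"),
                                  seed = 1L) {
  scale <- match.arg(scale)
  groups <- data.frame(
    name = c("GC", "EC", "LC", "BC", "CCA", "CRC", "COPD", "PM", "CTL"),
    n    = c(47L, 14L, 33L, 17L, 25L, 22L, 17L, 23L, 33L),
    stringsAsFactors = FALSE
  )
  groups$class <- binarize_labels(groups$name)
  panel <- default_panel()
  p <- length(panel$symbols)
  baseline <- data.frame(
    protein = panel$symbols,
    meanlog = seq(2, 6, length.out = p),  # iFOT display scale ~ e^2 .. e^6
    sdlog   = rep(1.0, p),
    stringsAsFactors = FALSE
  )
  effects <- matrix(0, nrow = p, ncol = nrow(groups),
                    dimnames = list(panel$symbols, groups$name))
  down <- list(
    CCT1     = c("LC", "CCA", "CRC", "EC"),
    CCT5     = c("LC", "BC", "CCA", "CRC", "EC"),
    FKBP4    = c("LC", "BC", "CCA", "CRC", "GC"),
    HSP90AB1 = c("CRC", "GC")
  )
  up <- list(
    HSPB5 = c("CCA"),
    HSPA9 = c("LC", "BC", "EC"),
    TRAP1 = c("LC", "BC", "CCA", "EC")
  )
  for (pr in names(down)) effects[pr, down[[pr]]] <- -effect_size
  for (pr in names(up))   effects[pr, up[[pr]]]   <- +effect_size
  dropout <- stats::setNames(rep(dropout, p), panel$symbols)
  structure(list(
    groups = groups, panel = panel, baseline = baseline, effects = effects,
    dropout = dropout, sentinel = MISSING_SENTINEL,
    scale_factor = if (scale == "display") 1 else 1e-5,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

validate_cohort_config <- function(config) {
  if (!inherits(config, "cohort_config")) stop("not a cohort_config object")
  g <- config$groups
  if (anyDuplicated(g$name)) stop("invalid config: duplicate group names")
  if (any(g$n < 1)) stop("invalid config: group n must be >= 1")
  if (!is.numeric(config$sentinel) || config$sentinel <= 0)
    stop("invalid config: sentinel must be > 0")
  if (any(config$dropout < 0 | config$dropout > 1))
    stop("invalid config: dropout probabilities must lie in [0, 1]")
  syms <- config$panel$symbols
  if (!setequal(rownames(config$effects), syms))
    stop("invalid config: effects rows must match the panel symbols")
  if (!setequal(config$baseline$protein, syms))
    stop("invalid config: baseline must cover every panel symbol")
  if (!setequal(names(config$dropout), syms))
    stop("invalid config: dropout must cover every panel symbol")
  invisible(config)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", sum(x$groups$n), " donors in ", nrow(x$groups),
      " groups; ", length(x$panel$symbols), " proteins; seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Generate a labeled synthetic cohort
#'
#' Draws a samples x proteins iFOT intensity matrix. For sample in group g
#' and protein j, the observed value is log-normal with log-mean
#' `baseline meanlog + effect[j, g]` and log-sd `baseline sdlog`; with the
#' protein's dropout probability the value is replaced by the missingness
#' sentinel. Identical seeds yield bit-identical cohorts: values are drawn
#' protein by protein, in panel order, from a single seeded stream.
#'
#' @param config A `cohort_config`, e.g. from [default_cohort_config()].
#' @return An object of class `labeled_cohort`: list with `matrix` (numeric
#'   matrix, sample ids as row names), `groups` (per-sample group label) and
#'   `classes` (per-sample 0/1 cancer label).
#' @export
#' @examples
#' co <- generate_cohort(default_cohort_config())
#' dim(co$matrix)
generate_cohort <- function(config = default_cohort_config()) {
  validate_cohort_config(config)
  g <- config$groups
  n <- sum(g$n)
  group_of <- rep(g$name, g$n)
  sample_ids <- sprintf("%s_%02d", group_of,
                        unlist(lapply(g$n, seq_len), use.names = FALSE))
  syms <- config$panel$symbols
  base <- config$baseline[match(syms, config$baseline$protein), ]
  mat <- matrix(NA_real_, n, length(syms),
                dimnames = list(sample_ids, syms))
  withr::with_seed(config$seed, {
    for (j in seq_along(syms)) {
      mu <- base$meanlog[j] + config$effects[syms[j], group_of]
      x <- stats::rlnorm(n, meanlog = mu, sdlog = base$sdlog[j])
      drop <- stats::runif(n) < config$dropout[[syms[j]]]
      x[drop] <- config$sentinel
      mat[, j] <- x
    }
  })
  mat <- mat * config$scale_factor
  if (config$scale_factor != 1)  # sentinel encodes missing on any scale
    mat[mat == config$sentinel * config$scale_factor] <- config$sentinel
  structure(list(matrix = mat, groups = group_of,
                 classes = binarize_labels(group_of)),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat("<labeled_cohort> ", nrow(x$matrix), " samples x ", ncol(x$matrix),
      " proteins (", sum(x$classes), " cancer / ",
      sum(x$classes == 0), " non-cancer)\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk as intensity table plus annotation
#'
#' @param cohort A `labeled_cohort`.
#' @param matrix_path Output path for the TSV intensity table.
#' @param annotation_path Output path for the two-column (sample_id, group)
#'   TSV annotation.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, matrix_path, annotation_path) {
  write_intensity_table(cohort$matrix, matrix_path)
  ann <- data.frame(sample_id = rownames(cohort$matrix),
                    group = cohort$groups, stringsAsFactors = FALSE)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, annotation_path))
}
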