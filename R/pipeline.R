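#' Default pipeline configuration
#'
#' @param out_dir Report directory.
#' @param seed Master seed propagated to every stochastic stage.
#' @param matrix_path,annotation_path Optional paths to an existing iFOT
#'   intensity table and annotation; when `NULL` (default) a synthetic
#'   cohort is generated.
#' @param feature_path Optional feature-definition file (one expression per
#'   line); default uses [default_feature_set()].
#' @param alpha Screening significance level (default 0.05).
#' @param max_missing_fraction Detection-filter threshold (default 0.30).
#' @param search A [search_config()]; its seed is overridden by `seed`.
#' @param threshold Classification threshold (default 0.5).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, matrix_path = NULL,
                            annotation_path = NULL, feature_path = NULL,
                            alpha = 0.05, max_missing_fraction = 0.30,
                            search = search_config(), threshold = 0.5) {
  search$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 matrix_path = matrix_path,
                 annotation_path = annotation_path,
                 feature_path = feature_path, alpha = alpha,
                 max_missing_fraction = max_missing_fraction,
                 search = search, threshold = threshold),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `search` may be
#' a nested map with n1, n2, K, ucb_kappa.
#'
#' @param path YAML file.
#' @param out_dir Report directory (overrides any value in the file).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  sc <- do.call(search_config, c(y$search, list()))
  pipeline_config(
    out_dir = if (is.null(out_dir)) y$out_dir else out_dir,
    seed = if (is.null(y$seed)) 1L else y$seed,
    matrix_path = y$matrix_path, annotation_path = y$annotation_path,
    feature_path = y$feature_path,
    alpha = if (is.null(y$alpha)) 0.05 else y$alpha,
    max_missing_fraction = if (is.null(y$max_missing_fraction)) 0.30
                           else y$max_missing_fraction,
    search = sc,
    threshold = if (is.null(y$threshold)) 0.5 else y$threshold)
}

#' Run the full screening / training / explanation pipeline
#'
#' Stages: load (or simulate) the cohort, select the HSP panel, apply the
#' detection filter, run the two-stage nonparametric screen, evaluate the
#' chaperone-network features, run the Bayesian-optimization /
#' feature-elimination training loop, evaluate the selected model, and
#' compute Shapley attributions and the clipped z-score heatmap. All
#' tabular outputs are written as TSV under `config$out_dir`, together with
#' a JSON run manifest.
#'
#' Written files: `screening_long.tsv`, `screening_wide.tsv`,
#' `filter_report.tsv`, `feature_matrix.tsv`, `trajectory.tsv`,
#' `evaluation.tsv`, `attributions.tsv`, `shap_summary.tsv`,
#' `heatmap_z.tsv`, `manifest.json`.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `screening`, `features`, `selection`, `attributions`, `heatmap`,
#'   `files`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  if (is.null(config$matrix_path)) {
    cohort <- generate_cohort(default_cohort_config(seed = config$seed))
    mat <- cohort$matrix
    groups <- cohort$groups
  } else {
    mat <- read_intensity_table(config$matrix_path)
    ann <- read_annotation(config$annotation_path)
    ann <- ann[match(rownames(mat), ann$sample_id), ]
    if (anyNA(ann$sample_id))
      stop("annotation does not cover every sample in ",
           config$matrix_path)
    groups <- ann$group
  }
  labels <- binarize_labels(groups)

  mat <- select_panel(mat)
  mat <- filter_low_detection(
    mat, max_missing_fraction = config$max_missing_fraction)
  write_tsv_report(attr(mat, "filter_report"), out("filter_report.tsv"))

  screening <- screen_panel(mat, groups, alpha = config$alpha)
  write_tsv_report(as.data.frame(screening), out("screening_long.tsv"))
  write_tsv_report(screening_wide(screening), out("screening_wide.tsv"))

  feats <- if (is.null(config$feature_path)) {
    panel <- default_panel()
    kept <- panel_definition(colnames(mat),
                             lapply(panel$families, intersect,
                                    colnames(mat)))
    default_feature_set(kept)
  } else {
    read_feature_file(config$feature_path)
  }
  fx <- evaluate_feature_set(mat, feats)
  write_intensity_table(fx, out("feature_matrix.tsv"))

  selection <- run_selection_loop(fx, labels, config$search,
                                  threshold = config$threshold)
  write_tsv_report(selection$trajectory, out("trajectory.tsv"))
  ev <- selection$evaluation
  write_tsv_report(data.frame(
    metric = c("tp", "fp", "tn", "fn", "precision", "accuracy",
               "balanced_accuracy", "fold_mean_precision",
               "fold_mean_accuracy", "fold_mean_balanced_accuracy",
               "cv_logloss"),
    value = c(ev$confusion, ev$pooled$precision, ev$pooled$accuracy,
              ev$pooled$balanced_accuracy, ev$fold_mean$precision,
              ev$fold_mean$accuracy, ev$fold_mean$balanced_accuracy,
              selection$selected_logloss)), out("evaluation.tsv"))

  model <- fit_selected_model(fx, labels, selection)
  attributions <- shapley_attributions(
    model, fx[, selection$selected_features, drop = FALSE])
  adf <- data.frame(sample_id = rownames(fx),
                    as.data.frame(attributions$values),
                    check.names = FALSE)
  write_tsv_report(adf, out("attributions.tsv"))
  write_tsv_report(shap_summary(attributions), out("shap_summary.tsv"))

  heatmap <- zscore_clipped(mat)
  hdf <- data.frame(sample_id = rownames(mat), group = groups,
                    as.data.frame(heatmap$z_values), check.names = FALSE)
  write_tsv_report(hdf, out("heatmap_z.tsv"))

  manifest <- list(
    package = "hspmark",
    version = as.character(utils::packageVersion("hspmark")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, alpha = config$alpha,
    max_missing_fraction = config$max_missing_fraction,
    threshold = config$threshold,
    search = config$search[c("n1", "n2", "K", "ucb_kappa", "seed")],
    n_samples = nrow(mat), n_proteins = ncol(mat),
    n_features = ncol(fx),
    selected_features = selection$selected_features,
    synthetic = is.null(config$matrix_path))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(cohort = list(matrix = mat, groups = groups,
                               classes = labels),
                 screening = screening, features = fx,
                 selection = selection, attributions = attributions,
                 heatmap = heatmap,
                 files = vapply(c("screening_long.tsv", "screening_wide.tsv",
                                  "filter_report.tsv", "feature_matrix.tsv",
                                  "trajectory.tsv", "evaluation.tsv",
                                  "attributions.tsv", "shap_summary.tsv",
                                  "heatmap_z.tsv", "manifest.json"),
                                out, "")))
}
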