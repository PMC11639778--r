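#' Resolved configuration for a full pipeline run
#'
#' Bundles every tunable of the three-phase pipeline (descriptor block
#' width, selection thresholds, NCA settings, ensemble grid bounds,
#' validation schemes, selection/classification protocol mode, seed) so that
#' a run is fully determined by the configuration plus the input data.
#'
#' @param W Block width and code base of the descriptor (default 16).
#' @param duration_s Segment duration in seconds (default 15).
#' @param normalize Normalize descriptor histograms to frequencies
#'   (default `FALSE`: raw counts).
#' @param t_start,t_stop Cumulative-weight thresholds of the selector
#'   (defaults 0.85 / 0.99).
#' @param nca An [nca_settings()] object.
#' @param k_max Largest neighbor count of the ensemble grid (default 10,
#'   giving the 90-configuration pool).
#' @param schemes Validation schemes to run: subset of
#'   `c("tenfold", "loro")`.
#' @param mode `"paper"` (select once on the full matrix, ensemble
#'   self-organizes on pooled test predictions) or `"honest"` (selection and
#'   winner choice re-done inside every training fold). Paper mode
#'   reproduces the method's published protocol and is optimistic; see the
#'   vignette.
#' @param seed Seed for fold assignment (default 42).
#' @param n_folds Folds for the tenfold scheme (default 10).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(W = 16L, duration_s = 15, normalize = FALSE,
                            t_start = 0.85, t_stop = 0.99,
                            nca = nca_settings(), k_max = 10L,
                            schemes = c("tenfold", "loro"),
                            mode = c("paper", "honest"), seed = 42L,
                            n_folds = 10L) {
  mode <- match.arg(mode)
  schemes <- match.arg(schemes, c("tenfold", "loro"), several.ok = TRUE)
  structure(list(W = as.integer(W), duration_s = duration_s,
                 normalize = normalize, t_start = t_start, t_stop = t_stop,
                 nca = nca, k_max = as.integer(k_max), schemes = schemes,
                 mode = mode, seed = as.integer(seed),
                 n_folds = as.integer(n_folds)),
            class = "pipeline_config")
}

# Honest pipeline: feature selection and ensemble winner choice are redone
# inside every training fold; test rows only ever meet the chosen model.
honest_sofe_pipeline <- function(config) {
  grid <- knn_grid(config$k_max)
  f <- function(X, y, folds_vec) {
    y <- factor(y)
    final <- integer(length(y))
    for (fo in sort(unique(folds_vec))) {
      te <- folds_vec == fo
      sel <- cwinca_select(X[!te, , drop = FALSE], y[!te],
                           t_start = config$t_start, t_stop = config$t_stop,
                           settings = config$nca, seed = config$seed)
      hp <- honest_fold_predict(X[!te, sel$selected, drop = FALSE],
                                as.integer(y)[!te],
                                X[te, sel$selected, drop = FALSE],
                                grid, nlevels(y))
      final[te] <- hp$predictions
    }
    factor(levels(y)[final], levels = levels(y))
  }
  attr(f, "mode") <- "honest"
  f
}

#' Run the full three-phase pipeline on a set of records
#'
#' Executes descriptor extraction, cumulative-weight iterative feature
#' selection, and the self-organized kNN ensemble, then evaluates under the
#' requested cross-validation schemes. In `"paper"` mode features are
#' selected once on the full matrix before the outer CV (the method's
#' published protocol; optimistic because selection sees all labels); in
#' `"honest"` mode selection and ensemble winner choice are repeated inside
#' every training fold. Every defaulted decision (thresholds, mode, seed,
#' selected feature count) is reported via `message()`.
#'
#' @param records List of [signal_record()]s, or a precomputed
#'   `feature_matrix`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the feature matrix,
#'   selection JSON-ready list, outcome-pool table and reports are written
#'   there as CSV/JSON artifacts.
#' @return List of class `pipeline_result`: `reports` (one
#'   `evaluation_report` per scheme), `selection` (paper mode only),
#'   `features` (the `feature_matrix`), `config`.
#' @export
run_pipeline <- function(records, config = pipeline_config(),
                         out_dir = NULL) {
  fm <- if (inherits(records, "feature_matrix")) records else
    build_feature_matrix(records, duration_s = config$duration_s,
                         W = config$W, normalize = config$normalize)
  message(sprintf("pipeline: %d segments x %d features; mode = %s; seed = %d",
                  nrow(fm$X), ncol(fm$X), config$mode, config$seed))
  selection <- NULL
  grid <- knn_grid(config$k_max)
  if (config$mode == "paper") {
    selection <- cwinca_select(fm$X, fm$y, t_start = config$t_start,
                               t_stop = config$t_stop, settings = config$nca,
                               seed = config$seed)
    message(sprintf(
      "pipeline: thresholds (%.2f, %.2f) -> range [%d, %d], selected %d features",
      config$t_start, config$t_stop, selection$start, selection$stop,
      selection$r_star))
    Xsel <- fm$X[, selection$selected, drop = FALSE]
    pipe <- tknn_pipeline(mode = "paper", grid = grid)
  } else {
    Xsel <- fm$X
    pipe <- honest_sofe_pipeline(config)
  }
  reports <- list()
  if ("tenfold" %in% config$schemes) {
    reports$tenfold <- tenfold_cv(Xsel, fm$y, fm$record_ids, pipeline = pipe,
                                  seed = config$seed,
                                  n_folds = config$n_folds)
  }
  if ("loro" %in% config$schemes) {
    reports$loro <- loro_cv(Xsel, fm$y, fm$record_ids, pipeline = pipe)
  }
  res <- structure(list(reports = reports, selection = selection,
                        features = fm, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %-8s accuracy %.2f | g-mean %.2f | F1 %.2f\n", nm,
                r$accuracy, r$geometric_mean, r$f1))
  }
  invisible(x)
}

report_as_list <- function(r, config = NULL) {
  out <- list(scheme = r$scheme, mode = r$mode, seed = r$seed,
              accuracy = r$accuracy, geometric_mean = r$geometric_mean,
              precision = r$precision, recall = r$recall, f1 = r$f1,
              per_class = r$per_class,
              confusion = as.data.frame(as.table(r$confusion)))
  if (!is.null(config)) out$config <- unclass_config(config)
  out
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$nca <- unclass(cfg$nca)
  cfg
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_matrix(res$features, file.path(out_dir, "features.csv"))
  if (!is.null(res$selection) &&
      requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(selection_as_list(res$selection),
                         file.path(out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      lapply(res$reports, report_as_list, config = res$config),
      file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(res$reports)) {
    write.csv(res$reports[[nm]]$confusion,
              file.path(out_dir, paste0("confusion_", nm, ".csv")))
  }
  invisible(out_dir)
}
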