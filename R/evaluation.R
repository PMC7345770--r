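# Stability aggregation across dataset x exposure runs, and external
# validation on an independent dataset.

#' Aggregate LOOCV results into a performance-stability report
#'
#' Summarises a collection of per-(dataset, exposure) AUCs into the
#' stability metrics: the median AUC and interquartile range over all
#' entries, the coefficient of variation of the per-dataset median AUCs
#' (C.V.d) and of the per-exposure median AUCs (C.V.e), and a stability
#' verdict. A model is called stable when the IQR is at most 0.05 on the
#' AUC scale and both coefficients of variation are at most 5%.
#'
#' Conventions (recorded in the report metadata): quartiles use linear
#' interpolation between order statistics (quantile type 7); per-group
#' summaries use the median; coefficients of variation use the sample
#' standard deviation (denominator n - 1) and are reported in percent. A
#' grouping level with a single entry contributes its value; a C.V. over
#' fewer than two groups is 0.
#'
#' @param results List of `CvResult`s (each tagged with `dataset_id` and
#'   `exposure_style`), or a numeric AUC vector together with `datasets`
#'   and `exposures` tags.
#' @param datasets,exposures Grouping tags, only needed when `results` is
#'   a bare numeric vector.
#' @return A `StabilityReport`: list with `entries` (data frame dataset,
#'   exposure, algorithm, auc), `median_auc`, `iqr`, `cvd`, `cve`,
#'   `stable`, and `conventions`.
#' @export
aggregate_stability <- function(results, datasets = NULL, exposures = NULL) {
  if (is.numeric(results)) {
    entries <- data.frame(dataset = datasets, exposure = exposures,
                          algorithm = NA_character_, auc = results,
                          stringsAsFactors = FALSE)
  } else {
    entries <- do.call(rbind, lapply(results, function(r) {
      data.frame(dataset = r$dataset_id, exposure = r$exposure_style,
                 algorithm = r$algorithm, auc = r$auc,
                 stringsAsFactors = FALSE)
    }))
  }
  if (nrow(entries) < 2L) {
    stop_input("aggregate_stability: need >= 2 cross-validation entries")
  }
  aucs <- entries$auc
  q <- stats::quantile(aucs, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  cv_pct <- function(v) {
    if (length(v) < 2L) return(0)
    100 * stats::sd(v) / mean(v)
  }
  by_ds <- tapply(aucs, entries$dataset, stats::median)
  by_ex <- tapply(aucs, entries$exposure, stats::median)
  cvd <- cv_pct(as.numeric(by_ds))
  cve <- cv_pct(as.numeric(by_ex))
  iqr <- q[3] - q[1]
  structure(list(entries = entries,
                 median_auc = q[2], iqr = iqr, cvd = cvd, cve = cve,
                 stable = iqr <= 0.05 && cvd <= 5 && cve <= 5,
                 conventions = list(quantile_type = 7,
                                    group_summary = "median",
                                    sd_denominator = "n-1")),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat("StabilityReport over", nrow(x$entries), "dataset x exposure runs\n")
  cat(sprintf("  median AUC %.3f | IQR %.3f | C.V.d %.2f%% | C.V.e %.2f%%\n",
              x$median_auc, x$iqr, x$cvd, x$cve))
  cat("  stable:", if (x$stable) "yes" else
    "no (IQR > 0.05 or a C.V. > 5%)", "\n")
  invisible(x)
}

#' Serialise / restore a stability report as JSON
#'
#' @param report A `StabilityReport`.
#' @param path JSON file path.
#' @return `write_stability_report` returns `path` invisibly;
#'   `read_stability_report` the restored `StabilityReport`.
#' @export
write_stability_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_stability_report
#' @export
read_stability_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$entries <- as.data.frame(x$entries, stringsAsFactors = FALSE)
  structure(x, class = "StabilityReport")
}

#' Train on one dataset, score another
#'
#' Fits the classifier once on every training chemical and reports the
#' AUC of its scores on the test dataset's chemicals. Feature columns are
#' restricted to the genes the two platforms share (logged); this is how
#' a model trained on one platform is applied to another that lacks some
#' probes.
#'
#' @param train,test `FeatureTable`s.
#' @param algorithm One of [classifier_tags()].
#' @param params Algorithm parameters (see [loocv()]).
#' @param seed Seed for stochastic learners.
#' @return List with `auc`, `scores` (test chemicals), `genes_used`.
#' @export
external_validate <- function(train, test, algorithm, params = list(),
                              seed = 1L) {
  common <- intersect(colnames(train$x), colnames(test$x))
  if (length(common) == 0L) {
    stop_input("external_validate: train and test share no biomarker genes")
  }
  if (length(common) < ncol(train$x) || length(common) < ncol(test$x)) {
    message("external_validate: restricted to ", length(common),
            " shared gene(s)")
  }
  if (length(unique(test$labels)) < 2L) {
    stop_input("external_validate: test set has a single class; ",
               "AUC undefined")
  }
  y <- factor(train$labels, levels = c("NGHC", "NHC"))
  set.seed(seed)
  scores <- fit_and_score(algorithm, train$x[, common, drop = FALSE], y,
                          test$x[, common, drop = FALSE], params)
  names(scores) <- rownames(test$x)
  list(auc = auc_mw(scores, test$labels), scores = scores,
       genes_used = common)
}
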