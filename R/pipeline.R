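# End-to-end orchestration: profiles -> DEGs -> consensus -> invariance
# -> features -> LOOCV -> stability report (-> external validation,
# enrichment).

#' Discover time-invariant biomarkers across datasets and exposures
#'
#' The core discovery chain: per dataset x exposure, per-chemical profiles
#' ([chemical_profiles()]) and NGHC-vs-NHC DEG calls
#' ([test_differential()]); a cross-dataset consensus set at the source
#' exposure ([consensus_set()]); and a cross-exposure modulation table
#' with time-invariance flags ([cross_check()]).
#'
#' @param studies List of `ExpressionStudy` objects.
#' @param labels Named vector chemical_id -> class (NGHC/NHC).
#' @param exposures Exposure styles to analyse; these are also the
#'   required exposures of the invariance rule. Default: the styles
#'   present in the first study.
#' @param source_exposure Exposure whose consensus set is cross-checked
#'   (default `"3d"` when available, else the first exposure).
#' @param alpha,fold_threshold,test_variant DEG settings (see
#'   [test_differential()]).
#' @param dose_group,control_policy Profile settings (see
#'   [chemical_profiles()]).
#' @param min_datasets Consensus requirement (see [consensus_set()]).
#' @return List with `profiles` (dataset -> exposure -> profile matrix),
#'   `deg_by_exposure`, `consensus`, `modulation`, `invariant` (the
#'   time-invariant `BiomarkerSet`).
#' @export
discover_invariant_biomarkers <- function(studies, labels,
                                          exposures = NULL,
                                          source_exposure = NULL,
                                          alpha = 0.05,
                                          fold_threshold = 1.5,
                                          test_variant = "welch",
                                          dose_group = "high",
                                          control_policy = "pooled",
                                          min_datasets = NULL) {
  if (is.null(exposures)) {
    exposures <- unique(studies[[1]]$samples$exposure_style)
  }
  if (is.null(source_exposure)) {
    source_exposure <- if ("3d" %in% exposures) "3d" else exposures[1]
  }
  if (!source_exposure %in% exposures) {
    stop_input("source_exposure '", source_exposure,
               "' not among the analysed exposures")
  }
  profiles <- lapply(studies, function(st) {
    out <- lapply(exposures, function(e) {
      chemical_profiles(st, e, dose_group = dose_group,
                        control_policy = control_policy, labels = labels)
    })
    names(out) <- exposures
    out
  })
  deg_by_exposure <- lapply(exposures, function(e) {
    lapply(profiles, function(p) {
      test_differential(p[[e]], alpha = alpha,
                        fold_threshold = fold_threshold,
                        test_variant = test_variant)
    })
  })
  names(deg_by_exposure) <- exposures
  consensus <- consensus_set(deg_by_exposure[[source_exposure]],
                             min_datasets = min_datasets,
                             name = paste0("consensus_", source_exposure),
                             source_exposure = source_exposure)
  modulation <- cross_check(consensus, deg_by_exposure,
                            required_exposures = exposures)
  list(profiles = profiles, deg_by_exposure = deg_by_exposure,
       consensus = consensus, modulation = modulation,
       invariant = invariant_set(modulation, consensus))
}

#' Run the full biomarker discovery and evaluation pipeline
#'
#' Orchestrates simulate (or read) -> profiles -> DEGs -> consensus ->
#' invariance -> features -> LOOCV -> stability report, with optional
#' cross-dataset external validation and enrichment analysis, and writes
#' every stage's result to `out_dir`. Re-running with the same
#' configuration and seed reproduces the outputs.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{simulation}{Arguments for [simulation_config()] (mutually
#'       exclusive with `studies`).}
#'     \item{studies}{List of per-dataset lists (expression, metadata,
#'       dataset_id, platform) read by [read_study()]; requires `labels`
#'       (path to labels.tsv).}
#'     \item{genemap, collapse}{Optional probe map applied via
#'       [map_to_genes()].}
#'     \item{exposures, source_exposure, alpha, fold_threshold,
#'       dose_group, control_policy, min_datasets}{Discovery settings
#'       (defaults as in [discover_invariant_biomarkers()]).}
#'     \item{algorithms}{Classifier tags to cross-validate (default
#'       `"rf"`).}
#'     \item{rf_trees}{`"auto"` for grid selection or a fixed count
#'       (default 50).}
#'     \item{external}{Optional list(train = dataset_id, test =
#'       dataset_id, exposure = tag) for external validation.}
#'     \item{catalog}{Optional annotation TSV for [enrich()].}
#'     \item{seed}{Mandatory integer seed.}
#'   }
#' @param out_dir Output directory.
#' @return List with `discovery`, `cv_results`, `report`, and (when
#'   configured) `external`, `enrichment`; also written to `out_dir` as
#'   modulation.tsv, biomarkers.tsv, report.json/report.tsv,
#'   external.tsv, enrich.tsv, resolved_config.yaml and run.log.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop_input("run_pipeline: config$seed is ",
                                       "mandatory")
  has_sim <- !is.null(config$simulation)
  has_real <- !is.null(config$studies)
  if (has_sim == has_real) {
    stop_input("run_pipeline: specify exactly one of config$simulation ",
               "or config$studies")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(paste0(..., "\n"), file = logf,
                                append = TRUE)
  cat("", file = logf)

  if (has_sim) {
    sim_args <- config$simulation
    sim_args$seed <- sim_args$seed %||% config$seed
    sim <- simulate_studies(do.call(simulation_config, sim_args))
    studies <- sim$studies
    labels <- stats::setNames(sim$labels$class, sim$labels$chemical_id)
    log_line("stage simulate: ", length(studies), " datasets, ",
             nrow(studies[[1]]$expression), " genes")
  } else {
    sim <- NULL
    studies <- lapply(config$studies, function(s) {
      read_study(s$expression, s$metadata, s$dataset_id,
                 s$platform %||% "unknown")
    })
    names(studies) <- vapply(studies, function(s) s$dataset_id, "")
    labels <- read_labels(config$labels)
    log_line("stage read: ", length(studies), " datasets")
  }
  if (!is.null(config$genemap)) {
    map <- read_genemap(config$genemap)
    studies <- lapply(studies, map_to_genes, map = map,
                      collapse = config$collapse %||% "mean")
    log_line("stage genemap: collapsed to gene symbols (",
             config$collapse %||% "mean", ")")
  }

  disc <- discover_invariant_biomarkers(
    studies, labels,
    exposures = config$exposures,
    source_exposure = config$source_exposure,
    alpha = config$alpha %||% 0.05,
    fold_threshold = config$fold_threshold %||% 1.5,
    dose_group = config$dose_group %||% "high",
    control_policy = config$control_policy %||% "pooled",
    min_datasets = config$min_datasets)
  log_line("stage consensus: ", nrow(disc$consensus), " consensus gene(s)",
           " at '", attr(disc$consensus, "source_exposure"), "'")
  log_line("stage invariance: ", nrow(disc$invariant),
           " time-invariant gene(s)")
  utils::write.table(disc$modulation, file.path(out_dir, "modulation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(disc$invariant, file.path(out_dir, "biomarkers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cv_results <- list()
  report <- NULL
  if (nrow(disc$invariant) > 0L) {
    algorithms <- config$algorithms %||% "rf"
    rf_trees <- config$rf_trees %||% 50
    for (algo in algorithms) {
      params <- if (algo == "rf") list(ntree = rf_trees) else list()
      for (ds in names(disc$profiles)) {
        for (e in names(disc$profiles[[ds]])) {
          feats <- build_features(disc$profiles[[ds]][[e]], disc$invariant)
          cv <- loocv(feats, algo, params = params, seed = config$seed)
          cv_results[[length(cv_results) + 1L]] <- cv
          log_line("stage loocv: ", ds, " x ", e, " x ", algo,
                   " AUC ", sprintf("%.3f", cv$auc))
        }
      }
    }
    if (length(cv_results) >= 2L) {
      report <- aggregate_stability(cv_results)
      write_stability_report(report, file.path(out_dir, "report.json"))
      rep_tsv <- data.frame(
        signature = attr(disc$invariant, "name"),
        n_genes = nrow(disc$invariant),
        median_auc = report$median_auc, iqr = report$iqr,
        cvd = report$cvd, cve = report$cve, stable = report$stable)
      utils::write.table(rep_tsv, file.path(out_dir, "report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      log_line("stage report: skipped (a single cross-validation entry)")
    }
  } else {
    log_line("stage loocv: skipped (no time-invariant genes)")
  }

  external <- NULL
  if (!is.null(config$external) && nrow(disc$invariant) > 0L) {
    ex <- config$external
    e <- ex$exposure %||% names(disc$profiles[[ex$train]])[1]
    tr <- build_features(disc$profiles[[ex$train]][[e]], disc$invariant)
    te <- build_features(disc$profiles[[ex$test]][[e]], disc$invariant)
    external <- external_validate(tr, te,
                                  algorithm = ex$algorithm %||% "rf",
                                  params = list(ntree =
                                                  config$rf_trees %||% 50),
                                  seed = config$seed)
    utils::write.table(
      data.frame(train = ex$train, test = ex$test, exposure = e,
                 auc = external$auc),
      file.path(out_dir, "external.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("stage external: train ", ex$train, " test ", ex$test,
             " AUC ", sprintf("%.3f", external$auc))
  }

  enrichment <- NULL
  if (!is.null(config$catalog) && nrow(disc$invariant) > 0L) {
    cat_obj <- annotation_catalog(config$catalog)
    enrichment <- enrich(disc$invariant$gene, cat_obj)
    utils::write.table(enrichment, file.path(out_dir, "enrich.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("stage enrich: ", sum(enrichment$significant),
             " significant term(s)")
  }

  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  invisible(list(discovery = disc, cv_results = cv_results,
                 report = report, external = external,
                 enrichment = enrichment, simulation = sim))
}
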