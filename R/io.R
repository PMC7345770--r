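# Constructors and TSV I/O for the pipeline's tabular contracts.
#
# expression.tsv : first column probe/gene ID, remaining columns sample IDs
# samples.tsv    : sample_id, chemical_id, exposure_style, dose_group,
#                  replicate, is_control
# labels.tsv     : chemical_id, class in {NGHC, NHC}
# genemap.tsv    : platform, probe_id, gene_symbol ("NA" = absent)

new_expression_study <- function(dataset_id, platform, expression, samples,
                                 exposure_vocab = NULL) {
  st <- structure(list(dataset_id = dataset_id, platform = platform,
                       expression = expression, samples = samples,
                       exposure_vocab = exposure_vocab),
                  class = "ExpressionStudy")
  validate_study(st)
  st
}

#' Validate an ExpressionStudy
#'
#' Checks the study invariants: unique sample IDs, exact agreement between
#' the expression matrix columns and the metadata sample IDs, finite
#' expression values, and (if the study carries an exposure vocabulary)
#' that every exposure style is in it.
#'
#' @param study An `ExpressionStudy`.
#' @return The study, invisibly; stops with a message naming every
#'   offender otherwise.
#' @export
validate_study <- function(study) {
  s <- study$samples
  need <- c("sample_id", "chemical_id", "exposure_style", "dose_group",
            "replicate", "is_control")
  miss <- setdiff(need, names(s))
  if (length(miss) > 0L) {
    stop_input("study '", study$dataset_id, "': metadata lacks column(s) ",
               paste(miss, collapse = ", "))
  }
  dup <- s$sample_id[duplicated(s$sample_id)]
  if (length(dup) > 0L) {
    stop_input("study '", study$dataset_id, "': duplicated sample_id(s): ",
               paste(unique(dup), collapse = ", "))
  }
  only_meta <- setdiff(s$sample_id, colnames(study$expression))
  only_mat <- setdiff(colnames(study$expression), s$sample_id)
  if (length(only_meta) > 0L || length(only_mat) > 0L) {
    stop_input("study '", study$dataset_id,
               "': matrix/metadata sample mismatch",
               if (length(only_meta) > 0L)
                 paste0("; metadata-only: ",
                        paste(only_meta, collapse = ", ")),
               if (length(only_mat) > 0L)
                 paste0("; matrix-only: ", paste(only_mat, collapse = ", ")))
  }
  if (!all(is.finite(study$expression))) {
    bad <- rownames(study$expression)[!apply(is.finite(study$expression),
                                             1, all)]
    stop_input("study '", study$dataset_id,
               "': non-finite expression values in row(s): ",
               paste(utils::head(bad, 10), collapse = ", "))
  }
  if (!is.null(study$exposure_vocab)) {
    unk <- setdiff(unique(s$exposure_style), study$exposure_vocab)
    if (length(unk) > 0L) {
      stop_input("study '", study$dataset_id,
                 "': unknown exposure_style(s): ",
                 paste(unk, collapse = ", "))
    }
  }
  invisible(study)
}

#' Read one dataset's expression matrix and sample metadata
#'
#' Both files are plain TSV with header rows. Expression values must parse
#' as finite numbers; any row with a non-numeric or missing cell is
#' rejected with an error naming the row.
#'
#' @param expression_path TSV, first column probe/gene ID, remaining
#'   columns one per sample (log2 scale).
#' @param metadata_path TSV with columns sample_id, chemical_id,
#'   exposure_style, dose_group, replicate, is_control.
#' @param dataset_id,platform Identifiers attached to the study.
#' @param exposure_vocab Optional allowed exposure tags; metadata using
#'   any other tag is rejected.
#' @return An `ExpressionStudy`.
#' @export
read_study <- function(expression_path, metadata_path, dataset_id,
                       platform = "unknown", exposure_vocab = NULL) {
  for (p in c(expression_path, metadata_path)) {
    if (!file.exists(p)) stop_input("file not found: ", p)
  }
  tab <- utils::read.delim(expression_path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) {
    stop_input(expression_path, ": expected an ID column plus >= 1 sample")
  }
  ids <- tab[[1]]
  vals <- suppressWarnings(
    vapply(tab[-1], as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1L) vals <- matrix(vals, nrow = 1L,
                                      dimnames = list(NULL, names(tab)[-1]))
  bad <- !apply(is.finite(vals), 1, all)
  if (any(bad)) {
    stop_input(expression_path, ": non-numeric expression value(s) in ",
               "row(s): ", paste(utils::head(ids[bad], 10), collapse = ", "))
  }
  rownames(vals) <- ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  meta$is_control <- as.logical(meta$is_control)
  new_expression_study(dataset_id, platform, vals, meta, exposure_vocab)
}

#' Write an ExpressionStudy back to its two TSV files
#'
#' Inverse of [read_study()]: `read_study(write_study(x))` reproduces the
#' expression matrix and metadata exactly (numeric values are written with
#' full precision).
#'
#' @param study An `ExpressionStudy`.
#' @param expression_path,metadata_path Output paths.
#' @return The study, invisibly.
#' @export
write_study <- function(study, expression_path, metadata_path) {
  expr <- study$expression
  df <- data.frame(probe_id = rownames(expr),
                   as.data.frame(expr, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$samples, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(study)
}

#' Read a chemical label table
#'
#' @param path TSV with columns chemical_id, class (NGHC or NHC).
#' @return Named character vector chemical_id -> class.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chemical_id", "class") %in% names(tab))) {
    stop_input(path, ": need columns chemical_id, class")
  }
  bad <- setdiff(unique(tab$class), c("NGHC", "NHC"))
  if (length(bad) > 0L) {
    stop_input(path, ": unknown class value(s): ",
               paste(bad, collapse = ", "))
  }
  if (anyDuplicated(tab$chemical_id)) {
    stop_input(path, ": duplicated chemical_id(s): ",
               paste(unique(tab$chemical_id[duplicated(tab$chemical_id)]),
                     collapse = ", "))
  }
  stats::setNames(tab$class, tab$chemical_id)
}

#' Read a probe-to-gene map
#'
#' @param path TSV with columns platform, probe_id, gene_symbol. A
#'   gene_symbol of `"NA"` means the gene has no probe on that platform;
#'   such rows are dropped.
#' @return Data frame (platform, probe_id, gene_symbol), `(platform,
#'   probe_id)` unique.
#' @export
read_genemap <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("platform", "probe_id", "gene_symbol") %in% names(tab))) {
    stop_input(path, ": need columns platform, probe_id, gene_symbol")
  }
  tab <- tab[!is.na(tab$gene_symbol) & tab$gene_symbol != "NA" &
               nzchar(tab$gene_symbol), , drop = FALSE]
  key <- paste(tab$platform, tab$probe_id)
  if (anyDuplicated(key)) {
    stop_input(path, ": duplicated (platform, probe_id) pair(s): ",
               paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  tab
}

#' Collapse a probe-level study to gene symbols
#'
#' Re-indexes the expression rows from probe IDs to gene symbols using the
#' map rows for the study's platform. Multiple probes mapping to one gene
#' are collapsed by the chosen statistic; probes absent from the map are
#' dropped (their count is reported in a message).
#'
#' @param study An `ExpressionStudy` with probe-level rows.
#' @param map A gene map as returned by [read_genemap()].
#' @param collapse One of `"mean"`, `"median"`, `"max"`.
#' @return An `ExpressionStudy` with gene-symbol rows.
#' @export
map_to_genes <- function(study, map, collapse = c("mean", "median", "max")) {
  collapse <- match.arg(collapse)
  m <- map[map$platform == study$platform, , drop = FALSE]
  m <- m[m$probe_id %in% rownames(study$expression), , drop = FALSE]
  if (nrow(m) == 0L) {
    stop_input("map_to_genes: no probes of study '", study$dataset_id,
               "' (platform '", study$platform, "') found in the map")
  }
  dropped <- nrow(study$expression) - nrow(m)
  if (dropped > 0L) {
    message("map_to_genes: dropped ", dropped,
            " unmapped probe(s) from study '", study$dataset_id, "'")
  }
  expr <- study$expression[m$probe_id, , drop = FALSE]
  fun <- switch(collapse, mean = colMeans,
                median = function(x) apply(x, 2, stats::median),
                max = function(x) apply(x, 2, max))
  genes <- sort(unique(m$gene_symbol))
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(expr),
                dimnames = list(genes, colnames(expr)))
  for (g in genes) {
    rows <- which(m$gene_symbol == g)
    block <- expr[rows, , drop = FALSE]
    out[g, ] <- if (length(rows) == 1L) block[1, ] else fun(block)
  }
  new_expression_study(study$dataset_id, study$platform, out, study$samples,
                       study$exposure_vocab)
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy '", x$dataset_id, "' (platform ", x$platform, ")\n",
      sep = "")
  cat("  ", nrow(x$expression), " genes x ", ncol(x$expression),
      " samples; ", sum(!x$samples$is_control), " treated, ",
      sum(x$samples$is_control), " control\n", sep = "")
  cat("  exposure styles:",
      paste(unique(x$samples$exposure_style), collapse = ", "), "\n")
  invisible(x)
}
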