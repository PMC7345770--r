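# Per-chemical profiles and NGHC-vs-NHC differential expression calls.

#' Per-chemical log2 treated-vs-control expression profiles
#'
#' For one dataset and exposure style, summarises each chemical into a
#' single per-gene profile: mean over its treated replicates minus mean
#' over the applicable control replicates (both on the log2 scale, so the
#' profile is a log2 ratio). The control group is either the dataset's
#' pooled controls for that exposure/dose (`"pooled"`) or the chemical's
#' own matched controls (`"matched"`).
#'
#' @param study An `ExpressionStudy`.
#' @param exposure_style Exposure tag to profile.
#' @param dose_group Dose arm (default `"high"`).
#' @param control_policy `"pooled"` or `"matched"`.
#' @param labels Optional named vector chemical_id -> class (NGHC/NHC),
#'   attached to the result.
#' @return A `ChemicalProfileMatrix`: list with `dataset_id`,
#'   `exposure_style`, `ratios` (genes x chemicals), `labels`.
#' @export
chemical_profiles <- function(study, exposure_style, dose_group = "high",
                              control_policy = c("pooled", "matched"),
                              labels = NULL) {
  control_policy <- match.arg(control_policy)
  s <- study$samples
  sel <- s$exposure_style == exposure_style & s$dose_group == dose_group
  if (!any(sel)) {
    stop_input("chemical_profiles: study '", study$dataset_id,
               "' has no samples at (", exposure_style, ", ", dose_group, ")")
  }
  sub <- s[sel, , drop = FALSE]
  expr <- study$expression[, sub$sample_id, drop = FALSE]
  trt <- sub[!sub$is_control, , drop = FALSE]
  ctl <- sub[sub$is_control, , drop = FALSE]
  chems <- unique(trt$chemical_id)
  if (nrow(ctl) == 0L) {
    stop_input("chemical_profiles: no control samples for (",
               study$dataset_id, ", ", exposure_style, ")")
  }

  trt_means <- group_row_means(expr[, trt$sample_id, drop = FALSE],
                               factor(trt$chemical_id, levels = chems))
  if (control_policy == "pooled") {
    ctl_mean <- rowMeans(expr[, ctl$sample_id, drop = FALSE])
    ratios <- trt_means - ctl_mean
  } else {
    missing <- setdiff(chems, unique(ctl$chemical_id))
    if (length(missing) > 0L) {
      stop_input("chemical_profiles: no matched controls for chemical(s) ",
                 paste(missing, collapse = ", "), " at (",
                 study$dataset_id, ", ", exposure_style, ")")
    }
    ctl_means <- group_row_means(expr[, ctl$sample_id, drop = FALSE],
                                 factor(ctl$chemical_id, levels = chems))
    ratios <- trt_means - ctl_means
  }
  colnames(ratios) <- chems
  if (!is.null(labels)) {
    unl <- setdiff(chems, names(labels))
    if (length(unl) > 0L) {
      stop_input("chemical_profiles: unlabelled chemical(s): ",
                 paste(unl, collapse = ", "))
    }
    labels <- labels[chems]
  }
  structure(list(dataset_id = study$dataset_id,
                 exposure_style = exposure_style,
                 ratios = ratios, labels = labels),
            class = "ChemicalProfileMatrix")
}

#' Differential expression between NGHC and NHC chemical profiles
#'
#' Runs a two-sided two-sample t-test per gene comparing the NGHC
#' chemicals' profile values against the NHC chemicals', and flags a gene
#' as differentially expressed when the p-value is below `alpha` AND the
#' absolute mean log2 difference reaches `log2(fold_threshold)`. The unit
#' of replication is the chemical, not the animal. The default test is
#' Welch's (unequal variances); Student's pooled-variance variant is
#' available for sensitivity checks.
#'
#' @param profiles A `ChemicalProfileMatrix` with labels attached.
#' @param alpha Significance level on the raw p-value (default 0.05; no
#'   multiple-testing correction — robustness comes from the
#'   cross-dataset/cross-exposure intersections downstream).
#' @param fold_threshold Fold-change threshold on the natural scale
#'   (default 1.5, i.e. |delta| >= 0.585 log2 units; equality passes).
#' @param test_variant `"welch"` or `"student"`.
#' @return A `DegTable` data frame: gene, p_value, delta (mean NGHC -
#'   mean NHC, log2), direction ("+"/"-"), is_deg.
#' @export
test_differential <- function(profiles, alpha = 0.05, fold_threshold = 1.5,
                              test_variant = c("welch", "student")) {
  test_variant <- match.arg(test_variant)
  if (is.null(profiles$labels)) {
    stop_input("test_differential: profiles carry no chemical labels")
  }
  x <- profiles$ratios
  lab <- profiles$labels[colnames(x)]
  g1 <- which(lab == "NGHC")
  g2 <- which(lab == "NHC")
  if (length(g1) < 2L || length(g2) < 2L) {
    stop_input("test_differential: need >= 2 chemicals per class (have ",
               length(g1), " NGHC, ", length(g2), " NHC)")
  }
  x1 <- x[, g1, drop = FALSE]
  x2 <- x[, g2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- row_vars(x1); v2 <- row_vars(x2)
  delta <- m1 - m2

  if (test_variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- delta / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(delta))
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate genes: both groups constant. delta == 0 -> no evidence
  # either way (p = 1); delta != 0 -> perfectly separated (p -> 0).
  degen <- !is.finite(p)
  p[degen & delta == 0] <- 1
  p[degen & delta != 0] <- 0

  lfc <- log2(fold_threshold)
  is_deg <- (p < alpha) & (abs(delta) >= lfc) & (delta != 0)
  direction <- ifelse(delta > 0, "+", ifelse(delta < 0, "-", NA_character_))
  structure(data.frame(gene = rownames(x), p_value = p, delta = delta,
                       direction = direction, is_deg = is_deg,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("DegTable", "data.frame"),
            dataset_id = profiles$dataset_id,
            exposure_style = profiles$exposure_style,
            alpha = alpha, fold_threshold = fold_threshold,
            test_variant = test_variant)
}
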