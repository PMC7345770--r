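#' Configuration for the synthetic multi-dataset toxicogenomic simulator
#'
#' Builds and validates the parameter set for [simulate_studies()]. The
#' defaults describe a short-term rodent liver study compendium: three
#' datasets on two microarray platforms, chemicals labelled NGHC
#' (non-genotoxic hepatocarcinogen) or NHC (non-hepatocarcinogen) at the
#' imbalanced ratios typical of the public archives, biological
#' triplicates, and planted signature genes that are either
#' constant-direction across exposure styles (time-invariant) or
#' sign-flipping/transient (time-variant).
#'
#' @param n_genes Number of genes in the simulated genome.
#' @param n_datasets Number of datasets (studies) to generate.
#' @param platforms Character vector of platform tags, one per dataset.
#'   Datasets sharing a tag share a probe ID space and therefore share
#'   which genes are missing. Default alternates two platforms.
#' @param exposure_styles Ordered exposure-duration tags. Default is the
#'   three short-term styles `c("1d", "3d", "1w")`.
#' @param n_nghc,n_nhc Chemicals per class in every dataset. The default
#'   26:62 reflects the strong class imbalance of the real archives.
#' @param n_replicates Biological replicates per chemical x exposure.
#' @param n_invariant_up,n_invariant_down Planted genes shifted up/down by
#'   NGHCs with the same direction at every exposure style.
#' @param n_variant Planted genes whose NGHC effect flips sign or vanishes
#'   at some exposure styles (three archetypes: sign-flip at one exposure,
#'   early-only, late-only).
#' @param effect_size Planted NGHC shift in log2 units; the default
#'   `log2(1.5)` matches the conventional 1.5-fold effect.
#' @param noise_sd Per-probe per-sample Gaussian noise, log2 units.
#' @param dataset_shift_sd SD of additive per-dataset per-gene offsets
#'   (technical disagreement between datasets), log2 units.
#' @param missing_probe_fraction Fraction of genes absent from each
#'   platform's probe space.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log2
#'   intensities.
#' @param control_design `"pooled"` (one control group per dataset x
#'   exposure, shared by all chemicals) or `"matched"` (each chemical has
#'   its own control replicates).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A validated list of class `"SimulationConfig"`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_datasets = 3,
                              platforms = NULL,
                              exposure_styles = c("1d", "3d", "1w"),
                              n_nghc = 26,
                              n_nhc = 62,
                              n_replicates = 3,
                              n_invariant_up = 10,
                              n_invariant_down = 10,
                              n_variant = 10,
                              effect_size = log2(1.5),
                              noise_sd = 0.5,
                              dataset_shift_sd = 0.25,
                              missing_probe_fraction = 0.05,
                              baseline_mean = 8,
                              baseline_sd = 1.5,
                              control_design = c("pooled", "matched"),
                              seed = 1L) {
  control_design <- match.arg(control_design)
  if (is.null(platforms)) {
    platforms <- rep(c("PL_A", "PL_B"), length.out = n_datasets)
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_datasets = as.integer(n_datasets),
    platforms = as.character(platforms),
    exposure_styles = as.character(exposure_styles),
    n_nghc = as.integer(n_nghc), n_nhc = as.integer(n_nhc),
    n_replicates = as.integer(n_replicates),
    n_invariant_up = as.integer(n_invariant_up),
    n_invariant_down = as.integer(n_invariant_down),
    n_variant = as.integer(n_variant),
    effect_size = as.numeric(effect_size),
    noise_sd = as.numeric(noise_sd),
    dataset_shift_sd = as.numeric(dataset_shift_sd),
    missing_probe_fraction = as.numeric(missing_probe_fraction),
    baseline_mean = as.numeric(baseline_mean),
    baseline_sd = as.numeric(baseline_sd),
    control_design = control_design,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_simulation_config <- function(cfg) {
  counts <- c("n_genes", "n_datasets", "n_nghc", "n_nhc", "n_replicates",
              "n_invariant_up", "n_invariant_down", "n_variant")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0L) {
      stop_input("invalid simulation config: field '", f,
                 "' must be a single non-negative count")
    }
  }
  planted <- cfg$n_invariant_up + cfg$n_invariant_down + cfg$n_variant
  if (planted > cfg$n_genes) {
    stop_input("invalid simulation config: field 'n_genes' smaller than ",
               "the total number of planted genes (", planted, ")")
  }
  if (length(cfg$exposure_styles) == 0L ||
      anyDuplicated(cfg$exposure_styles) ||
      any(!nzchar(cfg$exposure_styles))) {
    stop_input("invalid simulation config: field 'exposure_styles' must be ",
               "a non-empty vector of unique non-empty tags")
  }
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stop_input("invalid simulation config: field 'noise_sd' must be > 0")
  }
  if (length(cfg$platforms) != cfg$n_datasets) {
    stop_input("invalid simulation config: field 'platforms' must have ",
               "one tag per dataset")
  }
  if (cfg$missing_probe_fraction < 0 || cfg$missing_probe_fraction >= 1) {
    stop_input("invalid simulation config: field 'missing_probe_fraction' ",
               "must be in [0, 1)")
  }
  if (cfg$n_datasets < 1L) {
    stop_input("invalid simulation config: field 'n_datasets' must be >= 1")
  }
  invisible(cfg)
}

# Per-exposure effect multipliers for planted genes. Invariant genes keep
# multiplier 1 everywhere; variant genes follow one of three archetypes.
variant_pattern <- function(archetype, n_exposures, flip_at) {
  mult <- rep(1, n_exposures)
  # "early" = exposures strictly before the midpoint, "late" = strictly
  # after, so a transient gene carries no planted signal at the middle
  # (typical source) exposure style
  k <- max(1L, n_exposures %/% 2L)
  switch(archetype,
    sign_flip = {
      mult[flip_at] <- -1
      mult
    },
    early_only = {
      if (k < n_exposures) mult[(k + 1):n_exposures] <- 0
      mult
    },
    late_only = {
      mult[seq_len(n_exposures - k)] <- 0
      mult
    },
    stop_input("unknown variant archetype: ", archetype)
  )
}

#' Simulate a multi-dataset, multi-exposure toxicogenomic compendium
#'
#' Generates one [ExpressionStudy][read_study] per dataset together with
#' the ground truth used to plant signal. Control samples are baseline +
#' per-dataset offset + noise; NGHC-treated samples are additionally
#' shifted by `effect_size` on planted genes (with a per-exposure
#' direction pattern for time-variant genes); NHC-treated samples carry no
#' planted signal.
#'
#' @param config A [simulation_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{studies}{List of `ExpressionStudy`, one per dataset.}
#'     \item{truth}{`GroundTruth`: `invariant_genes` (named direction
#'       vector), `variant_genes` (gene x exposure multiplier matrix with
#'       a `direction` attribute), `chemical_labels`.}
#'     \item{labels}{Data frame (chemical_id, class) for the label table.}
#'     \item{config}{The config used.}
#'   }
#' @examples
#' sim <- simulate_studies(simulation_config(n_genes = 100, seed = 7))
#' dim(sim$studies[[1]]$expression)
#' @export
simulate_studies <- function(config) {
  if (!inherits(config, "SimulationConfig")) {
    config <- do.call(simulation_config, config)
  }
  validate_simulation_config(config)
  set.seed(config$seed)
  G <- config$n_genes
  E <- length(config$exposure_styles)
  genes <- sprintf("g%05d", seq_len(G))

  # --- ground truth ------------------------------------------------------
  n_planted <- config$n_invariant_up + config$n_invariant_down +
    config$n_variant
  planted_idx <- if (n_planted > 0L) sample.int(G, n_planted) else integer(0)
  up_idx <- planted_idx[seq_len(config$n_invariant_up)]
  down_idx <- planted_idx[config$n_invariant_up +
                            seq_len(config$n_invariant_down)]
  var_idx <- planted_idx[config$n_invariant_up + config$n_invariant_down +
                           seq_len(config$n_variant)]
  invariant_genes <- c(
    stats::setNames(rep("+", length(up_idx)), genes[up_idx]),
    stats::setNames(rep("-", length(down_idx)), genes[down_idx])
  )
  archetypes <- rep(c("sign_flip", "early_only", "late_only"),
                    length.out = length(var_idx))
  variant_dir <- sample(c("+", "-"), length(var_idx), replace = TRUE)
  variant_mult <- matrix(0, nrow = length(var_idx), ncol = E,
                         dimnames = list(genes[var_idx],
                                         config$exposure_styles))
  if (length(var_idx) > 0L) {
    flip_at <- sample.int(E, length(var_idx), replace = TRUE)
    for (i in seq_along(var_idx)) {
      variant_mult[i, ] <- variant_pattern(archetypes[i], E, flip_at[i])
    }
    attr(variant_mult, "direction") <- stats::setNames(variant_dir,
                                                       genes[var_idx])
    attr(variant_mult, "archetype") <- stats::setNames(archetypes,
                                                       genes[var_idx])
  }

  chems <- c(sprintf("nghc_%03d", seq_len(config$n_nghc)),
             sprintf("nhc_%03d", seq_len(config$n_nhc)))
  chem_labels <- stats::setNames(
    c(rep("NGHC", config$n_nghc), rep("NHC", config$n_nhc)), chems)

  # Signed per-gene per-exposure effect (log2), same for every dataset.
  effect <- matrix(0, nrow = G, ncol = E,
                   dimnames = list(genes, config$exposure_styles))
  effect[up_idx, ] <- config$effect_size
  effect[down_idx, ] <- -config$effect_size
  if (length(var_idx) > 0L) {
    sgn <- ifelse(variant_dir == "+", 1, -1)
    effect[var_idx, ] <- sgn * config$effect_size * variant_mult
  }

  baseline <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)

  # Shared probe space per platform tag.
  platform_genes <- list()
  for (pl in unique(config$platforms)) {
    n_missing <- round(config$missing_probe_fraction * G)
    keep <- rep(TRUE, G)
    if (n_missing > 0L) keep[sample.int(G, n_missing)] <- FALSE
    platform_genes[[pl]] <- genes[keep]
  }

  studies <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    ds_id <- sprintf("DS%d", d)
    pl <- config$platforms[d]
    shift <- stats::rnorm(G, 0, config$dataset_shift_sd)

    # sample metadata in one pass
    meta <- list()
    for (e in seq_len(E)) {
      exp_tag <- config$exposure_styles[e]
      if (config$control_design == "pooled") {
        ctrl <- data.frame(
          sample_id = sprintf("%s_%s_CTRL_r%d", ds_id, exp_tag,
                              seq_len(config$n_replicates)),
          chemical_id = "CONTROL",
          exposure_style = exp_tag, dose_group = "high",
          replicate = seq_len(config$n_replicates), is_control = TRUE,
          stringsAsFactors = FALSE)
      } else {
        ctrl <- data.frame(
          sample_id = sprintf("%s_%s_%s_ctrl_r%d", ds_id, exp_tag,
                              rep(chems, each = config$n_replicates),
                              rep(seq_len(config$n_replicates),
                                  length(chems))),
          chemical_id = rep(chems, each = config$n_replicates),
          exposure_style = exp_tag, dose_group = "high",
          replicate = rep(seq_len(config$n_replicates), length(chems)),
          is_control = TRUE, stringsAsFactors = FALSE)
      }
      trt <- data.frame(
        sample_id = sprintf("%s_%s_%s_r%d", ds_id, exp_tag,
                            rep(chems, each = config$n_replicates),
                            rep(seq_len(config$n_replicates), length(chems))),
        chemical_id = rep(chems, each = config$n_replicates),
        exposure_style = exp_tag, dose_group = "high",
        replicate = rep(seq_len(config$n_replicates), length(chems)),
        is_control = FALSE, stringsAsFactors = FALSE)
      meta[[e]] <- rbind(ctrl, trt)
    }
    meta <- do.call(rbind, meta)
    S <- nrow(meta)

    mu <- matrix(baseline + shift, nrow = G, ncol = S,
                 dimnames = list(genes, meta$sample_id))
    # planted signal only on NGHC-treated columns
    nghc_trt <- which(!meta$is_control &
                        chem_labels[meta$chemical_id] == "NGHC")
    if (length(nghc_trt) > 0L && n_planted > 0L) {
      e_of <- match(meta$exposure_style[nghc_trt], config$exposure_styles)
      mu[planted_idx, nghc_trt] <- mu[planted_idx, nghc_trt] +
        effect[planted_idx, e_of, drop = FALSE]
    }
    expr <- mu + matrix(stats::rnorm(G * S, 0, config$noise_sd),
                        nrow = G, ncol = S)
    expr <- expr[platform_genes[[pl]], , drop = FALSE]
    studies[[d]] <- new_expression_study(ds_id, pl, expr, meta,
                                         exposure_vocab =
                                           config$exposure_styles)
  }
  names(studies) <- vapply(studies, function(s) s$dataset_id, "")

  truth <- structure(list(invariant_genes = invariant_genes,
                          variant_genes = variant_mult,
                          chemical_labels = chem_labels),
                     class = "GroundTruth")
  labels <- data.frame(chemical_id = chems, class = unname(chem_labels),
                       stringsAsFactors = FALSE)
  list(studies = studies, truth = truth, labels = labels, config = config)
}

#' Write a simulated compendium to a directory of TSV files
#'
#' Emits, per dataset, the `<id>_expression.tsv` / `<id>_samples.tsv` pair
#' read back by [read_study()], plus `labels.tsv`, a `truth.tsv` listing
#' every planted gene with its role and direction pattern, and the
#' configuration as YAML.
#'
#' @param sim Result of [simulate_studies()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (st in sim$studies) {
    write_study(st, file.path(dir, paste0(st$dataset_id, "_expression.tsv")),
                file.path(dir, paste0(st$dataset_id, "_samples.tsv")))
  }
  utils::write.table(sim$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  rows <- data.frame(gene = names(tr$invariant_genes),
                     role = "invariant",
                     direction = unname(tr$invariant_genes),
                     stringsAsFactors = FALSE)
  if (nrow(tr$variant_genes) > 0L) {
    dirpat <- apply(tr$variant_genes, 1, function(m) paste(m, collapse = ","))
    rows <- rbind(rows, data.frame(
      gene = rownames(tr$variant_genes), role = "variant",
      direction = paste0(attr(tr$variant_genes, "direction"), ":", dirpat),
      stringsAsFactors = FALSE))
  }
  utils::write.table(rows, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$config)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
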