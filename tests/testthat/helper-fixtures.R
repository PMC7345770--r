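# In-code fixtures and independent oracles shared across the suite.

make_profiles <- function(ratios, labels = NULL, dataset_id = "DS1",
                          exposure = "3d") {
  structure(list(dataset_id = dataset_id, exposure_style = exposure,
                 ratios = ratios, labels = labels),
            class = "ChemicalProfileMatrix")
}

# DegTable consistent with its own invariants
make_deg <- function(genes, delta, p, dataset = "DS1", exposure = "3d",
                     alpha = 0.05, fold = 1.5) {
  is_deg <- (p < alpha) & (abs(delta) >= log2(fold)) & (delta != 0)
  structure(data.frame(gene = genes, p_value = p, delta = delta,
                       direction = ifelse(delta > 0, "+",
                                          ifelse(delta < 0, "-", NA)),
                       is_deg = is_deg, stringsAsFactors = FALSE),
            class = c("DegTable", "data.frame"),
            dataset_id = dataset, exposure_style = exposure,
            alpha = alpha, fold_threshold = fold, test_variant = "welch")
}

make_features <- function(x, labels, dataset = "DS1", exposure = "3d") {
  structure(list(x = x, labels = labels, dataset_id = dataset,
                 exposure_style = exposure), class = "FeatureTable")
}

# chemicals x 3-gene table, NGHC at +2, NHC at -2 (exactly constant by
# default, so every held-out chemical coincides with its training cluster)
separable_features <- function(n_per_class = 10, jitter_sd = 0,
                               seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rep(c(2, -2), each = n_per_class), nrow = n, ncol = 3) +
    matrix(rnorm(3 * n, 0, jitter_sd), nrow = n)
  rownames(x) <- sprintf("chem%02d", seq_len(n))
  colnames(x) <- c("gA", "gB", "gC")
  labels <- setNames(rep(c("NGHC", "NHC"), each = n_per_class),
                     rownames(x))
  make_features(x, labels)
}

# a tiny 3-gene x 4-sample study with pooled controls
tiny_study <- function() {
  expr <- matrix(c(4, 5, 2, 2,
                   1, 1, 1, 1,
                   0, 2, 4, 4), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"),
                                 c("s1", "s2", "s3", "s4")))
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    chemical_id = c("chemX", "chemX", "CONTROL", "CONTROL"),
    exposure_style = "3d", dose_group = "high",
    replicate = c(1, 2, 1, 2),
    is_control = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  tinvmark:::new_expression_study("DS1", "PL_A", expr, meta)
}

# --- independent oracles -------------------------------------------------

# AUC by exhaustive (positive, negative) pair counting, ties = 1/2
auc_pair_oracle <- function(scores, labels, positive = "NGHC") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# linear interpolation between order statistics (quantile type 7)
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[pmin(lo + 2, n)] - x[lo + 1])
}

# P(overlap >= k) by an explicit combinatorial sum
hyper_tail_oracle <- function(k, term_size, universe_size, query_size) {
  jmax <- min(term_size, query_size)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j) {
    choose(term_size, j) * choose(universe_size - term_size,
                                  query_size - j)
  }, numeric(1))) / choose(universe_size, query_size)
}

# small simulated compendium used by several suites
small_sim <- function(seed = 5, ...) {
  args <- list(n_genes = 300, n_datasets = 2,
               exposure_styles = c("1d", "3d", "1w"),
               n_nghc = 8, n_nhc = 16, n_invariant_up = 3,
               n_invariant_down = 3, n_variant = 3, effect_size = 1.2,
               noise_sd = 0.3, missing_probe_fraction = 0, seed = seed)
  args[names(list(...))] <- list(...)
  simulate_studies(do.call(simulation_config, args))
}
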