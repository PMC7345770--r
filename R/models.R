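# Feature tables and leave-one-chemical-out cross-validated classifiers.

#' Build a per-chemical feature table from a biomarker set
#'
#' Transposes the profile matrix to chemicals x genes and restricts the
#' columns to the biomarker genes measured on the profile's platform.
#' Biomarker genes absent from the platform are dropped with a message
#' (e.g. a gene with no probe on the Codelink array simply contributes no
#' feature there).
#'
#' @param profiles A `ChemicalProfileMatrix` with labels.
#' @param set A `BiomarkerSet` (or character vector of genes).
#' @return A `FeatureTable`: list with `x` (chemicals x genes matrix),
#'   `labels`, `dataset_id`, `exposure_style`.
#' @export
build_features <- function(profiles, set) {
  genes <- if (is.data.frame(set)) set$gene else as.character(set)
  present <- intersect(genes, rownames(profiles$ratios))
  if (length(present) == 0L) {
    stop_input("build_features: none of the ", length(genes),
               " biomarker genes are measured in dataset '",
               profiles$dataset_id, "'")
  }
  dropped <- setdiff(genes, present)
  if (length(dropped) > 0L) {
    message("build_features: dropped ", length(dropped),
            " biomarker gene(s) absent from '", profiles$dataset_id,
            "': ", paste(dropped, collapse = ", "))
  }
  x <- t(profiles$ratios[present, , drop = FALSE])
  labels <- profiles$labels[rownames(x)]
  if (any(table(labels) < 1L) || length(unique(labels)) < 2L) {
    stop_input("build_features: need at least one chemical per class")
  }
  structure(list(x = x, labels = labels,
                 dataset_id = profiles$dataset_id,
                 exposure_style = profiles$exposure_style),
            class = "FeatureTable")
}

#' Implemented classifier tags
#'
#' @return Character vector of the algorithm tags accepted by [loocv()]
#'   and [external_validate()]: decision tree (`"dt"`, rpart), bagged
#'   trees (`"bagging"`), gradient-boosted trees (`"boosting"`, xgboost),
#'   k-nearest neighbour (`"knn"`), naive Bayes (`"nb"`), support vector
#'   machine (`"svm"`, RBF kernel), and random forest (`"rf"`).
#' @export
classifier_tags <- function() {
  c("dt", "bagging", "boosting", "knn", "nb", "svm", "rf")
}

# Fit `algorithm` on (x, y) and return P(NGHC) for newx rows. y is a
# factor with levels c("NGHC", "NHC"). Assumes both classes present.
fit_and_score <- function(algorithm, x, y, newx, params = list()) {
  x <- as.matrix(x); newx <- as.matrix(newx)
  switch(algorithm,
    dt = {
      df <- data.frame(.y = y, x, check.names = TRUE)
      nd <- data.frame(newx, check.names = TRUE)
      names(nd) <- names(df)[-1]
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            minsplit = params$minsplit %||% 5, cp = 0.01))
      unname(stats::predict(fit, nd, type = "prob")[, "NGHC"])
    },
    bagging = {
      # bootstrap-aggregated rpart trees; averaged class probabilities
      B <- params$n_bags %||% 25
      df <- data.frame(.y = y, x, check.names = TRUE)
      nd <- data.frame(newx, check.names = TRUE)
      names(nd) <- names(df)[-1]
      acc <- rep(0, nrow(nd))
      used <- 0L
      for (b in seq_len(B)) {
        idx <- sample.int(nrow(df), replace = TRUE)
        if (length(unique(df$.y[idx])) < 2L) next
        fit <- rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                            method = "class",
                            control = rpart::rpart.control(
                              minsplit = params$minsplit %||% 5, cp = 0.01))
        acc <- acc + stats::predict(fit, nd, type = "prob")[, "NGHC"]
        used <- used + 1L
      }
      if (used == 0L) rep(0.5, nrow(nd)) else unname(acc / used)
    },
    boosting = {
      yb <- as.numeric(y == "NGHC")
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth %||% 3,
                      eta = params$eta %||% 0.3, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = yb, nthread = 1),
        nrounds = params$nrounds %||% 30, verbose = 0)
      unname(stats::predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1)))
    },
    knn = {
      k <- min(params$k %||% 3, nrow(x))
      pred <- class::knn(x, newx, cl = y, k = k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "NGHC", p, 1 - p)
    },
    nb = {
      fit <- e1071::naiveBayes(x, y)
      unname(stats::predict(fit, newx, type = "raw")[, "NGHC"])
    },
    svm = {
      fit <- suppressWarnings(
        e1071::svm(x, y, kernel = params$kernel %||% "radial",
                   cost = params$cost %||% 1, scale = FALSE))
      dv_train <- attr(stats::predict(fit, x, decision.values = TRUE),
                       "decision.values")
      dv_new <- attr(stats::predict(fit, newx, decision.values = TRUE),
                     "decision.values")
      # orient so larger means more NGHC-like, then calibrate to [0, 1]
      # by the empirical CDF of the training decision values
      # (rank-preserving; AUC only needs ranks)
      flip <- if (grepl("^NGHC", colnames(dv_train)[1])) 1 else -1
      stats::ecdf(flip * dv_train[, 1])(flip * dv_new[, 1])
    },
    rf = {
      p <- ncol(x)
      fit <- randomForest::randomForest(
        x, y, ntree = params$ntree %||% 50,
        mtry = params$mtry %||% max(1, floor(sqrt(p))))
      unname(stats::predict(fit, newx, type = "prob")[, "NGHC"])
    },
    stop_input("unknown algorithm '", algorithm, "'; see classifier_tags()")
  )
}

#' Leave-one-chemical-out cross-validation
#'
#' The fold unit is the chemical: for each chemical the model is trained
#' on all others and emits a probability-of-NGHC score for the held-out
#' one; the AUC is computed from the pooled out-of-fold scores by the
#' Mann-Whitney convention ([auc_mw()]). A training fold degenerating to a
#' single class scores 0.5 with a warning. The seed is reset before every
#' fold so stochastic learners are reproducible and no fold's result
#' depends on another fold's random draws.
#'
#' @param features A `FeatureTable`.
#' @param algorithm One of [classifier_tags()].
#' @param params Named list of algorithm parameters. For `"rf"`,
#'   `ntree = "auto"` selects the tree count on the same LOOCV via
#'   [select_n_trees()].
#' @param seed Integer seed governing every stochastic learner.
#' @return A `CvResult`: list with `dataset_id`, `exposure_style`,
#'   `algorithm`, `scores` (named per chemical), `labels`, `auc`, and
#'   `n_trees_selected` for the random forest with automatic selection.
#' @export
loocv <- function(features, algorithm, params = list(), seed = 1L) {
  labs <- features$labels
  if (min(table(labs)) < 2L) {
    stop_input("loocv: need >= 2 chemicals per class")
  }
  n_trees_selected <- NULL
  if (algorithm == "rf" && identical(params$ntree, "auto")) {
    n_trees_selected <- select_n_trees(features, seed = seed)
    params$ntree <- n_trees_selected
  }
  chems <- rownames(features$x)
  y <- factor(labs, levels = c("NGHC", "NHC"))
  scores <- stats::setNames(rep(NA_real_, length(chems)), chems)
  for (i in seq_along(chems)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      warning("loocv: single-class training fold for chemical '",
              chems[i], "'; scoring 0.5")
      scores[i] <- 0.5
      next
    }
    set.seed(seed)
    scores[i] <- fit_and_score(algorithm,
                               features$x[-i, , drop = FALSE], ytr,
                               features$x[i, , drop = FALSE], params)
  }
  structure(list(dataset_id = features$dataset_id,
                 exposure_style = features$exposure_style,
                 algorithm = algorithm, scores = scores,
                 labels = labs, auc = auc_mw(scores, labs),
                 n_trees_selected = n_trees_selected),
            class = "CvResult")
}

#' Select the random-forest tree count by LOOCV AUC
#'
#' Replays the leave-one-chemical-out cross-validation at every tree count
#' on the grid and returns the count with the highest AUC, breaking ties
#' toward the smaller count. Note the selection uses the same LOOCV later
#' used for reporting, so the reported AUC of the selected count carries
#' the usual optimistic selection bias.
#'
#' @param features A `FeatureTable`.
#' @param counts Tree-count grid (default 10 to 100 in steps of 10).
#' @param seed Seed passed to every LOOCV replay.
#' @return The selected tree count (integer). The full grid of AUCs is
#'   attached as attribute `"grid_auc"`.
#' @export
select_n_trees <- function(features, counts = seq(10L, 100L, by = 10L),
                           seed = 1L) {
  if (length(counts) == 0L) stop_input("select_n_trees: empty grid")
  counts <- sort(as.integer(counts))
  aucs <- vapply(counts, function(nt) {
    loocv(features, "rf", params = list(ntree = nt), seed = seed)$auc
  }, numeric(1))
  structure(counts[which.max(aucs)],
            grid_auc = stats::setNames(aucs, counts))
}
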