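mk_entries <- function(aucs, datasets, exposures) {
  aggregate_stability(aucs, datasets = datasets, exposures = exposures)
}

test_that("constant AUCs give zero variance and a stable verdict", {
  rep_const <- mk_entries(rep(0.8, 6),
                          datasets = rep(c("D1", "D2", "D3"), 2),
                          exposures = rep(c("1d", "3d"), each = 3))
  expect_equal(rep_const$median_auc, 0.8)
  expect_equal(rep_const$iqr, 0)
  expect_equal(rep_const$cvd, 0)
  expect_equal(rep_const$cve, 0)
  expect_true(rep_const$stable)
})

test_that("two-entry reports match the hand-coded closed form", {
  r <- mk_entries(c(0.6, 0.8), datasets = c("D1", "D2"),
                  exposures = c("1d", "1d"))
  expect_equal(r$median_auc, 0.7)
  expect_equal(r$iqr, 0.1)          # type-7 quartiles of {0.6, 0.8}
  expect_equal(r$cvd, 100 * sd(c(0.6, 0.8)) / mean(c(0.6, 0.8)))
  expect_equal(r$cve, 0)            # a single exposure group
})

test_that("median and IQR equal an independent sort-and-interpolate
           oracle on random AUC tables", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    aucs <- round(runif(n, 0.4, 1), 3)
    r <- mk_entries(aucs, datasets = sample(c("D1", "D2"), n, TRUE),
                    exposures = sample(c("1d", "3d", "1w"), n, TRUE))
    expect_equal(r$median_auc, quantile7_oracle(aucs, 0.5))
    expect_equal(r$iqr, quantile7_oracle(aucs, 0.75) -
                   quantile7_oracle(aucs, 0.25))
  }
  # two-pass sample-sd C.V. over per-group medians, hand-coded
  aucs <- c(0.9, 0.7, 0.8, 0.6)
  ds <- c("D1", "D1", "D2", "D2")
  ex <- c("1d", "3d", "1d", "3d")
  r <- mk_entries(aucs, ds, ex)
  med_ds <- c(median(aucs[ds == "D1"]), median(aucs[ds == "D2"]))
  m <- mean(med_ds)
  s <- sqrt(sum((med_ds - m)^2) / (length(med_ds) - 1))
  expect_equal(r$cvd, 100 * s / m)
  med_ex <- c(median(aucs[ex == "1d"]), median(aucs[ex == "3d"]))
  expect_equal(r$cve, 100 * sd(med_ex) / mean(med_ex))
})

test_that("the 5% rule flips the verdict exactly at the boundary", {
  # IQR of {0, 0, 0, d} under type 7 is 0.25 * d; 0.25 * 0.2 is exactly
  # the double nearest 0.05, so this sits exactly on the threshold
  at <- mk_entries(c(0, 0, 0, 0.2),
                   datasets = "D1", exposures = "1d")
  expect_identical(at$iqr, 0.05)
  expect_true(at$stable)            # <= is stable
  over <- mk_entries(c(0, 0, 0, 0.21),
                     datasets = "D1", exposures = "1d")
  expect_gt(over$iqr, 0.05)
  expect_false(over$stable)
  # a C.V.d just above 5% alone breaks stability
  x <- c(0.7, 0.7, 0.774, 0.774)    # cvd ~ 7%, iqr type7 = 0.0555 -> also >
  r <- mk_entries(c(0.7, 0.73), datasets = c("D1", "D2"),
                  exposures = c("1d", "1d"))
  expect_lt(r$iqr, 0.05)
  expect_lt(r$cvd, 5)
  expect_true(r$stable)
  r2 <- mk_entries(c(0.7, 0.755), datasets = c("D1", "D2"),
                   exposures = c("1d", "1d"))
  expect_gt(r2$cvd, 5)
  expect_false(r2$stable)
})

test_that("aggregation ignores entry order and serialises losslessly", {
  set.seed(42)
  aucs <- runif(8, 0.5, 1)
  ds <- rep(c("D1", "D2"), 4)
  ex <- rep(c("1d", "3d", "1w", "14d"), each = 2)
  a <- mk_entries(aucs, ds, ex)
  perm <- sample(8)
  b <- mk_entries(aucs[perm], ds[perm], ex[perm])
  for (f in c("median_auc", "iqr", "cvd", "cve", "stable")) {
    expect_equal(a[[f]], b[[f]])
  }
  path <- withr::local_tempfile(fileext = ".json")
  write_stability_report(a, path)
  back <- read_stability_report(path)
  expect_equal(back$median_auc, a$median_auc)
  expect_equal(back$cvd, a$cvd)
  expect_equal(back$entries$auc, a$entries$auc)
  expect_equal(back$stable, a$stable)
})

test_that("external validation scores an independent dataset", {
  tr <- separable_features(10, seed = 1)
  te <- separable_features(10, seed = 2)
  ext <- external_validate(tr, te, "knn")
  expect_equal(ext$auc, 1.0)
  expect_equal(ext$auc, auc_pair_oracle(ext$scores, te$labels))
  # permuted test labels -> chance-level AUC
  set.seed(43)
  x <- matrix(rnorm(60 * 3), nrow = 60,
              dimnames = list(sprintf("c%02d", 1:60), colnames(tr$x)))
  labs <- setNames(sample(rep(c("NGHC", "NHC"), each = 30)), rownames(x))
  ext0 <- external_validate(tr, make_features(x, labs), "nb")
  expect_lt(abs(ext0$auc - 0.5), 0.15)
  # no shared genes, or a single-class test set, are errors
  te_bad <- make_features(matrix(rnorm(20), 10,
                                 dimnames = list(paste0("c", 1:10),
                                                 c("zz1", "zz2"))),
                          setNames(rep(c("NGHC", "NHC"), 5),
                                   paste0("c", 1:10)))
  expect_error(external_validate(tr, te_bad, "knn"), "share no")
  te_one <- make_features(te$x, setNames(rep("NHC", 20),
                                         rownames(te$x)))
  expect_error(external_validate(tr, te_one, "knn"), "single class")
})
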