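test_that("chemical profiles are treated-mean minus control-mean", {
  expr <- rbind(gA = c(4, 5, 6, 2, 2, 2), gB = c(1, 1, 1, 1, 1, 1))
  colnames(expr) <- paste0("s", 1:6)
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     chemical_id = c(rep("chemX", 3), rep("CONTROL", 3)),
                     exposure_style = "3d", dose_group = "high",
                     replicate = c(1:3, 1:3),
                     is_control = rep(c(FALSE, TRUE), each = 3))
  st <- tinvmark:::new_expression_study("DS1", "PL_A", expr, meta)
  prof <- chemical_profiles(st, "3d")
  expect_equal(prof$ratios["gA", "chemX"], 3.0)
  expect_equal(prof$ratios["gB", "chemX"], 0.0)   # treated == control
  expect_error(chemical_profiles(st, "1d"), "no samples")
})

test_that("pooled and matched control policies agree when each chemical's
           controls equal the pool", {
  set.seed(4)
  ctrl_vals <- matrix(rnorm(5 * 2), nrow = 5)
  chems <- c("c1", "c2")
  cols <- list()
  meta <- list()
  for (ch in chems) {
    trt <- matrix(rnorm(5 * 2, mean = 1), nrow = 5)
    cols[[paste0(ch, "_t")]] <- trt
    cols[[paste0(ch, "_c")]] <- ctrl_vals      # same controls for both
    meta[[ch]] <- data.frame(
      sample_id = paste0(ch, c("_t1", "_t2", "_c1", "_c2")),
      chemical_id = ch, exposure_style = "3d", dose_group = "high",
      replicate = c(1, 2, 1, 2), is_control = c(FALSE, FALSE, TRUE, TRUE))
  }
  expr <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  colnames(expr) <- meta$sample_id
  rownames(expr) <- paste0("g", 1:5)
  st <- tinvmark:::new_expression_study("DS1", "PL_A", expr, meta)
  pooled <- chemical_profiles(st, "3d", control_policy = "pooled")
  matched <- chemical_profiles(st, "3d", control_policy = "matched")
  expect_equal(pooled$ratios, matched$ratios)
})

test_that("missing matched controls raise a cell-naming error", {
  st <- tiny_study()   # pooled controls only
  expect_error(chemical_profiles(st, "3d", control_policy = "matched"),
               "chemX")
})

test_that("forced separation is called a DEG and identical groups are
           not", {
  set.seed(9)
  ratios <- rbind(
    sep  = c(2, 2, 2, 2, 0, 0, 0, 0) + rnorm(8, 0, 1e-3),
    null = rep(1, 8))
  colnames(ratios) <- paste0("c", 1:8)
  labels <- setNames(rep(c("NGHC", "NHC"), each = 4), colnames(ratios))
  deg <- test_differential(make_profiles(ratios, labels))
  expect_true(deg$is_deg[deg$gene == "sep"])
  expect_identical(deg$direction[deg$gene == "sep"], "+")
  expect_false(deg$is_deg[deg$gene == "null"])
  expect_equal(deg$p_value[deg$gene == "null"], 1)  # zero variance, delta 0
})

test_that("Welch p-values and deltas match stats::t.test to 1e-10", {
  set.seed(11)
  ratios <- matrix(rnorm(50 * 14), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("c%02d", 1:14)))
  labels <- setNames(rep(c("NGHC", "NHC"), c(5, 9)), colnames(ratios))
  deg <- test_differential(make_profiles(ratios, labels))
  for (i in 1:50) {
    tt <- t.test(ratios[i, 1:5], ratios[i, 6:14], var.equal = FALSE)
    expect_lt(abs(deg$p_value[i] - tt$p.value), 1e-10)
    expect_lt(abs(deg$delta[i] - diff(rev(tt$estimate))), 1e-10)
  }
  st <- test_differential(make_profiles(ratios, labels),
                          test_variant = "student")
  for (i in c(1, 25, 50)) {
    tt <- t.test(ratios[i, 1:5], ratios[i, 6:14], var.equal = TRUE)
    expect_lt(abs(st$p_value[i] - tt$p.value), 1e-10)
  }
})

test_that("DEG calls are monotone in alpha and fold threshold", {
  set.seed(12)
  ratios <- matrix(rnorm(100 * 12, sd = 0.6), nrow = 100)
  ratios[1:20, 1:5] <- ratios[1:20, 1:5] + 0.8
  dimnames(ratios) <- list(sprintf("g%03d", 1:100), sprintf("c%02d", 1:12))
  labels <- setNames(rep(c("NGHC", "NHC"), c(5, 7)), colnames(ratios))
  prof <- make_profiles(ratios, labels)
  base <- test_differential(prof, alpha = 0.05, fold_threshold = 1.5)
  tighter_a <- test_differential(prof, alpha = 0.01, fold_threshold = 1.5)
  tighter_f <- test_differential(prof, alpha = 0.05, fold_threshold = 2)
  expect_true(all(base$is_deg[tighter_a$is_deg]))
  expect_true(all(base$is_deg[tighter_f$is_deg]))
  # a delta exactly at the threshold passes (>=); perfectly separated
  # constant groups get p = 0, not an error
  const <- rbind(edge = rep(c(log2(1.5), 0), c(5, 7)))
  colnames(const) <- colnames(ratios)
  d2 <- test_differential(make_profiles(const, labels),
                          fold_threshold = 1.5)
  expect_equal(d2$delta, log2(1.5))
  expect_true(d2$is_deg)
})

test_that("the test ignores chemical order and per-gene constant shifts", {
  set.seed(13)
  ratios <- matrix(rnorm(20 * 10), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("c%02d", 1:10)))
  labels <- setNames(rep(c("NGHC", "NHC"), each = 5), colnames(ratios))
  a <- test_differential(make_profiles(ratios, labels))
  perm <- sample(ncol(ratios))
  b <- test_differential(make_profiles(ratios[, perm], labels[perm]))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$delta, b$delta)
  shifted <- ratios + 5
  c <- test_differential(make_profiles(shifted, labels))
  expect_equal(a$p_value, c$p_value, tolerance = 1e-12)
})

test_that("fewer than two chemicals per class is an error", {
  ratios <- matrix(rnorm(5 * 3), nrow = 5,
                   dimnames = list(paste0("g", 1:5), paste0("c", 1:3)))
  labels <- setNames(c("NGHC", "NHC", "NHC"), colnames(ratios))
  expect_error(test_differential(make_profiles(ratios, labels)),
               "2 chemicals per class")
})
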