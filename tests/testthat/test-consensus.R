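test_that("consensus keeps unanimous DEGs and drops conflicts", {
  t1 <- make_deg(c("up", "conf", "weak"), c(1, 1, 1), c(0.01, 0.01, 0.5))
  t2 <- make_deg(c("up", "conf", "weak"), c(1.2, 1, 0.9),
                 c(0.02, 0.03, 0.01), dataset = "DS2")
  t3 <- make_deg(c("up", "conf", "weak"), c(0.9, -1, 1),
                 c(0.01, 0.01, 0.01), dataset = "DS3")
  set <- consensus_set(list(t1, t2, t3))
  expect_identical(set$gene, "up")              # unanimous in all three
  expect_identical(set$direction, "+")
  # "conf": up in two tables, down in one -> excluded
  # "weak": not significant in DS1 -> excluded under the all-datasets rule
  loose <- consensus_set(list(t1, t2, t3), min_datasets = 2)
  expect_true("weak" %in% loose$gene)
  expect_false("conf" %in% loose$gene)          # direction conflict stays out
})

test_that("min_datasets = 1 gives the union of direction-unanimous DEGs", {
  t1 <- make_deg(c("a", "b"), c(1, 0.1), c(0.01, 0.5))
  t2 <- make_deg(c("a", "b"), c(0.1, -1), c(0.5, 0.01), dataset = "DS2")
  u <- consensus_set(list(t1, t2), min_datasets = 1)
  expect_setequal(u$gene, c("a", "b"))
  expect_identical(u$direction[u$gene == "b"], "-")
})

test_that("consensus matches an exhaustive per-gene scan on a random
           200-gene fixture", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:200)
  tabs <- lapply(1:3, function(d) {
    make_deg(genes, delta = round(rnorm(200), 1) * 0.8,
             p = runif(200), dataset = paste0("DS", d))
  })
  got <- consensus_set(tabs)
  expected <- character(0)
  for (i in 1:200) {
    deg_in <- vapply(tabs, function(t) t$is_deg[i], logical(1))
    dirs <- vapply(tabs, function(t) t$direction[i], character(1))
    if (all(deg_in) && length(unique(dirs[deg_in])) == 1L) {
      expected <- c(expected, genes[i])
    }
  }
  expect_setequal(got$gene, expected)
})

test_that("empty intersections give an empty set with a message", {
  t1 <- make_deg("a", 1, 0.01)
  t2 <- make_deg("a", 1, 0.9, dataset = "DS2")
  expect_message(s <- consensus_set(list(t1, t2)), "empty")
  expect_equal(nrow(s), 0L)
})

test_that("cross-exposure calls follow sign unanimity and drive the
           time-invariance flag", {
  mk <- function(deltas, exposure, dataset) {
    make_deg(c("inv", "flip", "tie", "gone"), deltas,
             rep(0.01, 4), dataset = dataset, exposure = exposure)
  }
  deg_by <- list(
    "1d" = list(mk(c(1, -1, 1, 1), "1d", "DS1"),
                mk(c(1, -1, 1, 1), "1d", "DS2")),
    "3d" = list(mk(c(1, -1, 0.5, 1), "3d", "DS1"),
                mk(c(1, -1, 0.7, 1), "3d", "DS2")),
    "1w" = list(mk(c(1, 1, 0, 1), "1w", "DS1"),
                mk(c(1, 1, 0.2, 1), "1w", "DS2")))
  # "gone" is unmeasured at 1w
  deg_by[["1w"]] <- lapply(deg_by[["1w"]], function(t) t[t$gene != "gone", ])
  cons <- structure(data.frame(gene = c("inv", "flip", "tie", "gone"),
                               direction = c("+", "-", "+", "+")),
                    class = c("BiomarkerSet", "data.frame"),
                    name = "fix", source_exposure = "3d")
  mod <- cross_check(cons, deg_by, required_exposures = c("1d", "3d", "1w"))
  expect_identical(unlist(mod[mod$gene == "inv", c("1d", "3d", "1w")],
                          use.names = FALSE), c("+", "+", "+"))
  expect_true(mod$time_invariant[mod$gene == "inv"])
  # sign flip at 1w -> calls (-, -, +), not invariant
  expect_false(mod$time_invariant[mod$gene == "flip"])
  # delta exactly 0 in one dataset -> "+/-" at that exposure
  expect_identical(mod[mod$gene == "tie", "1w"], "+/-")
  expect_false(mod$time_invariant[mod$gene == "tie"])
  # absent at a required exposure -> "absent", not invariant
  expect_identical(mod[mod$gene == "gone", "1w"], "absent")
  expect_false(mod$time_invariant[mod$gene == "gone"])
  # a single required exposure with unanimous signs is trivially invariant
  mod1 <- cross_check(cons, deg_by["1d"], required_exposures = "1d")
  expect_true(all(mod1$time_invariant))
  # flags do not depend on dataset or exposure ordering
  deg_rev <- lapply(deg_by, rev)[c("1w", "3d", "1d")]
  mod_rev <- cross_check(cons, deg_rev,
                         required_exposures = c("1w", "3d", "1d"))
  expect_identical(mod$time_invariant[order(mod$gene)],
                   mod_rev$time_invariant[order(mod_rev$gene)])
})

test_that("the invariance rule reproduces the published verdicts of the
           shipped modulation fixture", {
  tab <- read_modulation_calls()
  expect_equal(nrow(tab), 57L)
  flags <- modulation_flags(tab[, c("call_1d", "call_3d", "call_1w")])
  expect_identical(unname(flags), tab$time_invariant == "Yes")
  three_day <- tab[tab$set == "consensus_3d" & flags, ]
  expect_setequal(three_day$gene,
                  c("A2m", "Akr7a3", "Aqp7", "Ca3", "Cdc2a", "Cdkn3",
                    "Cyp2c11", "Ntf3", "Sds"))
})

test_that("invariant_set subsets the consensus to flagged genes", {
  cons <- structure(data.frame(gene = c("a", "b"), direction = c("+", "-")),
                    class = c("BiomarkerSet", "data.frame"),
                    name = "c3d", source_exposure = "3d")
  mod <- data.frame(gene = c("a", "b"), time_invariant = c(TRUE, FALSE))
  inv <- invariant_set(mod, cons)
  expect_identical(inv$gene, "a")
  expect_identical(attr(inv, "source_exposure"), "3d")
})
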