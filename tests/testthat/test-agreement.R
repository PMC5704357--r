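test_that("confusion tables cross-tabulate per-unit labels", {
  ref <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  tab <- confusionTable(ref, ref)
  expect_equal(tab@FP, 0L); expect_equal(tab@FN, 0L)
  expect_equal(sensitivity(tab), 1); expect_equal(specificity(tab), 1)

  tabNeg <- confusionTable(ref, rep(FALSE, 5))
  expect_equal(tabNeg@TP, 0L); expect_equal(tabNeg@FP, 0L)
  expect_equal(sensitivity(tabNeg), 0)
  expect_equal(specificity(tabNeg), 1)

  expect_error(confusionTable(c(TRUE, FALSE), TRUE), "mismatch")
  expect_error(confusionTable(logical(), logical()), "at least one")
})

test_that("confusion counts match a four-way counting oracle", {
  set.seed(61)
  ref <- runif(100) < 0.5
  test <- runif(100) < 0.4
  tab <- confusionTable(ref, test)
  expect_equal(tab@TP, sum(ref & test))
  expect_equal(tab@FP, sum(!ref & test))
  expect_equal(tab@FN, sum(ref & !test))
  expect_equal(tab@TN, sum(!ref & !test))
  expect_equal(tab@TP + tab@FP + tab@FN + tab@TN, 100L)
})

test_that("undefined sensitivity or specificity is NA, not a number", {
  allNeg <- confusionTable(c(FALSE, FALSE), c(FALSE, TRUE))
  expect_true(is.na(sensitivity(allNeg)))
  allPos <- confusionTable(c(TRUE, TRUE), c(TRUE, FALSE))
  expect_true(is.na(specificity(allPos)))
})

test_that("marginal counts reconstruct the published agreement tables", {
  # spine, per image set
  spine <- confusionFromCounts(85, 60, 56, 19)
  expect_equal(c(spine@TP, spine@FN, spine@FP, spine@TN),
               c(50L, 10L, 6L, 19L))
  expect_equal(sensitivity(spine), 50 / 60)
  expect_equal(specificity(spine), 19 / 25)
  expect_equal(round(100 * sensitivity(spine)), 83)
  expect_equal(round(100 * specificity(spine)), 76)
  # sacroiliac joints, per image set
  si <- confusionFromCounts(95, 35, 25, 53)
  expect_equal(round(100 * sensitivity(si)), 51)
  expect_equal(round(100 * specificity(si)), 88)
  # sacroiliac joints, per slice
  slices <- confusionFromCounts(570, 84, 92, 434)
  expect_equal(round(100 * sensitivity(slices)), 48)
  expect_equal(round(100 * specificity(slices)), 89)
})

test_that("inconsistent marginal counts name the offending cell", {
  expect_error(confusionFromCounts(10, 2, 1, 9), "FP")
  expect_error(confusionFromCounts(10, 2, 1, 2), "TP")
  expect_error(confusionFromCounts(10, 2, 9, 8), "FN")
})

test_that("count-based and label-based tables agree when labels exist", {
  set.seed(62)
  for (i in 1:10) {
    ref <- runif(40) < 0.5
    test <- runif(40) < 0.5
    tab <- confusionTable(ref, test)
    tab2 <- confusionFromCounts(40, sum(ref), sum(test), sum(!ref & !test))
    expect_equal(c(tab2@TP, tab2@FP, tab2@FN, tab2@TN),
                 c(tab@TP, tab@FP, tab@FN, tab@TN))
  }
})

test_that("swapping reference and test transposes, not relabels, the table", {
  ref <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  tst <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  a <- confusionTable(ref, tst)
  b <- confusionTable(tst, ref)
  expect_equal(b@TP, a@TP); expect_equal(b@TN, a@TN)
  expect_equal(b@FP, a@FN); expect_equal(b@FN, a@FP)
  expect_false(isTRUE(all.equal(sensitivity(a), sensitivity(b))))
})

test_that("Spearman's rho follows the mid-rank Pearson definition", {
  expect_equal(spearmanRho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearmanRho(1:3, c(3, 2, 1)), -1)
  set.seed(63)
  for (i in 1:20) {
    x <- sample(1:8, 50, replace = TRUE)   # heavy ties
    y <- x + rpois(50, 3) - sample(0:2, 50, replace = TRUE)
    expect_equal(spearmanRho(x, y), spearmanOracle(x, y), tolerance = 1e-12)
  }
})

test_that("Spearman's rho is invariant under increasing transforms", {
  set.seed(64)
  x <- rnorm(30); y <- rnorm(30) + 0.5 * x
  rho <- spearmanRho(x, y)
  expect_equal(spearmanRho(exp(x), y), rho, tolerance = 1e-12)
  expect_equal(spearmanRho(x, y^3 + 10 * y), rho, tolerance = 1e-12)
  expect_warning(out <- spearmanRho(rep(1, 5), 1:5), "undefined")
  expect_true(is.na(out))
  expect_error(spearmanRho(1:2, 1:2), "3")
})

test_that("cohort aggregation spreads positive-set means over all sets", {
  # 60 positive spine sets, mean score 10.5, 85 sets in total
  spine <- aggregateCohort(rep(10.5, 60), nTotal = 85)
  expect_equal(round(spine[["mean"]], 1), 7.4)
  expect_equal(spine[["min"]], 0)
  # 25 lesion-positive SI sets with mean volume 2.77 cm^3 among 95
  si <- aggregateCohort(rep(2.77, 25), nTotal = 95)
  expect_equal(round(si[["mean"]], 2), 0.73)
  # positives-only view of a single value
  one <- aggregateCohort(5.5, nTotal = 10, includeZeros = FALSE)
  expect_equal(unname(one), c(5.5, 5.5, 5.5))
  expect_error(aggregateCohort(1:3, nTotal = 0), "nTotal")
  expect_error(aggregateCohort(1:3, nTotal = 2), "nTotal")
  expect_error(aggregateCohort(1:3, nTotal = 5, nPositive = 2), "nPositive")
})

test_that("agreementStats joins results to labels and cross-tabulates", {
  results <- data.frame(id = c("s1", "s2", "s3", "s4"),
                        volume_hyper = c(0, 2.5, 0.3, 0),
                        n_objects = c(0L, 2L, 1L, 0L))
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject,image_set,slice,score",
               "p1,s1,,0", "p1,s2,,12", "p2,s3,,3", "p2,s4,,4"), f)
  labels <- readLabelTable(f)
  out <- agreementStats(results, labels)
  expect_equal(out$table@TP, 2L)
  expect_equal(out$table@FN, 1L)
  expect_equal(out$table@TN, 1L)
  expect_equal(out$spearman,
               spearmanOracle(c(0, 12, 3, 4), c(0, 2.5, 0.3, 0)))
  unlink(f)
})
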