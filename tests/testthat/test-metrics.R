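test_that("per-base confusion counts follow the sample definitions", {
  # hand-counted example: reference pairs (1,10),(2,9); prediction
  # (1,10),(3,8); bases 1,10 TP; 2,9 FN; 3,8 FP; 4..7 TN
  ref <- pairs_to_contact(rbind(c(1, 10), c(2, 9)), 10)
  pred <- pairs_to_contact(rbind(c(1, 10), c(3, 8)), 10)
  cc <- confusion_per_base(ref, pred)
  expect_identical(unclass(cc)[c("TP", "TN", "FP", "FN")],
                   list(TP = 2L, TN = 4L, FP = 2L, FN = 2L))
  # perfect prediction
  cc2 <- confusion_per_base(ref, ref)
  expect_identical(c(cc2$FP, cc2$FN), c(0L, 0L))
  expect_identical(c(cc2$TP, cc2$TN), c(4L, 6L))
  # empty vs empty
  empty <- matrix(0, 7, 7)
  cc3 <- confusion_per_base(empty, empty)
  expect_identical(cc3$TN, 7L)
  expect_identical(cc3$TP + cc3$FP + cc3$FN, 0L)
  # a wrongly partnered reference base is FN only, never FP
  ref4 <- pairs_to_contact(rbind(c(1, 10)), 14)
  pred4 <- pairs_to_contact(rbind(c(1, 12)), 14)
  cc4 <- confusion_per_base(ref4, pred4)
  expect_identical(unclass(cc4)[c("TP", "TN", "FP", "FN")],
                   list(TP = 0L, TN = 11L, FP = 1L, FN = 2L))
  expect_error(confusion_per_base(empty, matrix(0, 8, 8)), "disagree")
})

test_that("confusion counts always conserve the number of bases", {
  set.seed(14)
  for (rep in 1:25) {
    L <- sample(15:50, 1)
    cfg <- fixture_config(length_min = 20L, length_max = 60L, seed = rep)
    p1 <- sample_structure(L, cfg)
    p2 <- sample_structure(L, cfg)
    cc <- confusion_per_base(pairs_to_contact(p1, L), pairs_to_contact(p2, L))
    expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, L)
  }
})

test_that("metrics match their defining formulas", {
  m <- compute_metrics(structure(list(TP = 2L, TN = 4L, FP = 2L, FN = 2L),
                                 class = "confusion_counts"))
  expect_equal(m$acc, 0.6)
  expect_equal(m$sen, 0.5)
  expect_equal(m$ppv, 0.5)
  expect_equal(m$fscore, 0.5)
  perfect <- compute_metrics(structure(list(TP = 5L, TN = 5L, FP = 0L, FN = 0L),
                                       class = "confusion_counts"))
  expect_equal(c(perfect$acc, perfect$sen, perfect$ppv, perfect$fscore),
               rep(1, 4))
  # harmonic mean sits between sensitivity and precision
  set.seed(3)
  for (rep in 1:20) {
    cc <- structure(as.list(setNames(sample(0:30, 4, replace = TRUE) + 1L,
                                     c("TP", "TN", "FP", "FN"))),
                    class = "confusion_counts")
    m <- compute_metrics(cc)
    expect_gte(m$fscore, min(m$sen, m$ppv) - 1e-12)
    expect_lte(m$fscore, max(m$sen, m$ppv) + 1e-12)
  }
  # undefined ratios are flagged, not NaN
  m0 <- compute_metrics(structure(list(TP = 0L, TN = 5L, FP = 0L, FN = 0L),
                                  class = "confusion_counts"))
  expect_false(m0$sen_defined)
  expect_equal(m0$fscore, 0)
  expect_error(compute_metrics(structure(list(TP = 0L, TN = 0L, FP = 0L,
                                              FN = 0L),
                                         class = "confusion_counts")),
               "zero")
})

test_that("metrics ignore the orientation pairs are supplied in", {
  ref <- pairs_to_contact(rbind(c(10, 1), c(2, 9)), 10)   # (j, i) order
  ref2 <- pairs_to_contact(rbind(c(1, 10), c(9, 2)), 10)
  pred <- pairs_to_contact(rbind(c(1, 10)), 10)
  expect_identical(unclass(confusion_per_base(ref, pred)),
                   unclass(confusion_per_base(ref2, pred)))
})

test_that("micro aggregation pools counts before ratios", {
  refs <- list(pairs_to_contact(rbind(c(1, 10)), 10),
               pairs_to_contact(rbind(c(1, 8), c(2, 7)), 12))
  preds <- list(pairs_to_contact(rbind(c(1, 10)), 10),
                pairs_to_contact(matrix(integer(0), ncol = 2), 12))
  micro <- evaluate_structures(refs, preds)
  expect_equal(micro$counts$TP, 2L)
  expect_equal(micro$counts$FN, 4L)
  expect_equal(micro$sen, 2 / 6)
  macro <- evaluate_structures(refs, preds, macro = TRUE)
  expect_equal(macro$sen, mean(c(1, 0)))
})

test_that("cross-validation folds partition deterministically", {
  folds <- crossval_split(10L, k = 4L, seed = 3L)
  expect_identical(sort(lengths(folds), decreasing = TRUE), c(3L, 3L, 2L, 2L))
  expect_identical(sort(unlist(folds)), 1:10)
  expect_identical(folds, crossval_split(10L, k = 4L, seed = 3L))
  expect_false(identical(folds, crossval_split(10L, k = 4L, seed = 4L)))
  expect_error(crossval_split(3L, k = 4L), "more folds")
  # fold export
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fold_assignments(sprintf("r%02d", 1:10), folds, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 10L)
  expect_identical(sort(unique(tab$fold)), 1:4)
})
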