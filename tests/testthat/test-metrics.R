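# Confusion-matrix metrics.

cm_of <- function(tp, fp, fn, tn) axunet:::new_confusion(tp, fp, fn, tn)

test_that("metric formulas reproduce the hand-computed values", {
  cm <- cm_of(3, 2, 1, 10)
  expect_equal(accuracy(cm), 13 / 16)
  expect_equal(miou(cm), (3 / 6 + 10 / 13) / 2)
  expect_equal(recall(cm), 0.75)

  perfect <- cm_of(5, 0, 0, 11)
  expect_equal(accuracy(perfect), 1)
  expect_equal(miou(perfect), 1)
  expect_equal(recall(perfect), 1)

  expect_equal(accuracy(cm_of(0, 4, 4, 0)), 0)
  expect_equal(recall(cm_of(0, 0, 3, 5)), 0)
  expect_equal(recall(cm_of(4, 0, 0, 5)), 1)
  expect_error(recall(cm_of(0, 2, 0, 5)), "positive")
  expect_error(accuracy(cm_of(0, 0, 0, 0)))
})

test_that("degenerate classes follow the absent-class convention", {
  # everything positive in both pred and truth: both IoUs defined as 1
  all_pos <- cm_of(9, 0, 0, 0)
  expect_equal(miou(all_pos), 1)
  all_neg <- cm_of(0, 0, 0, 9)
  expect_equal(miou(all_neg), 1)
  # truth empty but predictions present: foreground IoU 0
  expect_equal(miou(cm_of(0, 3, 0, 6)), (0 + 6 / 9) / 2)
})

test_that("confusion counting respects the >= threshold convention", {
  truth <- matrix(c(1, 0, 1, 0), 2, 2)
  pred <- matrix(c(0.9, 0.4, 0.2, 0.6), 2, 2)
  cm <- confusion(pred, truth, 0.5)
  expect_equal(unlist(cm[c("TP", "FP", "FN", "TN")]),
               c(TP = 1, FP = 1, FN = 1, TN = 1))
  # threshold 0: every pixel positive
  cm0 <- confusion(pred, truth, 0)
  expect_equal(cm0$TN, 0)
  expect_equal(cm0$FN, 0)
  # boundary: a pixel exactly at the threshold counts as positive
  cmb <- confusion(matrix(0.5, 1, 1), matrix(1, 1, 1), 0.5)
  expect_equal(cmb$TP, 1)

  expect_error(confusion(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
  expect_error(confusion(matrix(0.2, 2, 2), matrix(0.5, 2, 2)), "binary")

  # perfect prediction
  cmp <- confusion(truth, truth, 0.5)
  expect_equal(cmp$FP + cmp$FN, 0)
})

test_that("metrics are label-swap symmetric and pool additively", {
  set.seed(30)
  cm <- cm_of(7, 3, 2, 20)
  swapped <- cm_of(20, 2, 3, 7)
  expect_equal(accuracy(cm), accuracy(swapped))
  expect_equal(miou(cm), miou(swapped))

  # aggregation: dataset confusion = sum of per-image confusions
  preds <- lapply(1:5, function(i) matrix(runif(64), 8, 8))
  truths <- lapply(1:5, function(i) matrix((runif(64) > 0.5) * 1, 8, 8))
  per <- Map(confusion, preds, truths)
  pooled <- confusion(do.call(c, lapply(preds, as.numeric)),
                      do.call(c, lapply(truths, as.numeric)))
  expect_equal(unclass(cm_sum(per)), unclass(pooled))
})

test_that("random pairs agree with the brute-force pixel-loop oracle", {
  set.seed(31)
  for (rep in 1:50) {
    pred <- matrix(runif(64), 8, 8)
    truth <- matrix((runif(64) > runif(1, 0.2, 0.8)) * 1, 8, 8)
    th <- runif(1)
    o <- oracle_confusion(pred, truth, th)
    cm <- confusion(pred, truth, th)
    expect_equal(unclass(cm)[c("TP", "FP", "FN", "TN")],
                 o[c("TP", "FP", "FN", "TN")])
    expect_equal(accuracy(cm), o$acc, tolerance = 1e-12)
    expect_equal(miou(cm), o$miou, tolerance = 1e-12)
    if (!is.na(o$recall)) expect_equal(recall(cm), o$recall, tolerance = 1e-12)
  }
})

test_that("metric reports serialize as two-decimal percentages", {
  path <- tempfile(fileext = ".json")
  write_metric_report(list(miou = 0.91234, acc = 0.995, recall = 1 / 3), path)
  r <- jsonlite::read_json(path)
  expect_equal(r$miou, 91.23)
  expect_equal(r$acc, 99.5)
  expect_equal(r$recall, 33.33)
})
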