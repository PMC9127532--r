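test_that("confusion counts partition the image", {
  t1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  same <- confusion(t1, t1)
  expect_equal(same$fp, 0); expect_equal(same$fn, 0)
  inv <- confusion(!t1, t1)
  expect_equal(inv$tp, 0); expect_equal(inv$tn, 0)
  # truth column-major {T,T,F,F}; pred {T,F,T,F}
  pred <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  cc <- confusion(pred, t1)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 4L)
  expect_error(confusion(matrix(TRUE, 1, 2), t1), "dimensions")
})

test_that("precision, recall and F follow the F1 definitions", {
  perfect <- precision_recall_f(confusion(matrix(c(TRUE, FALSE), 1, 2),
                                          matrix(c(TRUE, FALSE), 1, 2)))
  expect_equal(perfect, list(precision = 1, recall = 1, f = 1))
  prf <- precision_recall_f(structure(list(tp = 2, fp = 1, fn = 1, tn = 0),
                                      class = "confusion_counts"))
  expect_equal(prf$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(prf$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(prf$f, 2 / 3, tolerance = 1e-12)
  zero <- precision_recall_f(structure(list(tp = 0, fp = 3, fn = 2, tn = 1),
                                       class = "confusion_counts"))
  expect_equal(zero$precision, 0); expect_equal(zero$f, 0)
  expect_warning(
    und <- precision_recall_f(structure(list(tp = 0, fp = 0, fn = 2, tn = 2),
                                        class = "confusion_counts")),
    "undefined")
  expect_true(is.nan(und$precision))
  expect_true(is.nan(und$f))
})

test_that("F lies between precision and recall", {
  set.seed(41)
  for (i in 1:200) {
    cc <- structure(as.list(stats::rpois(4, 5) + c(1, 0, 0, 0)),
                    class = "confusion_counts")
    names(cc) <- c("tp", "fp", "fn", "tn")
    prf <- precision_recall_f(cc)
    expect_gte(prf$f, min(prf$precision, prf$recall) - 1e-12)
    expect_lte(prf$f, max(prf$precision, prf$recall) + 1e-12)
  }
})

test_that("hausdorff distance measures boundary mismatch", {
  m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
  expect_equal(hausdorff(m, m), 0)
  a <- matrix(FALSE, 8, 8); a[1, 1] <- TRUE
  b <- matrix(FALSE, 8, 8); b[4, 5] <- TRUE   # (0,0) vs (3,4)
  expect_equal(hausdorff(a, b), 5.0)
  expect_equal(hausdorff(b, a), hausdorff(a, b))
  expect_error(hausdorff(matrix(FALSE, 2, 2), matrix(TRUE, 2, 2)), "non-empty")
  set.seed(17)
  for (i in 1:20) {
    x <- matrix(stats::runif(64) < 0.4, 8, 8)
    y <- matrix(stats::runif(64) < 0.4, 8, 8)
    if (any(x) && any(y)) expect_equal(hausdorff(x, y), hausdorff(y, x))
  }
})

test_that("boundary pixels are mask pixels with a 4-neighbor outside", {
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  b <- boundary_pixels(m)
  expect_equal(nrow(b), 8L)          # 3x3 block minus its interior pixel
  full <- boundary_pixels(matrix(TRUE, 3, 3))
  expect_equal(nrow(full), 8L)       # image border counts as outside; only
                                     # the center pixel is interior
})

test_that("ROC/AUC integrates the anchored curve by trapezoids", {
  truth <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 2, 3)
  perfect <- roc_auc(function(th) truth, truth, grid = c(1, 2))
  expect_equal(perfect$auc, 1.0)
  flat <- roc_auc(function(th) matrix(th > 1.5, 2, 3), truth, grid = c(1, 2))
  expect_equal(flat$auc, 0.5)        # only all-false / all-true predictions
  # one interior point (fpr, tpr) = (0.5, 0.75): tp = 3, fp = 1
  mid <- truth; mid[1, 1] <- FALSE; mid[1, 3] <- TRUE
  fam <- function(th) if (th < 1.5) matrix(FALSE, 2, 3) else mid
  r <- roc_auc(fam, truth, grid = c(1, 2))
  expect_equal(r$auc, 0.625, tolerance = 1e-12)
  expect_error(roc_auc(fam, matrix(TRUE, 2, 3), c(1, 2)), "degenerate")
  expect_error(roc_auc(fam, truth, 1), "at least 2")
})
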