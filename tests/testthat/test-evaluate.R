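test_that("confusion matrix counts pairs exactly", {
  cm <- confusion_matrix(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(unname(diag(unclass(cm))), rep(1L, 5))
  expect_equal(sum(cm), 5)
  empty <- confusion_matrix(integer(0), integer(0))
  expect_equal(sum(empty), 0)
  with_seed(1, {
    t_ <- sample(5, 500, replace = TRUE)
    p_ <- sample(5, 500, replace = TRUE)
    expect_equal(unclass(confusion_matrix(t_, p_)),
                 oracle_confusion(t_, p_, 5), ignore_attr = TRUE)
  })
  expect_error(confusion_matrix(1:3, 1:2), "length")
  expect_error(confusion_matrix(c(1, 6), c(1, 2)), "1..5")
  # string labels are accepted case-insensitively
  cml <- confusion_matrix(c("Normal", "Cancer"), c("normal", "ulcer"))
  expect_equal(cml["normal", "normal"], 1L)
  expect_equal(cml["cancer", "ulcer"], 1L)
})

test_that("per-class rates follow the one-vs-rest formulas", {
  diagcm <- confusion_matrix(rep(1:5, 4), rep(1:5, 4))
  for (i in 1:5)
    expect_equal(unname(per_class_rates(diagcm, i)), c(1, 1, 1),
                 ignore_attr = TRUE)
  with_seed(2, {
    t_ <- sample(5, 300, replace = TRUE)
    p_ <- sample(5, 300, replace = TRUE)
    cm <- confusion_matrix(t_, p_)
    for (i in 1:5)
      expect_equal(unname(per_class_rates(cm, i)),
                   unname(oracle_rates(t_, p_, i)), ignore_attr = TRUE)
  })
  # absent class: undefined sensitivity reported as 0 and flagged
  cm0 <- confusion_matrix(c(1, 1, 2), c(1, 2, 2))
  r <- per_class_rates(cm0, 5)
  expect_equal(unname(r["sensitivity"]), 0, ignore_attr = TRUE)
  expect_false(attr(r, "defined")["sensitivity"])
})

test_that("macro metrics match formula-by-formula recomputation", {
  diagcm <- confusion_matrix(rep(1:5, 4), rep(1:5, 4))
  mm <- macro_metrics(diagcm)
  expect_equal(c(mm$se_macro, mm$sp_macro, mm$pr_macro, mm$f1), rep(1, 4))
  # one class fully misclassified, others perfect
  t_ <- rep(1:5, each = 10)
  p_ <- ifelse(t_ == 3, 4, t_)
  expect_equal(macro_metrics(confusion_matrix(t_, p_))$se_macro, 4 / 5)
  with_seed(3, for (rep in 1:100) {
    cm <- matrix(sample(0:30, 25, replace = TRUE), 5, 5)
    class(cm) <- c("confusion_matrix", "matrix")
    mm <- macro_metrics(cm)
    o <- oracle_macro(cm)
    expect_equal(c(mm$se_macro, mm$sp_macro, mm$pr_macro, mm$f1),
                 unname(o), tolerance = 1e-12)
  })
})

test_that("macro F1 is the harmonic mean of macro SE and Pr, not mean F1", {
  cm <- confusion_matrix(c(1, 1, 1, 2, 2, 3, 4, 5), c(1, 2, 2, 2, 3, 3, 4, 5))
  mm <- macro_metrics(cm)
  expect_equal(mm$f1, 2 * mm$se_macro * mm$pr_macro /
                 (mm$se_macro + mm$pr_macro))
  per_f1 <- mean(apply(mm$per_class, 1, function(r)
    if (r[1] + r[3] > 0) 2 * r[1] * r[3] / (r[1] + r[3]) else 0))
  expect_false(isTRUE(all.equal(mm$f1, per_f1)))
})

test_that("class permutations permute per-class but fix macro values", {
  with_seed(4, {
    t_ <- sample(5, 200, replace = TRUE)
    p_ <- sample(5, 200, replace = TRUE)
  })
  perm <- c(3, 1, 5, 2, 4)
  mm1 <- macro_metrics(confusion_matrix(t_, p_))
  mm2 <- macro_metrics(confusion_matrix(perm[t_], perm[p_]))
  expect_equal(mm1$f1, mm2$f1)
  expect_equal(mm1$se_macro, mm2$se_macro)
  expect_equal(unname(mm1$per_class[order(perm), ]), unname(mm2$per_class))
})

test_that("one-vs-rest AUC equals the pairwise count with tie credit", {
  n <- 50
  with_seed(5, {
    y <- sample(5, n, replace = TRUE)
    s <- matrix(round(stats::runif(n * 5), 2), n, 5)  # rounding forces ties
  })
  for (k in 1:5)
    expect_equal(ovr_auc(s, y, k), oracle_auc(s[, k], y == k))
  # perfectly separating scores
  sep <- matrix(0, 10, 5); sep[, 2] <- c(rep(1, 5), rep(0, 5))
  expect_equal(ovr_auc(sep, rep(c(2, 1), each = 5), 2), 1)
  # label-independent (constant) scores
  expect_equal(ovr_auc(matrix(0.5, 10, 5), rep(c(1, 2), 5), 1), 0.5)
  expect_error(ovr_auc(s, rep(1, n), 1), "degenerate")
})

test_that("DeLong interval matches pROC and reflects under label swap", {
  skip_if_not_installed("pROC")
  with_seed(6, {
    y <- rep(c(1, 2), c(70, 130))
    s <- matrix(stats::runif(200 * 5), 200, 5)
    s[, 1] <- ifelse(y == 1, stats::rnorm(200, 1), stats::rnorm(200))
  })
  r <- delong_ci(s, y, 1)
  pr <- pROC::roc(response = y == 1, predictor = s[, 1], quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(c(r$ci_low, r$auc, r$ci_high), ci, tolerance = 1e-10)
  # swapping positives and negatives maps auc -> 1 - auc, CI reflected:
  # score class 2 (the former negatives) with the same predictor
  s2 <- s; s2[, 2] <- s[, 1]
  r2 <- delong_ci(s2, y, 2)
  expect_equal(r2$auc, 1 - r$auc)
  expect_equal(c(r2$ci_low, r2$ci_high), c(1 - r$ci_high, 1 - r$ci_low))
})

test_that("perfect separation yields a degenerate DeLong interval", {
  s <- matrix(0, 20, 5); s[, 3] <- rep(c(1, 0), each = 10)
  y <- rep(c(3, 1), each = 10)
  expect_warning(r <- delong_ci(s, y, 3), "perfect separation")
  expect_equal(c(r$ci_low, r$auc, r$ci_high), c(1, 1, 1))
})

test_that("full evaluation report assembles all components", {
  with_seed(7, {
    y <- sample(5, 100, replace = TRUE)
    s <- matrix(stats::runif(500), 100, 5)
    s[cbind(seq_len(100), y)] <- s[cbind(seq_len(100), y)] + 0.5
    s <- s / rowSums(s)
  })
  ev <- evaluate_predictions(s, y)
  expect_s3_class(ev$confusion, "confusion_matrix")
  expect_equal(sum(ev$confusion), 100)
  expect_length(ev$auc, 5)
  for (a in ev$auc) expect_true(is.null(a) || a$ci_low <= a$auc)
})
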