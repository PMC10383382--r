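test_that("confusion matrix from the study's printed columns", {
  ds <- pfas_hsa_data(classes = "printed")
  r <- ds$records
  train <- r$split == "train"
  cm <- confusion(r$observed_class[train], r$predicted_class_lda[train])
  expect_equal(cm$TP, 7); expect_equal(cm$FN, 1)
  expect_equal(cm$TN, 8); expect_equal(cm$FP, 0)
  cmt <- confusion(r$observed_class[!train], r$predicted_class_lda[!train])
  expect_equal(cmt$TP, 4); expect_equal(cmt$TN, 4)
  expect_equal(cmt$FP + cmt$FN, 0)
  expect_error(confusion(c("H"), c("H", "L")), "equal length")
  # degenerate all-wrong case
  aw <- confusion(rep("H", 5), rep("L", 5))
  expect_equal(aw$FN, 5); expect_equal(aw$TP, 0)
})

test_that("classification metric battery matches the published values", {
  m <- classification_metrics(
    structure(list(TP = 7, FP = 0, TN = 8, FN = 1, positive = "H"),
              class = "confusion_matrix"))
  expect_equal(m$accuracy, 93.75)
  expect_equal(m$sensitivity, 87.5)
  expect_equal(m$specificity, 100)
  expect_equal(m$precision, 100)
  expect_equal(round(m$f_measure, 2), 93.33)
  expect_equal(round(m$mcc, 2), 0.88)
  expect_equal(round(m$kappa, 2), 0.88)
  expect_equal(round(m$g_means, 1), 93.5)
  perfect <- classification_metrics(
    structure(list(TP = 4, FP = 0, TN = 4, FN = 0, positive = "H"),
              class = "confusion_matrix"))
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "precision",
                                   "accuracy", "f_measure", "g_means")]) ==
                    100))
  expect_equal(perfect$mcc, 1); expect_equal(perfect$kappa, 1)
  chance <- classification_metrics(
    structure(list(TP = 25, FP = 25, TN = 25, FN = 25, positive = "H"),
              class = "confusion_matrix"))
  expect_equal(chance$mcc, 0); expect_equal(chance$kappa, 0)
  expect_equal(chance$accuracy, 50)
  # zero denominators are flagged undefined, not 0
  nopos <- classification_metrics(
    structure(list(TP = 0, FP = 0, TN = 5, FN = 0, positive = "H"),
              class = "confusion_matrix"))
  expect_true(is.na(nopos$sensitivity))
  expect_true(is.na(nopos$precision))
})

test_that("metrics agree with brute-force recounts from raw label vectors", {
  recount <- function(TP, FP, TN, FN) {
    obs <- c(rep("H", TP), rep("L", FP), rep("L", TN), rep("H", FN))
    pred <- c(rep("H", TP), rep("H", FP), rep("L", TN), rep("L", FN))
    cm <- confusion(obs, pred)
    expect_equal(c(cm$TP, cm$FP, cm$TN, cm$FN), c(TP, FP, TN, FN))
    m <- classification_metrics(cm)
    if (!is.na(m$sensitivity)) {
      expect_equal(m$sensitivity, 100 * mean(pred[obs == "H"] == "H"))
    }
    if (!is.na(m$accuracy)) expect_equal(m$accuracy, 100 * mean(obs == pred))
    if (!is.na(m$f_measure) && m$precision > 0 && m$sensitivity > 0) {
      # harmonic mean of precision and sensitivity
      expect_equal(m$f_measure, 2 / (1 / m$precision + 1 / m$sensitivity))
    }
    if (!is.na(m$g_means)) {
      expect_equal((m$g_means / 100)^2,
                   (m$sensitivity / 100) * (m$specificity / 100))
    }
  }
  # exhaustive over small tables
  for (TP in 0:6) for (FP in 0:6) for (TN in 0:6) for (FN in 0:6) {
    if (TP + FP + TN + FN >= 1) recount(TP, FP, TN, FN)
  }
  # random larger tables
  set.seed(61)
  for (k in 1:200) {
    cnt <- sample(0:20, 4, replace = TRUE)
    if (sum(cnt) >= 1) recount(cnt[1], cnt[2], cnt[3], cnt[4])
  }
})

test_that("ROC analysis behaves at the extremes and matches pROC", {
  obs <- rep(c("H", "L"), each = 10)
  perfect <- c(rnorm(10, 5), rnorm(10, -5))
  expect_equal(roc_auc(perfect, obs)$auc, 1)
  expect_equal(roc_auc(rep(1, 20), obs)$auc, 0.5)
  expect_error(roc_auc(perfect, rep("H", 20)), "both classes")
  set.seed(62)
  sc <- rnorm(1000); ob <- sample(c("H", "L"), 1000, replace = TRUE)
  expect_equal(roc_auc(sc, ob)$auc, 0.5, tolerance = 0.05)
  # monotone-transform invariance
  expect_equal(roc_auc(exp(sc), ob)$auc, roc_auc(sc, ob)$auc)
  skip_if_not_installed("pROC")
  set.seed(63)
  sc2 <- round(rnorm(60), 1)  # ties on purpose
  ob2 <- sample(c("H", "L"), 60, replace = TRUE, prob = c(0.4, 0.6))
  ref <- suppressMessages(pROC::auc(pROC::roc(ob2, sc2, levels = c("L", "H"),
                                              direction = "<")))
  expect_equal(roc_auc(sc2, ob2)$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("Wilks' lambda separates groups and is affine invariant", {
  set.seed(64)
  x <- matrix(c(rnorm(8, -5, 0.1), rnorm(8, 5, 0.1)), ncol = 1)
  y <- rep(c("H", "L"), each = 8)
  w <- wilks_lambda(x, y)
  expect_lt(w$lambda, 0.01)
  expect_equal(w$df, c(1, 14))
  same <- wilks_lambda(matrix(rnorm(40), ncol = 2), rep(c("H", "L"), 10))
  expect_gt(same$lambda, 0.5)
  x2 <- matrix(rnorm(60), ncol = 3)
  y2 <- rep(c("a", "b"), 10)
  w1 <- wilks_lambda(x2, y2)
  w2 <- wilks_lambda(sweep(x2, 2, c(10, 0.1, 3), "*") +
                       matrix(rep(c(1, -5, 2), each = 20), ncol = 3), y2)
  expect_equal(w1$lambda, w2$lambda, tolerance = 1e-10)
  expect_equal(w1$F, w2$F, tolerance = 1e-10)
})

test_that("regression metrics reproduce the published MAE and R2", {
  ds <- pfas_hsa_data()
  r <- ds$records
  both <- !is.na(r$ec50_mM) & !is.na(r$predicted_ec50_pls)
  m <- regression_metrics(r$ec50_mM[both], r$predicted_ec50_pls[both])
  expect_equal(m$n, 22)
  expect_equal(round(m$mae, 3), 0.205)
  expect_equal(m$r2, 0.802, tolerance = 0.002 / 0.802)
  # identities
  y <- rnorm(20)
  expect_equal(regression_metrics(y, y)$r2, 1)
  expect_equal(regression_metrics(y, y)$mae, 0)
  expect_equal(regression_metrics(y, rep(mean(y), 20))$r2, 0)
  expect_error(regression_metrics(rep(1, 5), rnorm(5)), "variance")
})

test_that("MAE95 equals brute-force recomputation after sorting", {
  set.seed(65)
  for (n in c(10, 22, 40)) {
    y <- rnorm(n); p <- y + rnorm(n, sd = 0.5)
    m <- regression_metrics(y, p)
    ae <- sort(abs(y - p))
    keep <- ae[seq_len(n - ceiling(0.05 * n))]
    expect_equal(m$mae95, mean(keep))
    expect_lte(m$mae95, max(ae))
  }
})

test_that("leave-one-out Q2 equals its per-fold refit definition", {
  set.seed(66)
  x <- matrix(rnorm(22 * 3), ncol = 3)
  y <- drop(x %*% c(1, -1, 2))
  expect_equal(q2_loo(x, y)$q2, 1, tolerance = 1e-10)
  # agreement between the naive loop and the closed-form OLS shortcut
  yn <- y + rnorm(22, sd = 0.5)
  expect_equal(q2_loo(x, yn)$q2, pfasqsar:::.q2_loo_ols(x, yn),
               tolerance = 1e-10)
  # pure noise: Q2 <= 0 in the vast majority of replicates
  bad <- 0
  for (s in 1:50) {
    set.seed(600 + s)
    xs <- matrix(rnorm(22 * 3), ncol = 3)
    ys <- rnorm(22)
    if (q2_loo(xs, ys)$q2 <= 0) bad <- bad + 1
  }
  expect_gte(bad / 50, 0.9)
})

test_that("rm2 metrics satisfy their defining identities and bounds", {
  y <- rnorm(25)
  ident <- rm2_metrics(y, y)
  expect_equal(ident$rm2_bar, 1)
  expect_equal(ident$delta_rm2, 0)
  set.seed(67)
  for (k in 1:1000) {
    o <- rnorm(8); p <- rnorm(8)
    if (stats::sd(p) == 0) next
    m <- rm2_metrics(o, p)
    expect_lte(m$rm2_bar, m$r2 + 1e-12)
    expect_gte(m$delta_rm2, 0)
  }
  anti <- rm2_metrics(1:10, seq(10, 1))
  expect_lt(anti$rm2_bar, 0.15)
  expect_error(rm2_metrics(rep(1, 5), rnorm(5)), "constant")
})

test_that("applicability domain flags standardized outliers", {
  set.seed(68)
  xt <- matrix(rnorm(200), ncol = 4,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  inside <- applicability_domain(xt, xt[1, , drop = FALSE])
  expect_true(inside$inside)
  far <- xt[1, , drop = FALSE]
  far[, "c"] <- mean(xt[, "c"]) + 10 * stats::sd(xt[, "c"])
  out <- applicability_domain(xt, far)
  expect_false(out$inside)
  expect_equal(out$worst_descriptor, "c")
  # outside fraction approximates the normal tail for big samples
  xt2 <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "z"))
  xq <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "z"))
  frac <- mean(!applicability_domain(xt2, xq)$inside)
  expect_equal(frac, 2 * stats::pnorm(-3), tolerance = 0.5 * frac + 0.005)
  expect_warning(
    applicability_domain(cbind(xt, e = 1), cbind(xt[1:2, ], e = 1)),
    "zero-variance")
})

test_that("response scrambling destroys the fit quality", {
  d <- make_descriptor_dataset(
    synthetic_spec(n = 22, pool = 4, true_idx = 1:4,
                   beta = c(2, -1, 1, 0.5), sigma = "relative", seed = 8))
  yr <- y_randomization(d$x, d$y, n_perm = 50, seed = 9)
  expect_gt(yr$observed, 0.9)
  expect_lt(max(yr$null), yr$observed)
  expect_lt(yr$p_value, 0.05)
})
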