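# Validation metric battery for classification and regression QSAR.
#
# Percent metrics are on the 0-100 scale (reported to 2 decimals by the
# print helpers, matching the precision of the published tables); MCC and
# Cohen's kappa are on [-1, 1]; undefined metrics (zero denominators) are
# reported as NA rather than 0.

#' Confusion matrix from observed and predicted labels
#'
#' @param observed,predicted equal-length label vectors.
#' @param positive the positive-class label (default `"H"`, high affinity).
#' @return A `confusion_matrix`: list with `TP`, `FP`, `TN`, `FN`,
#'   `positive`.
#' @export
confusion <- function(observed, predicted, positive = "H") {
  observed <- as.character(observed); predicted <- as.character(predicted)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) == 0L) stop("empty label vectors", call. = FALSE)
  structure(list(
    TP = sum(observed == positive & predicted == positive),
    FP = sum(observed != positive & predicted == positive),
    TN = sum(observed != positive & predicted != positive),
    FN = sum(observed == positive & predicted != positive),
    positive = positive
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(predicted = c(x$positive, "other"),
                              observed = c(x$positive, "other")))
  print(m)
  invisible(x)
}

.safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from a confusion matrix
#'
#' Sensitivity, specificity, precision, accuracy, F-measure, G-means (all in
#' percent), plus Matthews correlation coefficient and Cohen's kappa.
#' G-means is the geometric mean of sensitivity and specificity, reported on
#' the percent scale. Metrics with zero denominators are `NA`.
#'
#' @param cm a [confusion()] matrix.
#' @return Named list of metrics plus `n`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm$TP; FP <- cm$FP; TN <- cm$TN; FN <- cm$FN
  n <- TP + FP + TN + FN
  sens <- .safe_div(TP, TP + FN)
  spec <- .safe_div(TN, TN + FP)
  prec <- .safe_div(TP, TP + FP)
  acc <- .safe_div(TP + TN, n)
  fmeas <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den
  pra <- (TP + TN) / n
  pre <- ((TP + FP) * (TP + FN) + (TN + FP) * (TN + FN)) / n^2
  kappa <- if (pre == 1) NA_real_ else (pra - pre) / (1 - pre)
  gmeans <- if (is.na(sens) || is.na(spec)) NA_real_ else
    100 * sqrt(sens * spec)
  list(sensitivity = 100 * sens, specificity = 100 * spec,
       precision = 100 * prec, accuracy = 100 * acc,
       f_measure = 100 * fmeas, mcc = mcc, kappa = kappa, g_means = gmeans,
       n = n)
}

#' ROC curve and AUROC
#'
#' Threshold sweep over the unique scores with trapezoidal area; equivalent
#' to the Mann-Whitney statistic with tied scores contributing 1/2. Scores
#' are oriented so that larger values indicate the positive class (pass
#' `decreasing = TRUE` for score conventions like the discriminant model,
#' where low scores mean high affinity).
#'
#' @param scores numeric scores.
#' @param observed labels.
#' @param positive positive-class label.
#' @param decreasing do smaller scores indicate the positive class?
#' @return list with `points` (data.frame of FPR/TPR per threshold) and
#'   `auc`.
#' @export
roc_auc <- function(scores, observed, positive = "H", decreasing = FALSE) {
  observed <- as.character(observed)
  stopifnot(length(scores) == length(observed))
  is_pos <- observed == positive
  if (all(is_pos) || !any(is_pos)) {
    stop("both classes must be present for a ROC curve", call. = FALSE)
  }
  s <- if (decreasing) -scores else scores
  thr <- sort(unique(s), decreasing = TRUE)
  pts <- data.frame(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(s[is_pos] >= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(s[!is_pos] >= t), numeric(1)))
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Wilks' lambda and its F transform for a two-group separation
#'
#' \eqn{\lambda = \det(W)/\det(B + W)} with `W` and `B` the within- and
#' between-group cross-product matrices, and the standard two-group
#' transformation \eqn{F = \frac{1-\lambda}{\lambda}\frac{n-p-1}{p}} on
#' `(p, n-p-1)` degrees of freedom. Invariant under affine rescaling of the
#' descriptor columns.
#'
#' @param x descriptor matrix.
#' @param y two-group labels.
#' @return list with `lambda`, `F`, `df`, `p_value`.
#' @export
wilks_lambda <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  lv <- unique(y)
  if (length(lv) != 2L) stop("wilks_lambda requires exactly 2 groups",
                             call. = FALSE)
  n <- nrow(x); p <- ncol(x)
  W <- matrix(0, p, p)
  for (g in lv) {
    xg <- x[y == g, , drop = FALSE]
    W <- W + crossprod(scale(xg, scale = FALSE))
  }
  Tm <- crossprod(scale(x, scale = FALSE))
  dT <- det(Tm)
  if (!is.finite(dT) || abs(dT) < .Machine$double.eps) {
    stop("singular total scatter matrix", call. = FALSE)
  }
  lambda <- det(W) / dT
  df <- c(p, n - p - 1L)
  Fstat <- (1 - lambda) / lambda * df[2] / df[1]
  list(lambda = lambda, F = Fstat, df = df,
       p_value = stats::pf(Fstat, df[1], df[2], lower.tail = FALSE))
}

#' Generic variance-ratio F statistic
#'
#' The ratio of two variance ratios \eqn{(s_1^2/\sigma_1^2) /
#' (s_2^2/\sigma_2^2)}: each sample variance over its population variance.
#'
#' @param s1,s2 sample standard deviations.
#' @param sigma1,sigma2 population standard deviations.
#' @export
variance_ratio_f <- function(s1, sigma1, s2, sigma2) {
  (s1^2 / sigma1^2) / (s2^2 / sigma2^2)
}

#' Regression quality metrics
#'
#' `R2` relative to the training-set mean response, plain mean absolute
#' error, and the 95% variant `MAE95` recomputed after discarding the
#' `ceiling(5% of n)` largest absolute errors.
#'
#' @param y_obs,y_pred observed and predicted responses.
#' @param y_train_mean mean response of the training set (defaults to
#'   `mean(y_obs)`, the whole-set convention of the small-dataset workflow).
#' @return list with `r2`, `mae`, `mae95`, `n`.
#' @export
regression_metrics <- function(y_obs, y_pred, y_train_mean = mean(y_obs)) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2L)
  if (stats::sd(y_obs) == 0) stop("zero variance in y_obs", call. = FALSE)
  err <- y_obs - y_pred
  r2 <- 1 - sum(err^2) / sum((y_obs - y_train_mean)^2)
  abs_err <- abs(err)
  drop_n <- ceiling(0.05 * length(y_obs))
  kept <- sort(abs_err)[seq_len(length(abs_err) - drop_n)]
  list(r2 = r2, mae = mean(abs_err), mae95 = mean(kept), n = length(y_obs))
}

#' Leave-one-out cross-validated Q2
#'
#' Naive refit-per-left-out-sample loop: each observation is predicted from
#' a model fitted to the remaining `n - 1`, and
#' \eqn{Q^2 = 1 - \mathrm{PRESS} / \sum(Y_{obs} - \bar Y)^2} with the mean
#' over the full set.
#'
#' @param x descriptor matrix.
#' @param y response.
#' @param fit fitting function `(x, y) -> qsar_model` (default [qsar_mlr()]).
#' @return list with `q2`, `press`, `loo_pred`, and per-fold failures (if
#'   any) under `failed`.
#' @export
q2_loo <- function(x, y, fit = qsar_mlr) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= 3L, length(y) == n)
  pred <- rep(NA_real_, n)
  failed <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      m <- fit(x[-i, , drop = FALSE], y[-i])
      predict(m, x[i, , drop = FALSE])
    }, error = function(e) {
      failed <<- c(failed, sprintf("fold %d: %s", i, conditionMessage(e)))
      NA_real_
    })
    pred[i] <- res
  }
  press <- sum((y - pred)^2, na.rm = TRUE)
  q2 <- 1 - press / sum((y - mean(y))^2)
  out <- list(q2 = q2, press = press, loo_pred = pred)
  if (length(failed) > 0L) out$failed <- failed
  out
}

#' Roy's scaled rm2 predictivity metrics
#'
#' Min-max scales both vectors by the observed range, then computes the
#' correlation-based predictivity pair: \eqn{r_m^2 = r^2 (1 -
#' \sqrt{r^2 - r_0^2})} (with `r0^2` from the regression of observed on
#' predicted through the origin, and the primed variant with the roles
#' swapped), their mean and absolute difference.
#'
#' @param y_obs,y_pred observed and predicted responses (>= 3 points,
#'   non-constant).
#' @return list with `rm2`, `rm2_prime`, `rm2_bar`, `delta_rm2`, `r2`,
#'   `r02`, `r02_prime`, `k`, `k_prime`.
#' @export
rm2_metrics <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3L)
  rng <- range(y_obs)
  if (diff(rng) == 0 || stats::sd(y_pred) == 0) {
    stop("constant input; rm2 metrics undefined", call. = FALSE)
  }
  o <- (y_obs - rng[1]) / diff(rng)
  p <- (y_pred - rng[1]) / diff(rng)
  r2 <- stats::cor(o, p)^2
  k <- sum(o * p) / sum(p^2)
  kp <- sum(o * p) / sum(o^2)
  r02 <- 1 - sum((o - k * p)^2) / sum((o - mean(o))^2)
  r02p <- 1 - sum((p - kp * o)^2) / sum((p - mean(p))^2)
  rm2 <- r2 * (1 - sqrt(pmax(r2 - r02, 0)))
  rm2p <- r2 * (1 - sqrt(pmax(r2 - r02p, 0)))
  list(rm2 = rm2, rm2_prime = rm2p, rm2_bar = (rm2 + rm2p) / 2,
       delta_rm2 = abs(rm2 - rm2p), r2 = r2, r02 = r02, r02_prime = r02p,
       k = k, k_prime = kp)
}

#' Standardization-based applicability domain
#'
#' A query compound lies outside the model's applicability domain when any
#' of its descriptors, standardized by the training mean and standard
#' deviation, deviates by more than `k` (default 3) standard deviations.
#' Zero-variance training columns are flagged and excluded from the check.
#'
#' @param x_train training descriptor matrix.
#' @param x_query query descriptor matrix (same columns).
#' @param k standardized-deviation cutoff.
#' @return data.frame per query: `inside`, `max_abs_z`, `worst_descriptor`;
#'   the per-descriptor standardized deviations are attached as the
#'   `"z"` attribute and flagged zero-variance columns as
#'   `"degenerate_columns"`.
#' @export
applicability_domain <- function(x_train, x_query, k = 3) {
  x_train <- as.matrix(x_train); x_query <- as.matrix(x_query)
  if (is.null(colnames(x_train)))
    colnames(x_train) <- paste0("x", seq_len(ncol(x_train)))
  if (is.null(colnames(x_query))) colnames(x_query) <- colnames(x_train)
  if (!identical(sort(colnames(x_train)), sort(colnames(x_query)))) {
    stop("training and query descriptor columns differ", call. = FALSE)
  }
  x_query <- x_query[, colnames(x_train), drop = FALSE]
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  degenerate <- names(sdv)[sdv == 0]
  if (length(degenerate) > 0L) {
    warning("zero-variance training column(s): ",
            paste(degenerate, collapse = ", "))
  }
  use <- sdv > 0
  z <- sweep(sweep(x_query[, use, drop = FALSE], 2, mu[use]), 2, sdv[use],
             "/")
  max_abs <- apply(abs(z), 1, max)
  worst <- colnames(z)[apply(abs(z), 1, which.max)]
  out <- data.frame(inside = max_abs <= k, max_abs_z = max_abs,
                    worst_descriptor = worst, stringsAsFactors = FALSE)
  attr(out, "z") <- z
  attr(out, "degenerate_columns") <- degenerate
  out
}

#' Y-randomization (response scrambling) check
#'
#' Refits the model on seeded permutations of the response and reports the
#' null distribution of the chosen quality metric, to show that the original
#' fit is not a chance correlation.
#'
#' @param x descriptor matrix.
#' @param y response (numeric) or classes.
#' @param fit fitting function `(x, y) -> qsar_model`.
#' @param metric function `model -> numeric` (defaults to training R2 for
#'   regression models, Wilks' lambda for discriminant models).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `observed`, `null` (vector), `p_value` (fraction of
#'   null fits at least as good as the observed).
#' @export
y_randomization <- function(x, y, fit = qsar_mlr, metric = NULL,
                            n_perm = 100, seed = 1) {
  m0 <- fit(x, y)
  if (is.null(metric)) {
    metric <- if (m0$kind == "LDA") function(m) m$wilks else function(m) m$r2
  }
  better <- if (m0$kind == "LDA") `<=` else `>=`   # lower lambda is better
  obs <- metric(m0)
  null <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      metric(fit(x, sample(y)))
    }, numeric(1))
  })
  list(observed = obs, null = null,
       p_value = (1 + sum(better(null, obs))) / (n_perm + 1))
}

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
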