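# Linear QSAR models as classed S3 objects.
#
# All models collapse to a linear predictor: intercept + <coefficients, x>.
# Discriminant models carry a decision threshold on the score with the
# study's orientation: scores ABOVE the threshold classify as "L" (low
# affinity), scores at or below as "H".

.new_qsar_model <- function(kind, descriptors, coefficients, intercept,
                            extra = list()) {
  stopifnot(length(descriptors) == length(coefficients))
  m <- c(list(kind = kind,
              descriptors = as.character(descriptors),
              coefficients = stats::setNames(as.numeric(coefficients),
                                             descriptors),
              intercept = as.numeric(intercept)),
         extra)
  class(m) <- c(paste0("qsar_", tolower(kind)), "qsar_model")
  m
}

.score_matrix <- function(object, newdata) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata[,
    sapply(newdata, is.numeric), drop = FALSE])
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
    dimnames = list(NULL, names(newdata)))
  cn <- colnames(newdata)
  if (is.null(cn)) {
    if (ncol(newdata) != length(object$descriptors)) {
      stop("newdata has ", ncol(newdata), " columns; model expects ",
           length(object$descriptors), call. = FALSE)
    }
    colnames(newdata) <- object$descriptors
    cn <- object$descriptors
  }
  missing <- setdiff(object$descriptors, cn)
  if (length(missing) > 0L) {
    stop("missing descriptor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  newdata[, object$descriptors, drop = FALSE]
}

#' Linear score of a QSAR model
#'
#' @param object a `qsar_model`.
#' @param newdata matrix or data.frame with named descriptor columns (order
#'   irrelevant), or a single named vector.
#' @keywords internal
.linear_score <- function(object, newdata) {
  x <- .score_matrix(object, newdata)
  drop(object$intercept + x %*% object$coefficients)
}

#' Fisher linear discriminant QSAR model
#'
#' Two-class Fisher discriminant on a descriptor matrix. The discriminant
#' direction is `Sw^-1 (mean_L - mean_H)` (pooled within-class covariance),
#' oriented so that larger scores indicate the `L` (low-affinity) class; the
#' intercept centres the decision threshold at 0, the midpoint of the two
#' class-mean scores. Wilks' lambda and its F transform are reported
#' alongside.
#'
#' @param x numeric matrix/data.frame of descriptors (rows > columns).
#' @param y class labels with exactly two levels, containing `"H"` and
#'   `"L"` (or any two labels; the first sorted level plays the `H` role).
#' @return A `qsar_lda` model with `wilks`, `F`, `df` fields.
#' @export
qsar_lda <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) != 2L) stop("qsar_lda requires exactly 2 classes",
                             call. = FALSE)
  pos <- if ("H" %in% lv) "H" else lv[1]   # high-affinity role
  neg <- setdiff(lv, pos)
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 1L) stop("need more rows than descriptors", call. = FALSE)
  xH <- x[y == pos, , drop = FALSE]; xL <- x[y == neg, , drop = FALSE]
  mH <- colMeans(xH); mL <- colMeans(xL)
  W <- crossprod(scale(xH, center = mH, scale = FALSE)) +
       crossprod(scale(xL, center = mL, scale = FALSE))
  Sw <- W / (n - 2L)
  a <- tryCatch(solve(Sw, mL - mH), error = function(e) {
    stop("singular within-class scatter; prune collinear descriptors",
         call. = FALSE)
  })
  mid <- sum(a * (mH + mL)) / 2
  wl <- wilks_lambda(x, y)
  m <- .new_qsar_model("LDA", colnames(x), a, -mid,
                       extra = list(threshold = 0, positive_class = pos,
                                    negative_class = neg,
                                    wilks = wl$lambda, F = wl$F, df = wl$df,
                                    class_means = c(H = sum(a * mH) - mid,
                                                    L = sum(a * mL) - mid)))
  m
}

#' Multiple linear regression QSAR model
#'
#' Ordinary least squares on a full-column-rank descriptor matrix.
#'
#' @param x numeric matrix/data.frame of descriptors.
#' @param y numeric response (EC50 in mM for the study models).
#' @return A `qsar_mlr` model with `fitted`, `residuals`, `sigma`, `r2`.
#' @export
qsar_mlr <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("need more rows than descriptors", call. = FALSE)
  X1 <- cbind(`(Intercept)` = 1, x)
  fit <- stats::lm.fit(X1, y)
  if (fit$rank < ncol(X1)) {
    stop("rank-deficient descriptor matrix; remove collinear columns",
         call. = FALSE)
  }
  co <- fit$coefficients
  .new_qsar_model("MLR", colnames(x), co[-1], co[1],
                  extra = list(
                    fitted = drop(X1 %*% co),
                    residuals = y - drop(X1 %*% co),
                    y = y,
                    sigma = sqrt(sum(fit$residuals^2) / (n - p - 1L)),
                    r2 = 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)))
}

#' Partial least squares (PLS1) QSAR model
#'
#' NIPALS PLS with a single response, collapsed to an equivalent linear
#' predictor on the original descriptor scale. Descriptors are autoscaled by
#' default (`scale = FALSE` for centring only). With `n_lv` equal to the
#' number of descriptors on full-rank data, predictions coincide with
#' [qsar_mlr()].
#'
#' @inheritParams qsar_mlr
#' @param n_lv number of latent variables, `1 <= n_lv <= ncol(x)`.
#' @param scale autoscale descriptors before decomposition?
#' @return A `qsar_pls` model with `n_lv`, `fitted`, `residuals`, `r2`, and
#'   the latent `scores`.
#' @export
qsar_pls <- function(x, y, n_lv, scale = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  p <- ncol(x)
  if (n_lv < 1L || n_lv > p) {
    stop("n_lv must be between 1 and the number of descriptors (", p, ")",
         call. = FALSE)
  }
  mx <- colMeans(x); my <- mean(y)
  sx <- if (scale) apply(x, 2, stats::sd) else rep(1, p)
  if (any(sx == 0)) stop("constant descriptor column; pretreat first",
                         call. = FALSE)
  Xc <- sweep(sweep(x, 2, mx), 2, sx, "/")
  yc <- y - my
  Wm <- Pm <- matrix(0, p, n_lv)
  qv <- numeric(n_lv)
  Tm <- matrix(0, nrow(x), n_lv)
  Xd <- Xc
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xd, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_lv <- a - 1L; break }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    pl <- drop(crossprod(Xd, t)) / tt
    q <- sum(yc * t) / tt
    Xd <- Xd - tcrossprod(t, pl)
    yc <- yc - q * t
    Wm[, a] <- w; Pm[, a] <- pl; qv[a] <- q; Tm[, a] <- t
  }
  if (n_lv == 0L) stop("response uncorrelated with descriptors", call. = FALSE)
  Wm <- Wm[, seq_len(n_lv), drop = FALSE]
  Pm <- Pm[, seq_len(n_lv), drop = FALSE]
  qv <- qv[seq_len(n_lv)]
  # coefficients on the scaled X: B = W (P'W)^-1 q
  B <- drop(Wm %*% solve(crossprod(Pm, Wm), qv))
  beta <- B / sx
  intercept <- my - sum(beta * mx)
  fitted <- drop(intercept + x %*% beta)
  .new_qsar_model("PLS", colnames(x), beta, intercept,
                  extra = list(n_lv = n_lv,
                               scaled = scale,
                               scores = Tm[, seq_len(n_lv), drop = FALSE],
                               fitted = fitted,
                               residuals = y - fitted,
                               y = y,
                               r2 = 1 - sum((y - fitted)^2) /
                                 sum((y - mean(y))^2)))
}

#' The study's frozen discriminant model for PFAS-albumin binding class
#'
#' The published three-descriptor discriminant function
#' \deqn{\Delta P = -14.668 + 33.651\,Eig12\_AEA(bo) + 0.378\,DECC
#'   + 30.405\,X4A}
#' separating high (H) from low (L) HSA binding affinity. Scores above the
#' potency threshold classify as L, scores at or below as H. The published
#' work does not print a numeric threshold; by default it is 0, and
#' `calibrate` data (a descriptor matrix plus classes) re-centres it at the
#' midpoint of the two class-mean scores.
#'
#' @param calibrate optional list `list(x = descriptor matrix, y = classes)`
#'   used to set the decision threshold.
#' @return A `qsar_lda` model object.
#' @export
hsa_discriminant_model <- function(calibrate = NULL) {
  m <- .new_qsar_model(
    "LDA",
    c("Eig12_AEA_bo", "DECC", "X4A"),
    c(Eig12_AEA_bo = 33.651, DECC = 0.378, X4A = 30.405),
    -14.668,
    extra = list(threshold = 0, positive_class = "H", negative_class = "L",
                 wilks = 0.26, F = 10.45, df = c(3, 12))
  )
  if (!is.null(calibrate)) {
    sc <- .linear_score(m, calibrate$x)
    y <- as.character(calibrate$y)
    m$threshold <- (mean(sc[y == "H"]) + mean(sc[y == "L"])) / 2
  }
  m
}

#' The study's frozen PLS regression model for PFAS-albumin EC50
#'
#' The published four-descriptor PLS-derived predictor
#' \deqn{EC_{50}(mM) = 24.427 - 23.551\,PDI - 0.862\,GATS8v - 0.607\,MATS8m
#'   - 4.388\,QED}
#' All four descriptors contribute negatively: higher packing density,
#' autocorrelation, or drug-likeness predicts a lower EC50, i.e. stronger
#' binding.
#'
#' @return A `qsar_pls` model object (3 latent variables in the original
#'   fit, carried as metadata).
#' @export
hsa_ec50_model <- function() {
  .new_qsar_model(
    "PLS",
    c("PDI", "GATS8v", "MATS8m", "QED"),
    c(PDI = -23.551, GATS8v = -0.862, MATS8m = -0.607, QED = -4.388),
    24.427,
    extra = list(n_lv = 3L)
  )
}

#' Predict from a QSAR model
#'
#' Deterministic linear scoring. Discriminant models return class labels
#' (`type = "class"`, default) or raw scores; regression models return
#' predicted responses. Descriptor columns are matched by name, so column
#' order is irrelevant.
#'
#' @param object a `qsar_model`.
#' @param newdata matrix/data.frame with the model's descriptors as named
#'   columns.
#' @param type for discriminant models, `"class"` or `"score"`.
#' @param ... unused.
#' @export
predict.qsar_model <- function(object, newdata, type = c("class", "score"),
                               ...) {
  score <- .linear_score(object, newdata)
  if (object$kind != "LDA") return(score)
  type <- match.arg(type)
  if (type == "score") return(score)
  ifelse(score > object$threshold, object$negative_class,
         object$positive_class)
}

#' @export
coef.qsar_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
residuals.qsar_model <- function(object, ...) {
  if (is.null(object$residuals)) {
    stop("frozen reference models carry no training residuals", call. = FALSE)
  }
  object$residuals
}

#' @export
print.qsar_model <- function(x, digits = 4, ...) {
  cat(x$kind, "QSAR model:",
      if (x$kind == "LDA") "discriminant score" else "predicted response",
      "=\n  ", format(x$intercept, digits = digits))
  for (k in seq_along(x$coefficients)) {
    co <- x$coefficients[k]
    cat(if (co >= 0) " + " else " - ", format(abs(co), digits = digits),
        " * ", x$descriptors[k], sep = "")
  }
  cat("\n")
  if (x$kind == "LDA") {
    cat("  score >", format(x$threshold, digits = digits), "->",
        x$negative_class, "; otherwise ->", x$positive_class, "\n")
    if (!is.null(x$wilks)) {
      cat("  Wilks' lambda =", format(x$wilks, digits = digits),
          ", F(", x$df[1], ",", x$df[2], ") =", format(x$F, digits = digits),
          "\n")
    }
  }
  if (!is.null(x$n_lv)) cat("  latent variables:", x$n_lv, "\n")
  if (!is.null(x$r2)) cat("  training R2 =", format(x$r2, digits = digits),
                          "\n")
  invisible(x)
}

#' @export
summary.qsar_model <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$residuals)) {
    cat("residuals:\n")
    print(summary(object$residuals))
  }
  invisible(object)
}

#' Serialize a QSAR model to JSON
#'
#' Plain-document serialization (descriptor names, coefficients, intercept,
#' threshold and metadata) readable by [read_qsar_model()].
#'
#' @param model a `qsar_model`.
#' @param path output file.
#' @export
write_qsar_model <- function(model, path) {
  stopifnot(inherits(model, "qsar_model"))
  keep <- c("kind", "descriptors", "coefficients", "intercept", "threshold",
            "positive_class", "negative_class", "n_lv", "wilks", "F", "df")
  doc <- model[intersect(keep, names(model))]
  doc$coefficients <- as.list(model$coefficients)  # keep names in JSON
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qsar_model
#' @export
read_qsar_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- doc[setdiff(names(doc),
                       c("kind", "descriptors", "coefficients", "intercept"))]
  .new_qsar_model(doc$kind, doc$descriptors,
                  unlist(doc$coefficients)[doc$descriptors], doc$intercept,
                  extra = extra)
}
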