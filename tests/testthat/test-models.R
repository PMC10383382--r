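test_that("frozen discriminant model carries the published constants", {
  m <- hsa_discriminant_model()
  expect_equal(m$intercept, -14.668)
  expect_equal(m$coefficients,
               c(Eig12_AEA_bo = 33.651, DECC = 0.378, X4A = 30.405))
  expect_equal(m$descriptors, c("Eig12_AEA_bo", "DECC", "X4A"))
  expect_equal(m$wilks, 0.26)
  expect_equal(m$F, 10.45)
  # zero descriptor vector scores at the intercept
  z <- c(Eig12_AEA_bo = 0, DECC = 0, X4A = 0)
  expect_equal(predict(m, z, type = "score"), -14.668)
  # score below threshold -> H, above -> L
  expect_equal(unname(predict(m, z)), "H")
  hi <- c(Eig12_AEA_bo = 1, DECC = 1, X4A = 1)
  expect_equal(unname(predict(m, hi)), "L")
  # two calls return equal models
  expect_identical(hsa_discriminant_model(), hsa_discriminant_model())
})

test_that("frozen regression model carries the published constants", {
  m <- hsa_ec50_model()
  expect_equal(m$intercept, 24.427)
  expect_equal(m$coefficients,
               c(PDI = -23.551, GATS8v = -0.862, MATS8m = -0.607,
                 QED = -4.388))
  z <- c(PDI = 0, GATS8v = 0, MATS8m = 0, QED = 0)
  expect_equal(predict(m, z), 24.427)
  # linearity of the contributions
  expect_equal(predict(m, z + c(QED = 0, PDI = 0, GATS8v = 0, MATS8m = 0) +
                         c(PDI = 0, GATS8v = 0, MATS8m = 0, QED = 1)) -
                 predict(m, z), -4.388)
  zp <- z; zp["PDI"] <- 0.1
  expect_equal(predict(m, zp) - predict(m, z), -2.3551)
  expect_equal(m$n_lv, 3L)
})

test_that("Fisher discriminant separates well-separated classes", {
  set.seed(11)
  x <- matrix(c(rnorm(50, -5, 0.5), rnorm(50, 5, 0.5)), ncol = 1)
  colnames(x) <- "d"
  y <- rep(c("H", "L"), each = 50)
  m <- qsar_lda(x, y)
  expect_equal(mean(predict(m, x) == y), 1)
  expect_lt(m$wilks, 0.05)
  # flipped labels negate the direction, same lambda
  m2 <- qsar_lda(x, rep(c("L", "H"), each = 50))
  expect_equal(unname(m2$coefficients), -unname(m$coefficients))
  expect_equal(m2$wilks, m$wilks)
})

test_that("identical class means give no separation", {
  set.seed(12)
  x <- matrix(rnorm(120), ncol = 2)
  y <- rep(c("H", "L"), 30)
  m <- qsar_lda(x, y)
  expect_gt(m$wilks, 0.85)
})

test_that("discriminant direction agrees with an independent LDA fit", {
  skip_if_not_installed("MASS")
  set.seed(13)
  d <- make_classification_dataset(
    synthetic_spec(n = 80, pool = 3, true_idx = 1:2, beta = c(1, 1),
                   sigma = 0, seed = 21), delta = 2)
  m <- qsar_lda(d$x, d$labels)
  ref <- MASS::lda(d$x, grouping = d$labels)
  # same direction up to scale
  ratio <- m$coefficients / drop(ref$scaling)
  expect_equal(max(abs(ratio / mean(ratio) - 1)), 0, tolerance = 1e-6)
  # identical class assignments
  expect_equal(unname(predict(m, d$x)),
               as.character(predict(ref, d$x)$class))
})

test_that("MLR recovers exact and noisy linear responses", {
  set.seed(14)
  x <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + 2 * x[, 1] - 3 * x[, 2]
  m <- qsar_mlr(x, y)
  expect_equal(sum(residuals(m)^2), 0, tolerance = 1e-20)
  # duplicated column -> rank error
  xdup <- cbind(x, a2 = x[, "a"])
  expect_error(qsar_mlr(xdup, y), "rank")
  # parameter recovery at sigma = 0.01
  xn <- matrix(rnorm(100), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  yn <- 2 * xn[, 1] - 3 * xn[, 2] + rnorm(50, sd = 0.01)
  mn <- qsar_mlr(xn, yn)
  expect_equal(unname(mn$coefficients), c(2, -3), tolerance = 0.05 / 2)
})

test_that("PLS equals MLR at full latent rank and is reproducible", {
  set.seed(15)
  x <- matrix(rnorm(22 * 4), ncol = 4)
  colnames(x) <- paste0("d", 1:4)
  y <- drop(x %*% c(1, -2, 0.5, 3)) + rnorm(22, sd = 0.3)
  mlr <- qsar_mlr(x, y)
  for (scale in c(TRUE, FALSE)) {
    pls <- qsar_pls(x, y, n_lv = 4, scale = scale)
    expect_equal(predict(pls, x), predict(mlr, x), tolerance = 1e-8)
  }
  expect_identical(coef(qsar_pls(x, y, 2)), coef(qsar_pls(x, y, 2)))
  expect_error(qsar_pls(x, y, 5), "n_lv")
  expect_error(qsar_pls(x, y, 0), "n_lv")
})

test_that("one-LV PLS on orthonormal centred columns is the covariance direction", {
  set.seed(16)
  n <- 40
  x <- qr.Q(qr(matrix(rnorm(n * 3), ncol = 3)))
  x <- scale(x, scale = FALSE)
  x <- qr.Q(qr(x))          # orthonormal, centred
  colnames(x) <- paste0("v", 1:3)
  y <- rnorm(n)
  pls <- qsar_pls(x, y, n_lv = 1, scale = FALSE)
  covs <- drop(crossprod(x, y - mean(y)))
  # closed form: beta = cov * (w'w terms); proportionality suffices
  b <- unname(pls$coefficients)
  expect_equal(b / sqrt(sum(b^2)), unname(covs / sqrt(sum(covs^2))),
               tolerance = 1e-8)
})

test_that("predictions are invariant to descriptor column order", {
  m <- hsa_ec50_model()
  x <- matrix(rnorm(40), ncol = 4,
              dimnames = list(NULL, c("PDI", "GATS8v", "MATS8m", "QED")))
  p1 <- predict(m, x)
  p2 <- predict(m, x[, c(3, 1, 4, 2)])
  expect_equal(p1, p2)
  expect_error(predict(m, x[, 1:3]), "QED")
})

test_that("models serialize to JSON and back", {
  tmp <- withr::local_tempfile(fileext = ".json")
  m <- hsa_discriminant_model()
  write_qsar_model(m, tmp)
  back <- read_qsar_model(tmp)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$kind, "LDA")
  x <- c(Eig12_AEA_bo = 0.3, DECC = 2, X4A = 0.1)
  expect_equal(predict(back, x, type = "score"),
               predict(m, x, type = "score"))
  expect_equal(predict(back, x), predict(m, x))
})
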