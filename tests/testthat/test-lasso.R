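test_that("on orthonormal designs the path equals soft-thresholding", {
  n <- 30
  Q <- orthonormal_design(n, 3, seed = 2)
  # build y with prescribed inner products c = (3, 1, 0.5)
  cvec <- c(3, 1, 0.5)
  y <- drop(Q %*% cvec)
  path <- lasso_path(Q, y, standardize = FALSE)
  enters <- path$events[path$events$action == "enter", ]
  expect_equal(enters$lambda, c(3, 1, 0.5), tolerance = 1e-10)
  expect_equal(enters$predictor, c("x1", "x2", "x3"))
  # soft-thresholding closed form at several lambdas
  for (lam in c(2, 0.75, 0.2, 0)) {
    soft <- sign(cvec) * pmax(abs(cvec) - lam, 0)
    expect_equal(unname(coef_at(path, lam)), soft, tolerance = 1e-10)
  }
  # at lambda = 2 only predictor 1 is active, coefficient 3 - 2 = 1
  b <- coef_at(path, 2)
  expect_equal(unname(b), c(1, 0, 0), tolerance = 1e-10)
})

test_that("a response orthogonal to every predictor yields an empty path", {
  n <- 20
  Q <- orthonormal_design(n, 4, seed = 3)
  # residual of a fit on Q plus intercept: exactly orthogonal to every
  # column and mean-centered
  y <- unname(residuals(lm(rnorm(n) ~ Q)))
  path <- lasso_path(Q, y, standardize = FALSE)
  expect_equal(nrow(path$events), 0)
  expect_equal(unname(coef_at(path, 0.1)), rep(0, 4))
})

test_that("a single predictor enters at |x'y| with the sign of the fit", {
  set.seed(4)
  x <- rnorm(50)
  X <- cbind(x1 = x)
  y <- 2 * x
  path <- lasso_path(X, y, standardize = FALSE)
  yc <- y - mean(y); xc <- x  # path centers y internally
  expect_equal(path$events$lambda[1], abs(sum(x * yc)), tolerance = 1e-8)
  expect_equal(path$events$sign[1], 1)
  expect_equal(path$events$action[1], "enter")
})

test_that("KKT conditions hold at every knot of random paths", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 40; p <- 8
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X[, 1:2] %*% c(2, -1)) + rnorm(n, 0, 0.7)
    path <- lasso_path(X, y)
    for (k in seq_along(path$knots)) {
      lam <- path$knots[k]
      b <- path$beta[, k]
      r <- path$y - drop(path$X %*% b)
      cj <- drop(crossprod(path$X, r))
      act <- which(b != 0)
      if (length(act) > 0) {
        expect_lt(max(abs(abs(cj[act]) - lam)), 1e-8)
        if (lam > 1e-8) {
          # the sign condition is only meaningful away from lambda = 0,
          # where the active correlations vanish
          expect_equal(sign(cj[act]), sign(b[act]))
        }
      }
      inact <- which(b == 0)
      if (length(inact) > 0) {
        expect_lt(max(abs(cj[inact])) - lam, 1e-8)
      }
    }
  }
})

test_that("path solutions agree with glmnet at matched penalties", {
  set.seed(7)
  n <- 60; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% c(1.5, -1, 0, 0, 0.5, 0)) + rnorm(n, 0, 0.5)
  path <- lasso_path(X, y)
  for (k in c(2, 4, length(path$knots) - 1)) {
    lam <- mean(path$knots[k:(k + 1)])    # interior of a segment
    fit <- glmnet::glmnet(path$X, path$y, intercept = FALSE,
                          standardize = FALSE, thresh = 1e-12,
                          lambda = lam / n)
    bg <- as.numeric(glmnet::coef.glmnet(fit, s = lam / n))[-1]
    expect_equal(unname(coef_at(path, lam)), bg, tolerance = 1e-5)
  }
})

test_that("constant predictors are rejected by name", {
  X <- cbind(x1 = rnorm(10), flat = rep(2, 10))
  expect_error(lasso_path(X, rnorm(10)), "flat",
               class = "astronet_config_error")
})

test_that("covariance statistics: zero gives p = 1 and strong signal tiny p", {
  expect_equal(exp(-0), 1)   # tail convention: p = exp(-T)
  set.seed(8)
  n <- 100
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("TF", 1:10)))
  y <- 5 * X[, 3] + rnorm(n, 0, 0.5)
  s2 <- estimate_noise_variance(X, y)
  ct <- covariance_test(lasso_path(X, y), s2)
  expect_equal(ct$predictor[1], "TF3")
  expect_lt(ct$p[1], 5e-5)
  expect_error(covariance_test(lasso_path(X, y), -1),
               class = "astronet_config_error")
})

test_that("noise variance is recovered in low and high dimensions", {
  set.seed(10)
  # n > p + 1: residual variance of the OLS fit
  x <- rnorm(200)
  y <- x + rnorm(200, 0, 1)
  s2 <- estimate_noise_variance(cbind(x = x), y)
  expect_gt(s2, 0.8); expect_lt(s2, 1.25)
  # pure noise with irrelevant predictors
  X <- matrix(rnorm(200 * 5), 200, 5)
  ynull <- rnorm(200, 0, 2)
  s2n <- estimate_noise_variance(X, ynull)
  expect_gt(s2n, 3); expect_lt(s2n, 5.5)
  # p >= n: cross-validated support refit
  Xp <- matrix(rnorm(40 * 60), 40, 60)
  yp <- drop(Xp[, 1:2] %*% c(3, -3)) + rnorm(40, 0, 1)
  s2p <- estimate_noise_variance(Xp, yp, seed = 2)
  expect_gt(s2p, 0.3); expect_lt(s2p, 3)
  # numerically exact fits hit the variance floor with a warning
  xe <- rnorm(30)
  expect_warning(s2e <- estimate_noise_variance(cbind(x = xe), 2 * xe),
                 "floor")
  expect_equal(s2e, 1e-8)
})

test_that("tidy and glance summarize paths", {
  set.seed(12)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- X[, 1] + rnorm(50, 0, 0.5)
  path <- lasso_path(X, y)
  expect_equal(tidy(path), path$events)
  g <- glance(path)
  expect_equal(g$n_predictors, 4)
  expect_true(g$completed)
  expect_equal(g$n_knots, length(path$knots))
})
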