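test_that("zip_loglik has the right closed-form limits", {
  # single observation T = 0 with p = 0.5, mu = ln 2:
  # f(0) = 0.5 + 0.5 * 0.5 = 0.75
  d <- zip_design(0L, matrix(numeric(0), 1, 0))
  expect_equal(zip_loglik(0, log(log(2)), d), log(0.75))

  # zero-inflation pinned at p = 0 reduces to the Poisson log-likelihood
  set.seed(2)
  y <- rpois(30, 1.5)
  X <- matrix(rnorm(30), dimnames = list(NULL, "x"))
  d2 <- zip_design(y, X)
  beta <- c(0.3, 0.2)
  ll_pois <- sum(dpois(y, exp(0.3 + 0.2 * X[, 1]), log = TRUE))
  expect_equal(zip_loglik(c(-1e3, 0), beta, d2), ll_pois, tolerance = 1e-12)
})

test_that("zip_loglik matches a term-by-term density oracle", {
  set.seed(99)
  for (i in 1:30) {
    case <- random_zip_case(n = 20, seed = i)
    gamma <- case$gamma + rnorm(2, sd = 0.3)
    beta <- case$beta + rnorm(2, sd = 0.3)
    expect_equal(zip_loglik(gamma, beta, case$design),
                 naive_zip_loglik(gamma, beta, case$design),
                 tolerance = 1e-10)
  }
})

test_that("zip_loglik rejects non-finite linear predictors", {
  y <- c(0L, 1L)
  X <- matrix(c(1e300, -1e300), dimnames = list(NULL, "huge"))
  d <- zip_design(y, X)
  expect_error(zip_loglik(c(0, 2), c(0, 2), d), "huge")
})

test_that("degenerate outcomes trigger explicit fallbacks", {
  X <- matrix(rnorm(40), dimnames = list(NULL, "x"))
  d0 <- zip_design(rep(0L, 40), X)
  f0 <- fit_zip(d0)
  expect_equal(f0$fallback, "degenerate")
  expect_error(wald_test(f0, "x"), "degenerate")

  # no zeros at all: Poisson fallback with the plain Poisson MLE
  set.seed(4)
  y <- rpois(200, 8); y[y == 0] <- 1L
  X2 <- matrix(rnorm(200), dimnames = list(NULL, "x"))
  d1 <- zip_design(y, X2)
  f1 <- fit_zip(d1)
  expect_equal(f1$fallback, "poisson")
  ref <- glm(y ~ X2, family = poisson)
  expect_equal(unname(f1$beta), unname(coef(ref)), tolerance = 1e-6)
  w <- wald_test(f1, "x")
  expect_equal(w$se, sqrt(vcov(ref)[2, 2]), tolerance = 1e-4)
})

test_that("intercept-only fit solves the zero-fraction/mean system", {
  set.seed(10)
  y <- simulate_zip_counts(matrix(1, 500), matrix(1, 500),
                           qlogis(0.3), log(2), seed = 10)
  d <- zip_design(y, matrix(numeric(0), 500, 0))
  f <- fit_zip(d)
  oracle <- zip_moment_mle(y)
  expect_equal(unname(plogis(f$gamma[1])), unname(oracle["p"]), tolerance = 1e-5)
  expect_equal(unname(exp(f$beta[1])), unname(oracle["mu"]), tolerance = 1e-5)
})

test_that("the fitted ZIP likelihood dominates its Poisson warm start", {
  for (i in 1:10) {
    case <- random_zip_case(n = 300, seed = 100 + i)
    f <- fit_zip(case$design)
    expect_true(f$converged)
    expect_gte(f$loglik, f$loglik_poisson - 1e-8)
  }
})

test_that("fit agrees with an independent mixture fitter", {
  skip_if_not_installed("glmmTMB")
  case <- random_zip_case(n = 800, seed = 77)
  f <- fit_zip(case$design)
  df <- data.frame(y = case$design$y, x = case$design$Xm[, "x1"])
  ref <- glmmTMB::glmmTMB(y ~ x, ziformula = ~x, family = poisson, data = df)
  expect_equal(unname(f$beta), unname(glmmTMB::fixef(ref)$cond),
               tolerance = 1e-3)
  expect_equal(unname(f$gamma), unname(glmmTMB::fixef(ref)$zi),
               tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  se <- sqrt(diag(vcov(ref)$cond))
  expect_equal(sqrt(f$vcov["x1", "x1"]), unname(se["x"]), tolerance = 1e-2)
})

test_that("Wald test follows the normal reference", {
  case <- random_zip_case(n = 400, seed = 5)
  f <- fit_zip(case$design)
  w <- wald_test(f, "x1")
  expect_equal(w$p.value, 2 * pnorm(-abs(w$estimate / w$se)))
  # hand-built fits pin the trivial quantiles
  fake <- structure(list(beta = c(`(Intercept)` = 0, x = 0),
                         gamma = NULL, fallback = "poisson",
                         vcov = diag(2), converged = TRUE),
                    class = "zip_fit")
  dimnames(fake$vcov) <- list(c("(Intercept)", "x"), c("(Intercept)", "x"))
  expect_equal(wald_test(fake, "x")$p.value, 1)
  fake$beta["x"] <- 1.959964
  expect_equal(wald_test(fake, "x")$p.value, 0.05, tolerance = 1e-6)
})

test_that("likelihood-ratio test bookkeeping and asymptotics", {
  case <- random_zip_case(n = 600, seed = 21)
  f <- fit_zip(case$design)
  expect_equal(lrt_test(f, f)$statistic, 0)
  expect_equal(lrt_test(f, f)$p.value, 1)

  red <- fit_zip(zip_design(case$design$y, matrix(numeric(0), 600, 0)))
  lr <- lrt_test(f, red)
  expect_equal(lr$df, 2L)  # x1 dropped from both components
  expect_equal(lr$p.value, pchisq(lr$statistic, 2, lower.tail = FALSE))
  expect_error(lrt_test(red, f), "more coefficients")

  # Wald and LRT agree within a factor of 2 at moderate significance
  w <- wald_test(f, "x1")
  if (w$p.value > 1e-4 && w$p.value < 0.5) {
    lr1 <- lrt_test(f, fit_zip(zip_design(
      case$design$y, case$design$Xm[, 0, drop = FALSE])))
    expect_lt(abs(log(w$p.value / lr1$p.value)), log(2) + log(10))
  }
})

test_that("null Wald p-values are approximately uniform", {
  set.seed(2024)
  n <- 400
  pvals <- numeric(300)
  for (i in 1:300) {
    x <- rnorm(n)
    X <- matrix(x, dimnames = list(NULL, "x"))
    y <- simulate_zip_counts(cbind(1, X), cbind(1, X), c(-1, 0), c(0.3, 0),
                             seed = 5000 + i)
    f <- fit_zip(zip_design(y, X))
    pvals[i] <- wald_test(f, "x")$p.value
  }
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("beta estimates approach the truth as N grows", {
  bias <- sapply(c(500, 2000, 8000), function(n) {
    est <- sapply(1:8, function(i) {
      case <- random_zip_case(n = n, seed = 3000 + i)
      fit_zip(case$design)$beta["x1"]
    })
    abs(mean(est) - 0.4)
  })
  expect_lt(bias[3], 0.03)
  expect_lt(bias[3], bias[1] + 0.02)
})
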