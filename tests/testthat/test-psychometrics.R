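# psychometric GLM fitting, diagnostics, thresholds, bootstrap

test_that("IRLS matches the derivative-free ML oracle on small tables", {
  toy <- fixture_toy_trials()
  for (lk in c("logit", "probit", "cloglog")) {
    f <- suppressWarnings(fit_binomial_glm(toy, "x", link = lk))
    expect_true(f$converged)
    oracle <- ml_oracle(toy, "x", lk)
    expect_equal(unname(f$coefficients), unname(oracle), tolerance = 1e-6)
  }
  # and against stats::glm as a second, independent route
  g <- stats::glm(response ~ x, stats::binomial("logit"), toy,
                  control = stats::glm.control(epsilon = 1e-12))
  f <- fit_binomial_glm(toy, "x", link = "logit")
  expect_equal(unname(f$coefficients), unname(stats::coef(g)),
               tolerance = 1e-7)
  expect_equal(unname(f$se),
               unname(sqrt(diag(stats::vcov(g)))), tolerance = 1e-5)
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-9)
})

test_that("mirror-symmetric data give a zero intercept under the logit link", {
  # base pattern plus its mirror (x, y) -> (-x, 1 - y); the overlap at
  # +/-0.5 prevents separation, so the MLE is finite and exactly symmetric
  base <- data.frame(response = c(0, 0, 1, 0, 1, 1),
                     x = c(-2, -1, -0.5, 0.5, 1, 2))
  t <- rbind(base, data.frame(response = 1 - base$response, x = -base$x))
  f <- suppressWarnings(fit_binomial_glm(t, "x", link = "logit"))
  expect_lt(abs(f$coefficients[["(intercept)"]]), 1e-8)
})

test_that("degenerate and rank-deficient designs are handled", {
  t <- data.frame(response = rep(0, 12), x = 1:12)
  expect_warning(f <- fit_binomial_glm(t, "x"), "separation")
  t2 <- data.frame(response = rep(0:1, 6), x = 1:12, x2 = 2 * (1:12))
  expect_error(suppressWarnings(fit_binomial_glm(t2, c("x", "x2"))),
               "rank-deficient")
  expect_error(fit_binomial_glm(data.frame(response = c(0, 1, 2), x = 1:3),
                                "x"), "0/1")
})

test_that("diagnostics reproduce the closed-form formulas", {
  # AICc arithmetic: LL = -40, k = 3, n = 82
  f <- fixture_glm_fit(loglik = -40, null_loglik = -50, n = 82, k = 3)
  d <- fit_diagnostics(f)
  expect_equal(d$aic, 86)
  expect_equal(d$aicc, 86 + 24 / 78, tolerance = 1e-12)

  # Nagelkerke: n = 10, LL0 = 10 ln(1/2), LL1 = -3
  f2 <- fixture_glm_fit(loglik = -3, null_loglik = 10 * log(0.5), n = 10,
                        k = 2)
  expect_equal(fit_diagnostics(f2)$nagelkerke_r2, 0.72595, tolerance = 1e-4)
  expect_equal(fit_diagnostics(f2)$nagelkerke_r2,
               (1 - exp(-0.78629)) / 0.75, tolerance = 1e-4)

  # intercept-only model: R2 = 0, chi2 = 0
  f3 <- fixture_glm_fit(loglik = -6.9315, null_loglik = -6.9315, n = 10,
                        k = 1)
  expect_equal(fit_diagnostics(f3)$nagelkerke_r2, 0)
  expect_equal(fit_diagnostics(f3)$model_chi2, 0)

  # AICc -> AIC as n grows (n = 1e6)
  f4 <- fixture_glm_fit(loglik = -40, null_loglik = -50, n = 1e6, k = 3)
  expect_equal(fit_diagnostics(f4)$aicc, fit_diagnostics(f4)$aic,
               tolerance = 1e-4)

  # AICc undefined when n <= k + 1
  expect_error(fit_diagnostics(fixture_glm_fit(-1, -2, n = 4, k = 3)),
               "AICc undefined")
})

test_that("VIF is 1 for orthogonal predictors and >1 for correlated ones", {
  set.seed(3)
  n <- 40
  a <- rep(c(-1, 1), n / 2)
  b <- rep(c(-1, -1, 1, 1), n / 4)  # orthogonal to a by construction
  t <- data.frame(response = stats::rbinom(n, 1, 0.5), a = a, b = b)
  f <- suppressWarnings(fit_binomial_glm(t, c("a", "b")))
  expect_equal(unname(fit_diagnostics(f)$vif), c(1, 1), tolerance = 1e-9)
  t$c <- a + stats::rnorm(n, 0, 0.3)
  f2 <- suppressWarnings(fit_binomial_glm(t, c("a", "c")))
  expect_true(all(fit_diagnostics(f2)$vif > 1.5))
})

test_that("threshold closed forms hold for every link", {
  mkfit <- function(b0, b1, link) {
    f <- fixture_glm_fit(-5, -6, n = 20, k = 2, predictors = "x",
                         X = cbind("(intercept)" = rep(1, 20), x = 1:20))
    f$coefficients <- c("(intercept)" = b0, x = b1)
    f$link <- link
    f
  }
  expect_equal(threshold_location(mkfit(0, 2, "logit")), 0)
  expect_equal(threshold_location(mkfit(0.97, 0.40, "logit")), -2.425)
  expect_equal(threshold_location(mkfit(0.97, 0.40, "probit")),
               -0.97 / 0.40)
  expect_equal(threshold_location(mkfit(0, 1, "cloglog")), log(log(2)),
               tolerance = 1e-9)
  expect_equal(threshold_location(mkfit(0, 1, "cloglog")), -0.36651,
               tolerance = 1e-5)
  expect_error(threshold_location(mkfit(1, 1e-10, "logit")),
               "threshold undefined")
})

test_that("logit fits are equivariant under predictor rescaling", {
  t <- fixture_logit_trials(200, beta0 = -1, beta1 = 1.5, seed = 9)
  f1 <- fit_binomial_glm(t, "x")
  t2 <- t; t2$x <- t$x * 4
  f2 <- fit_binomial_glm(t2, "x")
  expect_equal(f2$coefficients[["x"]], f1$coefficients[["x"]] / 4,
               tolerance = 1e-6)
  expect_equal(threshold_location(f2), 4 * threshold_location(f1),
               tolerance = 1e-6)
})

test_that("bootstrap threshold: determinism, B = 1, degenerate IQR, recovery", {
  t <- fixture_logit_trials(60, beta0 = 0.5, beta1 = 1.2, seed = 2)
  b1 <- bootstrap_threshold(t, "x", B = 50, seed = 123)
  b2 <- bootstrap_threshold(t, "x", B = 50, seed = 123)
  expect_identical(b1, b2)
  expect_false(identical(b1$values,
                         bootstrap_threshold(t, "x", B = 50, seed = 124)$values))

  # B = 1 equals a single seeded resample refit, and has zero IQR
  # (no resampling variance); a 2-distinct-row table cannot exercise this
  # because two-point binary data are perfectly separated under a GLM
  b <- bootstrap_threshold(t, "x", B = 1, seed = 77)
  set.seed(77)
  idx <- sample.int(nrow(t), nrow(t), replace = TRUE)
  fm <- suppressWarnings(fit_binomial_glm(t[idx, ], "x"))
  expect_equal(b$boot_median, threshold_location(fm), tolerance = 1e-12)
  expect_identical(b$boot_iqr, 0)

  # a fully separated table: every replicate dropped, flagged unreliable
  sep <- data.frame(response = rep(c(0, 1), each = 10),
                    x = rep(c(0, 1), each = 10))
  bs <- suppressWarnings(bootstrap_threshold(sep, "x", B = 10, seed = 4))
  expect_false(bs$reliable)
  expect_equal(bs$n_failed, 10)

  # parameter recovery: true threshold 2.0, slope 2.4, n = 500
  tt <- fixture_logit_trials(500, beta0 = -2.0 * 2.4, beta1 = 2.4, seed = 31,
                             xmin = -1, xmax = 5)
  br <- bootstrap_threshold(tt, "x", B = 2000, seed = 8)
  expect_lt(abs(br$boot_median - 2.0), 0.15)
  expect_true(br$reliable)
})
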