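test_that("noiseless data recovers the generating coefficients exactly", {
  beta <- c(-6, 0.5, -0.01, -0.002)
  d <- noiseless_rows(beta)
  fit <- fit_qspr(d)
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
  expect_false(fit$underdetermined)
  expect_false(fit$condition_warning)
})

test_that("a degenerate all-zero design collapses to the intercept-only fit", {
  d <- data.frame(logp = 0, tpsa = 0, mv = 0,
                  log_kp = c(-4, -5, -6, -7, -8))
  fit <- fit_qspr(d)
  expect_equal(unname(coef(fit)[["intercept"]]), mean(d$log_kp),
               tolerance = 1e-12)
  expect_equal(unname(coef(fit))[2:4], c(0, 0, 0))
  expect_true(fit$condition_warning)
})

test_that("the fit matches two independent OLS oracles on random designs", {
  for (seed in c(1, 7, 19)) {
    d <- with_toy_seed(seed, data.frame(
      logp = runif(12, -3, 5), tpsa = runif(12, 0, 150),
      mv = runif(12, 60, 480), log_kp = runif(12, -9, -3)))
    fit <- fit_qspr(d)
    expect_equal(unname(coef(fit)), oracle_ols_normal(d), tolerance = 1e-8)
    expect_equal(unname(coef(fit)), oracle_ols_pinv(d), tolerance = 1e-8)
  }
})

test_that("OLS residuals are orthogonal to every design column", {
  d <- with_toy_seed(3, data.frame(
    logp = runif(20, -3, 5), tpsa = runif(20, 0, 150),
    mv = runif(20, 60, 480), log_kp = runif(20, -9, -3)))
  fit <- fit_qspr(d)
  X <- cbind(1, d$logp, d$tpsa, d$mv)
  dots <- abs(crossprod(X, residuals(fit)))
  scale <- sqrt(colSums(X^2)) * sqrt(sum(residuals(fit)^2))
  expect_true(all(dots / scale < 1e-6))
  expect_lt(abs(sum(residuals(fit))), 1e-8)
})

test_that("underdetermined fits are flagged and the n = 2 R^2 is withheld", {
  d2 <- noiseless_rows(n = 2, seed = 5)
  fit2 <- fit_qspr(d2)
  expect_true(fit2$underdetermined)
  expect_true(is.na(fit2$r_squared))
  expect_lt(fit2$rmse, 1e-9) # rank-deficient fit is exact

  d3 <- noiseless_rows(n = 3, seed = 5)
  fit3 <- fit_qspr(d3)
  expect_true(fit3$underdetermined)
  expect_equal(fit3$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_qspr(d2[1, , drop = FALSE]), "at least 2 rows")
})

test_that("rescaling a descriptor rescales its coefficient and nothing else", {
  d <- with_toy_seed(11, data.frame(
    logp = runif(15, -3, 5), tpsa = runif(15, 0, 150),
    mv = runif(15, 60, 480), log_kp = runif(15, -9, -3)))
  fit <- fit_qspr(d)
  d10 <- transform(d, tpsa = tpsa * 10)
  fit10 <- fit_qspr(d10)
  expect_equal(coef(fit10)[["tpsa"]], coef(fit)[["tpsa"]] / 10,
               tolerance = 1e-9)
  expect_equal(predict(fit10, d10), predict(fit, d), tolerance = 1e-9)
})

test_that("duplicating a row pulls the fit toward that observation", {
  d <- data.frame(logp = c(0, 1, 2, 3, 4), tpsa = 0, mv = 0,
                  log_kp = c(-6, -5.6, -5.4, -4.6, -4.4))
  base_pred <- predict(fit_qspr(d), d[5, ])
  heavier <- predict(fit_qspr(rbind(d, d[5, ], d[5, ])), d[5, ])
  expect_lt(abs(heavier - d$log_kp[5]), abs(base_pred - d$log_kp[5]))
})

test_that("prediction is the stated affine form", {
  eq2 <- qspr_published(-6.136, 0.818, -0.005, -0.007)
  expect_identical(predict(eq2, data.frame(logp = 0, tpsa = 0, mv = 0)),
                   -6.136)
  # hand arithmetic: -6.136 + 0.818 - 0.05 - 0.70
  expect_equal(predict(eq2, data.frame(logp = 1, tpsa = 10, mv = 100)),
               -6.068, tolerance = 1e-12)
  d <- data.frame(logp = 1.3, tpsa = 44, mv = 210)
  d2 <- transform(d, logp = 2 * logp, tpsa = 2 * tpsa, mv = 2 * mv)
  d0 <- data.frame(logp = 0, tpsa = 0, mv = 0)
  expect_equal(predict(eq2, d2) - predict(eq2, d),
               predict(eq2, d) - predict(eq2, d0), tolerance = 1e-12)
})

test_that("evaluation metrics match long-hand arithmetic on a tiny set", {
  model <- qspr_published(0, 1, 0, 0) # logKp = logp
  rows <- data.frame(logp = c(1, 2, 3), tpsa = 0, mv = 0,
                     log_kp = c(2, 2, 5))
  m <- evaluate_qspr(model, rows)
  # residuals 1, 0, 2 -> SSE 5; SST about mean 3 is 6; RMSE sqrt(5/3)
  expect_equal(m$r_squared_sse, 1 - 5 / 6, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(m$r_squared_pearson, cor(c(1, 2, 3), c(2, 2, 5))^2,
               tolerance = 1e-12)
  expect_equal(m$n, 3)
})

test_that("the two R-squared conventions agree on training data", {
  d <- with_toy_seed(23, data.frame(
    logp = runif(25, -3, 5), tpsa = runif(25, 0, 150),
    mv = runif(25, 60, 480)))
  d$log_kp <- -6 + 0.5 * d$logp - 0.01 * d$tpsa - 0.002 * d$mv +
    with_toy_seed(24, rnorm(25, sd = 0.4))
  fit <- fit_qspr(d)
  m <- evaluate_qspr(fit, d)
  expect_equal(m$r_squared_sse, m$r_squared_pearson, tolerance = 1e-9)
  expect_equal(m$r_squared_sse, fit$r_squared, tolerance = 1e-12)
  expect_equal(m$rmse, fit$rmse, tolerance = 1e-12)
})

test_that("perfect prediction and zero-variance responses are handled", {
  model <- qspr_published(-6, 0.5, -0.01, -0.002)
  rows <- noiseless_rows(c(-6, 0.5, -0.01, -0.002))
  m <- evaluate_qspr(model, rows)
  expect_equal(m$r_squared_sse, 1, tolerance = 1e-12)
  expect_equal(m$r_squared_pearson, 1, tolerance = 1e-9)
  expect_equal(m$rmse, 0, tolerance = 1e-12)

  flat <- data.frame(logp = 1:5, tpsa = 0, mv = 0, log_kp = -5)
  m2 <- evaluate_qspr(model, flat)
  expect_true(is.na(m2$r_squared_sse))
  expect_true(is.na(m2$r_squared_pearson))
})

test_that("model methods expose the fit consistently", {
  d <- noiseless_rows(n = 8, seed = 31)
  d$log_kp <- d$log_kp + with_toy_seed(32, rnorm(8, sd = 0.2))
  fit <- fit_qspr(d, scenario = "abdomen/epidermis/diluted/20-25")
  expect_equal(fitted(fit) + residuals(fit), d$log_kp, tolerance = 1e-12)
  expect_output(print(fit), "logKp = ")
  s <- summary(fit)
  expect_equal(unname(s$coefficients[, "Estimate"]), unname(coef(fit)))
  expect_output(print(s), "Std. Error")
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(8, 3))
  # seeded simulation is reproducible and does not disturb the RNG
  before <- runif(1)
  sims2 <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(sims, sims2)
})
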