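planted_three <- list(
  "abdomen/epidermis/diluted/20-25" = c(-6, 0.8, -0.005, -0.007),
  "breast/dermis/concentrated/26-30" = c(-4, 0.3, -0.01, -0.002),
  "thigh/epidermis+dermis/diluted/36-40" = c(-7, 0.5, 0.002, -0.004))

test_that("the scenario table recovers planted models without noise", {
  cfg <- generator_config(n_compounds = 45, records_per_compound = c(1, 1),
                          scenario_coefficients = planted_three,
                          noise_sd = 0, missingness_rate = 0,
                          outlier_fraction = 0, seed = 21)
  sim <- generate_dataset(cfg)
  a <- assign_scenarios(sim$dataset$records, sim$dataset$descriptors)
  table <- build_scenario_table(a)
  expect_equal(nrow(table$summary), length(planted_three))
  expect_equal(table$summary$scenario,
               intersect(enumerate_scenarios(), names(planted_three)))
  for (key in names(planted_three)) {
    expect_equal(unname(coef(table$models[[key]])), planted_three[[key]],
                 tolerance = 1e-9)
  }
  expect_equal(table$summary$n_records,
               table$summary$n_compounds) # one record per compound here
})

test_that("scenario groups too small to fit become flagged placeholder rows", {
  rec <- toy_records(1)
  desc <- toy_descriptors(1)
  a <- assign_scenarios(rec, desc)
  table <- build_scenario_table(a)
  expect_equal(nrow(table$summary), 1)
  expect_true(table$summary$underdetermined)
  expect_true(is.na(table$summary$intercept))
  expect_null(table$models[[table$summary$scenario[1]]])
})

test_that("best-model selection applies the size floor and R^2 ranking", {
  reg <- published_models()
  best <- select_best(reg$table)
  expect_equal(best$scenario, "abdomen/epidermis/diluted/20-25")
  expect_equal(best$n, 36L)
  expect_equal(best$r_squared, 0.8545)
  # too high a floor: informative error reporting the largest n
  expect_error(select_best(reg$table, min_n = 100), "largest available n is 45")
})

test_that("select_best breaks ties toward the earlier scenario", {
  mk <- function(key, n, r2) {
    m <- qspr_published(-6, 0.5, 0, 0, n = n, r_squared = r2,
                        scenario = key)
    list(model = m,
         row = data.frame(scenario = key, parse_scenario(key),
                          n_records = n, n_compounds = n, r_squared = r2,
                          rmse = NA_real_, intercept = -6, coef_logp = 0.5,
                          coef_tpsa = 0, coef_mv = 0,
                          underdetermined = FALSE))
  }
  keys <- c("abdomen/epidermis/diluted/20-25",
            "thigh/epidermis/diluted/36-40")
  parts <- lapply(keys, mk, n = 20, r2 = 0.9)
  table <- structure(list(
    models = setNames(lapply(parts, `[[`, "model"), keys),
    summary = do.call(rbind, lapply(parts, `[[`, "row"))),
    class = "qspr_table")
  expect_equal(select_best(table)$scenario, keys[1])
})

test_that("split sizes reproduce the published train/test arithmetic", {
  d36 <- with_toy_seed(41, data.frame(
    logp = runif(36, -3, 5), tpsa = runif(36, 0, 150),
    mv = runif(36, 60, 480)))
  d36$log_kp <- -6 + 0.8 * d36$logp + with_toy_seed(42, rnorm(36, sd = 0.3))
  s36 <- split_train_test(d36, seed = 1)
  expect_equal(nrow(s36$train), 29)
  expect_equal(nrow(s36$test), 7)

  d214 <- with_toy_seed(43, data.frame(
    logp = runif(214, -3, 5), tpsa = runif(214, 0, 150),
    mv = runif(214, 60, 480)))
  d214$log_kp <- -5.8 + 0.3 * d214$logp + with_toy_seed(44, rnorm(214, sd = 0.7))
  s214 <- split_train_test(d214, seed = 1)
  expect_equal(nrow(s214$train), 171)
  expect_equal(nrow(s214$test), 43)
})

test_that("splits are seed-deterministic, disjoint and exhaustive", {
  d <- with_toy_seed(45, data.frame(
    logp = runif(30, -3, 5), tpsa = runif(30, 0, 150),
    mv = runif(30, 60, 480), log_kp = runif(30, -8, -4)))
  a <- split_train_test(d, seed = 99)
  b <- split_train_test(d, seed = 99)
  expect_identical(a$train, b$train)
  expect_identical(a$test, b$test)
  combined <- rbind(a$train, a$test)
  expect_equal(nrow(combined), nrow(d))
  key <- function(x) paste(x$logp, x$tpsa, x$mv, x$log_kp)
  expect_setequal(key(combined), key(d))
  expect_length(intersect(key(a$train), key(a$test)), 0)
  # the training-set metrics are the model's own fit diagnostics
  expect_equal(a$train_metrics$r_squared_sse, a$model$r_squared,
               tolerance = 1e-12)
})

test_that("the coverage rule resamples or fails informatively", {
  # one extreme logP row: a test set without it spans < 25% of the spread
  d <- data.frame(logp = c(rep(0:4, 3), 100), tpsa = runif(16, 0, 150),
                  mv = runif(16, 60, 480), log_kp = runif(16, -8, -4))
  s <- split_train_test(d, seed = 7, max_attempts = 500)
  for (col in c("logp", "tpsa", "mv")) {
    expect_gte(diff(range(s$test[[col]])), 0.25 * diff(range(d[[col]])))
  }
  expect_true(s$n_resample_attempts >= 1)
  # impossible coverage: demand more spread than any 20% subset can have
  expect_error(
    split_train_test(d, seed = 7, max_attempts = 3, coverage_fraction = 2),
    "logp")
})

test_that("preference scoring keeps the best-matching record per compound", {
  rec <- rbind(
    # c01: first record matches everything, second nothing
    toy_records(1, compound_id = "c01", skin_source = "abdomen",
                skin_layer = "dermis", donor_concentration = "concentrated",
                donor_temperature_c = 32, donor_ph = 7.2),
    toy_records(1, compound_id = "c01", skin_source = "breast",
                skin_layer = "stratum_corneum",
                donor_concentration = "diluted",
                donor_temperature_c = 22, donor_ph = 5),
    # c02: single record, poor match, still kept
    toy_records(1, compound_id = "c02", skin_source = "thigh",
                donor_temperature_c = 22, donor_ph = 5))
  rec$log_kp <- c(-5, -6, -7)
  ds <- huskin_dataset(rec, toy_descriptors(2))
  out <- select_one_per_compound(ds)
  expect_equal(nrow(out), 2)
  expect_equal(out$log_kp[out$compound_id == "c01"], -5)
  expect_equal(out$preference_score[out$compound_id == "c01"], 5)
  expect_equal(out$log_kp[out$compound_id == "c02"], -7)
})

test_that("preference ties break toward the first record in input order", {
  rec <- rbind(
    toy_records(1, compound_id = "c01", donor_temperature_c = 22),
    toy_records(1, compound_id = "c01", donor_temperature_c = 23))
  rec$log_kp <- c(-5, -6)
  out <- select_one_per_compound(huskin_dataset(rec, toy_descriptors(1)))
  expect_equal(out$log_kp, -5)
})

test_that("missing metadata never satisfies a preference criterion", {
  rec <- rbind(
    toy_records(1, compound_id = "c01", skin_source = "abdomen",
                skin_layer = "epidermis",
                donor_concentration = "diluted",
                donor_temperature_c = 22, donor_ph = 7.2),
    toy_records(1, compound_id = "c01"))
  rec$skin_source[2] <- NA
  rec$donor_ph[2] <- NA
  rec$log_kp <- c(-5, -6)
  out <- select_one_per_compound(huskin_dataset(rec, toy_descriptors(1)))
  expect_equal(out$log_kp, -5) # scores 3 vs at most 2
})

test_that("the outlier filter removes planted gross errors and refits closer", {
  truth <- c(-5.8, 0.4, -0.003, -0.004)
  cfg <- generator_config(
    n_compounds = 253, records_per_compound = c(1, 1),
    scenario_coefficients = list(
      "abdomen/epidermis+dermis/concentrated/31-35" = truth),
    noise_sd = 0.5, missingness_rate = 0, outlier_fraction = 40 / 253,
    outlier_offset = 3, seed = 311)
  sim <- generate_dataset(cfg)
  rows <- select_one_per_compound(sim$dataset)
  expect_equal(nrow(rows), 253)
  filt <- outlier_filter_refit(rows, threshold = 1.5)
  planted <- sim$dataset$records$compound_id[sim$truth$outlier_rows]
  expect_length(planted, 40)
  recall <- mean(planted %in% filt$removed$compound_id)
  expect_gte(recall, 0.9)
  err <- function(m) sqrt(sum((coef(m) - truth)^2))
  expect_lt(err(filt$model_after), err(filt$model_before))
  # partition invariants
  res_before <- rows$log_kp - predict(filt$model_before, rows)
  expect_true(all(abs(res_before[rows$compound_id %in%
                                   filt$removed$compound_id]) > 1.5))
  expect_true(all(abs(res_before[rows$compound_id %in%
                                   filt$kept$compound_id]) <= 1.5))
})

test_that("an infinite threshold makes the outlier filter the identity", {
  d <- with_toy_seed(51, data.frame(
    logp = runif(20, -3, 5), tpsa = runif(20, 0, 150),
    mv = runif(20, 60, 480), log_kp = runif(20, -9, -2)))
  filt <- outlier_filter_refit(d, threshold = Inf)
  expect_equal(nrow(filt$removed), 0)
  expect_identical(coef(filt$model_after), coef(filt$model_before))
})

test_that("the pooled workflow composes its stages deterministically", {
  truth <- c(-5.8, 0.4, -0.003, -0.004)
  cfg <- generator_config(
    n_compounds = 120, records_per_compound = c(1, 2),
    scenario_coefficients = list(
      "abdomen/dermis/concentrated/31-35" = truth),
    noise_sd = 0.4, missingness_rate = 0, outlier_fraction = 0.1,
    outlier_offset = 3, seed = 313)
  sim <- generate_dataset(cfg)
  p1 <- suppressMessages(run_pooled_workflow(sim$dataset, seed = 4))
  p2 <- suppressMessages(run_pooled_workflow(sim$dataset, seed = 4))
  expect_equal(p1$n_compounds, 120)
  expect_equal(nrow(p1$filter$kept),
               p1$n_compounds - nrow(p1$filter$removed))
  expect_identical(coef(p1$model_full), coef(p2$model_full))
  expect_identical(p1$split$test, p2$split$test)
  expect_equal(nrow(p1$split$train), floor(0.8 * nrow(p1$filter$kept) + 0.5))
})

test_that("parameter recovery error shrinks with sample size", {
  truth <- c(-6, 0.8, -0.005, -0.007)
  median_err <- sapply(c(20, 100, 500), function(n) {
    errs <- sapply(1:20, function(r) {
      cfg <- generator_config(
        n_compounds = n, records_per_compound = c(1, 1),
        scenario_coefficients = list(
          "abdomen/epidermis/diluted/20-25" = truth),
        noise_sd = 0.3, missingness_rate = 0, outlier_fraction = 0,
        seed = 1000 + r * 7 + n)
      sim <- generate_dataset(cfg)
      fit <- fit_qspr(sim$dataset$records |>
                        merge(sim$dataset$descriptors, by = "compound_id"))
      sqrt(sum((coef(fit) - truth)^2))
    })
    median(errs)
  })
  expect_true(all(diff(median_err) < 0))
})
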