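# The two modelling workflows: per-scenario model tables with best-model
# selection, and the pooled outlier-filtered model, plus the shared
# train/test validation protocol.

#' Fit one QSPR model per non-empty scenario
#'
#' Fits [fit_qspr()] on every scenario group of an assignment, in
#' [enumerate_scenarios()] order. Groups with fewer than two rows yield a
#' flagged, coefficient-free placeholder row so the table still accounts
#' for every non-empty scenario.
#'
#' @param assignment A `"scenario_assignment"` from [assign_scenarios()].
#' @return An object of class `"qspr_table"`: a list with `models` (named
#'   list of `"qspr"` objects or `NULL` placeholders, keyed by scenario)
#'   and `summary` (data frame, one row per non-empty scenario, with the
#'   scenario columns, `n_records`, `n_compounds`, `r_squared`, `rmse`,
#'   the four coefficients and the `underdetermined` flag).
#' @export
build_scenario_table <- function(assignment) {
  stopifnot(inherits(assignment, "scenario_assignment"))
  keys <- names(assignment$groups)
  models <- vector("list", length(keys))
  names(models) <- keys
  rows <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    g <- assignment$groups[[i]]
    key <- keys[i]
    parsed <- parse_scenario(key)
    n_compounds <- length(unique(g$compound_id))
    if (nrow(g) >= 2) {
      m <- fit_qspr(g, scenario = key)
      models[[i]] <- m
      rows[[i]] <- data.frame(
        scenario = key, parsed,
        n_records = m$n, n_compounds = n_compounds,
        r_squared = m$r_squared, rmse = m$rmse,
        intercept = m$coefficients[["intercept"]],
        coef_logp = m$coefficients[["logp"]],
        coef_tpsa = m$coefficients[["tpsa"]],
        coef_mv = m$coefficients[["mv"]],
        underdetermined = m$underdetermined,
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        scenario = key, parsed,
        n_records = nrow(g), n_compounds = n_compounds,
        r_squared = NA_real_, rmse = NA_real_,
        intercept = NA_real_, coef_logp = NA_real_,
        coef_tpsa = NA_real_, coef_mv = NA_real_,
        underdetermined = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(summary) <- NULL
  structure(list(models = models, summary = summary), class = "qspr_table")
}

#' @export
print.qspr_table <- function(x, ...) {
  cat(sprintf("QSPR scenario table: %d model(s)\n", nrow(x$summary)))
  if (nrow(x$summary)) {
    print(x$summary[, c("scenario", "n_records", "n_compounds",
                        "r_squared", "rmse", "underdetermined")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.qspr_table <- function(x, ...) x$summary

#' Write a scenario model table as CSV
#'
#' @param table A `"qspr_table"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models_csv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Select the best scenario model
#'
#' Among scenario models fitted on at least `min_n` rows (and not flagged
#' underdetermined or lacking an R^2), returns the one with the highest
#' coefficient of determination; ties break deterministically toward the
#' scenario earlier in [enumerate_scenarios()] order. The size floor
#' reflects the source study's rule that scenarios with 15 or fewer
#' compounds are too small to trust as QSPR models.
#'
#' @param table A `"qspr_table"` (fitted or published).
#' @param min_n Minimum rows for eligibility (default 16).
#' @return The winning `"qspr"` model.
#' @export
select_best <- function(table, min_n = 16) {
  stopifnot(inherits(table, "qspr_table"))
  s <- table$summary
  if (nrow(s) == 0) stop("empty model table", call. = FALSE)
  eligible <- s$n_records >= min_n & !s$underdetermined & !is.na(s$r_squared)
  if (!any(eligible)) {
    stop(sprintf(
      "no scenario model with n >= %d; largest available n is %d",
      min_n, max(s$n_records)), call. = FALSE)
  }
  idx <- which(eligible)
  best <- idx[which.max(s$r_squared[idx])] # which.max takes the first tie
  table$models[[s$scenario[best]]]
}

#' Split rows into a training and test set and validate a QSPR fit
#'
#' Randomly partitions labelled rows with `round(0.8 n)` (half rounded
#' up) in the training set — reproducing the published 36 to 29/7 and
#' 214 to 171/43 splits — refits the QSPR on the training rows only and
#' evaluates both sets. The draw is resampled (up to `max_attempts`)
#' until the test set covers a range of every descriptor: its spread
#' (max - min) must reach `coverage_fraction` of the full set's spread
#' for logP, TPSA and MV alike.
#'
#' @param data Data frame with `logp`, `tpsa`, `mv`, `log_kp`; at least 5
#'   rows.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed controlling the draw; the caller's RNG state
#'   is restored afterwards.
#' @param max_attempts Resampling budget for the coverage check.
#' @param coverage_fraction Required test-set spread as a fraction of the
#'   full spread, per descriptor (default 0.25).
#' @return An object of class `"qspr_split"`: list with `train`, `test`
#'   (row data frames), `model` (fit on train), `train_metrics`,
#'   `test_metrics` ([evaluate_qspr()] lists), `seed` and
#'   `n_resample_attempts`.
#' @export
split_train_test <- function(data, train_fraction = 0.8, seed = NULL,
                             max_attempts = 1000, coverage_fraction = 0.25) {
  n <- nrow(data)
  if (n < 5) stop("need at least 5 rows to split", call. = FALSE)
  if (any(!is.finite(as.matrix(data[, c("logp", "tpsa", "mv", "log_kp")])))) {
    stop("descriptors and log_kp must be finite", call. = FALSE)
  }
  n_train <- round_half_up(train_fraction * n)
  descriptors <- c("logp", "tpsa", "mv")
  spread <- function(x) diff(range(x))
  full_spread <- vapply(descriptors, function(d) spread(data[[d]]), 1.0)

  result <- with_seed(seed, {
    attempts <- 0L
    failing <- character()
    repeat {
      attempts <- attempts + 1L
      test_idx <- sort(sample.int(n, n - n_train))
      test_spread <- vapply(descriptors,
                            function(d) spread(data[[d]][test_idx]), 1.0)
      ok <- full_spread == 0 | test_spread >= coverage_fraction * full_spread
      if (all(ok)) break
      failing <- descriptors[!ok]
      if (attempts >= max_attempts) {
        stop(sprintf(
          "test-set coverage not achieved in %d attempt(s); failing descriptor(s): %s",
          max_attempts, paste(failing, collapse = ", ")), call. = FALSE)
      }
    }
    list(test_idx = test_idx, attempts = attempts)
  })
  test <- data[result$test_idx, , drop = FALSE]
  train <- data[-result$test_idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  model <- fit_qspr(train)
  structure(list(
    train = train, test = test, model = model,
    train_metrics = evaluate_qspr(model, train),
    test_metrics = evaluate_qspr(model, test),
    seed = seed, n_resample_attempts = result$attempts
  ), class = "qspr_split")
}

#' @export
print.qspr_split <- function(x, digits = 4, ...) {
  fmt <- function(m) {
    sprintf("n = %d, R^2 = %s, RMSE = %s", m$n,
            format(round(m$r_squared_sse, digits)),
            format(round(m$rmse, digits)))
  }
  cat("Train/test validation\n")
  cat("  ", qspr_equation(x$model), "\n", sep = "")
  cat("  training set: ", fmt(x$train_metrics), "\n", sep = "")
  cat("  test set:     ", fmt(x$test_metrics), "\n", sep = "")
  cat(sprintf("  seed = %s, resample attempts = %d\n",
              x$seed %||% "NULL", x$n_resample_attempts))
  invisible(x)
}

#' Plot a validated split, training and test sets distinguished
#'
#' Predicted versus experimental log Kp for both partitions of a
#' [split_train_test()] result.
#'
#' @param x A `"qspr_split"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the combined predicted/observed data frame.
#' @export
plot.qspr_split <- function(x, ...) {
  both <- rbind(
    data.frame(set = "train", predicted = predict(x$model, x$train),
               observed = x$train$log_kp),
    data.frame(set = "test", predicted = predict(x$model, x$test),
               observed = x$test$log_kp))
  graphics::plot(both$predicted, both$observed,
                 pch = ifelse(both$set == "train", 1, 17),
                 xlab = "predicted logKp (cm/s)",
                 ylab = "experimental logKp (cm/s)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("training", "test"),
                   pch = c(1, 17), bty = "n")
  invisible(both)
}

#' Preference criteria for reducing repeated measurements to one
#'
#' When a compound has several Kp measurements, the pooled workflow keeps
#' the record best matching a preferred experimental profile. Each of the
#' five criteria contributes one point when the record's field matches
#' (or falls inside the range); a missing field never matches.
#'
#' Defaults follow the profile used by the source study: abdomen site,
#' the epidermis and dermis layers, concentrated donor solution, donor
#' temperature 30-35 degrees C and donor pH 7-7.5. `skin_layer` accepts a
#' vector of acceptable levels.
#'
#' @param skin_source Preferred source level.
#' @param skin_layer Acceptable layer level(s).
#' @param donor_concentration Preferred concentration class.
#' @param temperature_range Closed interval, degrees Celsius.
#' @param ph_range Closed interval.
#' @return A list of class `"preference_criteria"`.
#' @export
preference_criteria <- function(skin_source = "abdomen",
                                skin_layer = c("epidermis", "dermis"),
                                donor_concentration = "concentrated",
                                temperature_range = c(30, 35),
                                ph_range = c(7, 7.5)) {
  stopifnot(length(temperature_range) == 2,
            temperature_range[1] <= temperature_range[2],
            length(ph_range) == 2, ph_range[1] <= ph_range[2])
  structure(list(skin_source = skin_source, skin_layer = skin_layer,
                 donor_concentration = donor_concentration,
                 temperature_range = as.numeric(temperature_range),
                 ph_range = as.numeric(ph_range)),
            class = "preference_criteria")
}

score_preference <- function(records, criteria) {
  in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  (!is.na(records$skin_source) &
     records$skin_source %in% criteria$skin_source) +
    (!is.na(records$skin_layer) &
       records$skin_layer %in% criteria$skin_layer) +
    (!is.na(records$donor_concentration) &
       records$donor_concentration %in% criteria$donor_concentration) +
    in_range(records$donor_temperature_c, criteria$temperature_range) +
    in_range(records$donor_ph, criteria$ph_range)
}

#' Reduce a dataset to one Kp value per compound
#'
#' Scores every record of each compound against [preference_criteria()]
#' and keeps the highest-scoring record (ties break toward the first
#' record in input order), attaching descriptors. Compounds without a
#' descriptor entry are dropped with a warning.
#'
#' @param dataset A [huskin_dataset()].
#' @param criteria A [preference_criteria()] object.
#' @return A data frame with one row per compound: the kept record's
#'   fields, its `preference_score`, and `logp`, `tpsa`, `mv`. Compounds
#'   appear in order of first appearance in the records.
#' @export
select_one_per_compound <- function(dataset,
                                    criteria = preference_criteria()) {
  stopifnot(inherits(dataset, "huskin_dataset"))
  records <- dataset$records
  if (nrow(records) == 0) stop("dataset has no records", call. = FALSE)
  descriptors <- dataset$descriptors
  has_desc <- records$compound_id %in% descriptors$compound_id
  if (any(!has_desc)) {
    warning(sprintf("%d compound(s) dropped: no descriptor entry",
                    length(unique(records$compound_id[!has_desc]))),
            call. = FALSE)
    records <- records[has_desc, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no records with descriptors", call. = FALSE)
  records$preference_score <- score_preference(records, criteria)
  keep_idx <- vapply(split(seq_len(nrow(records)), factor(
    records$compound_id, levels = unique(records$compound_id))),
    function(ix) ix[which.max(records$preference_score[ix])], 1L)
  out <- records[keep_idx, , drop = FALSE]
  didx <- match(out$compound_id, descriptors$compound_id)
  out$logp <- descriptors$logp[didx]
  out$tpsa <- descriptors$tpsa[didx]
  out$mv <- descriptors$mv[didx]
  rownames(out) <- NULL
  out
}

#' Remove gross outliers and refit
#'
#' Fits a model on all rows, removes every row whose absolute residual
#' (observed minus predicted log Kp) exceeds `threshold` log10 units, and
#' refits on the kept rows. The filter is a single pass: rows that become
#' outlying under the refitted model are not re-removed.
#'
#' @param data Labelled rows (`logp`, `tpsa`, `mv`, `log_kp`); at least 5.
#' @param threshold Absolute-residual cutoff in log10 units (default
#'   1.5).
#' @return An object of class `"qspr_outlier_filter"`: list with `kept`,
#'   `removed` (row data frames), `threshold`, `model_before` and
#'   `model_after`.
#' @export
outlier_filter_refit <- function(data, threshold = 1.5) {
  if (nrow(data) < 5) stop("need at least 5 rows", call. = FALSE)
  stopifnot(is.numeric(threshold), threshold > 0)
  model_before <- fit_qspr(data)
  res <- data$log_kp - predict(model_before, data)
  remove <- abs(res) > threshold
  if (all(remove)) stop("all rows removed as outliers", call. = FALSE)
  kept <- data[!remove, , drop = FALSE]
  removed <- data[remove, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  model_after <- if (any(remove)) fit_qspr(kept) else model_before
  structure(list(kept = kept, removed = removed, threshold = threshold,
                 model_before = model_before, model_after = model_after),
            class = "qspr_outlier_filter")
}

#' @export
print.qspr_outlier_filter <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Outlier filter (|residual| > %s): %d removed, %d kept\n",
    format(x$threshold), nrow(x$removed), nrow(x$kept)))
  cat(sprintf("  before: n = %d, R^2 = %s\n", x$model_before$n,
              format(round(x$model_before$r_squared, digits))))
  cat(sprintf("  after:  n = %d, R^2 = %s\n", x$model_after$n,
              format(round(x$model_after$r_squared, digits))))
  invisible(x)
}

#' Run the pooled outlier-filtered modelling workflow
#'
#' Composes the pooled-model pipeline: reduce the dataset to one Kp value
#' per compound ([select_one_per_compound()]), fit on all compounds,
#' remove extreme outliers and refit ([outlier_filter_refit()]), then
#' validate with a train/test split ([split_train_test()]) on the kept
#' rows. Intermediate counts are logged via [message()] and returned.
#'
#' Two candidate final models are reported: the fit on all kept rows
#' (`model_full`) and the training-set fit of the split (`model_train`).
#'
#' @param dataset A [huskin_dataset()].
#' @param criteria [preference_criteria()] for the one-per-compound step.
#' @param threshold Outlier cutoff in log10 units (default 1.5).
#' @param seed Seed for the split.
#' @param ... Passed to [split_train_test()].
#' @return An object of class `"qspr_pooled"`: list with `n_compounds`,
#'   `rows` (one per compound), `filter` (`"qspr_outlier_filter"`),
#'   `split` (`"qspr_split"`), `model_full`, `model_train` and `seed`.
#' @export
run_pooled_workflow <- function(dataset, criteria = preference_criteria(),
                                threshold = 1.5, seed = NULL, ...) {
  rows <- select_one_per_compound(dataset, criteria)
  message(sprintf("pooled workflow: %d compound(s) after one-per-compound selection",
                  nrow(rows)))
  filt <- outlier_filter_refit(rows, threshold)
  message(sprintf("pooled workflow: %d outlier(s) removed at |residual| > %s; %d kept",
                  nrow(filt$removed), format(threshold), nrow(filt$kept)))
  split <- split_train_test(filt$kept, seed = seed, ...)
  message(sprintf("pooled workflow: train n = %d, test n = %d",
                  nrow(split$train), nrow(split$test)))
  structure(list(n_compounds = nrow(rows), rows = rows, filter = filt,
                 split = split, model_full = filt$model_after,
                 model_train = split$model, seed = seed),
            class = "qspr_pooled")
}

#' @export
print.qspr_pooled <- function(x, ...) {
  cat("Pooled outlier-filtered QSPR workflow\n")
  cat(sprintf("  compounds in: %d; outliers removed: %d; kept: %d\n",
              x$n_compounds, nrow(x$filter$removed), nrow(x$filter$kept)))
  print(x$split)
  invisible(x)
}
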