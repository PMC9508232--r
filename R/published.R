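# The published equations, shipped as ready-to-use predictors: the 27
# per-scenario equations (packaged as a transcribed CSV fixture), the
# best-scenario model, the pooled outlier-filtered model, and a
# Potts-Guy-style logP/MW baseline.
#
# Unit conventions: the scenario, best and pooled models are in
# log10(cm/s) (the database's convention). The Potts-Guy baseline is kept
# exactly as printed; its original publication used cm/h and no unit
# reconciliation is attempted here, so it carries the tag "as published"
# and nothing in the package silently converts it.

# md5 of inst/extdata/table1.csv; any edit to the transcription must be
# deliberate and update this constant
TABLE1_MD5 <- "6273d579329a2684a84f3f499bd6e9ad"

eq2_coefficients <- function() {
  c(intercept = -6.136, logp = 0.818, tpsa = -0.005, mv = -0.007)
}

eq3_coefficients <- function() {
  c(intercept = -5.820, logp = 0.319, tpsa = -0.001, mv = -0.005)
}

#' Registry of published skin-permeability models
#'
#' Loads the packaged transcription of the 27 per-scenario QSPR equations
#' and bundles them with the published best-scenario model (`eq2`,
#' trained on 36 compounds: training n = 29, R^2 = 0.8428, RMSE = 0.30;
#' test n = 7, R^2 = 0.8949, RMSE = 0.35), the pooled outlier-filtered
#' model (`eq3`, 214 compounds: training n = 171, R^2 = 0.5042,
#' RMSE = 0.73; test n = 43, R^2 = 0.5057, RMSE = 0.84) and the
#' Potts-Guy baseline `logKp = 0.71 logP - 0.0061 MW - 6.3` (n = 93,
#' r^2 = 0.67).
#'
#' The fixture is validated against a frozen md5 checksum at load time;
#' any edit fails loudly.
#'
#' @param path Path to the transcription CSV; defaults to the packaged
#'   fixture.
#' @return An object of class `"qspr_registry"`: list with `table` (a
#'   `"qspr_table"` of the 27 published scenario models, in
#'   [enumerate_scenarios()] order), `models` (the same models keyed by
#'   scenario), `eq2`, `eq3` (`"qspr"` objects) and `potts_guy`
#'   (coefficient list).
#' @examples
#' reg <- published_models()
#' length(reg$models)
#' @export
published_models <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(package_env$registry)) return(package_env$registry)
  if (default) {
    path <- system.file("extdata", "table1.csv", package = "skinqspr",
                        mustWork = TRUE)
  }
  checksum <- unname(tools::md5sum(path))
  if (!identical(checksum, TABLE1_MD5)) {
    stop("scenario-model transcription failed checksum validation: ", path,
         call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  keys <- scenario_key(raw$skin_source, raw$skin_layer,
                       raw$donor_concentration, raw$temperature_bin)
  if (anyDuplicated(keys)) stop("duplicate scenario in transcription",
                                call. = FALSE)
  num <- function(x) ifelse(x == "", NA_real_, as.numeric(x))
  models <- vector("list", length(keys))
  names(models) <- keys
  for (i in seq_along(keys)) {
    models[[i]] <- qspr_published(
      intercept = num(raw$intercept[i]), logp = num(raw$coef_logp[i]),
      tpsa = num(raw$coef_tpsa[i]), mv = num(raw$coef_mv[i]),
      n = as.integer(raw$n_compounds[i]),
      r_squared = num(raw$r_squared[i]),
      scenario = keys[i], label = "scenario model")
  }
  summary <- data.frame(
    scenario = keys, parse_scenario(keys),
    n_records = as.integer(raw$n_compounds),
    n_compounds = as.integer(raw$n_compounds),
    r_squared = num(raw$r_squared), rmse = NA_real_,
    intercept = num(raw$intercept), coef_logp = num(raw$coef_logp),
    coef_tpsa = num(raw$coef_tpsa), coef_mv = num(raw$coef_mv),
    underdetermined = as.integer(raw$n_compounds) <= 4,
    stringsAsFactors = FALSE)
  table <- structure(list(models = models, summary = summary),
                     class = "qspr_table")
  registry <- structure(list(
    table = table,
    models = models,
    eq2 = do.call(qspr_published, c(as.list(eq2_coefficients()), list(
      n = 36L, r_squared = 0.8545, rmse = 0.30, label = "best scenario model"))),
    eq3 = do.call(qspr_published, c(as.list(eq3_coefficients()), list(
      n = 214L, r_squared = 0.5044, rmse = 0.73,
      label = "pooled outlier-filtered model"))),
    potts_guy = list(intercept = -6.3, coef_logp = 0.71, coef_mw = -0.0061,
                     n = 93L, r_squared = 0.67, unit = "as published"),
    raw = raw
  ), class = "qspr_registry")
  if (default) package_env$registry <- registry
  registry
}

#' @export
print.qspr_registry <- function(x, ...) {
  cat(sprintf("Published QSPR registry: %d scenario model(s) + eq2, eq3, Potts-Guy baseline\n",
              length(x$models)))
  invisible(x)
}

#' Re-serialize the packaged transcription
#'
#' Rebuilds the transcription CSV lines from the parsed registry, for
#' byte-for-byte comparison with the packaged fixture.
#'
#' @param registry A [published_models()] registry.
#' @return Character vector of CSV lines (header first).
#' @export
serialize_table1 <- function(registry = published_models()) {
  raw <- registry$raw
  c(paste(names(raw), collapse = ","),
    apply(raw, 1, paste, collapse = ","))
}

#' Look up the published model for raw experimental conditions
#'
#' Normalizes the inputs (concentration wording via
#' [normalize_donor_concentration()], temperature via
#' [bin_temperature()]) and returns the published scenario model, or
#' `NULL` when no model was published for that scenario.
#'
#' @param skin_source,skin_layer Raw level strings.
#' @param donor_concentration Raw wording (e.g. `"neat"`, `"dilute"`).
#' @param temperature Donor temperature, degrees Celsius.
#' @param registry A [published_models()] registry.
#' @return A `"qspr"` object or `NULL`.
#' @examples
#' lookup_published("abdomen", "epidermis", "diluted", 22)
#' @export
lookup_published <- function(skin_source, skin_layer, donor_concentration,
                             temperature, registry = published_models()) {
  source <- normalize_skin_source(skin_source)
  layer <- normalize_skin_layer(skin_layer)
  conc <- normalize_donor_concentration(donor_concentration)
  bin <- bin_temperature(temperature)
  if (is.na(source) || is.na(layer) || is.na(conc) || is.na(bin)) {
    return(NULL)
  }
  key <- scenario_key(source, layer, conc, bin)
  registry$models[[key]]
}

#' Potts-Guy-style baseline prediction
#'
#' The classic two-descriptor permeability baseline,
#' `logKp = 0.71 logP - 0.0061 MW - 6.3`, kept exactly as printed (its
#' original publication expressed Kp in cm/h; no unit conversion is
#' applied).
#'
#' @param log_p Octanol-water partition coefficient(s).
#' @param mw Molecular weight(s), g/mol; must be positive.
#' @return Numeric vector of baseline logKp predictions.
#' @examples
#' predict_potts_guy(2, 100)
#' @export
predict_potts_guy <- function(log_p, mw) {
  log_p <- as.numeric(log_p)
  mw <- as.numeric(mw)
  if (any(is.na(mw)) || any(mw <= 0)) {
    stop("mw must be positive", call. = FALSE)
  }
  0.71 * log_p - 0.0061 * mw - 6.3
}

#' Predict log Kp with a published model
#'
#' @param model_id `"eq2"` (best scenario model), `"eq3"` (pooled
#'   outlier-filtered model) or a scenario key present in the registry.
#' @param newdata Data frame with `logp`, `tpsa`, `mv`.
#' @param registry A [published_models()] registry.
#' @return Numeric vector of predicted log10 Kp (cm/s).
#' @examples
#' predict_published("eq2", data.frame(logp = 0, tpsa = 0, mv = 0))
#' @export
predict_published <- function(model_id, newdata,
                              registry = published_models()) {
  model <- if (identical(model_id, "eq2")) {
    registry$eq2
  } else if (identical(model_id, "eq3")) {
    registry$eq3
  } else {
    registry$models[[model_id]]
  }
  if (is.null(model)) {
    stop("unknown model id '", model_id, "'; available: eq2, eq3, ",
         paste(names(registry$models), collapse = ", "), call. = FALSE)
  }
  predict(model, newdata)
}
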