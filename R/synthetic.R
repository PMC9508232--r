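# Synthetic HuskinDB-like data with known ground truth. The generator
# emulates the statistical structure the analysis assumes — log Kp linear
# in logP/TPSA/MV within each experimental scenario, plus Gaussian noise —
# with planted metadata missingness and gross outliers so exclusion and
# filtering logic can be checked against exact bookkeeping.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the scale and conditions of the curated permeability
#' database the pipeline targets: 253 compounds with one to three Kp
#' measurements each (roughly 550 records), descriptors spanning
#' realistic medicinal-chemistry ranges, residual noise of 0.3 log10
#' units, a 20% metadata-missingness rate, and 15% gross outliers offset
#' by 3 log10 units. Scenario ground truth defaults to the 27 published
#' scenario equations.
#'
#' @param n_compounds Number of compounds.
#' @param records_per_compound Length-2 integer vector `c(min, max)`;
#'   each compound receives a uniform number of records in that range.
#' @param descriptor_ranges Named list of length-2 numeric ranges for
#'   `logp` (dimensionless), `tpsa` (square Angstrom) and `mv` (cubic
#'   Angstrom).
#' @param scenario_coefficients Named list mapping scenario keys to
#'   numeric coefficient quadruples `(intercept, logp, tpsa, mv)`;
#'   `NULL` means the 27 published scenario equations.
#' @param noise_sd Gaussian noise standard deviation, log10 units.
#' @param missingness_rate Fraction of records with one stratification
#'   field blanked.
#' @param outlier_fraction Fraction of records offset by
#'   `outlier_offset`.
#' @param outlier_offset Gross-error magnitude, log10 units (sign
#'   random).
#' @param descriptor_correlation Common pairwise correlation of the three
#'   descriptors, induced through a Gaussian copula (0 = independent).
#' @param seed RNG seed; the generator is fully reproducible from it.
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_compounds = 253,
                             records_per_compound = c(1, 3),
                             descriptor_ranges = list(
                               logp = c(-4, 5), tpsa = c(0, 160),
                               mv = c(50, 500)),
                             scenario_coefficients = NULL,
                             noise_sd = 0.3,
                             missingness_rate = 0.2,
                             outlier_fraction = 0.15,
                             outlier_offset = 3,
                             descriptor_correlation = 0,
                             seed = 1) {
  stopifnot(n_compounds >= 1,
            length(records_per_compound) == 2,
            records_per_compound[1] >= 1,
            records_per_compound[1] <= records_per_compound[2],
            noise_sd >= 0,
            missingness_rate >= 0, missingness_rate <= 1,
            outlier_fraction >= 0, outlier_fraction <= 1,
            outlier_offset >= 0,
            descriptor_correlation >= 0, descriptor_correlation < 1)
  for (d in c("logp", "tpsa", "mv")) {
    r <- descriptor_ranges[[d]]
    if (is.null(r) || length(r) != 2 || r[1] >= r[2]) {
      stop("descriptor_ranges$", d, " must be a non-empty interval",
           call. = FALSE)
    }
  }
  if (is.null(scenario_coefficients)) {
    reg <- published_models()
    scenario_coefficients <- lapply(reg$models, function(m) {
      unname(m$coefficients)
    })
  }
  stopifnot(length(scenario_coefficients) >= 1,
            !is.null(names(scenario_coefficients)),
            all(vapply(scenario_coefficients, length, 1L) == 4))
  parse_scenario(names(scenario_coefficients)) # validates the keys
  structure(list(
    n_compounds = as.integer(n_compounds),
    records_per_compound = as.integer(records_per_compound),
    descriptor_ranges = descriptor_ranges,
    scenario_coefficients = scenario_coefficients,
    noise_sd = noise_sd,
    missingness_rate = missingness_rate,
    outlier_fraction = outlier_fraction,
    outlier_offset = outlier_offset,
    descriptor_correlation = descriptor_correlation,
    seed = seed
  ), class = "generator_config")
}

draw_descriptors <- function(config) {
  n <- config$n_compounds
  rho <- config$descriptor_correlation
  u <- if (rho > 0) {
    # Gaussian copula with common pairwise correlation
    z0 <- stats::rnorm(n)
    z <- vapply(1:3, function(i) {
      sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n)
    }, numeric(n))
    stats::pnorm(matrix(z, nrow = n))
  } else {
    matrix(stats::runif(3 * n), nrow = n)
  }
  scale_to <- function(u, r) r[1] + u * (r[2] - r[1])
  data.frame(
    compound_id = sprintf("c%04d", seq_len(n)),
    logp = scale_to(u[, 1], config$descriptor_ranges$logp),
    tpsa = scale_to(u[, 2], config$descriptor_ranges$tpsa),
    mv = scale_to(u[, 3], config$descriptor_ranges$mv),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic permeability dataset with ground truth
#'
#' Draws descriptors uniformly within the configured ranges, assigns each
#' record a scenario uniformly at random among the configured scenarios,
#' computes `log_kp` from the scenario's true coefficients plus Gaussian
#' noise, then plants gross outliers (an extra offset of random sign) and
#' metadata missingness (one of the four stratification fields blanked
#' per affected record). Fully reproducible from `config$seed`; the
#' caller's RNG state is untouched.
#'
#' @param config A [generator_config()].
#' @return A list of class `"huskin_sim"` with `dataset` (a
#'   [huskin_dataset()]) and `truth`: the true `coefficients` per
#'   scenario, `record_scenario` (scenario key per record, in record
#'   order), `outlier_rows`, `missing_rows` (integer row indices into the
#'   records) and `missing_field`.
#' @examples
#' sim <- generate_dataset(generator_config(n_compounds = 20, seed = 42))
#' sim$dataset
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    descriptors <- draw_descriptors(config)
    lo <- config$records_per_compound[1]
    hi <- config$records_per_compound[2]
    k <- if (lo == hi) rep(lo, config$n_compounds) else {
      lo + sample.int(hi - lo + 1, config$n_compounds, replace = TRUE) - 1L
    }
    n_records <- sum(k)
    compound_id <- rep(descriptors$compound_id, times = k)

    keys <- names(config$scenario_coefficients)
    scen_idx <- sample.int(length(keys), n_records, replace = TRUE)
    scen <- keys[scen_idx]
    parsed <- parse_scenario(scen)
    temp <- vapply(parsed$temperature_bin, function(b) {
      bounds <- bin_bounds(b)
      stats::runif(1, bounds[1], bounds[2])
    }, 1.0, USE.NAMES = FALSE)

    didx <- match(compound_id, descriptors$compound_id)
    beta <- matrix(unlist(config$scenario_coefficients), nrow = 4)
    log_kp <- beta[1, scen_idx] +
      beta[2, scen_idx] * descriptors$logp[didx] +
      beta[3, scen_idx] * descriptors$tpsa[didx] +
      beta[4, scen_idx] * descriptors$mv[didx] +
      stats::rnorm(n_records, sd = config$noise_sd)

    n_outliers <- round(config$outlier_fraction * n_records)
    outlier_rows <- if (n_outliers > 0) {
      sort(sample.int(n_records, n_outliers))
    } else integer()
    if (n_outliers > 0) {
      sign <- sample(c(-1, 1), n_outliers, replace = TRUE)
      log_kp[outlier_rows] <- log_kp[outlier_rows] +
        sign * config$outlier_offset
    }

    records <- data.frame(
      compound_id = compound_id,
      compound_name = NA_character_,
      log_kp = log_kp,
      skin_source = parsed$skin_source,
      skin_layer = parsed$skin_layer,
      donor_concentration = parsed$donor_concentration,
      donor_temperature_c = temp,
      donor_ph = stats::runif(n_records, 5, 8.5),
      stringsAsFactors = FALSE
    )

    n_missing <- round(config$missingness_rate * n_records)
    missing_rows <- if (n_missing > 0) {
      sort(sample.int(n_records, n_missing))
    } else integer()
    fields <- c("skin_source", "skin_layer", "donor_concentration",
                "donor_temperature_c")
    missing_field <- if (n_missing > 0) {
      sample(fields, n_missing, replace = TRUE)
    } else character()
    for (i in seq_along(missing_rows)) {
      records[missing_rows[i], missing_field[i]] <-
        if (missing_field[i] == "donor_temperature_c") NA_real_ else
          NA_character_
    }

    structure(list(
      dataset = huskin_dataset(records, descriptors),
      truth = list(
        coefficients = config$scenario_coefficients,
        record_scenario = scen,
        outlier_rows = outlier_rows,
        missing_rows = missing_rows,
        missing_field = missing_field
      )
    ), class = "huskin_sim")
  })
}

#' @export
print.huskin_sim <- function(x, ...) {
  cat("Synthetic permeability dataset with ground truth\n")
  print(x$dataset)
  cat(sprintf("  scenarios: %d; planted outliers: %d; planted missing: %d\n",
              length(x$truth$coefficients), length(x$truth$outlier_rows),
              length(x$truth$missing_rows)))
  invisible(x)
}

#' Generate a dataset shaped like the published scenario table
#'
#' Emits a complete synthetic dataset whose non-empty scenarios and group
#' sizes match the published per-scenario compound counts (27 scenarios,
#' group sizes 2 to 45, 342 rows in total), with `log_kp` generated from
#' each scenario's published coefficients plus noise. Useful for
#' end-to-end rehearsals of the per-scenario workflow at the realistic
#' scale.
#'
#' @param noise_sd Gaussian noise, log10 units (default 0.3).
#' @param seed RNG seed.
#' @param descriptor_ranges As in [generator_config()].
#' @return A [huskin_dataset()]; each compound appears in exactly one
#'   scenario with one record.
#' @export
make_table1_like <- function(noise_sd = 0.3, seed = 1,
                             descriptor_ranges = list(
                               logp = c(-4, 5), tpsa = c(0, 160),
                               mv = c(50, 500))) {
  reg <- published_models()
  s <- reg$table$summary
  with_seed(seed, {
    total <- sum(s$n_records)
    scale_to <- function(u, r) r[1] + u * (r[2] - r[1])
    descriptors <- data.frame(
      compound_id = sprintf("t%04d", seq_len(total)),
      logp = scale_to(stats::runif(total), descriptor_ranges$logp),
      tpsa = scale_to(stats::runif(total), descriptor_ranges$tpsa),
      mv = scale_to(stats::runif(total), descriptor_ranges$mv),
      stringsAsFactors = FALSE
    )
    idx <- rep(seq_len(nrow(s)), times = s$n_records)
    temp <- vapply(s$temperature_bin[idx], function(b) {
      bounds <- bin_bounds(b)
      stats::runif(1, bounds[1], bounds[2])
    }, 1.0, USE.NAMES = FALSE)
    log_kp <- s$intercept[idx] +
      s$coef_logp[idx] * descriptors$logp +
      s$coef_tpsa[idx] * descriptors$tpsa +
      s$coef_mv[idx] * descriptors$mv +
      stats::rnorm(total, sd = noise_sd)
    records <- data.frame(
      compound_id = descriptors$compound_id,
      compound_name = NA_character_,
      log_kp = log_kp,
      skin_source = s$skin_source[idx],
      skin_layer = s$skin_layer[idx],
      donor_concentration = s$donor_concentration[idx],
      donor_temperature_c = temp,
      donor_ph = stats::runif(total, 5, 8.5),
      stringsAsFactors = FALSE
    )
    huskin_dataset(records, descriptors)
  })
}

#' Write a simulated dataset to disk
#'
#' Writes the permeability table, the descriptor table and a ground-truth
#' CSV (record index, scenario, planted-outlier and planted-missing
#' flags) under a common file prefix.
#'
#' @param sim A `"huskin_sim"` from [generate_dataset()].
#' @param prefix Path prefix for the three output files.
#' @return Character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "huskin_sim"))
  paths <- paste0(prefix, c("permeability.csv", "descriptors.csv",
                            "truth.csv"))
  write_permeability_table(sim$dataset$records, paths[1])
  write_descriptor_table(sim$dataset$descriptors, paths[2])
  n <- nrow(sim$dataset$records)
  truth <- data.frame(
    row = seq_len(n),
    compound_id = sim$dataset$records$compound_id,
    scenario = sim$truth$record_scenario,
    planted_outlier = seq_len(n) %in% sim$truth$outlier_rows,
    planted_missing = seq_len(n) %in% sim$truth$missing_rows,
    stringsAsFactors = FALSE
  )
  utils::write.table(truth, paths[3], sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
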