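# Fixture builders shared across the suite. All data is generated in
# code; nothing is read from disk except files the tests write first.

# a well-conditioned descriptor block with no exact collinearity
toy_descriptors <- function(n = 6, seed = 101) {
  with_toy_seed(seed, data.frame(
    compound_id = sprintf("c%02d", seq_len(n)),
    logp = round(runif(n, -2, 4), 2),
    tpsa = round(runif(n, 5, 120), 1),
    mv = round(runif(n, 80, 400), 1),
    stringsAsFactors = FALSE
  ))
}

# regression rows generated exactly from known coefficients
noiseless_rows <- function(beta = c(-6, 0.5, -0.01, -0.002), n = 6,
                           seed = 101) {
  d <- toy_descriptors(n, seed)
  d$log_kp <- beta[1] + beta[2] * d$logp + beta[3] * d$tpsa + beta[4] * d$mv
  d
}

# complete permeability records placed in a single scenario
toy_records <- function(n, compound_id = sprintf("c%02d", seq_len(n)),
                        log_kp = rep(-5, n),
                        skin_source = "abdomen", skin_layer = "epidermis",
                        donor_concentration = "diluted",
                        donor_temperature_c = 22, donor_ph = 7.2) {
  data.frame(compound_id = compound_id,
             compound_name = rep(NA_character_, n),
             log_kp = log_kp, skin_source = rep_len(skin_source, n),
             skin_layer = rep_len(skin_layer, n),
             donor_concentration = rep_len(donor_concentration, n),
             donor_temperature_c = rep_len(donor_temperature_c, n),
             donor_ph = rep_len(donor_ph, n), stringsAsFactors = FALSE)
}

with_toy_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# independent OLS oracle: explicit 4x4 normal equations solved with
# solve(), plus a pseudoinverse route via MASS::ginv — both different
# code paths from the package's QR/SVD implementation
oracle_ols_normal <- function(data) {
  X <- cbind(1, data$logp, data$tpsa, data$mv)
  y <- data$log_kp
  drop(solve(t(X) %*% X, t(X) %*% y))
}

oracle_ols_pinv <- function(data) {
  X <- cbind(1, data$logp, data$tpsa, data$mv)
  drop(MASS::ginv(X) %*% data$log_kp)
}
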