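# The QSPR core: ordinary least squares of log10 Kp on three molecular
# descriptors, solved in closed form.
#
# The model is  logKp = b0 + b1*logP + b2*TPSA + b3*MV  with logKp in
# log10(cm/s). The full-rank solution comes from a QR decomposition of
# the design (the numerically stable route to the normal-equation
# minimizer); rank-deficient designs get the minimum-norm least-squares
# solution via the SVD pseudoinverse, deterministically, with a condition
# warning. RMSE uses divisor n (population style), which is the
# convention the reported models are consistent with; the choice is
# isolated here.

qspr_design <- function(data) {
  req <- c("logp", "tpsa", "mv", "log_kp")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("data must contain column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- cbind(intercept = 1, logp = as.numeric(data$logp),
             tpsa = as.numeric(data$tpsa), mv = as.numeric(data$mv))
  y <- as.numeric(data$log_kp)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("descriptors and log_kp must be finite", call. = FALSE)
  }
  list(X = X, y = y)
}

#' Fit a three-descriptor QSPR by ordinary least squares
#'
#' Fits `log_kp ~ logp + tpsa + mv` by minimizing the sum of squared
#' residuals in closed form. For a full-rank design the solution is the
#' unique OLS estimate (computed via QR); an exactly collinear design
#' yields the deterministic minimum-norm solution with
#' `condition_warning = TRUE`. Fits with `n <= 4` rows (at most as many
#' rows as parameters) are flagged `underdetermined`: coefficients are
#' still produced, mirroring how the published per-scenario tables print
#' equations even for two or three compounds, but they should not be used
#' for prediction.
#'
#' Diagnostics: `r_squared = 1 - SS_res/SS_tot` (about the response mean;
#' reported as `NA` when the response has no variance or when `n = 2`,
#' where the rank-deficient fit is always exact and the statistic carries
#' no information), and `rmse = sqrt(SS_res/n)`.
#'
#' @param data Data frame with numeric columns `logp`, `tpsa`, `mv` and
#'   `log_kp` (log10 cm/s); at least two rows.
#' @param scenario Optional scenario key ([scenario_key()]) recorded on
#'   the model.
#' @param label Optional free-text label.
#' @return An object of class `"qspr"`: a list with `coefficients`
#'   (named `intercept`, `logp`, `tpsa`, `mv`), `n`, `r_squared`, `rmse`,
#'   `underdetermined`, `condition_warning`, `provenance` (`"fitted"`),
#'   `residuals`, `fitted.values`, `ss_res`, `ss_tot`, the training
#'   `data`, and the unit tag.
#' @examples
#' d <- data.frame(logp = c(0, 1, 2, 3, 4, 5), tpsa = c(10, 40, 20, 80, 60, 30),
#'                 mv = c(100, 150, 200, 250, 300, 120))
#' d$log_kp <- -6 + 0.5 * d$logp - 0.01 * d$tpsa - 0.002 * d$mv
#' fit <- fit_qspr(d)
#' coef(fit)
#' @seealso [predict.qspr()], [evaluate_qspr()]
#' @export
fit_qspr <- function(data, scenario = NULL, label = NULL) {
  des <- qspr_design(data)
  X <- des$X
  y <- des$y
  n <- nrow(X)
  if (n < 2) stop("need at least 2 rows to fit", call. = FALSE)

  qx <- qr(X)
  condition_warning <- FALSE
  if (qx$rank == ncol(X)) {
    beta <- qr.coef(qx, y)
    # the normal-equation matrix squares the conditioning of X
    if (kappa(X, exact = FALSE)^2 > 1e12) condition_warning <- TRUE
  } else {
    sv <- svd(X)
    tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    beta <- drop(sv$v %*% (dinv * crossprod(sv$u, y)))
    names(beta) <- colnames(X)
    condition_warning <- TRUE
  }
  fitted <- drop(X %*% beta)
  residuals <- y - fitted
  ss_res <- sum(residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r_squared <- if (n == 2) {
    NA_real_
  } else if (ss_tot > 0) {
    1 - ss_res / ss_tot
  } else if (ss_res < 1e-20) 1 else NA_real_

  structure(list(
    coefficients = beta,
    n = n,
    r_squared = r_squared,
    rmse = sqrt(ss_res / n),
    underdetermined = n <= ncol(X),
    condition_warning = condition_warning,
    provenance = "fitted",
    scenario = scenario,
    label = label %||% "",
    residuals = residuals,
    fitted.values = fitted,
    ss_res = ss_res,
    ss_tot = ss_tot,
    data = data[, c("logp", "tpsa", "mv", "log_kp")],
    unit = "log10(cm/s)"
  ), class = "qspr")
}

#' Construct a QSPR model from published coefficients
#'
#' Wraps printed equation coefficients as a `"qspr"` object with
#' `provenance = "published"`, so published and freshly fitted models
#' share one prediction interface.
#'
#' @param intercept,logp,tpsa,mv Equation coefficients (log10 cm/s scale
#'   unless `unit` says otherwise).
#' @param n,r_squared,rmse Printed diagnostics, if any.
#' @param scenario,label,unit Provenance metadata.
#' @return A `"qspr"` object.
#' @export
qspr_published <- function(intercept, logp, tpsa, mv, n = NA_integer_,
                           r_squared = NA_real_, rmse = NA_real_,
                           scenario = NULL, label = "",
                           unit = "log10(cm/s)") {
  beta <- c(intercept = as.numeric(intercept), logp = as.numeric(logp),
            tpsa = as.numeric(tpsa), mv = as.numeric(mv))
  if (any(!is.finite(beta))) stop("coefficients must be finite", call. = FALSE)
  structure(list(
    coefficients = beta,
    n = as.integer(n),
    r_squared = as.numeric(r_squared),
    rmse = as.numeric(rmse),
    underdetermined = !is.na(n) && n <= 4,
    condition_warning = FALSE,
    provenance = "published",
    scenario = scenario,
    label = label,
    residuals = NULL,
    fitted.values = NULL,
    ss_res = NA_real_,
    ss_tot = NA_real_,
    data = NULL,
    unit = unit
  ), class = "qspr")
}

#' Predict log Kp from a QSPR model
#'
#' @param object A `"qspr"` model.
#' @param newdata Data frame with columns `logp`, `tpsa`, `mv` (extra
#'   columns ignored). Omitted: returns the fitted values of a fitted
#'   model.
#' @param ... Unused.
#' @return Numeric vector of predicted log10 Kp (cm/s, unless the model's
#'   unit tag says otherwise).
#' @export
predict.qspr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fitted.values)) {
      stop("no training data stored; supply newdata", call. = FALSE)
    }
    return(object$fitted.values)
  }
  missing_cols <- setdiff(c("logp", "tpsa", "mv"), names(newdata))
  if (length(missing_cols)) {
    stop("newdata must contain column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  b <- object$coefficients
  drop(b[["intercept"]] + b[["logp"]] * as.numeric(newdata$logp) +
         b[["tpsa"]] * as.numeric(newdata$tpsa) +
         b[["mv"]] * as.numeric(newdata$mv))
}

#' @export
coef.qspr <- function(object, ...) object$coefficients

#' @export
residuals.qspr <- function(object, ...) {
  if (is.null(object$residuals)) {
    stop("published models carry no residuals", call. = FALSE)
  }
  object$residuals
}

#' @export
fitted.qspr <- function(object, ...) object$fitted.values

#' Format a QSPR model as an equation string
#'
#' @param object A `"qspr"` model.
#' @param digits Digits for coefficients.
#' @return A string such as
#'   `"logKp = -6.052 + 0.777 logP - 0.004 TPSA - 0.008 MV"`.
#' @export
qspr_equation <- function(object, digits = 3) {
  b <- object$coefficients
  term <- function(value, name) {
    sprintf("%s %s %s", if (value < 0) "-" else "+",
            format(abs(round(value, digits))), name)
  }
  sprintf("logKp = %s %s %s %s", format(round(b[["intercept"]], digits)),
          term(b[["logp"]], "logP"), term(b[["tpsa"]], "TPSA"),
          term(b[["mv"]], "MV"))
}

#' @export
print.qspr <- function(x, digits = 4, ...) {
  cat(sprintf("QSPR model (%s%s): %s\n", x$provenance,
              if (!is.null(x$scenario)) paste0(", ", x$scenario) else "",
              qspr_equation(x)))
  cat(sprintf("  n = %s, R^2 = %s, RMSE = %s [%s]\n",
              ifelse(is.na(x$n), "?", x$n),
              ifelse(is.na(x$r_squared), "NA",
                     format(round(x$r_squared, digits))),
              ifelse(is.na(x$rmse), "NA", format(round(x$rmse, digits))),
              x$unit))
  if (isTRUE(x$underdetermined)) {
    cat("  underdetermined: rows <= parameters; do not use for prediction\n")
  }
  if (isTRUE(x$condition_warning)) {
    cat("  condition warning: near-singular or rank-deficient design\n")
  }
  invisible(x)
}

#' @export
summary.qspr <- function(object, ...) {
  out <- list(model = object)
  if (!is.null(object$data) && !object$underdetermined &&
      !object$condition_warning) {
    des <- qspr_design(object$data)
    X <- des$X
    p <- ncol(X)
    sigma2 <- object$ss_res / (object$n - p)
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * diag(xtx_inv))
    tval <- object$coefficients / se
    pval <- 2 * stats::pt(abs(tval), df = object$n - p, lower.tail = FALSE)
    out$coefficients <- cbind(Estimate = object$coefficients,
                              `Std. Error` = se, `t value` = tval,
                              `Pr(>|t|)` = pval)
    out$sigma <- sqrt(sigma2)
    out$df_residual <- object$n - p
  }
  class(out) <- "summary.qspr"
  out
}

#' @export
print.summary.qspr <- function(x, ...) {
  print(x$model)
  if (!is.null(x$coefficients)) {
    cat("\nCoefficients:\n")
    stats::printCoefmat(x$coefficients)
    cat(sprintf("\nResidual standard error: %.4g on %d degrees of freedom\n",
                x$sigma, x$df_residual))
  }
  invisible(x)
}

#' Simulate responses from a QSPR model
#'
#' Draws `log_kp` values at the model's training descriptors (or at
#' `newdata`) as prediction plus Gaussian noise with standard deviation
#' equal to the model's RMSE.
#'
#' @param object A `"qspr"` model with a finite `rmse`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed (the caller's RNG state is restored).
#' @param newdata Optional descriptor data frame.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated responses.
#' @export
simulate.qspr <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                          ...) {
  if (is.na(object$rmse)) {
    stop("model has no RMSE; cannot simulate", call. = FALSE)
  }
  mu <- predict(object, newdata)
  with_seed(seed, {
    out <- as.data.frame(replicate(
      nsim, mu + stats::rnorm(length(mu), sd = object$rmse),
      simplify = FALSE), col.names = paste0("sim_", seq_len(nsim)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Plot observed against predicted log Kp
#'
#' @param x A fitted `"qspr"` model.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, a data frame of predicted and observed values.
#' @export
plot.qspr <- function(x, ...) {
  if (is.null(x$data)) stop("no training data stored", call. = FALSE)
  pred <- x$fitted.values
  obs <- x$data$log_kp
  graphics::plot(pred, obs, xlab = "predicted logKp (cm/s)",
                 ylab = "experimental logKp (cm/s)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(data.frame(predicted = pred, observed = obs))
}

#' Evaluate a QSPR model on labelled rows
#'
#' Computes out-of-sample (or in-sample) diagnostics. Two coefficients of
#' determination are always reported because the two common conventions
#' diverge off the training set: `r_squared_sse = 1 - SSE/SST` about the
#' evaluation rows' own mean, and `r_squared_pearson`, the squared
#' Pearson correlation between predicted and observed. On the training
#' rows of a full-rank OLS fit with intercept the two coincide.
#'
#' @param model A `"qspr"` model.
#' @param data Data frame with `logp`, `tpsa`, `mv`, `log_kp`; non-empty.
#' @return A list with `r_squared_sse`, `r_squared_pearson`, `rmse` and
#'   `n`. With zero variance in the observed values both R^2 variants are
#'   `NA`.
#' @export
evaluate_qspr <- function(model, data) {
  if (nrow(data) == 0) stop("no rows to evaluate", call. = FALSE)
  obs <- as.numeric(data$log_kp)
  pred <- predict(model, data)
  res <- obs - pred
  sse <- sum(res^2)
  sst <- sum((obs - mean(obs))^2)
  r2_sse <- if (sst > 0) 1 - sse / sst else NA_real_
  r2_pearson <- if (sst > 0 && stats::sd(pred) > 0) {
    stats::cor(pred, obs)^2
  } else {
    NA_real_
  }
  list(r_squared_sse = r2_sse, r_squared_pearson = r2_pearson,
       rmse = sqrt(mean(res^2)), n = nrow(data))
}
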