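#' Default g-prior for regression Bayes factors
#'
#' The Zellner-Siow default prior places a Cauchy distribution with
#' scale `r` on standardised regression effects, expressed as a scale
#' mixture of g-priors with an inverse-gamma(1/2, r^2 n / 2) mixing
#' density on the variance multiplier g:
#' \deqn{\pi(g; r) = \sqrt{r^2 n / 2}\,\Gamma(1/2)^{-1}\,
#'   g^{-3/2}\, e^{-r^2 n / (2g)}, \quad g > 0.}
#' The default scale `r = sqrt(2)/4` matches the conventional "medium"
#' default for multiple regression.
#'
#' @param rscale Prior scale `r > 0`.
#' @return An object of class `g_prior`.
#' @export
g_prior <- function(rscale = sqrt(2) / 4) {
  if (!is.numeric(rscale) || length(rscale) != 1L || rscale <= 0)
    stop("rscale must be a single positive number")
  structure(list(rscale = rscale), class = "g_prior")
}

#' Regression data for Bayes-factor computation
#'
#' Bundles a response vector and model regressors into the sufficient
#' statistics of the g-prior Bayes factor: the sample size `n`, model
#' dimension `p`, and the coefficient of determination `R^2` of the OLS
#' fit of `y` on `X` with intercept. Columns of `X` are centered; the
#' Bayes factor depends on `X` only through its column span, so any
#' invertible reparameterisation yields identical results.
#'
#' @param y Response vector.
#' @param X Numeric matrix of model regressors (one column per free
#'   weight); must have full column rank after centering.
#' @param n_eff Effective sample size to use in place of `length(y)`
#'   (e.g. after within-subject centering); defaults to `length(y)`.
#' @return An object of class `regression_data` with fields `n`, `p`,
#'   `r_squared`, plus the centered inputs.
#' @export
regression_data <- function(y, X, n_eff = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("y and X must have matching rows")
  n <- if (is.null(n_eff)) length(y) else as.integer(n_eff)
  p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (qr(Xc)$rank < p)
    stop("X is rank-deficient after centering")
  if (n <= p + 1L)
    stop("need n > p + 1 (got n = ", n, ", p = ", p, ")")
  yc <- y - mean(y)
  tss <- sum(yc^2)
  if (tss == 0) stop("response has zero variance")
  fit <- stats::lm.fit(Xc, yc)
  r2 <- 1 - sum(fit$residuals^2) / tss
  r2 <- min(max(r2, 0), 1)
  structure(list(n = n, p = p, r_squared = r2, y = yc, X = Xc),
            class = "regression_data")
}

# log of the JZS integrand after the substitution g = exp(u), including
# the Jacobian term; vectorised over u.
.log_jzs_integrand <- function(u, n, p, r2, rscale) {
  g <- exp(u)
  ((n - 1 - p) / 2) * log1p(g) -
    ((n - 1) / 2) * log1p(g * (1 - r2)) +
    0.5 * log(rscale^2 * n / 2) - lgamma(0.5) -
    1.5 * u - rscale^2 * n / (2 * g) +
    u
}

#' Log Bayes factor of a linear model against the intercept-only null
#'
#' Evaluates the default g-prior (Zellner-Siow / JZS) Bayes factor
#' \deqn{BF_{10} = \int_0^\infty (1+g)^{(n-1-p)/2}
#'   \left[1 + g(1-R^2)\right]^{-(n-1)/2} \pi(g; r)\, dg}
#' by deterministic adaptive quadrature on the log-g scale, with the
#' integrand rescaled by its maximum for numerical stability. The result
#' depends on the data only through `n`, `p` and `R^2`, and is therefore
#' invariant to rescaling of `y` and to invertible reparameterisation of
#' the regressor columns.
#'
#' @param data A [regression_data()] object (or a list with fields `n`,
#'   `p`, `r_squared`).
#' @param prior A [g_prior()].
#' @param rel_tol Requested relative tolerance of the quadrature.
#' @return An object of class `bf_result` with fields `log_bf` (natural
#'   log), `est_numerical_error` (relative error bound from the
#'   quadrature) and `method`.
#' @examples
#' set.seed(1)
#' X <- design_matrix("pc-pain")
#' y <- drop(X %*% c(1, 2)) + rnorm(6, 0, 0.1)
#' log_bf_vs_null(regression_data(y, X))
#' @export
log_bf_vs_null <- function(data, prior = g_prior(), rel_tol = 1e-10) {
  n <- data$n; p <- data$p; r2 <- data$r_squared
  if (r2 >= 1)
    stop("R^2 = 1: marginal likelihood diverges (saturated fit)")
  r <- prior$rscale
  f <- function(u) .log_jzs_integrand(u, n, p, r2, r)
  opt <- stats::optimize(f, interval = c(-40, 40), maximum = TRUE,
                         tol = 1e-10)
  m <- opt$objective
  q <- stats::integrate(function(u) exp(f(u) - m),
                        lower = -60, upper = 60,
                        rel.tol = rel_tol, abs.tol = 0,
                        subdivisions = 500L)
  structure(list(log_bf = m + log(q$value),
                 est_numerical_error = q$abs.error / q$value,
                 method = "jzs-quadrature",
                 n = n, p = p, r_squared = r2, rscale = r),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("log-BF vs null: %.4f  (n = %d, p = %d, R^2 = %.4f, r = %.4f)\n",
              x$log_bf, x$n, x$p, x$r_squared, x$rscale))
  invisible(x)
}

#' Within-subject centering of an amplitude table
#'
#' Subtracts each subject's mean across the six conditions from that
#' subject's amplitudes, removing between-subject intercept variance so
#' that model comparison targets the condition profile. Subjects missing
#' any of the six conditions are dropped with a warning. The effective
#' sample size `n_eff = n_obs - n_subjects + 1` accounts for the
#' centering constraints and is used in place of `n` in the Bayes-factor
#' integral.
#'
#' @param amplitudes Data frame with columns `subject`, `condition` and
#'   `amplitude` (one row per subject-condition cell; extra columns are
#'   ignored). `condition` must use [condition_table()] labels.
#' @return A data frame of centered amplitudes (same columns), with
#'   attributes `n_eff` and `n_subjects`.
#' @examples
#' tab <- data.frame(subject = 1, condition = condition_table()$condition,
#'                   amplitude = 1:6)
#' sum(within_subject_center(tab)$amplitude)  # 0
#' @export
within_subject_center <- function(amplitudes) {
  conds <- condition_table()$condition
  tab <- .condition_cells(amplitudes)
  keep <- vapply(split(tab$condition, tab$subject),
                 function(cc) setequal(cc, conds) && length(cc) == 6L,
                 logical(1))
  if (!all(keep)) {
    bad <- names(keep)[!keep]
    warning("dropping subject(s) with incomplete conditions: ",
            paste(bad, collapse = ", "))
    tab <- tab[!tab$subject %in% bad, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no complete subjects")
  mu <- tapply(tab$amplitude, tab$subject, mean)
  tab$amplitude <- tab$amplitude - mu[as.character(tab$subject)]
  n_sub <- length(unique(tab$subject))
  attr(tab, "n_eff") <- nrow(tab) - n_sub + 1L
  attr(tab, "n_subjects") <- n_sub
  rownames(tab) <- NULL
  tab
}

# Reduce an amplitude table to one row per subject x condition
# (averaging trials within a cell when trial-level rows are supplied).
.condition_cells <- function(amplitudes) {
  stopifnot(is.data.frame(amplitudes),
            all(c("subject", "condition", "amplitude") %in% names(amplitudes)))
  conds <- condition_table()$condition
  bad <- setdiff(unique(amplitudes$condition), conds)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  # non-response trials (valid = FALSE, amplitude 0) are retained in cell
  # means by default; drop them upstream if desired
  agg <- stats::aggregate(amplitude ~ subject + condition,
                          data = amplitudes, FUN = mean)
  agg$condition <- factor(agg$condition, levels = conds)
  agg <- agg[order(agg$subject, agg$condition), , drop = FALSE]
  agg$condition <- as.character(agg$condition)
  agg
}

# Build regression_data for one candidate model from an amplitude table.
.model_regression <- function(amplitudes, model, center = TRUE) {
  model <- .as_model(model)
  if (center) {
    tab <- within_subject_center(amplitudes)
    n_eff <- attr(tab, "n_eff")
  } else {
    tab <- .condition_cells(amplitudes)
    n_eff <- NULL
  }
  X6 <- design_matrix(model)
  idx <- match(tab$condition, rownames(X6))
  regression_data(tab$amplitude, X6[idx, , drop = FALSE], n_eff = n_eff)
}

#' Log Bayes factor of a candidate model on an amplitude table
#'
#' Convenience wrapper: builds the model's condition regressors for each
#' subject-condition cell, applies within-subject centering (optional)
#' and evaluates [log_bf_vs_null()].
#'
#' @param amplitudes Amplitude table (`subject`, `condition`,
#'   `amplitude`).
#' @param model Model id or `model_family`.
#' @param prior A [g_prior()].
#' @param center Remove per-subject mean levels and use the effective
#'   sample size correction (default `TRUE`).
#' @return A `bf_result`.
#' @export
log_bf_model <- function(amplitudes, model, prior = g_prior(),
                         center = TRUE) {
  log_bf_vs_null(.model_regression(amplitudes, model, center), prior)
}

#' Log Bayes factor comparing two candidate models
#'
#' Both models are referred to the same intercept-only null, so the
#' comparison is the difference of their null-referenced log Bayes
#' factors; it is antisymmetric in the two models, and exactly zero for
#' span-equivalent model pairs (the additive and signed-PE models).
#'
#' @inheritParams log_bf_model
#' @param model_a,model_b Model ids or `model_family` objects.
#' @return Scalar log Bayes factor in favour of `model_a` (natural log);
#'   values above 3 are conventionally read as strong evidence.
#' @examples
#' tab <- simulate_condition_amplitudes(generative_spec("pc-pain", c(1, 2),
#'   n_subjects = 12, sd_noise = 0.2, seed = 7))$amplitudes
#' log_bf_compare(tab, "pc-pain", "intensity")
#' @export
log_bf_compare <- function(amplitudes, model_a, model_b,
                           prior = g_prior(), center = TRUE) {
  bf_a <- log_bf_model(amplitudes, model_a, prior, center)
  bf_b <- log_bf_model(amplitudes, model_b, prior, center)
  bf_a$log_bf - bf_b$log_bf
}

#' Least-squares model weights from condition means
#'
#' Fits the model's free weights to grand condition-mean responses by
#' ordinary least squares with an intercept, and reports the
#' PE-to-prediction weight ratio `w2 / w1` where defined. For
#' predictive-coding models both weights are postulated to be positive;
#' violations are flagged, not enforced.
#'
#' @param amplitudes Amplitude table, or a named/ordered 6-vector of
#'   condition means in [condition_table()] order.
#' @param model Model id or `model_family`.
#' @return An object of class `model_weights` with fields `weights`
#'   (named), `ratio` (`w2/w1`, `NA` when undefined), and
#'   `positivity_ok`.
#' @examples
#' y <- predict_response("pc-pain", c(1, 2)) + 5
#' fit_weights(y, "pc-pain")$ratio  # 2
#' @export
fit_weights <- function(amplitudes, model) {
  model <- .as_model(model)
  if (is.data.frame(amplitudes)) {
    cells <- .condition_cells(amplitudes)
    y <- tapply(cells$amplitude, factor(cells$condition,
                                        levels = condition_table()$condition),
                mean)
  } else {
    if (length(amplitudes) != 6L)
      stop("condition-mean vector must have length 6")
    y <- as.numeric(amplitudes)
  }
  X <- design_matrix(model)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), as.numeric(y))
  w <- fit$coefficients[-1]
  ratio <- if (length(w) == 2L) {
    if (abs(w[[1]]) < .Machine$double.eps^0.5) NA_real_ else w[[2]] / w[[1]]
  } else NA_real_
  positivity_ok <- if (model$family == "predictive_coding")
    all(w > 0) else NA
  structure(list(model = model$id, weights = w, ratio = unname(ratio),
                 positivity_ok = positivity_ok,
                 intercept = fit$coefficients[[1]]),
            class = "model_weights")
}

#' @export
print.model_weights <- function(x, ...) {
  cat(sprintf("%s weights: %s", x$model,
              paste(sprintf("%s = %.4f", names(x$weights), x$weights),
                    collapse = ", ")))
  if (!is.na(x$ratio)) cat(sprintf("  (w2/w1 = %.3f)", x$ratio))
  if (isFALSE(x$positivity_ok)) cat("  [positivity postulate violated]")
  cat("\n")
  invisible(x)
}
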