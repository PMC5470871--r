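# Independent oracles and fixture builders used across the suite.

# Dense-grid trapezoid evaluation of the JZS Bayes-factor integral on
# the log-g scale, written directly from the integral definition and
# independent of the package's quadrature path.
oracle_log_bf <- function(n, p, r2, rscale, n_grid = 1e6,
                          lo = -20, hi = 20) {
  u <- seq(lo, hi, length.out = n_grid)
  g <- exp(u)
  logf <- ((n - 1 - p) / 2) * log1p(g) -
    ((n - 1) / 2) * log1p(g * (1 - r2)) +
    0.5 * log(rscale^2 * n / 2) - lgamma(0.5) -
    1.5 * log(g) - rscale^2 * n / (2 * g) +
    log(g)  # Jacobian of g = exp(u)
  m <- max(logf)
  h <- u[2] - u[1]
  f <- exp(logf - m)
  m + log(h * (sum(f) - (f[1] + f[length(f)]) / 2))
}

# Signed pairwise log-BF (a vs b) from a comparison_report, regardless
# of the order in which the pair was enumerated.
pair_logbf <- function(report, a, b) {
  p <- report$pairs
  i <- which(p$model_a == a & p$model_b == b)
  if (length(i)) return(p$log_bf[i])
  -p$log_bf[which(p$model_a == b & p$model_b == a)]
}

# Amplitude table with one row per subject x condition from a matrix
# of values (subjects in rows, conditions in condition_table order).
amp_table <- function(values) {
  values <- as.matrix(values)
  conds <- condition_table()$condition
  stopifnot(ncol(values) == 6L)
  data.frame(subject = rep(seq_len(nrow(values)), each = 6L),
             condition = rep(conds, nrow(values)),
             amplitude = as.vector(t(values)),
             stringsAsFactors = FALSE)
}

# Random amplitude table: pattern + subject intercepts + noise.
random_amp_table <- function(n_subjects, pattern = rep(0, 6),
                             sd_subject = 0.5, sd_noise = 0.3) {
  b <- rnorm(n_subjects, 0, sd_subject)
  eps <- matrix(rnorm(n_subjects * 6, 0, sd_noise), n_subjects)
  amp_table(matrix(pattern, n_subjects, 6, byrow = TRUE) + b + eps)
}
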