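#' Two-by-three repeated-measures factorial ANOVA
#'
#' Partitions the within-subject sums of squares of a complete
#' 2 (stimulus) x 3 (cue) design, testing the stimulus main effect
#' against the stimulus-by-subject interaction, the cue main effect
#' against the cue-by-subject interaction, and the cue-by-stimulus
#' interaction against its three-way residual. No sphericity correction
#' is applied. Subjects with missing cells are dropped with a warning.
#'
#' @param amplitudes Amplitude table (`subject`, `condition`,
#'   `amplitude`); trial-level rows are averaged to cell means.
#' @return An object of class `anova_2x3`: a data frame with one row
#'   per effect (`stimulus`, `cue`, `cue_by_stimulus`) and columns
#'   `F`, `df1`, `df2`, `p`, `ss_effect`, `ss_error`; `F` is `NA` with
#'   a `degenerate` flag when an error stratum has zero variance.
#' @export
rm_anova_2x3 <- function(amplitudes) {
  cells <- .condition_cells(amplitudes)
  ct <- condition_table()
  ok <- vapply(split(cells$condition, cells$subject),
               function(cc) setequal(cc, ct$condition), logical(1))
  if (!all(ok)) {
    warning("dropping subject(s) with incomplete cells: ",
            paste(names(ok)[!ok], collapse = ", "))
    cells <- cells[cells$subject %in% names(ok)[ok], , drop = FALSE]
  }
  subs <- unique(cells$subject)
  n <- length(subs)
  if (n < 2L) stop("need at least 2 complete subjects")
  idx <- match(cells$condition, ct$condition)
  Y <- array(NA_real_, dim = c(n, 2L, 3L))  # subject x stimulus x cue
  si <- match(cells$subject, subs)
  Y[cbind(si, ifelse(ct$stimulus[idx] == "pain", 2L, 1L),
          match(ct$cue[idx], c("low", "medium", "high")))] <- cells$amplitude
  m <- mean(Y)
  m_s <- apply(Y, 1, mean); m_i <- apply(Y, 2, mean); m_j <- apply(Y, 3, mean)
  m_si <- apply(Y, c(1, 2), mean); m_sj <- apply(Y, c(1, 3), mean)
  m_ij <- apply(Y, c(2, 3), mean)
  ss_stim <- 3 * n * sum((m_i - m)^2)
  ss_stim_err <- 3 * sum((m_si - outer(m_s, m_i, "+") + m)^2)
  ss_cue <- 2 * n * sum((m_j - m)^2)
  ss_cue_err <- 2 * sum((m_sj - outer(m_s, m_j, "+") + m)^2)
  ss_int <- n * sum((m_ij - outer(m_i, m_j, "+") + m)^2)
  resid <- Y
  for (s in seq_len(n)) for (i in 1:2) for (j in 1:3)
    resid[s, i, j] <- Y[s, i, j] - m_si[s, i] - m_sj[s, j] - m_ij[i, j] +
      m_s[s] + m_i[i] + m_j[j] - m
  ss_int_err <- sum(resid^2)
  eff <- data.frame(
    effect = c("stimulus", "cue", "cue_by_stimulus"),
    ss_effect = c(ss_stim, ss_cue, ss_int),
    df1 = c(1L, 2L, 2L),
    ss_error = c(ss_stim_err, ss_cue_err, ss_int_err),
    df2 = c(n - 1L, 2L * (n - 1L), 2L * (n - 1L)),
    stringsAsFactors = FALSE)
  eff$degenerate <- eff$ss_error <= .Machine$double.eps * max(1, abs(m))
  ms_eff <- eff$ss_effect / eff$df1
  ms_err <- eff$ss_error / eff$df2
  eff$F <- ifelse(eff$degenerate, NA_real_, ms_eff / ms_err)
  eff$p <- ifelse(eff$degenerate, NA_real_,
                  stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE))
  attr(eff, "n_subjects") <- n
  class(eff) <- c("anova_2x3", "data.frame")
  eff
}

#' Paired t-test
#'
#' Standard paired t statistic with a two-sided p-value, wrapping
#' [stats::t.test()]. A zero-variance difference vector is flagged
#' rather than erroring: identical inputs give `t = 0`, `p = 1`.
#'
#' @param a,b Paired numeric vectors of equal length (>= 2).
#' @return List with `t`, `df`, `p` and `zero_variance` flag.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("a and b must have equal length >= 2")
  d <- a - b
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                df = length(d) - 1L,
                p = if (md == 0) 1 else 0,
                zero_variance = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, zero_variance = FALSE)
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up false-discovery-rate control via [stats::p.adjust()].
#'
#' @param pvals P-values in \code{[0, 1]}.
#' @param q FDR level (default 0.05).
#' @return Logical vector of rejections (empty for empty input).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) return(logical(0))
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Compare all candidate models on an amplitude table
#'
#' Computes the null-referenced log Bayes factor of every candidate
#' model, all pairwise model comparisons, least-squares weights per
#' model, and strong-evidence calls at `|log-BF| > 3` (natural log).
#' The additive and signed-PE models span the same regressor subspace,
#' so their pairwise log-BF is exactly 0 and is reported as such.
#'
#' @param amplitudes Amplitude table.
#' @param models Character vector of model ids (default all five).
#' @param prior A [g_prior()].
#' @param center Within-subject centering (default `TRUE`).
#' @param threshold Strong-evidence threshold on `|log-BF|` (default 3).
#' @return An object of class `comparison_report`: list with `null_bf`
#'   (named vector of log-BF vs null), `pairs` (data frame `model_a`,
#'   `model_b`, `log_bf`, `call`), `weights` (list of
#'   [fit_weights()] results) and `n_eff`.
#' @export
compare_all_models <- function(amplitudes, models = candidate_models(),
                               prior = g_prior(), center = TRUE,
                               threshold = 3) {
  bfs <- vapply(models, function(mid)
    log_bf_model(amplitudes, mid, prior, center)$log_bf, numeric(1))
  prs <- utils::combn(models, 2)
  pairs <- data.frame(model_a = prs[1, ], model_b = prs[2, ],
                      stringsAsFactors = FALSE)
  pairs$log_bf <- unname(bfs[pairs$model_a] - bfs[pairs$model_b])
  pairs$call <- ifelse(pairs$log_bf > threshold, "a",
                       ifelse(pairs$log_bf < -threshold, "b", "none"))
  weights <- lapply(models, function(mid) fit_weights(amplitudes, mid))
  names(weights) <- models
  n_eff <- attr(within_subject_center(amplitudes), "n_eff")
  structure(list(null_bf = bfs, pairs = pairs, weights = weights,
                 n_eff = n_eff, threshold = threshold),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Model comparison (log-BF vs intercept-only null, n_eff =",
      x$n_eff, ")\n")
  print(round(x$null_bf, 3))
  cat("Pairwise (positive favours model_a; strong call at |log-BF| >",
      x$threshold, "):\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Model-recovery confusion matrix
#'
#' Simulates amplitude tables under each generating specification and
#' records which candidate model attains the largest null-referenced
#' log Bayes factor. The additive and signed-PE models are
#' span-equivalent (identical Bayes factors by construction), so a win
#' by either counts for the equivalence class of the generator.
#'
#' @param specs Named list of [generative_spec()] objects (names are
#'   the generating model ids).
#' @param replicates Replicates per generating model.
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param models Candidate set (default all five).
#' @param prior A [g_prior()].
#' @return Matrix of winner fractions, generating models in rows,
#'   candidates in columns; attribute `class_diagonal` gives the
#'   per-generator fraction of wins within the generator's span class.
#' @export
model_recovery <- function(specs, replicates = 100L, seed = 1L,
                           models = candidate_models(),
                           prior = g_prior()) {
  stopifnot(replicates >= 1L, length(specs) >= 1L)
  span_class <- function(id) if (id %in% c("additive", "pc-signed"))
    c("additive", "pc-signed") else id
  conf <- matrix(0, nrow = length(specs), ncol = length(models),
                 dimnames = list(names(specs), models))
  class_diag <- stats::setNames(numeric(length(specs)), names(specs))
  base <- as.integer(seed)
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    for (r in seq_len(replicates)) {
      spec$seed <- (base + 7919L * k + r) %% .Machine$integer.max
      tab <- simulate_condition_amplitudes(spec)$amplitudes
      bfs <- vapply(models, function(mid)
        log_bf_model(tab, mid, prior)$log_bf, numeric(1))
      winner <- models[which.max(bfs)]
      conf[k, winner] <- conf[k, winner] + 1
      if (winner %in% span_class(names(specs)[k]))
        class_diag[k] <- class_diag[k] + 1
    }
  }
  conf <- conf / replicates
  attr(conf, "class_diagonal") <- class_diag / replicates
  conf
}

# One-way any-condition repeated-measures F per voxel: condition effect
# tested against the condition-by-subject residual.
.omnibus_f_p <- function(Y) {  # Y: subjects x 6
  n <- nrow(Y)
  m <- mean(Y); m_s <- rowMeans(Y); m_c <- colMeans(Y)
  ss_cond <- n * sum((m_c - m)^2)
  resid <- Y - outer(m_s, m_c, "+") + m
  ss_err <- sum(resid^2)
  df1 <- 5L; df2 <- 5L * (n - 1L)
  if (ss_err <= 0) return(0)
  f <- (ss_cond / df1) / (ss_err / df2)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Voxel-wise log Bayes factor map
#'
#' Computes, for every voxel inside the grid mask that survives an
#' omnibus pre-mask (one-way any-condition repeated-measures F across
#' the six cells, p < 0.005 uncorrected), the log Bayes factor
#' comparing two candidate models, and a map thresholded at
#' `|log-BF| > 3`.
#'
#' @param grid A `voxel_grid`.
#' @param pair Length-2 character vector of model ids; positive values
#'   favour the first.
#' @param prior A [g_prior()].
#' @param premask_p Omnibus pre-mask threshold (default 0.005).
#' @param threshold Strong-evidence threshold (default 3).
#' @param center Within-subject centering (default `TRUE`).
#' @return List with `log_bf` (3-D array, `NA` outside the post-mask),
#'   `thresholded` (values only where `|log-BF|` exceeds the
#'   threshold), `premask` (logical array) and `pair`. Warns when the
#'   post-mask is empty.
#' @export
voxelwise_logbf <- function(grid, pair = c("pc-pain", "intensity"),
                            prior = g_prior(), premask_p = 0.005,
                            threshold = 3, center = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"), length(pair) == 2L)
  dims <- dim(grid$data)
  shape <- dims[1:3]; n_sub <- dims[5]
  if (!any(grid$mask)) stop("grid mask is empty")
  conds <- condition_table()$condition
  log_bf <- array(NA_real_, dim = shape)
  premask <- array(FALSE, dim = shape)
  vox <- which(grid$mask, arr.ind = TRUE)
  for (v in seq_len(nrow(vox))) {
    i <- vox[v, 1]; j <- vox[v, 2]; k <- vox[v, 3]
    Y <- t(grid$data[i, j, k, , ])  # subjects x 6
    p_omni <- .omnibus_f_p(Y)
    if (is.na(p_omni) || p_omni >= premask_p) next
    premask[i, j, k] <- TRUE
    tab <- data.frame(subject = rep(seq_len(n_sub), each = 6L),
                      condition = rep(conds, n_sub),
                      amplitude = as.vector(t(Y)))
    log_bf[i, j, k] <- log_bf_compare(tab, pair[1], pair[2], prior,
                                      center = center)
  }
  if (!any(premask))
    warning("omnibus pre-mask is empty; no voxel-wise Bayes factors computed")
  thresholded <- ifelse(abs(log_bf) > threshold, log_bf, NA_real_)
  list(log_bf = log_bf, thresholded = thresholded, premask = premask,
       pair = pair, threshold = threshold)
}

#' Anterior-posterior gradient profile of a log-BF map
#'
#' Averages in-mask voxel log Bayes factors within y-coordinate bins
#' (one bin per y slice by default), reported separately for the left
#' (x < 0) and right (x > 0) hemispheres.
#'
#' @param log_bf 3-D log-BF array (e.g. `voxelwise_logbf()$log_bf`).
#' @param coords Coordinate list (`x`, `y`, `z` in mm) as stored in a
#'   `voxel_grid`.
#' @param mask Optional logical array restricting the average; defaults
#'   to all voxels with finite log-BF.
#' @return Data frame with columns `y_mm`, `hemisphere`, `mean_log_bf`
#'   and `n_voxels`; bins without voxels carry `NA`.
#' @export
gradient_profile <- function(log_bf, coords, mask = NULL) {
  dims <- dim(log_bf)
  stopifnot(length(dims) == 3L,
            length(coords$x) == dims[1], length(coords$y) == dims[2])
  if (is.null(mask)) mask <- !is.na(log_bf)
  out <- expand.grid(y_mm = coords$y, hemisphere = c("left", "right"),
                     stringsAsFactors = FALSE)
  out$mean_log_bf <- NA_real_
  out$n_voxels <- 0L
  for (r in seq_len(nrow(out))) {
    iy <- match(out$y_mm[r], coords$y)
    xs <- if (out$hemisphere[r] == "left") which(coords$x < 0)
          else which(coords$x > 0)
    vals <- log_bf[xs, iy, ][mask[xs, iy, ] & !is.na(log_bf[xs, iy, ])]
    out$n_voxels[r] <- length(vals)
    if (length(vals)) out$mean_log_bf[r] <- mean(vals)
  }
  out
}

#' Multivariate pattern expression
#'
#' Scores the expression of a fixed voxel weight map (e.g. a
#' pain-signature pattern) in each subject's condition estimates as the
#' dot product over in-mask voxels, yielding one scalar per subject and
#' condition. The resulting table feeds directly into
#' [rm_anova_2x3()] and [compare_all_models()].
#'
#' @param weight_map 3-D numeric array matching the grid's spatial
#'   dimensions.
#' @param grid A `voxel_grid`.
#' @return Amplitude table (`subject`, `condition`, `amplitude`).
#' @export
pattern_expression <- function(weight_map, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  dims <- dim(grid$data)
  if (!identical(dim(weight_map), dims[1:3]))
    stop("weight map shape does not match the grid")
  keep <- which(grid$mask)
  w <- weight_map[keep]
  n_sub <- dims[5]
  conds <- condition_table()$condition
  out <- expand.grid(condition = conds, subject = seq_len(n_sub),
                     stringsAsFactors = FALSE)[, c("subject", "condition")]
  out$amplitude <- NA_real_
  for (s in seq_len(n_sub)) for (c6 in seq_len(6L)) {
    vol <- grid$data[, , , c6, s]
    out$amplitude[out$subject == s & out$condition == conds[c6]] <-
      sum(w * vol[keep])
  }
  out
}

#' Score a set of simulated or recorded trial traces
#'
#' Applies the modality-appropriate scoring chain to each trace of a
#' [simulate_trial_traces()] result (SCR: trough-to-peak scoring;
#' pupil: cleaning plus baseline-to-peak scoring) and log-transforms
#' the amplitudes, producing a trial-level amplitude table.
#'
#' @param sim List with `traces` and `meta` as returned by
#'   [simulate_trial_traces()].
#' @param subject Subject identifier recorded in the table (default 1).
#' @param log Apply [log_amplitude()] (default `TRUE`).
#' @return Amplitude table with columns `subject`, `block`, `trial`,
#'   `condition`, `amplitude`, `valid`.
#' @export
score_trial_traces <- function(sim, subject = 1L, log = TRUE) {
  stopifnot(is.list(sim$traces), is.data.frame(sim$meta))
  n <- length(sim$traces)
  amp <- numeric(n); valid <- logical(n)
  for (i in seq_len(n)) {
    tr <- sim$traces[[i]]
    if (tr$modality == "scr") {
      sc <- score_scr(tr)
      amp[i] <- sc$amplitude; valid[i] <- sc$valid
    } else {
      pp <- preprocess_pupil(tr)
      if (pp$discard) {
        amp[i] <- NA_real_; valid[i] <- FALSE
      } else {
        sc <- score_pupil(pp$trace)
        amp[i] <- sc$amplitude; valid[i] <- sc$valid
      }
    }
  }
  if (log) amp[!is.na(amp)] <- log_amplitude(amp[!is.na(amp)])
  data.frame(subject = subject, block = sim$meta$block,
             trial = sim$meta$trial, condition = sim$meta$condition,
             amplitude = amp, valid = valid, stringsAsFactors = FALSE)
}
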