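#' Generative specification for synthetic condition amplitudes
#'
#' Describes the ground truth for simulated data: the generating model
#' and its weights, the between-subject intercept SD, the within-cell
#' noise SD, and the number of subjects. Two named signal-to-noise
#' presets are provided: `"high"` (sd_subject 0.3, sd_noise 0.1) for
#' recovery validation, and `"study"` (sd_subject 0.5, sd_noise
#' 0.3), a plausible physiological regime for a 28-subject study.
#'
#' @param model Model id or `model_family`.
#' @param weights Generating weights (length matching the model).
#' @param n_subjects Number of simulated subjects (>= 2).
#' @param sd_subject Between-subject intercept SD.
#' @param sd_noise Within-cell Gaussian noise SD.
#' @param seed Integer seed.
#' @param snr Optional preset name overriding the two SDs: `"high"` or
#'   `"study"`.
#' @return An object of class `generative_spec`.
#' @export
generative_spec <- function(model, weights, n_subjects = 28L,
                            sd_subject = 0.5, sd_noise = 0.3,
                            seed = 1L, snr = NULL) {
  model <- .as_model(model)
  if (length(weights) != model$n_weights)
    stop("model '", model$id, "' takes ", model$n_weights, " weight(s)")
  if (!is.null(snr)) {
    preset <- switch(match.arg(snr, c("high", "study")),
                     "high" = c(sd_subject = 0.3, sd_noise = 0.1),
                     "study" = c(sd_subject = 0.5, sd_noise = 0.3))
    sd_subject <- preset[["sd_subject"]]
    sd_noise <- preset[["sd_noise"]]
  }
  if (sd_subject < 0 || sd_noise < 0) stop("SDs must be >= 0")
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  structure(list(model = model, weights = as.numeric(weights),
                 n_subjects = n_subjects, sd_subject = sd_subject,
                 sd_noise = sd_noise, seed = as.integer(seed)),
            class = "generative_spec")
}

#' Simulate condition-level amplitudes with recorded ground truth
#'
#' Each subject's six condition amplitudes are the generating model's
#' predicted pattern plus a Gaussian subject intercept and homoscedastic
#' Gaussian cell noise:
#' `y[s, c] = yhat_c + b_s + eps[s, c]`,
#' `b_s ~ N(0, sd_subject^2)`, `eps ~ N(0, sd_noise^2)`.
#' The returned truth record (model, weights, predicted pattern, and
#' every random draw) is sufficient to reconstruct the table exactly.
#'
#' @param spec A [generative_spec()].
#' @return List with `amplitudes` (long table: `subject`, `condition`,
#'   `amplitude`) and `truth`.
#' @examples
#' sim <- simulate_condition_amplitudes(
#'   generative_spec("pc-pain", c(1, 2), n_subjects = 4, seed = 2))
#' head(sim$amplitudes)
#' @export
simulate_condition_amplitudes <- function(spec) {
  stopifnot(inherits(spec, "generative_spec"))
  set.seed(spec$seed)
  yhat <- predict_response(spec$model, spec$weights)
  n <- spec$n_subjects
  b <- stats::rnorm(n, 0, spec$sd_subject)
  eps <- matrix(stats::rnorm(n * 6L, 0, spec$sd_noise), nrow = n)
  y <- matrix(yhat, nrow = n, ncol = 6L, byrow = TRUE) + b + eps
  conds <- condition_table()$condition
  amplitudes <- data.frame(
    subject = rep(seq_len(n), each = 6L),
    condition = rep(conds, n),
    amplitude = as.vector(t(y)),
    stringsAsFactors = FALSE)
  truth <- list(model = spec$model$id, weights = spec$weights,
                yhat = yhat, subject_intercepts = b, noise = eps,
                sd_subject = spec$sd_subject, sd_noise = spec$sd_noise,
                seed = spec$seed)
  list(amplitudes = amplitudes, truth = truth)
}

# Canonical response waveform: gamma-density bump normalised to unit
# peak; t in seconds from response onset.
.gamma_bump <- function(t, shape, rate) {
  mode_t <- (shape - 1) / rate
  peak <- stats::dgamma(mode_t, shape, rate)
  ifelse(t > 0, stats::dgamma(t, shape, rate) / peak, 0)
}

#' Simulate trial-locked physiological traces
#'
#' Produces one synthetic trace per trial of a plan: a canonical
#' gamma-shaped response bump with modality-typical latency, scaled by
#' the generating model's predicted amplitude for the trial's condition,
#' superposed on a constant baseline with additive Gaussian sample
#' noise. SCR traces (100 Hz) place the bump onset about 1.2 s after cue
#' onset with a peak near 3 s, inside the trough-to-peak search window.
#' Pupil traces (1000 Hz) span 3 s before to 10 s after stimulus onset,
#' respond after stimulus onset, and optionally receive random blink
#' intervals (a Poisson number per trial at `blink_rate` per second,
#' each about 0.2 s long).
#'
#' @param plan A [generate_design()] trial plan (one subject's trials).
#' @param spec A [generative_spec()]; its model and weights set the
#'   per-condition amplitude scale, and `sd_noise` (times `noise_scale`)
#'   the sample noise SD.
#' @param modality `"scr"` or `"pupil"`.
#' @param noise_scale Multiplier applied to `spec$sd_noise` for sample
#'   noise (traces need less noise than condition-level cells; default
#'   0.05).
#' @param blink_rate Expected blinks per second (pupil only; default 0).
#' @param blink_duration_s Mean blink duration (default 0.2 s).
#' @param seed Integer seed.
#' @return List with `traces` (list of `signal_trace`) and `meta` (data
#'   frame: `block`, `trial`, `condition`, `true_amplitude`).
#' @export
simulate_trial_traces <- function(plan, spec, modality = c("scr", "pupil"),
                                  noise_scale = 0.05, blink_rate = 0,
                                  blink_duration_s = 0.2, seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(is.data.frame(plan), inherits(spec, "generative_spec"))
  set.seed(as.integer(seed))
  yhat <- predict_response(spec$model, spec$weights)
  conds <- condition_table()$condition
  cond_of <- function(stimulus, cue) paste(stimulus, cue, sep = "_")
  sd_samp <- spec$sd_noise * noise_scale
  if (modality == "scr") {
    rate <- 100; cue_t <- 1; dur <- 12
    stim_t <- cue_t + 0.3
    latency <- 1.2; shape <- 3; grate <- 2  # bump mode 1 s after onset
    ref_t <- function() cue_t + latency
  } else {
    rate <- 1000; stim_t <- 3; dur <- 13
    cue_t <- stim_t - 0.3
    latency <- 0.4; shape <- 3; grate <- 4  # bump mode 0.5 s post onset
    ref_t <- function() stim_t + latency
  }
  n_samp <- round(dur * rate) + 1L
  tt <- (seq_len(n_samp) - 1) / rate
  traces <- vector("list", nrow(plan))
  meta <- data.frame(block = plan$block, trial = plan$trial,
                     condition = cond_of(plan$stimulus, plan$cue),
                     true_amplitude = NA_real_)
  for (i in seq_len(nrow(plan))) {
    amp <- yhat[[match(meta$condition[i], conds)]]
    meta$true_amplitude[i] <- amp
    x <- 2 + amp * .gamma_bump(tt - ref_t(), shape, grate)
    if (sd_samp > 0) x <- x + stats::rnorm(n_samp, 0, sd_samp)
    blinks <- NULL
    if (modality == "pupil" && blink_rate > 0) {
      k <- stats::rpois(1, blink_rate * dur)
      if (k > 0) {
        starts <- sort(stats::runif(k, 0, dur))
        blinks <- cbind(start_s = starts,
                        end_s = pmin(starts + blink_duration_s, dur))
        for (j in seq_len(k))
          x[tt >= blinks[j, 1] & tt <= blinks[j, 2]] <- NA_real_
      }
    }
    traces[[i]] <- signal_trace(x, rate = rate, cue_onset_s = cue_t,
                                stimulus_onset_s = stim_t,
                                modality = modality, blinks = blinks)
  }
  list(traces = traces, meta = meta)
}

#' Simulate a voxel grid with an anterior-posterior model gradient
#'
#' Builds a 4-D (x, y, z, condition) grid per subject in which each
#' voxel's six-condition pattern is a convex blend of the
#' predictive-coding (pain-PE) pattern and the stimulus-intensity
#' pattern: `lambda(y) * pc + (1 - lambda(y)) * intensity + noise`, with
#' `lambda` monotone along the posterior-to-anterior (y) axis. This
#' emulates the anterior-posterior gradient of model evidence observed
#' in the insula. The ground-truth lambda per y-slice is stored.
#'
#' @param shape Grid dimensions `c(nx, ny, nz)` (default 20 x 40 x 20).
#' @param lambda_fun Function of y (mm) returning the blend weight in
#'   \code{[0, 1]}, monotone in y; default a logistic ramp centred at y = 0.
#' @param spec_pc [generative_spec()] for the predictive-coding pattern
#'   (sets weights, subject count and noise SDs for the whole grid).
#' @param spec_int [generative_spec()] for the intensity pattern; must
#'   share `n_subjects` with `spec_pc`.
#' @param spacing_mm Voxel spacing (default 2 mm); coordinates are
#'   centred on 0 in x (left negative, right positive) and z, and run
#'   posterior (negative) to anterior (positive) in y.
#' @param mask Optional logical array `shape`; default keeps a central
#'   box spanning both hemispheres.
#' @param seed Integer seed.
#' @return An object of class `voxel_grid`: `data` (5-D array x, y, z,
#'   condition, subject), `mask`, `coords` (list of mm coordinate
#'   vectors), and `truth` (lambda per y-slice plus the two patterns).
#' @export
simulate_voxel_grid <- function(shape = c(20L, 40L, 20L),
                                lambda_fun = function(y) stats::plogis(y / 8),
                                spec_pc = generative_spec("pc-pain", c(1, 2)),
                                spec_int = generative_spec("intensity", 1),
                                spacing_mm = 2, mask = NULL, seed = 1L) {
  stopifnot(length(shape) == 3L)
  if (spec_pc$n_subjects != spec_int$n_subjects)
    stop("spec_pc and spec_int must share n_subjects")
  set.seed(as.integer(seed))
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  coords <- list(x = (seq_len(nx) - (nx + 1) / 2) * spacing_mm,
                 y = (seq_len(ny) - (ny + 1) / 2) * spacing_mm,
                 z = (seq_len(nz) - (nz + 1) / 2) * spacing_mm)
  lam <- lambda_fun(coords$y)
  if (any(lam < 0 | lam > 1)) stop("lambda must lie in [0, 1]")
  if (is.unsorted(lam) && is.unsorted(rev(lam)))
    stop("lambda must be monotone along y")
  pat_pc <- predict_response(spec_pc$model, spec_pc$weights)
  pat_int <- predict_response(spec_int$model, spec_int$weights)
  n_sub <- spec_pc$n_subjects
  if (is.null(mask)) {
    mask <- array(FALSE, dim = shape)
    xi <- seq_len(nx); zi <- seq_len(nz)
    mask[xi >= max(1, floor(nx * 0.15)) & xi <= ceiling(nx * 0.85),
         , zi >= max(1, floor(nz * 0.25)) & zi <= ceiling(nz * 0.75)] <- TRUE
  }
  stopifnot(identical(dim(mask), as.integer(shape)))
  data <- array(NA_real_, dim = c(shape, 6L, n_sub))
  b <- matrix(stats::rnorm(n_sub, 0, spec_pc$sd_subject), nrow = n_sub)
  for (iy in seq_len(ny)) {
    blend <- lam[iy] * pat_pc + (1 - lam[iy]) * pat_int
    nvox <- nx * nz
    for (s in seq_len(n_sub)) {
      noise <- matrix(stats::rnorm(nvox * 6L, 0, spec_pc$sd_noise),
                      nrow = nvox)
      vals <- matrix(blend, nrow = nvox, ncol = 6L, byrow = TRUE) +
        b[s] + noise
      data[, iy, , , s] <- array(vals, dim = c(nx, nz, 6L))
    }
  }
  structure(list(data = data, mask = mask, coords = coords,
                 truth = list(lambda = lam, pattern_pc = pat_pc,
                              pattern_int = pat_int,
                              sd_noise = spec_pc$sd_noise,
                              sd_subject = spec_pc$sd_subject,
                              seed = as.integer(seed))),
            class = "voxel_grid")
}

#' Export a voxel grid as NIfTI with a JSON truth sidecar
#'
#' Writes the across-subject mean condition estimates as a 4-D NIfTI
#' volume (condition as the fourth dimension) plus, when a truth record
#' is present, a JSON sidecar. Requires the suggested packages RNifti
#' and jsonlite.
#'
#' @param grid A `voxel_grid`.
#' @param path Output path (`.nii` or `.nii.gz`); the sidecar replaces
#'   the extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_voxel_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to write NIfTI output")
  mean4d <- apply(grid$data, 1:4, mean)
  RNifti::writeNifti(RNifti::asNifti(mean4d), path)
  if (!is.null(grid$truth) && requireNamespace("jsonlite", quietly = TRUE)) {
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(grid$truth, side, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
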