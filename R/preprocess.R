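#' Trial-locked physiological signal trace
#'
#' A single trial segment of skin conductance (SCR, typically 100 Hz) or
#' pupil diameter (typically 1000 Hz), with cue and stimulus onset times
#' expressed relative to the start of the segment. Pupil traces may
#' carry blink intervals, given as a two-column matrix or data frame of
#' (start_s, end_s) pairs.
#'
#' @param samples Numeric vector of samples; the first sample is at time
#'   0 within the segment.
#' @param rate Sampling rate in Hz.
#' @param cue_onset_s,stimulus_onset_s Event times (seconds) within the
#'   segment.
#' @param modality `"scr"` or `"pupil"`.
#' @param blinks Optional blink intervals (pupil only).
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(samples, rate, cue_onset_s, stimulus_onset_s,
                         modality = c("scr", "pupil"), blinks = NULL) {
  modality <- match.arg(modality)
  if (rate <= 0) stop("rate must be positive")
  samples <- as.numeric(samples)
  dur <- (length(samples) - 1) / rate
  if (cue_onset_s < 0 || cue_onset_s > dur)
    stop("cue onset outside segment")
  if (stimulus_onset_s < 0 || stimulus_onset_s > dur)
    stop("stimulus onset outside segment")
  if (!is.null(blinks)) {
    blinks <- as.matrix(blinks)[, 1:2, drop = FALSE]
    colnames(blinks) <- c("start_s", "end_s")
  }
  structure(list(samples = samples, rate = rate,
                 cue_onset_s = cue_onset_s,
                 stimulus_onset_s = stimulus_onset_s,
                 modality = modality, blinks = blinks),
            class = "signal_trace")
}

.trace_times <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$rate
}

# Centered moving-average smoother; width in seconds.
.smooth_ma <- function(x, rate, width_s = 0.05) {
  w <- max(1L, round(width_s * rate))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  sm <- stats::filter(x, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- x[is.na(sm)]  # keep edges unsmoothed
  sm
}

#' Score a skin conductance response amplitude
#'
#' Implements trough-to-peak scoring with a physiologically constrained
#' search window: the response onset (the first local minimum of the
#' lightly smoothed trace) must occur at least 1 s after cue onset, and
#' the peak must fall within 10 s after cue onset. The amplitude is the
#' difference between the maximum in the window and the preceding
#' trough. Trials without a qualifying trough-peak pair score 0 and are
#' flagged invalid. Scoring is invariant to adding a constant to the
#' whole trace. A local minimum is detected as a non-positive-to-positive
#' sign change of the first difference after 50 ms moving-average
#' smoothing.
#'
#' @param trace A `signal_trace` with modality `"scr"`; the segment must
#'   extend to at least 10 s after cue onset.
#' @return List with `amplitude`, `valid`, and (when valid) `t_trough_s`
#'   and `t_peak_s` relative to segment start.
#' @export
score_scr <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$modality != "scr") stop("score_scr expects an SCR trace")
  tt <- .trace_times(trace)
  if (max(tt) < trace$cue_onset_s + 10)
    stop("segment must cover 10 s after cue onset")
  x <- .smooth_ma(trace$samples, trace$rate)
  d <- diff(x)
  win_end <- trace$cue_onset_s + 10
  # candidate troughs: d changes from <= 0 to > 0 at sample i
  cand <- which(d[-1] > 0 & d[-length(d)] <= 0) + 1L
  cand <- cand[tt[cand] >= trace$cue_onset_s + 1 & tt[cand] < win_end]
  invalid <- list(amplitude = 0, valid = FALSE,
                  t_trough_s = NA_real_, t_peak_s = NA_real_)
  if (length(cand) == 0L) return(invalid)
  trough <- cand[1L]
  in_win <- which(tt > tt[trough] & tt <= win_end)
  if (length(in_win) == 0L) return(invalid)
  peak <- in_win[which.max(x[in_win])]
  amp <- x[peak] - x[trough]
  if (amp <= 0) return(invalid)
  list(amplitude = amp, valid = TRUE,
       t_trough_s = tt[trough], t_peak_s = tt[peak])
}

#' Preprocess a pupil diameter trace
#'
#' Standard pupillometry cleaning: samples within +/- 100 ms of any
#' blink interval are marked missing; trials with more than 50% of
#' samples missing are discarded; remaining gaps are linearly
#' interpolated; the trace is low-pass filtered at 2 Hz with a
#' zero-phase second-order Butterworth filter (applied forward and
#' backward), which also serves as the anti-alias filter before
#' decimation from the native rate (typically 1000 Hz) down to 250 Hz.
#'
#' @param trace A `signal_trace` with modality `"pupil"`. The native
#'   rate must be an integer multiple of `target_rate`.
#' @param target_rate Output sampling rate in Hz (default 250).
#' @param blink_pad_s Padding added around each blink interval (default
#'   0.1 s).
#' @param max_missing Missing-sample fraction above which the trial is
#'   discarded (default 0.5).
#' @param cutoff_hz Low-pass cutoff (default 2 Hz).
#' @return List with `trace` (cleaned `signal_trace` at `target_rate`,
#'   or `NULL` when discarded), `discard` flag and `missing_fraction`.
#' @export
preprocess_pupil <- function(trace, target_rate = 250, blink_pad_s = 0.1,
                             max_missing = 0.5, cutoff_hz = 2) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$modality != "pupil") stop("preprocess_pupil expects a pupil trace")
  dec <- trace$rate / target_rate
  if (abs(dec - round(dec)) > 1e-9 || dec < 1)
    stop("native rate must be an integer multiple of target_rate")
  dec <- as.integer(round(dec))
  x <- trace$samples
  tt <- .trace_times(trace)
  missing <- !is.finite(x)
  if (!is.null(trace$blinks) && nrow(trace$blinks) > 0) {
    for (i in seq_len(nrow(trace$blinks))) {
      missing <- missing |
        (tt >= trace$blinks[i, 1] - blink_pad_s &
           tt <= trace$blinks[i, 2] + blink_pad_s)
    }
  }
  frac <- mean(missing)
  if (frac > max_missing || all(missing))
    return(list(trace = NULL, discard = TRUE, missing_fraction = frac))
  if (any(missing)) {
    keep <- which(!missing)
    x <- stats::approx(tt[keep], x[keep], xout = tt, rule = 2)$y
  }
  if (cutoff_hz < trace$rate / 2) {
    bf <- signal::butter(2, cutoff_hz / (trace$rate / 2), type = "low")
    # odd-reflection padding suppresses start/end filter transients
    n <- length(x)
    pad <- min(n - 1L, ceiling(3 * trace$rate / cutoff_hz))
    xp <- c(2 * x[1] - x[(pad + 1L):2],
            x,
            2 * x[n] - x[(n - 1L):(n - pad)])
    xf <- signal::filtfilt(bf, xp)
    x <- xf[(pad + 1L):(pad + n)]
  }
  idx <- seq(1L, length(x), by = dec)
  cleaned <- signal_trace(x[idx], rate = target_rate,
                          cue_onset_s = trace$cue_onset_s,
                          stimulus_onset_s = trace$stimulus_onset_s,
                          modality = "pupil", blinks = trace$blinks)
  list(trace = cleaned, discard = FALSE, missing_fraction = frac)
}

#' Score a pupil dilation amplitude
#'
#' The amplitude is the maximum of the cleaned trace after stimulus
#' onset minus the mean over a 1 s pre-stimulus baseline window.
#' Negative amplitudes are permitted (the trace may peak before the
#' stimulus) and are flagged.
#'
#' @param cleaned A cleaned pupil `signal_trace` (see
#'   [preprocess_pupil()]); the segment must cover the full 1 s baseline
#'   before stimulus onset.
#' @param baseline_s Baseline window length (default 1 s).
#' @return List with `amplitude`, `valid` (baseline available) and
#'   `nonpositive` flag.
#' @export
score_pupil <- function(cleaned, baseline_s = 1) {
  stopifnot(inherits(cleaned, "signal_trace"))
  if (cleaned$modality != "pupil") stop("score_pupil expects a pupil trace")
  tt <- .trace_times(cleaned)
  s0 <- cleaned$stimulus_onset_s
  base_idx <- which(tt >= s0 - baseline_s & tt < s0)
  if (s0 - baseline_s < -1e-9 || length(base_idx) == 0L)
    return(list(amplitude = NA_real_, valid = FALSE, nonpositive = NA))
  post_idx <- which(tt >= s0)
  if (length(post_idx) == 0L)
    return(list(amplitude = NA_real_, valid = FALSE, nonpositive = NA))
  amp <- max(cleaned$samples[post_idx]) - mean(cleaned$samples[base_idx])
  list(amplitude = amp, valid = TRUE, nonpositive = amp <= 0)
}

#' Log transform for response amplitudes
#'
#' Applies `log(1 + max(a, 0))`: defined at zero (maps 0 to 0), monotone
#' on the nonnegative half-line, and close to the natural log for large
#' amplitudes. Used to improve normality of SCR and pupil amplitudes
#' before inference.
#'
#' @param amplitudes Numeric vector.
#' @return Transformed amplitudes.
#' @examples
#' log_amplitude(c(0, exp(1) - 1))  # 0, 1
#' @export
log_amplitude <- function(amplitudes) {
  if (any(!is.finite(amplitudes))) stop("amplitudes must be finite")
  log1p(pmax(amplitudes, 0))
}

#' Read a signal trace from tab-delimited text
#'
#' Trace files carry columns `time_s` and `value` at a fixed sampling
#' interval; pupil traces may come with a sidecar blink file with
#' columns `start_s` and `end_s`. Proprietary eye-tracker binary formats
#' are not parsed: convert to this plain-text contract first.
#'
#' @param path Trace TSV path.
#' @param modality `"scr"` or `"pupil"`.
#' @param cue_onset_s,stimulus_onset_s Event times within the segment.
#' @param blinks_path Optional blink sidecar TSV path.
#' @return A `signal_trace`.
#' @export
read_signal_trace <- function(path, modality, cue_onset_s,
                              stimulus_onset_s, blinks_path = NULL) {
  df <- utils::read.delim(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("trace file must have columns time_s, value")
  dt <- diff(df$time_s)
  if (length(dt) < 1L || any(dt <= 0)) stop("time_s must be increasing")
  rate <- 1 / stats::median(dt)
  blinks <- NULL
  if (!is.null(blinks_path)) {
    bd <- utils::read.delim(blinks_path)
    if (!all(c("start_s", "end_s") %in% names(bd)))
      stop("blink file must have columns start_s, end_s")
    blinks <- as.matrix(bd[, c("start_s", "end_s")])
  }
  signal_trace(df$value, rate = rate, cue_onset_s = cue_onset_s,
               stimulus_onset_s = stimulus_onset_s, modality = modality,
               blinks = blinks)
}

#' Read or write an amplitude table as tab-delimited text
#'
#' Amplitude tables have one row per scored trial (or per
#' subject-condition cell) with columns `subject`, `block`, `trial`,
#' `condition`, `amplitude` and `valid`; `block`/`trial` may be `NA` for
#' cell-level tables.
#'
#' @param amplitudes Amplitude data frame.
#' @param path File path.
#' @return `read_amplitude_table` returns the data frame;
#'   `write_amplitude_table` returns `path` invisibly.
#' @export
write_amplitude_table <- function(amplitudes, path) {
  utils::write.table(amplitudes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_amplitude_table
#' @export
read_amplitude_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("subject", "condition", "amplitude") %in% names(tab)))
    stop("amplitude table must have columns subject, condition, amplitude")
  tab
}
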