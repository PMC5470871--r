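#' Design configuration for the probabilistic cueing experiment
#'
#' Builds and validates the configuration of a cued heat-pain design in
#' which three visual cues signal the probability of receiving a painful
#' (vs. non-painful warm) stimulus. The default configuration reproduces
#' the canonical task: 4 blocks, 16 trials per cue per block (48 trials
#' per block, 192 in total), pain probabilities of 0.25/0.5/0.75 for the
#' low/medium/high cue, and 12.5% of trials carrying an attention target.
#'
#' @param n_blocks Number of experimental blocks.
#' @param trials_per_cue_per_block Trials per cue within each block.
#' @param pain_probabilities Named numeric vector mapping cue levels
#'   (`low`, `medium`, `high`) to the probability of a painful stimulus.
#'   Each probability times `trials_per_cue_per_block` must be an integer
#'   so that contingencies can be realised exactly, not just in expectation.
#' @param target_fraction Fraction of all trials flagged as attention
#'   targets; the implied target count must divide evenly across cues.
#' @param timing Named list of durations in seconds: `cue_lead` (cue onset
#'   precedes stimulus onset), `stimulus_duration`, `rating_delay_min` /
#'   `rating_delay_max` (uniform jitter before the rating screen),
#'   `rating_duration`, and `iti`.
#' @return An object of class `design_config`.
#' @examples
#' cfg <- design_config()
#' cfg$pain_probabilities
#' @export
design_config <- function(n_blocks = 4L,
                          trials_per_cue_per_block = 16L,
                          pain_probabilities = c(low = 0.25, medium = 0.5, high = 0.75),
                          target_fraction = 0.125,
                          timing = list(cue_lead = 0.3,
                                        stimulus_duration = 1.5,
                                        rating_delay_min = 3,
                                        rating_delay_max = 5,
                                        rating_duration = 2,
                                        iti = 12)) {
  n_blocks <- as.integer(n_blocks)
  trials_per_cue_per_block <- as.integer(trials_per_cue_per_block)
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  if (trials_per_cue_per_block < 0L) stop("trials_per_cue_per_block must be >= 0")
  p <- pain_probabilities
  if (is.null(names(p)) || !setequal(names(p), c("low", "medium", "high")))
    stop("pain_probabilities must be named 'low', 'medium', 'high'")
  p <- p[c("low", "medium", "high")]
  if (any(p <= 0) || any(p >= 1)) stop("pain probabilities must lie in (0, 1)")
  if (anyDuplicated(p)) stop("pain probabilities must be distinct")
  if (trials_per_cue_per_block > 0L) {
    n_pain <- p * trials_per_cue_per_block
    if (any(abs(n_pain - round(n_pain)) > 1e-9))
      stop("each pain probability times trials_per_cue_per_block must be an ",
           "integer; got ", paste(signif(n_pain, 6), collapse = ", "))
  }
  n_cues <- length(p)
  total <- n_blocks * n_cues * trials_per_cue_per_block
  n_targets <- target_fraction * total
  if (abs(n_targets - round(n_targets)) > 1e-9)
    stop("target_fraction times the total trial count must be an integer")
  n_targets <- round(n_targets)
  if (n_targets %% n_cues != 0L)
    stop("target count (", n_targets, ") must divide evenly across the ",
         n_cues, " cues")
  needed <- c("cue_lead", "stimulus_duration", "rating_delay_min",
              "rating_delay_max", "rating_duration", "iti")
  if (!all(needed %in% names(timing)))
    stop("timing must supply: ", paste(needed, collapse = ", "))
  durs <- unlist(timing[needed])
  if (any(durs <= 0)) stop("all durations must be positive")
  if (timing$rating_delay_max < timing$rating_delay_min)
    stop("rating_delay_max must be >= rating_delay_min")
  structure(list(n_blocks = n_blocks,
                 trials_per_cue_per_block = trials_per_cue_per_block,
                 pain_probabilities = p,
                 target_fraction = target_fraction,
                 n_targets = as.integer(n_targets),
                 timing = timing),
            class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat("Probabilistic cueing design configuration\n")
  cat(sprintf("  blocks: %d, trials/cue/block: %d (total %d trials)\n",
              x$n_blocks, x$trials_per_cue_per_block,
              x$n_blocks * 3L * x$trials_per_cue_per_block))
  cat(sprintf("  p(pain | cue): low %.2f, medium %.2f, high %.2f\n",
              x$pain_probabilities["low"], x$pain_probabilities["medium"],
              x$pain_probabilities["high"]))
  cat(sprintf("  targets: %d (%.1f%% of trials)\n",
              x$n_targets, 100 * x$target_fraction))
  invisible(x)
}

# Permute a within-block trial multiset, rejecting runs of more than
# max_run consecutive trials with the same cue.
.permute_with_run_limit <- function(cues, max_run = 4L, max_tries = 1000L) {
  n <- length(cues)
  if (n <= max_run) return(sample.int(n))
  for (i in seq_len(max_tries)) {
    ord <- sample.int(n)
    r <- rle(as.character(cues[ord]))
    if (max(r$lengths) <= max_run) return(ord)
  }
  stop("could not find a cue ordering without runs longer than ", max_run)
}

#' Generate a pseudo-randomised trial plan
#'
#' Lays out every trial of the experiment with exact within-block
#' counterbalancing: within each block and cue, the number of painful
#' stimuli equals that cue's pain probability times the per-cue trial
#' count exactly (counterbalanced sampling, not i.i.d. draws). Trial order
#' is a uniform random permutation within block, constrained to avoid
#' more than 4 consecutive trials with the same cue. Attention targets
#' are split equally across cues, with positions drawn uniformly within
#' each cue's trials. Onset times accumulate cue lead, stimulus duration,
#' a uniform 3-5 s rating delay, the rating period and the inter-trial
#' interval.
#'
#' @param config A [design_config()] object.
#' @param seed Integer seed; the plan is bit-identical for a fixed seed.
#' @return A `data.frame` of class `trial_plan` with columns `block`,
#'   `trial` (0-based within block), `cue`, `p_pain`, `stimulus`
#'   (`"warm"`/`"pain"`), `is_target` and `onset_s` (cue onset, seconds).
#' @examples
#' plan <- generate_design(design_config(), seed = 1)
#' nrow(plan)              # 192
#' table(plan$cue, plan$stimulus)
#' @export
generate_design <- function(config = design_config(), seed = 1L) {
  stopifnot(inherits(config, "design_config"))
  set.seed(as.integer(seed))
  p <- config$pain_probabilities
  m <- config$trials_per_cue_per_block
  cues <- names(p)
  if (m == 0L) {
    plan <- data.frame(block = integer(0), trial = integer(0),
                       cue = character(0), p_pain = numeric(0),
                       stimulus = character(0), is_target = logical(0),
                       onset_s = numeric(0))
    class(plan) <- c("trial_plan", "data.frame")
    return(plan)
  }
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    cue_col <- rep(cues, each = m)
    stim_col <- unlist(lapply(cues, function(cu) {
      n_pain <- round(p[[cu]] * m)
      c(rep("pain", n_pain), rep("warm", m - n_pain))
    }))
    ord <- .permute_with_run_limit(cue_col)
    blocks[[b]] <- data.frame(block = b - 1L,
                              trial = seq_len(3L * m) - 1L,
                              cue = cue_col[ord],
                              p_pain = unname(p[cue_col[ord]]),
                              stimulus = stim_col[ord],
                              stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, blocks)
  # targets: equal count per cue, uniform positions within that cue's trials
  plan$is_target <- FALSE
  per_cue <- config$n_targets %/% length(cues)
  for (cu in cues) {
    idx <- which(plan$cue == cu)
    if (per_cue > 0L)
      plan$is_target[sample(idx, per_cue)] <- TRUE
  }
  tm <- config$timing
  n <- nrow(plan)
  delay <- stats::runif(n, tm$rating_delay_min, tm$rating_delay_max)
  trial_len <- tm$cue_lead + tm$stimulus_duration + delay +
    tm$rating_duration + tm$iti
  plan$onset_s <- c(0, cumsum(trial_len[-n]))
  rownames(plan) <- NULL
  class(plan) <- c("trial_plan", "data.frame")
  plan
}

#' The 2 x 3 condition table
#'
#' The six factorial cells of the design, in the canonical order used by
#' every per-condition vector in this package: warm trials first, pain
#' trials second, each ordered low / medium / high cue. `S` dummy-codes
#' stimulus intensity (0 = warm, 1 = pain) and `P` is the cue-conditional
#' probability of pain.
#'
#' @return A 6-row `data.frame` with columns `condition`, `stimulus`,
#'   `cue`, `S` and `P`.
#' @examples
#' condition_table()
#' @export
condition_table <- function() {
  data.frame(
    condition = c("warm_low", "warm_medium", "warm_high",
                  "pain_low", "pain_medium", "pain_high"),
    stimulus = rep(c("warm", "pain"), each = 3),
    cue = rep(c("low", "medium", "high"), 2),
    S = rep(c(0, 1), each = 3),
    P = rep(c(0.25, 0.5, 0.75), 2),
    stringsAsFactors = FALSE
  )
}

#' Per-subject temperature calibration
#'
#' Fits an ordinary least-squares regression of visual-analogue-scale
#' (VAS, 0-100) intensity ratings on stimulation temperature and inverts
#' it to find the temperature rated as clearly noticeable but not painful
#' (VAS 30) and the temperature rated as painful but tolerable (VAS 75).
#' Both temperatures are capped at a hardware/safety ceiling.
#'
#' @param temperatures Numeric vector of stimulation temperatures
#'   (degrees C); repeats are weighted equally.
#' @param ratings VAS ratings, same length as `temperatures`.
#' @param ceiling Maximum deliverable temperature (default 49.5 C).
#' @return An object of class `calibration_result` with fields `slope`,
#'   `intercept`, `temp_warm` (VAS 30), `temp_pain` (VAS 75) and
#'   `ceiling`.
#' @examples
#' temps <- rep(seq(42, 49.5, by = 0.5), 2)
#' set.seed(1)
#' ratings <- pmin(100, pmax(0, 10 * (temps - 42) + rnorm(length(temps), 0, 4)))
#' calibrate_temperatures(temps, ratings)
#' @export
calibrate_temperatures <- function(temperatures, ratings, ceiling = 49.5) {
  if (length(temperatures) != length(ratings))
    stop("temperatures and ratings must have equal length")
  if (length(unique(temperatures)) < 2L)
    stop("need at least 2 distinct temperatures")
  if (stats::var(temperatures) == 0)
    stop("zero temperature variance")
  fit <- stats::lm.fit(cbind(1, temperatures), ratings)
  intercept <- fit$coefficients[[1]]
  slope <- fit$coefficients[[2]]
  if (!is.finite(slope) || slope <= 0)
    stop("implausible calibration: rating-on-temperature slope is not positive")
  temp_at <- function(vas) min((vas - intercept) / slope, ceiling)
  temp_warm <- temp_at(30)
  temp_pain <- temp_at(75)
  structure(list(slope = slope, intercept = intercept,
                 temp_warm = temp_warm, temp_pain = temp_pain,
                 ceiling = ceiling),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Temperature calibration: rating = %.2f + %.2f * temp\n",
              x$intercept, x$slope))
  cat(sprintf("  warm (VAS 30): %.2f C   pain (VAS 75): %.2f C   (ceiling %.1f C)\n",
              x$temp_warm, x$temp_pain, x$ceiling))
  invisible(x)
}

#' Read or write a trial plan as tab-delimited text
#'
#' Trial plans are exchanged as TSV with header columns `block`, `trial`,
#' `cue`, `p_pain`, `stimulus`, `is_target`, `onset_s`; times in seconds,
#' 0-based trial indices.
#'
#' @param plan A `trial_plan` data frame.
#' @param path File path.
#' @return `read_trial_plan` returns a `trial_plan` data frame;
#'   `write_trial_plan` returns `path` invisibly.
#' @export
write_trial_plan <- function(plan, path) {
  stopifnot(is.data.frame(plan))
  utils::write.table(plan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_plan
#' @export
read_trial_plan <- function(path) {
  plan <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("block", "trial", "cue", "p_pain", "stimulus", "is_target",
              "onset_s")
  if (!all(needed %in% names(plan)))
    stop("trial plan file must have columns: ", paste(needed, collapse = ", "))
  class(plan) <- c("trial_plan", "data.frame")
  plan
}
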