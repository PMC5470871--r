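#' Candidate response models
#'
#' Three families of models compete to explain condition-level response
#' amplitudes in the 2 (stimulus) x 3 (cue) design:
#'
#' * **intensity** — responses track the delivered stimulus only:
#'   `y = w * S`, one free weight.
#' * **additive** — stimulus plus an additive effect of expected pain:
#'   `y = w1 * S + w2 * P`, two free weights.
#' * **predictive coding** — responses sum a top-down prediction and a
#'   bottom-up prediction error: `y = w1 * P + w2 * PE`, two free
#'   weights, with three prediction-error variants (`pain`, `signed`,
#'   `absolute`).
#'
#' Models are identified by the strings `"intensity"`, `"additive"`,
#' `"pc-pain"`, `"pc-signed"`, `"pc-abs"` throughout the package.
#'
#' @param id Model identifier string (see above).
#' @return An object of class `model_family` with fields `id`, `family`,
#'   `pe_kind` (or `NA`), and `n_weights`.
#' @examples
#' model_family("pc-pain")
#' @export
model_family <- function(id = c("intensity", "additive", "pc-pain",
                                "pc-signed", "pc-abs")) {
  id <- match.arg(id)
  family <- switch(id,
                   "intensity" = "intensity",
                   "additive" = "additive",
                   "predictive_coding")
  pe_kind <- switch(id,
                    "pc-pain" = "pain",
                    "pc-signed" = "signed",
                    "pc-abs" = "absolute",
                    NA_character_)
  structure(list(id = id, family = family, pe_kind = pe_kind,
                 n_weights = if (family == "intensity") 1L else 2L),
            class = "model_family")
}

#' All candidate model identifiers
#' @return Character vector of the five model ids.
#' @export
candidate_models <- function() {
  c("intensity", "additive", "pc-pain", "pc-signed", "pc-abs")
}

.as_model <- function(model) {
  if (inherits(model, "model_family")) model else model_family(model)
}

#' Prediction error for a single trial outcome
#'
#' Computes the prediction error given the delivered stimulus and the
#' cue-conditional probability of pain. The `pain` variant is nonzero
#' only for painful outcomes (`1 - P` when `S = 1`, else 0); the
#' `signed` variant is `S - P`; the `absolute` variant is `|S - P|`.
#'
#' @param pe_kind One of `"pain"`, `"signed"`, `"absolute"`.
#' @param S Stimulus code, 0 (warm) or 1 (pain); vectorised.
#' @param P Expected probability of pain, in (0, 1); vectorised.
#' @return Numeric prediction error(s).
#' @examples
#' prediction_error("pain", S = 1, P = 0.25)   # 0.75
#' prediction_error("signed", S = 0, P = 0.75) # -0.75
#' @export
prediction_error <- function(pe_kind, S, P) {
  if (any(P <= 0 | P >= 1)) stop("P must lie in (0, 1)")
  if (any(!S %in% c(0, 1))) stop("S must be 0 (warm) or 1 (pain)")
  switch(match.arg(pe_kind, c("pain", "signed", "absolute")),
         pain = ifelse(S == 1, 1 - P, 0),
         signed = S - P,
         absolute = abs(S - P))
}

#' Per-condition design matrix of a candidate model
#'
#' Evaluates the model's regressors over the six conditions in
#' [condition_table()] order. The intensity model has the single column
#' `S`; the additive model has columns `S` and `P`; predictive-coding
#' models have columns `P` and `PE` with the PE evaluated per variant.
#'
#' @param model A `model_family` or a model id string.
#' @return A 6 x k numeric matrix with labelled columns; rows named by
#'   condition.
#' @examples
#' design_matrix("pc-pain")
#' @export
design_matrix <- function(model) {
  model <- .as_model(model)
  ct <- condition_table()
  X <- switch(model$family,
              intensity = cbind(S = ct$S),
              additive = cbind(S = ct$S, P = ct$P),
              predictive_coding = cbind(
                P = ct$P,
                PE = prediction_error(model$pe_kind, ct$S, ct$P)))
  rownames(X) <- ct$condition
  X
}

#' Predicted per-condition response pattern
#'
#' @param model A `model_family` or id string.
#' @param weights Numeric weight vector; length 1 for the intensity
#'   model, length 2 (`w1`, `w2`) otherwise.
#' @return Named 6-vector of predicted responses in [condition_table()]
#'   order.
#' @examples
#' predict_response("pc-pain", c(1, 2))
#' @export
predict_response <- function(model, weights) {
  model <- .as_model(model)
  X <- design_matrix(model)
  if (length(weights) != ncol(X))
    stop("model '", model$id, "' takes ", ncol(X), " weight(s), got ",
         length(weights))
  drop(X %*% weights)
}

#' Cue-by-stimulus interaction contrast of a response pattern
#'
#' The factorial signature separating predictive coding from the
#' intensity and additive models:
#' `(warm_high - warm_low) - (pain_high - pain_low)`.
#' It is zero for any pattern without cue-stimulus interaction (all
#' intensity, additive and signed-PE patterns) and `0.5 * w2 > 0` for a
#' pain-PE predictive-coding pattern with positive PE weight.
#'
#' @param pattern Numeric 6-vector in [condition_table()] order.
#' @return Scalar contrast value.
#' @examples
#' interaction_contrast(predict_response("pc-pain", c(1, 1)))  # 0.5
#' @export
interaction_contrast <- function(pattern) {
  if (length(pattern) != 6L)
    stop("pattern must have length 6 (condition_table order)")
  unname((pattern[3] - pattern[1]) - (pattern[6] - pattern[4]))
}

#' Export a model design matrix as tab-delimited text
#'
#' @param model Model id or `model_family`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_design <- function(model, path) {
  X <- design_matrix(model)
  df <- data.frame(condition = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
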