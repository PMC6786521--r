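# Fixation-bias indices and standardised regression predictors.

#' Fixation bias from per-trial durations
#'
#' Bias is the proportion of on-stimulus fixation time spent on the left
#' stimulus, `dur_left / (dur_left + dur_right)`; trials with no
#' on-stimulus fixation are missing (not imputed).
#'
#' @param fixations tidy fixation table.
#' @param phase which trial phase to index.
#' @return the phase's rows with an added `bias` column.
#' @export
compute_fixation_bias <- function(fixations, phase = "pre_outcome") {
  fx <- fixations[fixations$phase == phase, ]
  if (any(fx$dur_left < 0 | fx$dur_right < 0 | fx$dur_off < 0))
    stop("fixation durations must be non-negative", call. = FALSE)
  on <- fx$dur_left + fx$dur_right
  fx$bias <- ifelse(on > 0, fx$dur_left / on, NA_real_)
  fx
}

#' First-fixation metrics
#'
#' Per-trial first-fixation location and the left-minus-right difference
#' in first-fixation durations.
#'
#' @param fixations tidy fixation table with first-fixation fields.
#' @param phase trial phase.
#' @return data frame with `subject`, `block`, `trial`, `first_side`, and
#'   `first_dur_diff`.
#' @export
first_fixation_metrics <- function(fixations, phase = "pre_outcome") {
  fx <- fixations[fixations$phase == phase, ]
  data.frame(subject = fx$subject, block = fx$block, trial = fx$trial,
             first_side = fx$first_fix_side,
             first_dur_diff = fx$first_fix_dur_left - fx$first_fix_dur_right)
}

#' Build standardised regression rows for the fixation-bias analyses
#'
#' Computes the left-minus-right differences in value and uncertainty
#' (respecting each trial's side assignment), z-scores every predictor
#' within subject, and attaches the phase's fixation bias as outcome. In
#' the outcome phase, outcome, signed prediction error, and squared
#' prediction error differences are added. Value comes from reported
#' ratings by default or from the model-derived estimate; the
#' uncertainty-like predictor is the model variance or, as a model-free
#' variant, the previous trial's absolute prediction error.
#'
#' @param trials tidy trial table with ratings and sides.
#' @param traj matching trajectory from [run_trajectory()].
#' @param fixations tidy fixation table.
#' @param phase `"pre_outcome"` or `"outcome"`.
#' @param value_source `"rating"` (reported value) or `"model"`.
#' @param uncertainty `"sigma2"` (model variance) or `"pe_magnitude"`
#'   (previous-trial |PE|; drops each block's first trial).
#' @return data frame of regression rows: `subject`, `block`, `trial`,
#'   `y_bias` in (0, 1), `dV`, `dU`, and in the outcome phase `d_outcome`,
#'   `d_pe`, `d_pe2`. Trials without on-stimulus fixation are dropped.
#' @export
build_predictors <- function(trials, traj, fixations,
                             phase = c("pre_outcome", "outcome"),
                             value_source = c("rating", "model"),
                             uncertainty = c("sigma2", "pe_magnitude")) {
  phase <- match.arg(phase)
  value_source <- match.arg(value_source)
  uncertainty <- match.arg(uncertainty)
  if (!"side" %in% names(trials)) stop("side mapping missing", call. = FALSE)
  lr <- .lr_frame(trials, traj)
  fb <- compute_fixation_bias(fixations, phase)
  key <- interaction(lr$subject, lr$block, lr$trial)
  fkey <- interaction(fb$subject, fb$block, fb$trial)
  lr$y_bias <- fb$bias[match(key, fkey)]
  z <- function(x) .zscore_by(x, lr$subject)
  dV_raw <- if (value_source == "rating") lr$val_left - lr$val_right else
    lr$mu_left - lr$mu_right
  if (uncertainty == "sigma2") {
    dU_raw <- lr$sig_left - lr$sig_right
  } else {
    # previous trial's |PE| per side; first trial of each block undefined
    ord <- order(lr$subject, lr$block, lr$trial)
    lr <- lr[ord, ]
    dV_raw <- dV_raw[ord]
    lagged <- function(x) ave(x, interaction(lr$subject, lr$block),
                              FUN = function(v) c(NA, head(v, -1)))
    dU_raw <- lagged(abs(lr$del_left)) - lagged(abs(lr$del_right))
  }
  lr$dV <- z(dV_raw)
  lr$dU <- z(dU_raw)
  keep <- c("subject", "block", "trial", "y_bias", "dV", "dU")
  if (phase == "outcome") {
    lr$d_outcome <- z(lr$out_left - lr$out_right)
    lr$d_pe <- z(lr$del_left - lr$del_right)
    lr$d_pe2 <- z(lr$del_left^2 - lr$del_right^2)
    keep <- c(keep, "d_outcome", "d_pe", "d_pe2")
  }
  out <- lr[, keep]
  out[complete.cases(out), ]
}
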