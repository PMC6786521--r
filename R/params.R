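# Parameter container shared by all belief-update rules.

# canonical parameter order used by the C++ engine
.PAR_NAMES <- c("alpha", "alpha_pos", "alpha_neg", "omega", "k",
                "tau", "tau_pos", "tau_neg", "lam", "gamma", "theta")

.MODEL_IDS <- c("1", "2", "3", "4", "5", "6", "6A", "6B", "6A_bin", "6B_bin")

# parameters actually read by each model (obs_precision is plumbing shared
# by all observation models and is kept separately)
.MODEL_PARS <- list(
  "1"      = c("alpha", "omega"),
  "2"      = c("alpha_pos", "alpha_neg", "omega"),
  "3"      = c("alpha", "k"),
  "4"      = c("alpha", "k"),
  "5"      = c("tau", "lam", "omega"),
  "6"      = c("tau_pos", "tau_neg", "lam", "omega"),
  "6A"     = c("tau_pos", "tau_neg", "lam", "omega", "gamma"),
  "6B"     = c("tau_pos", "tau_neg", "lam", "omega", "theta"),
  "6A_bin" = c("tau_pos", "tau_neg", "lam", "omega", "gamma"),
  "6B_bin" = c("tau_pos", "tau_neg", "lam", "omega", "theta")
)

.model_code <- function(model_id) {
  match(match.arg(as.character(model_id), .MODEL_IDS), .MODEL_IDS)
}

#' Agent parameters for the belief-update models
#'
#' Bundles every free parameter used across the model family. Only the
#' fields relevant to `model_id` are read by the update rules; the rest are
#' ignored. Learning rates `alpha`, `alpha_pos`, `alpha_neg` live in
#' \[-1, 1\] (the fitting range used to detect gambler's-fallacy learners;
#' conventional learning uses \[0, 1\]). `lam` (evidence leak), `k`
#' (learning-rate adaptation) and `gamma` (attention modulation) live in
#' \[0, 1\]; the evidence increments `tau`, `tau_pos`, `tau_neg` and the
#' attention value-bonus weight `theta` are non-negative; `obs_precision`
#' is the positive concentration of the beta observation model for ratings.
#'
#' @param model_id one of `"1"`, `"2"`, `"3"`, `"4"`, `"5"`, `"6"`, `"6A"`,
#'   `"6B"`, `"6A_bin"`, `"6B_bin"`.
#' @param alpha,alpha_pos,alpha_neg learning rates.
#' @param omega cross-stimulus rate (interference from the other stimulus).
#' @param k learning-rate adaptation rate (hybrid models).
#' @param tau,tau_pos,tau_neg beta evidence increments.
#' @param lam evidence leak rate.
#' @param gamma attention-modulation weight (models 6A / 6A_bin).
#' @param theta attention value-bonus weight (models 6B / 6B_bin).
#' @param obs_precision rating-noise concentration.
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(model_id = "6", alpha = 0.3, alpha_pos = 0.3,
                         alpha_neg = 0.3, omega = 0, k = 0.3, tau = 0.5,
                         tau_pos = 0.5, tau_neg = 0.5, lam = 0.1,
                         gamma = 0.5, theta = 0.2, obs_precision = 20) {
  model_id <- match.arg(as.character(model_id), .MODEL_IDS)
  p <- list(model_id = model_id, alpha = alpha, alpha_pos = alpha_pos,
            alpha_neg = alpha_neg, omega = omega, k = k, tau = tau,
            tau_pos = tau_pos, tau_neg = tau_neg, lam = lam, gamma = gamma,
            theta = theta, obs_precision = obs_precision)
  used <- .MODEL_PARS[[model_id]]
  chk <- function(name, lo, hi) {
    if (name %in% used && (p[[name]] < lo || p[[name]] > hi))
      stop(sprintf("parameter '%s' must lie in [%g, %g]", name, lo, hi),
           call. = FALSE)
  }
  chk("alpha", -1, 1); chk("alpha_pos", -1, 1); chk("alpha_neg", -1, 1)
  chk("k", 0, 1); chk("lam", 0, 1); chk("gamma", 0, 1)
  chk("tau", 0, Inf); chk("tau_pos", 0, Inf); chk("tau_neg", 0, Inf)
  chk("theta", 0, Inf); chk("omega", if (model_id %in% c("1", "2")) -1 else 0, Inf)
  if (obs_precision <= 0) stop("obs_precision must be > 0", call. = FALSE)
  structure(p, class = "agent_params")
}

# params list -> 1 x 11 matrix in engine order
.par_matrix <- function(params) {
  stopifnot(inherits(params, "agent_params") || is.list(params))
  matrix(vapply(.PAR_NAMES, function(nm) as.numeric(params[[nm]]), 0),
         nrow = 1, dimnames = list(NULL, .PAR_NAMES))
}

#' @export
print.agent_params <- function(x, ...) {
  used <- .MODEL_PARS[[x$model_id]]
  vals <- vapply(used, function(nm) x[[nm]], 0)
  cat("agent_params, model", x$model_id, "\n")
  print(c(vals, obs_precision = x$obs_precision))
  invisible(x)
}
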