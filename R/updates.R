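# Pure per-trial belief-update rules. These scalar functions define the
# model family; the vectorised C++ engine used for simulation and fitting
# must agree with them exactly (this is asserted in the test suite).

#' Belief state for one stimulus
#'
#' @param V probability estimate in \[0, 1\] (Rescorla-Wagner family).
#' @param A,B shock / no-shock evidence masses (> 0, beta family).
#' @param alpha_t current dynamic learning rate (hybrid family).
#' @param delta last prediction error.
#' @return an object of class `belief_state` with fields `V`, `A`, `B`,
#'   `alpha_t`, `mu`, `sigma2`, `delta`; `mu` and `sigma2` are the beta
#'   mean/variance implied by `A` and `B`.
#' @export
belief_state <- function(V = 0.5, A = 1, B = 1, alpha_t = NA_real_,
                         delta = NA_real_) {
  if (A <= 0 || B <= 0) stop("evidence masses A and B must be > 0", call. = FALSE)
  m <- beta_moments(A, B)
  structure(list(V = V, A = A, B = B, alpha_t = alpha_t,
                 mu = m[["mu"]], sigma2 = m[["sigma2"]], delta = delta),
            class = "belief_state")
}

#' Per-trial input for one stimulus
#'
#' `outcome_x` is the binary shock outcome for the stimulus being updated,
#' `outcome_y` the outcome for the concurrently presented stimulus.
#' Fixation proportions are fractions of the relevant outcome-phase duration
#' spent on each stimulus (their sum is at most 1; the remainder is
#' off-stimulus gaze).
#'
#' @param outcome_x,outcome_y binary outcomes in \{0, 1\}.
#' @param fixation_x,fixation_y fixation proportions in \[0, 1\].
#' @return an object of class `trial_input`.
#' @export
trial_input <- function(outcome_x, outcome_y, fixation_x = NA_real_,
                        fixation_y = NA_real_) {
  stopifnot(outcome_x %in% c(0, 1), outcome_y %in% c(0, 1))
  if (!is.na(fixation_x) && !is.na(fixation_y)) {
    if (fixation_x < 0 || fixation_y < 0 || fixation_x + fixation_y > 1 + 1e-12)
      stop("fixation proportions must be non-negative and sum to at most 1",
           call. = FALSE)
  }
  structure(list(outcome_x = outcome_x, outcome_y = outcome_y,
                 fixation_x = fixation_x, fixation_y = fixation_y),
            class = "trial_input")
}

#' Mean and variance of a beta distribution from its evidence masses
#'
#' @param A,B positive evidence masses.
#' @return named vector with `mu = A / (A + B)` and
#'   `sigma2 = A * B / ((A + B)^2 * (A + B + 1))`.
#' @export
beta_moments <- function(A, B) {
  if (any(A <= 0) || any(B <= 0))
    stop("evidence masses A and B must be > 0", call. = FALSE)
  n <- A + B
  c(mu = A / n, sigma2 = A * B / (n^2 * (n + 1)))
}

.clip01 <- function(x) pmin(1, pmax(0, x))
.AB_FLOOR <- 1e-6

.set_beta <- function(state, A, B, delta) {
  A <- max(A, .AB_FLOOR); B <- max(B, .AB_FLOOR)
  m <- beta_moments(A, B)
  state$A <- A; state$B <- B
  state$mu <- m[["mu"]]; state$sigma2 <- m[["sigma2"]]
  state$V <- m[["mu"]]; state$delta <- delta
  state
}

#' Rescorla-Wagner update (models 1 and 2)
#'
#' Updates the probability estimate `V` by the own-stimulus prediction
#' error weighted by `alpha` (model 1) or by `alpha_pos`/`alpha_neg`
#' depending on the sign of the prediction error (model 2), plus the
#' cross-stimulus term `omega * (outcome_y - V)` applied in the same step.
#' The result is clipped to \[0, 1\] since it represents a probability.
#'
#' @param state a [belief_state()].
#' @param inp a [trial_input()].
#' @param params an [agent_params()] with `model_id` `"1"` or `"2"`.
#' @return the updated `belief_state` (with `delta` stored).
#' @export
rw_update <- function(state, inp, params) {
  if (!params$model_id %in% c("1", "2"))
    stop("rw_update requires model_id '1' or '2'", call. = FALSE)
  delta <- inp$outcome_x - state$V
  a <- if (params$model_id == "1") params$alpha else
    if (delta > 0) params$alpha_pos else params$alpha_neg
  state$V <- .clip01(state$V + a * delta + params$omega * (inp$outcome_y - state$V))
  state$mu <- state$V
  state$delta <- delta
  state
}

#' Hybrid Rescorla-Wagner / Pearce-Hall update (models 3 and 4)
#'
#' The value update uses the current dynamic learning rate `alpha_t`, which
#' is then adapted towards the squared (model 3) or absolute (model 4)
#' prediction error at rate `k`.
#'
#' @inheritParams rw_update
#' @export
hybrid_update <- function(state, inp, params) {
  if (!params$model_id %in% c("3", "4"))
    stop("hybrid_update requires model_id '3' or '4'", call. = FALSE)
  if (params$k < 0 || params$k > 1) stop("k must lie in [0, 1]", call. = FALSE)
  if (is.na(state$alpha_t)) state$alpha_t <- .clip01(params$alpha)
  delta <- inp$outcome_x - state$V
  state$V <- .clip01(state$V + state$alpha_t * delta)
  state$mu <- state$V
  mag <- if (params$model_id == "3") delta^2 else abs(delta)
  state$alpha_t <- state$alpha_t + params$k * (mag - state$alpha_t)
  state$delta <- delta
  state
}

#' Leaky beta update (models 5 and 6)
#'
#' Both evidence masses decay by the leak `1 - lam`, then the mass matching
#' the outcome grows by `tau` (model 5) or by `tau_pos` / `tau_neg`
#' (model 6, shock vs no-shock), with the other stimulus's outcome
#' contributing via `omega`. Masses are floored at a small positive
#' constant and the beta mean/variance are recomputed.
#'
#' @inheritParams rw_update
#' @export
beta_update <- function(state, inp, params) {
  if (!params$model_id %in% c("5", "6"))
    stop("beta_update requires model_id '5' or '6'", call. = FALSE)
  if (params$lam < 0 || params$lam > 1) stop("lam must lie in [0, 1]", call. = FALSE)
  tp <- if (params$model_id == "5") params$tau else params$tau_pos
  tn <- if (params$model_id == "5") params$tau else params$tau_neg
  delta <- inp$outcome_x - state$mu
  A <- (1 - params$lam) * state$A + tp * inp$outcome_x + params$omega * inp$outcome_y
  B <- (1 - params$lam) * state$B + tn * (1 - inp$outcome_x) +
    params$omega * (1 - inp$outcome_y)
  .set_beta(state, A, B, delta)
}

#' Attention-modulated leaky beta update (model 6A)
#'
#' The own-stimulus evidence increments are weighted by
#' `pi = fixation_x * gamma + (1 - gamma)`, so full attention gives a full
#' update and withdrawn attention shrinks it towards `1 - gamma`. The
#' cross-stimulus term is weighted by the fixation proportion on the other
#' stimulus.
#'
#' @inheritParams rw_update
#' @export
attention_update_6A <- function(state, inp, params) {
  if (params$model_id != "6A")
    stop("attention_update_6A requires model_id '6A'", call. = FALSE)
  if (params$gamma < 0 || params$gamma > 1)
    stop("gamma must lie in [0, 1]", call. = FALSE)
  pi_x <- inp$fixation_x * params$gamma + (1 - params$gamma)
  delta <- inp$outcome_x - state$mu
  A <- (1 - params$lam) * state$A + params$tau_pos * pi_x * inp$outcome_x +
    params$omega * inp$fixation_y * inp$outcome_y
  B <- (1 - params$lam) * state$B + params$tau_neg * pi_x * (1 - inp$outcome_x) +
    params$omega * inp$fixation_y * (1 - inp$outcome_y)
  .set_beta(state, A, B, delta)
}

#' Attention value-bonus leaky beta update (model 6B)
#'
#' Adds `theta * fixation_x` directly to the shock-evidence mass, so
#' attended stimuli acquire extra aversive value, while the cross-stimulus
#' term is weighted by fixation on the other stimulus.
#'
#' @inheritParams rw_update
#' @export
attention_update_6B <- function(state, inp, params) {
  if (params$model_id != "6B")
    stop("attention_update_6B requires model_id '6B'", call. = FALSE)
  if (params$theta < 0) stop("theta must be >= 0", call. = FALSE)
  delta <- inp$outcome_x - state$mu
  A <- (1 - params$lam) * state$A + params$tau_pos * inp$outcome_x +
    params$omega * inp$fixation_y * inp$outcome_y + params$theta * inp$fixation_x
  B <- (1 - params$lam) * state$B + params$tau_neg * (1 - inp$outcome_x) +
    params$omega * inp$fixation_y * (1 - inp$outcome_y)
  .set_beta(state, A, B, delta)
}

#' Binary-fixation variants of the attention-coupled updates
#'
#' `"6A_bin"` sets the update weight `pi` to 1 when the stimulus wins the
#' fixation comparison and to `1 - (fixation_x - fixation_y) * gamma`
#' otherwise. Note the second branch exceeds 1 when the fixation
#' difference is negative; the expression is applied as defined by the
#' model rather than silently corrected. `"6B_bin"` adds
#' `max(0, fixation_x - fixation_y) * theta` to the shock-evidence mass
#' and, unlike model 6B, leaves the cross-stimulus term unweighted by
#' fixation.
#'
#' @inheritParams rw_update
#' @param variant `"6A_bin"` or `"6B_bin"`.
#' @export
binary_attention_update <- function(state, inp, params,
                                    variant = c("6A_bin", "6B_bin")) {
  variant <- match.arg(variant)
  if (params$model_id != variant)
    stop("params$model_id must match the requested variant", call. = FALSE)
  delta <- inp$outcome_x - state$mu
  if (variant == "6A_bin") {
    if (params$gamma < 0 || params$gamma > 1)
      stop("gamma must lie in [0, 1]", call. = FALSE)
    pi_x <- if (inp$fixation_x > inp$fixation_y) 1 else
      1 - (inp$fixation_x - inp$fixation_y) * params$gamma
    A <- (1 - params$lam) * state$A + params$tau_pos * pi_x * inp$outcome_x +
      params$omega * inp$fixation_y * inp$outcome_y
    B <- (1 - params$lam) * state$B + params$tau_neg * pi_x * (1 - inp$outcome_x) +
      params$omega * inp$fixation_y * (1 - inp$outcome_y)
  } else {
    if (params$theta < 0) stop("theta must be >= 0", call. = FALSE)
    bonus <- max(0, inp$fixation_x - inp$fixation_y) * params$theta
    A <- (1 - params$lam) * state$A + params$tau_pos * inp$outcome_x +
      params$omega * inp$outcome_y + bonus
    B <- (1 - params$lam) * state$B + params$tau_neg * (1 - inp$outcome_x) +
      params$omega * (1 - inp$outcome_y)
  }
  .set_beta(state, A, B, delta)
}

#' Apply the update rule selected by `params$model_id`
#'
#' Dispatches one trial of belief updating to the matching rule.
#'
#' @inheritParams rw_update
#' @export
update_belief <- function(state, inp, params) {
  switch(params$model_id,
         "1" = , "2" = rw_update(state, inp, params),
         "3" = , "4" = hybrid_update(state, inp, params),
         "5" = , "6" = beta_update(state, inp, params),
         "6A" = attention_update_6A(state, inp, params),
         "6B" = attention_update_6B(state, inp, params),
         "6A_bin" = binary_attention_update(state, inp, params, "6A_bin"),
         "6B_bin" = binary_attention_update(state, inp, params, "6B_bin"),
         stop("unknown model_id", call. = FALSE))
}
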