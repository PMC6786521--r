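# The gaze regressions: hierarchical beta regression of fixation bias,
# WAIC comparison of regression variants, the estimation-error (attention
# to learning) regression, and the parameter-influence regression.

.REG_SPECS <- list(
  pre_outcome = c("dV", "dU"),
  outcome = c("dV", "dU", "d_outcome", "d_pe", "d_pe2"),
  no_uncertainty = c("dV"),
  pe_magnitude = c("dV", "dU"),
  model_value = c("dV", "dU"))

#' Hierarchical beta regression of fixation bias
#'
#' Regresses the per-trial fixation bias (logit link, beta likelihood with
#' per-subject precision) on standardised predictors, with subject-level
#' coefficients drawn from group-level normal distributions. Outcomes are
#' compressed away from \{0, 1\} before fitting.
#'
#' @param rows regression rows from [build_predictors()] (the
#'   `pe_magnitude` and `model_value` variants differ only in how the rows
#'   were built).
#' @param spec which predictor set to use.
#' @param sampler list of MCMC settings (chains, warmup, iterations, thin,
#'   prior scale), e.g. [sampler_config()].
#' @param seed integer seed.
#' @return an `lb_reg_fit`; `summary()` gives group posterior means and
#'   95% HPD intervals.
#' @export
fit_fixation_beta_regression <- function(rows,
                                         spec = c("pre_outcome", "outcome",
                                                  "no_uncertainty",
                                                  "pe_magnitude",
                                                  "model_value"),
                                         sampler = sampler_config(
                                           n_chains = 2, n_warmup = 500,
                                           n_iter = 500),
                                         seed = 1) {
  spec <- match.arg(spec)
  pred <- .REG_SPECS[[spec]]
  miss <- setdiff(pred, names(rows))
  if (length(miss)) stop("rows lack predictors: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (length(unique(rows$subject)) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  y <- .squeeze01(rows$y_bias, nrow(rows))
  if (any(y <= 0 | y >= 1)) stop("bias outside (0,1) after compression",
                                 call. = FALSE)
  X <- cbind(intercept = 1, as.matrix(rows[, pred, drop = FALSE]))
  .hier_reg_mcmc(y, X, rows$subject, family = "beta",
                 n_chains = sampler$n_chains, n_warmup = sampler$n_warmup,
                 n_iter = sampler$n_iter, thin = sampler$thin, seed = seed,
                 prior_scale = sampler$prior_scale)
}

#' Compare two regression fits by WAIC
#'
#' @param fit_full,fit_reduced `lb_reg_fit` objects fitted to the same
#'   observations.
#' @return list with each WAIC, the difference (full minus reduced, so
#'   negative favours the full model), its SE, and the preferred model.
#' @export
compare_regression_waic <- function(fit_full, fit_reduced) {
  if (length(fit_full$y) != length(fit_reduced$y) ||
      max(abs(fit_full$y - fit_reduced$y)) > 1e-12)
    stop("fits must share identical observations", call. = FALSE)
  ll_f <- .reg_pointwise_ll(fit_full)
  ll_r <- .reg_pointwise_ll(fit_reduced)
  wf <- .waic_from_ll(ll_f); wr <- .waic_from_ll(ll_r)
  dpt <- wf$pointwise - wr$pointwise
  list(waic_full = wf$waic, waic_reduced = wr$waic,
       diff = wf$waic - wr$waic,
       diff_se = sqrt(length(dpt) * var(dpt)),
       preferred = if (wf$waic <= wr$waic) "full" else "reduced")
}

# Standardised rows for the estimation-error regression: outcome is the
# reported-minus-true probability for each stimulus on each trial; the
# lagged regressors (previous trial's outcome and outcome-phase fixation
# proportion on the estimated stimulus) drop each block's first trial.
.estimation_error_rows <- function(trials, fixations) {
  wide <- .trials_wide(trials)
  f <- .fixation_wide(fixations, wide)
  lag_mat <- function(m) {
    out <- matrix(NA_real_, nrow(m), ncol(m))
    same <- c(FALSE, wide$block[-1] == wide$block[-wide$T])
    out[, which(same)] <- m[, which(same) - 1L]
    out
  }
  o1l <- lag_mat(wide$o1); o2l <- lag_mat(wide$o2)
  f1l <- lag_mat(f$f1); f2l <- lag_mat(f$f2)
  flat <- function(m) as.vector(t(m))
  base <- data.frame(subject = rep(wide$subjects, each = wide$T),
                     block = rep(wide$block, wide$S),
                     trial = rep(wide$trial, wide$S))
  one <- function(y, p_own, p_oth, out_l, fix_l) {
    cbind(base, data.frame(y = flat(y), p_own = flat(p_own),
                           p_oth = flat(p_oth), outc = flat(out_l),
                           prev_fix = flat(fix_l)))
  }
  rows <- rbind(one(wide$y1 - wide$p1, wide$p1, wide$p2, o1l, f1l),
                one(wide$y2 - wide$p2, wide$p2, wide$p1, o2l, f2l))
  rows <- rows[complete.cases(rows), ]
  rows$x_p_own <- .zscore_by(rows$p_own, rows$subject)
  rows$x_p_other <- .zscore_by(rows$p_oth, rows$subject)
  rows$x_outcome <- .zscore_by(rows$outc, rows$subject)
  rows$x_prev_fix <- .zscore_by(rows$prev_fix, rows$subject)
  rows[order(rows$subject, rows$block, rows$trial), ]
}

#' Hierarchical regression of estimation error on previous-trial attention
#'
#' The outcome is the estimation error (reported minus true shock
#' probability) per stimulus per trial; regressors are the standardised
#' true probabilities of both stimuli, the previous trial's outcome, and
#' the proportion of the previous trial's outcome phase spent fixating the
#' estimated stimulus. Gaussian likelihood on the error scale; each
#' block's first trial is dropped by the lag alignment.
#'
#' @param trials,fixations tidy cohort tables; ignored when `rows` is
#'   supplied.
#' @param rows prebuilt rows (e.g. from [simulate_estimation_errors()]).
#' @param sampler MCMC settings as in [fit_fixation_beta_regression()].
#' @param seed integer seed.
#' @return an `lb_reg_fit`.
#' @export
fit_estimation_error_regression <- function(trials = NULL, fixations = NULL,
                                            rows = NULL,
                                            sampler = sampler_config(
                                              n_chains = 2, n_warmup = 500,
                                              n_iter = 500),
                                            seed = 1) {
  if (is.null(rows)) rows <- .estimation_error_rows(trials, fixations)
  X <- cbind(intercept = 1, p_own = rows$x_p_own, p_other = rows$x_p_other,
             outcome = rows$x_outcome, prev_fix = rows$x_prev_fix)
  .hier_reg_mcmc(rows$y, X, rows$subject, family = "gaussian",
                 n_chains = sampler$n_chains, n_warmup = sampler$n_warmup,
                 n_iter = sampler$n_iter, thin = sampler$thin, seed = seed,
                 prior_scale = sampler$prior_scale)
}

#' Bayesian regression of mean value estimates on learning parameters
#'
#' One row per subject: the across-trial mean probability rating is
#' regressed on the standardised update parameters `tau_pos`, `tau_neg`
#' and the leak `lam`. With a flat prior the posterior is the standard
#' conjugate normal-inverse-gamma around the least-squares solution, so
#' posterior means coincide with the maximum-likelihood estimates.
#'
#' @param params data frame with one row per subject containing `tau_pos`,
#'   `tau_neg`, `lam` (fitted or true values).
#' @param mean_ratings per-subject mean probability rating, aligned with
#'   `params`.
#' @param n_draws posterior draws.
#' @param seed integer seed.
#' @return list with a coefficient table (posterior mean and 95% HPD) and
#'   the posterior draws.
#' @export
fit_parameter_influence_regression <- function(params, mean_ratings,
                                               n_draws = 4000, seed = 1) {
  n <- length(mean_ratings)
  if (n < 5) stop("need at least 5 subjects", call. = FALSE)
  zs <- function(x) if (sd(x) == 0) rep(0, length(x)) else
    (x - mean(x)) / sd(x)
  X <- cbind(intercept = 1, tau_pos = zs(params$tau_pos),
             tau_neg = zs(params$tau_neg), lam = zs(params$lam))
  X <- X[, c(TRUE, apply(X[, -1, drop = FALSE], 2, sd) > 0), drop = FALSE]
  y <- mean_ratings
  qr_x <- qr(X)
  bhat <- qr.coef(qr_x, y)
  rss <- sum(qr.resid(qr_x, y)^2)
  k <- ncol(X)
  XtX_inv <- chol2inv(qr.R(qr_x))
  set.seed(seed)
  sig2 <- rss / rgamma(n_draws, (n - k) / 2, 1 / 2)  # scaled inverse-chi^2
  z <- matrix(rnorm(n_draws * k), n_draws, k)
  draws <- t(bhat + t(z %*% chol(XtX_inv)) * rep(sqrt(sig2), each = k))
  colnames(draws) <- colnames(X)
  iv <- .hpd(draws)
  list(coef = data.frame(predictor = colnames(X), mean = colMeans(draws),
                         ml = bhat, lower = iv[, "lower"],
                         upper = iv[, "upper"], row.names = NULL),
       draws = draws)
}
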