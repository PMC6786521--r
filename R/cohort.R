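# Synthetic cohort generator: simulated agents producing probability
# ratings and phase-aggregated fixation durations with the statistical
# structure the downstream analyses assume.

# default group-level distributions for agent parameters (location on the
# natural scale, spread on the sampling scale). tau_pos > tau_neg encodes
# the learning bias towards shock outcomes; lam gives a mild recency
# weighting; omega a small cross-stimulus interference; obs_precision a
# rating noise SD of roughly 0.1 at mid-scale.
.DEFAULT_GROUP <- list(
  alpha = list(mean = 0.3, sd = 0.1, scale = "unit"),
  alpha_pos = list(mean = 0.35, sd = 0.1, scale = "unit"),
  alpha_neg = list(mean = 0.25, sd = 0.1, scale = "unit"),
  k = list(mean = 0.3, sd = 0.1, scale = "unit"),
  tau = list(mean = 0.6, sd = 0.25, scale = "log"),
  tau_pos = list(mean = 0.8, sd = 0.25, scale = "log"),
  tau_neg = list(mean = 0.4, sd = 0.25, scale = "log"),
  lam = list(mean = 0.36, sd = 0.4, scale = "logit"),
  omega = list(mean = 0.05, sd = 0.4, scale = "log"),
  gamma = list(mean = 0.5, sd = 0.5, scale = "logit"),
  theta = list(mean = 0.3, sd = 0.3, scale = "log"),
  obs_precision = list(mean = 20, sd = 0.3, scale = "log"))

# generative regression coefficients used to couple fixation bias to the
# learned quantities (logit scale for beta-distributed biases); intercepts
# are 0 (no side bias)
.DEFAULT_GEN_BETAS <- list(
  pre = c(intercept = 0, value = 0.13, uncertainty = -0.004),
  out = c(intercept = 0, value = 0.10, uncertainty = -0.004, outcome = 0.10,
          pe = 0.07, pe2 = 0.03),
  coef_sd_pre = c(0.10, 0.05, 0.05),
  coef_sd_out = c(0.10, 0.05, 0.05, 0.05, 0.05, 0.05),
  precision = c(pre = 20, out = 60))

.draw_param <- function(spec, n) {
  switch(spec$scale,
         log = exp(rnorm(n, log(spec$mean), spec$sd)),
         logit = plogis(rnorm(n, qlogis(spec$mean), spec$sd)),
         unit = pmin(0.95, pmax(0.02, rnorm(n, spec$mean, spec$sd))))
}

#' Simulate probability ratings from a belief trajectory
#'
#' Ratings are beta-distributed around the model's current estimate
#' (`mu_pre`, the belief held at rating time) with concentration
#' `obs_precision`; an infinite precision returns the estimate exactly.
#'
#' @param traj trajectory from [run_trajectory()].
#' @param obs_precision positive concentration of the rating noise.
#' @param seed integer seed.
#' @return `traj` with an added `rating` column in (0, 1).
#' @export
simulate_ratings <- function(traj, obs_precision = 20, seed = 1) {
  if (any(obs_precision <= 0)) stop("obs_precision must be > 0", call. = FALSE)
  set.seed(seed)
  mu <- .guard_mu(traj$mu_pre)
  if (is.infinite(obs_precision[1]) && length(obs_precision) == 1) {
    traj$rating <- mu
  } else {
    phi <- rep(obs_precision, length.out = nrow(traj))
    traj$rating <- pmin(1 - 1e-4, pmax(1e-4, rbeta(nrow(traj), mu * phi,
                                                   (1 - mu) * phi)))
  }
  traj
}

# per-trial left/right frame of values (ratings), model uncertainty,
# outcomes and prediction errors, used both to generate fixations and to
# build regression predictors
.lr_frame <- function(trials, traj) {
  key <- c("subject", "block", "trial")
  tj <- traj[order(traj$subject, traj$block, traj$trial, traj$stimulus), ]
  tr <- trials[order(trials$subject, trials$block, trials$trial,
                     trials$stimulus), ]
  if (nrow(tj) != nrow(tr)) stop("trials and trajectory misaligned", call. = FALSE)
  s1 <- tr$stimulus == 1
  left1 <- tr$side[s1] == "left"
  pickLR <- function(x) {
    x1 <- x[s1]; x2 <- x[!s1]
    list(left = ifelse(left1, x1, x2), right = ifelse(left1, x2, x1))
  }
  val <- pickLR(tr$rating)
  mu <- pickLR(tj$mu_pre)
  sig <- pickLR(tj$sigma2_pre)
  outc <- pickLR(tr$outcome)
  del <- pickLR(tj$delta)
  p <- pickLR(tr$p_shock)
  data.frame(tr[s1, key],
             val_left = val$left, val_right = val$right,
             mu_left = mu$left, mu_right = mu$right,
             sig_left = sig$left, sig_right = sig$right,
             out_left = outc$left, out_right = outc$right,
             del_left = del$left, del_right = del$right,
             p_left = p$left, p_right = p$right,
             stim_left = ifelse(left1, 1, 2))
}

#' Simulate phase-aggregated fixation tables
#'
#' Fixation bias (left-stimulus share of on-stimulus time) is drawn from a
#' beta distribution whose logit mean is a linear function of within-subject
#' standardised left-right differences: value and uncertainty in the
#' pre-outcome phase; value, uncertainty, outcome, prediction error and
#' squared prediction error in the outcome phase. Subject-level
#' coefficients scatter around the group values. Off-stimulus time is
#' drawn Beta(2, 8) per trial (mean 0.2, below the 80% exclusion threshold
#' by construction).
#'
#' @param trials tidy trial table including `rating` and `side`.
#' @param traj matching trajectory from [run_trajectory()].
#' @param gen_betas list with elements `pre`, `out` (group coefficients,
#'   intercept first), `coef_sd_pre`, `coef_sd_out`, `precision`; see
#'   package defaults.
#' @param seed integer seed.
#' @param off_shape shape parameters of the off-stimulus beta draw.
#' @return tidy fixation table: one row per subject x block x trial x
#'   phase with durations in ms and first-fixation fields.
#' @export
simulate_fixations <- function(trials, traj, gen_betas = .DEFAULT_GEN_BETAS,
                               seed = 1, off_shape = c(2, 8)) {
  set.seed(seed)
  lr <- .lr_frame(trials, traj)
  n <- nrow(lr)
  sub <- lr$subject
  z <- function(x) .zscore_by(x, sub)
  dval <- z(lr$val_left - lr$val_right)
  dsig <- z(ifelse(is.na(lr$sig_left), 0, lr$sig_left) -
            ifelse(is.na(lr$sig_right), 0, lr$sig_right))
  dout <- z(lr$out_left - lr$out_right)
  dpe <- z(lr$del_left - lr$del_right)
  dpe2 <- z(lr$del_left^2 - lr$del_right^2)
  subjects <- unique(sub)
  draw_coefs <- function(mu, sds) {
    m <- t(vapply(seq_along(subjects),
                  function(i) rnorm(length(mu), mu, sds), numeric(length(mu))))
    rownames(m) <- as.character(subjects)
    m
  }
  b_pre <- draw_coefs(gen_betas$pre, gen_betas$coef_sd_pre)
  b_out <- draw_coefs(gen_betas$out, gen_betas$coef_sd_out)
  si <- match(as.character(sub), rownames(b_pre))
  eta_pre <- b_pre[si, 1] + b_pre[si, 2] * dval + b_pre[si, 3] * dsig
  eta_out <- b_out[si, 1] + b_out[si, 2] * dval + b_out[si, 3] * dsig +
    b_out[si, 4] * dout + b_out[si, 5] * dpe + b_out[si, 6] * dpe2
  # per-phase bias precision (a scalar applies to both phases); the longer
  # outcome phase yields steadier bias measurements, hence its higher default
  phi_all <- rep(gen_betas$precision, length.out = 2)
  names(phi_all) <- c("pre_outcome", "outcome")
  draw_bias <- function(eta, phi) {
    m <- .guard_mu(plogis(eta))
    pmin(1 - 1e-6, pmax(1e-6, rbeta(n, m * phi, (1 - m) * phi)))
  }
  one_phase <- function(phase, eta, tot_range) {
    bias <- draw_bias(eta, phi_all[[phase]])
    tot <- runif(n, tot_range[1], tot_range[2])
    off <- rbeta(n, off_shape[1], off_shape[2])
    on <- tot * (1 - off)
    fdur <- runif(n, 200, 500)
    data.frame(subject = lr$subject, block = lr$block, trial = lr$trial,
               phase = phase,
               dur_left = bias * on, dur_right = (1 - bias) * on,
               dur_off = tot * off,
               first_fix_side = ifelse(rbinom(n, 1, bias) == 1, "left", "right"),
               first_fix_dur_left = bias * fdur,
               first_fix_dur_right = (1 - bias) * fdur)
  }
  out <- rbind(one_phase("pre_outcome", eta_pre, c(1000, 2000)),
               one_phase("outcome", eta_out, c(2000, 5000)))
  attr(out, "gen_coefs") <- list(pre = b_pre, out = b_out)
  out[order(out$subject, out$block, out$trial, out$phase), ]
}

#' Simulate estimation errors from the attention-to-learning regression
#'
#' Draws per-trial estimation errors (reported minus true shock
#' probability) from the hierarchical linear model with standardised
#' predictors: the true shock probability of the estimated stimulus and of
#' the other stimulus, the trial outcome, and the proportion of the
#' previous trial's outcome phase spent fixating the estimated stimulus.
#'
#' @param trials,fixations tidy cohort tables (see [generate_cohort()]).
#' @param gen_betas named group coefficients `(intercept, p_own, p_other,
#'   outcome, prev_fix)`.
#' @param coef_sd subject-level SDs of the coefficients.
#' @param resid_sd residual SD of the error.
#' @param seed integer seed.
#' @return regression rows as built by the fitting side, with the
#'   simulated `y` in place of the observed estimation error.
#' @export
simulate_estimation_errors <- function(trials, fixations,
                                       gen_betas = c(intercept = 0,
                                                     p_own = -0.18,
                                                     p_other = -0.02,
                                                     outcome = 0.05,
                                                     prev_fix = 0.017),
                                       coef_sd = c(0.02, 0.02, 0.01, 0.02, 0.01),
                                       resid_sd = 0.15, seed = 1) {
  rows <- .estimation_error_rows(trials, fixations)
  set.seed(seed)
  subjects <- unique(rows$subject)
  b <- t(vapply(seq_along(subjects),
                function(i) rnorm(length(gen_betas), gen_betas, coef_sd),
                numeric(length(gen_betas))))
  si <- match(rows$subject, subjects)
  X <- cbind(1, rows$x_p_own, rows$x_p_other, rows$x_outcome, rows$x_prev_fix)
  rows$y <- rowSums(X * b[si, ]) + rnorm(nrow(rows), 0, resid_sd)
  attr(rows, "gen_coefs") <- b
  rows
}

#' Generate a synthetic cohort of simulated subjects
#'
#' Draws subject-level parameters from group distributions, simulates each
#' subject's task (schedule, outcomes, belief trajectory, noisy ratings,
#' fixation tables), and optionally plants pathological agents that the
#' exclusion rules should catch: gambler's-fallacy learners (negative
#' learning rate), limited responders (ratings only in \{0, 0.5, 1\}), and
#' subjects fixating off-stimulus more than 80% of the time.
#'
#' For the attention-coupled models (6A/6B and binary variants) fixations
#' are generated from a first-pass model-6 trajectory and then used as the
#' attention input of the final trajectory, since fixations must exist
#' before they can modulate learning.
#'
#' @param n_subjects number of simulated subjects.
#' @param model_id generating model.
#' @param group named list overriding entries of the default group-level
#'   parameter distributions.
#' @param schedule_config list of arguments for [generate_schedule()].
#' @param gen_betas fixation-coupling coefficients, see
#'   [simulate_fixations()].
#' @param frac_gambler,frac_limited,frac_off_gaze probabilities with which
#'   each subject is replaced by the corresponding pathological agent.
#' @param seed integer seed; cohorts are reproducible byte-for-byte.
#' @return an object of class `lb_cohort`: list with `trials`,
#'   `fixations`, `params` (true parameters and pathology flags),
#'   `model_id`, `seed`.
#' @export
generate_cohort <- function(n_subjects = 48, model_id = "6", group = list(),
                            schedule_config = list(),
                            gen_betas = .DEFAULT_GEN_BETAS,
                            frac_gambler = 0, frac_limited = 0,
                            frac_off_gaze = 0, seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  model_id <- match.arg(as.character(model_id), .MODEL_IDS)
  gspec <- utils::modifyList(.DEFAULT_GROUP, group)
  set.seed(seed)
  pars <- as.data.frame(lapply(gspec, function(sp) .draw_param(sp, n_subjects)))
  pars$subject <- seq_len(n_subjects)
  pars$gambler <- runif(n_subjects) < frac_gambler
  pars$limited <- runif(n_subjects) < frac_limited
  pars$off_gaze <- runif(n_subjects) < frac_off_gaze
  pars$alpha[pars$gambler] <- -0.4
  attn <- .model_code(model_id) >= 7

  trials_all <- vector("list", n_subjects)
  fix_all <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    ssd <- .child_seed(seed, s)
    sched <- do.call(generate_schedule, c(schedule_config, list(seed = ssd)))
    tr <- sample_outcomes(sched, seed = ssd + 1L)
    tr$subject <- s
    p_s <- agent_params(model_id = if (pars$gambler[s]) "1" else model_id,
                        alpha = pars$alpha[s], alpha_pos = pars$alpha_pos[s],
                        alpha_neg = pars$alpha_neg[s], omega = pars$omega[s],
                        k = pars$k[s], tau = pars$tau[s],
                        tau_pos = pars$tau_pos[s], tau_neg = pars$tau_neg[s],
                        lam = pars$lam[s], gamma = pars$gamma[s],
                        theta = pars$theta[s],
                        obs_precision = pars$obs_precision[s])
    # pass 1: belief trajectory without attention coupling, used to couple
    # fixations to value/uncertainty
    p_base <- p_s
    if (attn) p_base$model_id <- "6"
    tj0 <- run_trajectory(tr, p_base)
    put_ratings <- function(tr, tjr) {
      tjr$rating[match(interaction(tr$block, tr$trial, tr$stimulus),
                       interaction(tjr$block, tjr$trial, tjr$stimulus))]
    }
    tr$rating <- put_ratings(tr, simulate_ratings(tj0, pars$obs_precision[s],
                                                  seed = ssd + 3L))
    fx <- simulate_fixations(tr, tj0, gen_betas, seed = ssd + 2L)
    # final trajectory (attention models consume the simulated fixations)
    if (attn) {
      tj <- run_trajectory(tr, p_s, fixations = fx)
      tr$rating <- put_ratings(tr, simulate_ratings(tj, pars$obs_precision[s],
                                                    seed = ssd + 3L))
    }
    if (pars$limited[s])
      tr$rating <- c(0, 0.5, 1)[max.col(-abs(outer(tr$rating, c(0, 0.5, 1), "-")))]
    if (pars$off_gaze[s]) {
      tot <- fx$dur_left + fx$dur_right + fx$dur_off
      offp <- runif(nrow(fx), 0.85, 0.95)
      onl <- fx$dur_left / (fx$dur_left + fx$dur_right)
      fx$dur_off <- tot * offp
      fx$dur_left <- tot * (1 - offp) * onl
      fx$dur_right <- tot * (1 - offp) * (1 - onl)
    }
    trials_all[[s]] <- tr
    fix_all[[s]] <- fx
  }
  trials <- do.call(rbind, trials_all)
  fixations <- do.call(rbind, fix_all)
  trials <- trials[, c("subject", setdiff(names(trials), "subject"))]
  structure(list(trials = trials, fixations = fixations, params = pars,
                 model_id = model_id, seed = seed),
            class = "lb_cohort")
}

#' @export
print.lb_cohort <- function(x, ...) {
  cat("synthetic cohort:", length(unique(x$trials$subject)), "subjects,",
      max(x$trials$block), "blocks x", max(x$trials$trial),
      "trials, generating model", x$model_id, "\n")
  invisible(x)
}
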