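# Hierarchical Bayesian fitting of the learning models to rating data.
#
# Subject-level parameters live on unconstrained sampling scales (logit for
# unit-interval and [-1, 1] parameters, log for positive ones) and are drawn
# from group-level normal distributions. The rating likelihood is a beta
# observation model around the trajectory's current estimate, with a free
# per-subject precision. Sampling mirrors the regression engine: adaptive
# per-subject Metropolis sweeps (one parameter at a time, all subjects in
# parallel through the vectorised trajectory engine), conjugate group means
# and Metropolis group SDs.

# sampling-scale definition per parameter
.par_transforms <- function(model_id, omega_zero = FALSE) {
  rw <- model_id %in% c("1", "2")
  tab <- list(
    alpha = if (rw) "sym" else "unit",
    alpha_pos = "sym", alpha_neg = "sym",
    omega = if (rw) "unit" else "log",
    k = "unit", tau = "log", tau_pos = "log", tau_neg = "log",
    lam = "unit", gamma = "unit", theta = "log")
  pars <- .MODEL_PARS[[model_id]]
  if (omega_zero) pars <- setdiff(pars, "omega")
  tab[pars]
}

.to_natural <- function(x, scale) {
  switch(scale, unit = plogis(x), sym = 2 * plogis(x) - 1, log = exp(x))
}

# weakly-informative prior locations on the sampling scale
.PRIOR_LOC <- c(alpha = 0, alpha_pos = 0, alpha_neg = 0, omega = -3,
                k = qlogis(0.3), tau = log(0.5), tau_pos = log(0.5),
                tau_neg = log(0.5), lam = qlogis(0.15), gamma = 0,
                theta = log(0.2), lphi = log(10))

#' Sampler configuration
#'
#' Defaults follow the fitting protocol of the model family's original use
#' (2 chains, 1000 warmup then 3000 kept iterations); reduced settings are
#' appropriate for simulation studies and tests.
#'
#' @param n_chains,n_warmup,n_iter,thin MCMC settings.
#' @param prior_scale multiplier on all prior SDs (sensitivity analyses).
#' @return a list of sampler settings.
#' @export
sampler_config <- function(n_chains = 2, n_warmup = 1000, n_iter = 3000,
                           thin = max(1L, as.integer(n_iter %/% 500)),
                           prior_scale = 1) {
  list(n_chains = n_chains, n_warmup = n_warmup, n_iter = n_iter,
       thin = thin, prior_scale = prior_scale)
}

# per-subject log-likelihood of ratings given cached trajectory means
.rating_ll <- function(y1, y2, m1, m2, phi) {
  g1 <- .guard_mu(m1); g2 <- .guard_mu(m2)
  rowSums(dbeta(y1, g1 * phi, (1 - g1) * phi, log = TRUE)) +
    rowSums(dbeta(y2, g2 * phi, (1 - g2) * phi, log = TRUE))
}

.learn_chain <- function(wide, f, model_id, trans, sampler, prior, chain_seed,
                         init_x, init_lphi) {
  set.seed(chain_seed)
  S <- wide$S
  pnames <- names(trans)
  P <- length(pnames)
  x <- init_x + matrix(rnorm(S * P, 0, 0.05), S, P,
                       dimnames = list(NULL, pnames))
  lphi <- init_lphi + rnorm(S, 0, 0.05)
  y1 <- wide$cy1; y2 <- wide$cy2

  natural_mat <- function(x) {
    pm <- matrix(0, S, length(.PAR_NAMES), dimnames = list(NULL, .PAR_NAMES))
    for (p in pnames) pm[, p] <- .to_natural(x[, p], trans[[p]])
    pm
  }
  run <- function(x) {
    tr <- .traj_engine(model_id, natural_mat(x), wide$o1, wide$o2, wide$block,
                       f$f1, f$f2, full = FALSE)
    list(m1 = tr$mu_pre1, m2 = tr$mu_pre2)
  }
  mu <- run(x)
  phi <- exp(lphi)
  ll_s <- .rating_ll(y1, y2, mu$m1, mu$m2, phi)
  mu_g <- colMeans(x); sigma_g <- pmax(apply(x, 2, sd), 0.05)
  mu_phi <- mean(lphi); sigma_phi <- max(sd(lphi), 0.05)

  lstep <- matrix(log(0.15), S, P); lstep_phi <- rep(log(0.15), S)
  lstep_sig <- rep(log(0.3), P + 1)
  n_keep <- floor(sampler$n_iter / sampler$thin)
  out <- list(x = array(NA_real_, c(n_keep, S, P)),
              lphi = matrix(NA_real_, n_keep, S),
              mu_g = matrix(NA_real_, n_keep, P),
              sigma_g = matrix(NA_real_, n_keep, P))

  for (it in seq_len(sampler$n_warmup + sampler$n_iter)) {
    adapting <- it <= sampler$n_warmup
    g <- if (adapting) min(0.25, 3 / sqrt(it)) else 0
    for (j in seq_len(P)) {
      xn <- x
      xn[, j] <- x[, j] + exp(lstep[, j]) * rnorm(S)
      mun <- run(xn)
      ll_new <- .rating_ll(y1, y2, mun$m1, mun$m2, phi)
      lr <- ll_new - ll_s +
        dnorm(xn[, j], mu_g[j], sigma_g[j], log = TRUE) -
        dnorm(x[, j], mu_g[j], sigma_g[j], log = TRUE)
      acc <- log(runif(S)) < lr
      if (any(acc)) {
        x[acc, j] <- xn[acc, j]
        mu$m1[acc, ] <- mun$m1[acc, ]; mu$m2[acc, ] <- mun$m2[acc, ]
        ll_s[acc] <- ll_new[acc]
      }
      if (adapting) lstep[, j] <- lstep[, j] + g * (acc - 0.44)
    }
    # observation-precision sweep (no trajectory rerun needed)
    lp_new <- lphi + exp(lstep_phi) * rnorm(S)
    ll_new <- .rating_ll(y1, y2, mu$m1, mu$m2, exp(lp_new))
    lr <- ll_new - ll_s +
      dnorm(lp_new, mu_phi, sigma_phi, log = TRUE) -
      dnorm(lphi, mu_phi, sigma_phi, log = TRUE)
    acc <- log(runif(S)) < lr
    if (any(acc)) {
      lphi[acc] <- lp_new[acc]; ll_s[acc] <- ll_new[acc]
      phi <- exp(lphi)
    }
    if (adapting) lstep_phi <- lstep_phi + g * (acc - 0.44)
    # group level
    upd_sigma <- function(sig, vals, m, j) {
      lp <- function(s) sum(dnorm(vals, m, s, log = TRUE)) +
        dnorm(s, 0, prior$sigma_half, log = TRUE) + log(s)
      sp <- sig * exp(exp(lstep_sig[j]) * rnorm(1))
      ok <- log(runif(1)) < lp(sp) - lp(sig)
      if (adapting) lstep_sig[j] <<- lstep_sig[j] + g * ((if (ok) 1 else 0) - 0.44)
      if (ok) sp else sig
    }
    for (j in seq_len(P)) {
      m0 <- prior$loc[pnames[j]]
      pv <- 1 / (S / sigma_g[j]^2 + 1 / prior$loc_sd^2)
      mu_g[j] <- rnorm(1, pv * (sum(x[, j]) / sigma_g[j]^2 + m0 / prior$loc_sd^2),
                       sqrt(pv))
      sigma_g[j] <- upd_sigma(sigma_g[j], x[, j], mu_g[j], j)
    }
    pv <- 1 / (S / sigma_phi^2 + 1 / prior$loc_sd^2)
    mu_phi <- rnorm(1, pv * (sum(lphi) / sigma_phi^2 +
                               prior$loc["lphi"] / prior$loc_sd^2), sqrt(pv))
    sigma_phi <- upd_sigma(sigma_phi, lphi, mu_phi, P + 1)

    if (!adapting) {
      j <- it - sampler$n_warmup
      if (j %% sampler$thin == 0) {
        i <- j %/% sampler$thin
        out$x[i, , ] <- x; out$lphi[i, ] <- lphi
        out$mu_g[i, ] <- mu_g; out$sigma_g[i, ] <- sigma_g
      }
    }
  }
  out
}

# crude but effective initialisation: score random parameter draws around
# the prior and keep the best per subject
.learn_init <- function(wide, f, model_id, trans, prior, seed, n_try = 60) {
  set.seed(seed)
  S <- wide$S
  pnames <- names(trans)
  best_x <- matrix(rep(prior$loc[pnames], each = S), S, length(pnames),
                   dimnames = list(NULL, pnames))
  best_lphi <- rep(prior$loc[["lphi"]], S)
  natural <- function(x) {
    pm <- matrix(0, S, length(.PAR_NAMES), dimnames = list(NULL, .PAR_NAMES))
    for (p in pnames) pm[, p] <- .to_natural(x[, p], trans[[p]])
    pm
  }
  score <- function(x, lphi) {
    tr <- .traj_engine(model_id, natural(x), wide$o1, wide$o2, wide$block,
                       f$f1, f$f2, full = FALSE)
    .rating_ll(wide$cy1, wide$cy2, tr$mu_pre1, tr$mu_pre2, exp(lphi))
  }
  best <- score(best_x, best_lphi)
  for (i in seq_len(n_try)) {
    x <- best_x * 0 + rep(rnorm(length(pnames), prior$loc[pnames], 0.8),
                          each = S)
    x <- x + matrix(rnorm(S * length(pnames), 0, 0.4), S, length(pnames))
    lphi <- rnorm(S, prior$loc[["lphi"]], 0.5)
    sc <- score(x, lphi)
    better <- sc > best
    if (any(better)) {
      best_x[better, ] <- x[better, ]
      best_lphi[better] <- lphi[better]
      best[better] <- sc[better]
    }
  }
  list(x = best_x, lphi = best_lphi)
}

#' Fit a learning model hierarchically to rating data
#'
#' @param trials tidy trial table with `subject`, `block`, `trial`,
#'   `stimulus`, `outcome`, `rating` (and `side` when fixations are used).
#' @param model_id which update rule to fit.
#' @param fixations tidy fixation table (required for attention-coupled
#'   models).
#' @param sampler a [sampler_config()].
#' @param omega_zero fix the cross-stimulus rate at zero (reduced-model
#'   comparison).
#' @param seed integer seed.
#' @param compute_loglik cache the pointwise log-likelihood matrix (needed
#'   for WAIC) at fit time.
#' @return an object of class `lb_fit` with posterior draws of subject- and
#'   group-level parameters, WAIC, and convergence diagnostics
#'   (split-chain R-hat and effective sample sizes for the group level;
#'   lack of convergence is flagged, never silent).
#' @export
fit_model <- function(trials, model_id = "6", fixations = NULL,
                      sampler = sampler_config(), omega_zero = FALSE,
                      seed = 1, compute_loglik = TRUE) {
  model_id <- match.arg(as.character(model_id), .MODEL_IDS)
  wide <- .trials_wide(trials)
  if (is.null(wide$y1)) stop("trial table must contain ratings", call. = FALSE)
  n_obs <- 2 * wide$S * wide$T
  wide$cy1 <- matrix(.squeeze01(wide$y1, n_obs), wide$S, wide$T)
  wide$cy2 <- matrix(.squeeze01(wide$y2, n_obs), wide$S, wide$T)
  f <- list(f1 = NULL, f2 = NULL)
  if (.model_code(model_id) >= 7) {
    if (is.null(fixations))
      stop("attention-coupled models require a fixation table", call. = FALSE)
    f <- .fixation_wide(fixations, wide)
  }
  trans <- .par_transforms(model_id, omega_zero)
  prior <- list(loc = .PRIOR_LOC, loc_sd = 1.5 * sampler$prior_scale,
                sigma_half = 1 * sampler$prior_scale)
  init <- .learn_init(wide, f, model_id, trans, prior, .child_seed(seed, 99))
  chains <- lapply(seq_len(sampler$n_chains), function(ch) {
    .learn_chain(wide, f, model_id, trans, sampler, prior,
                 .child_seed(seed, ch), init$x, init$lphi)
  })
  fit <- structure(list(model_id = model_id, omega_zero = omega_zero,
                        chains = chains, trans = trans, wide = wide, f = f,
                        subjects = wide$subjects,
                        settings = sampler, seed = seed),
                   class = "lb_fit")
  fit$diagnostics <- .fit_diagnostics(fit)
  if (compute_loglik) {
    fit$pointwise_loglik <- .fit_pointwise_ll(fit)
    fit$waic <- .waic_from_ll(fit$pointwise_loglik)
  }
  fit
}

# pooled subject-level draws on the natural scale: array draws x S x P
.fit_natural_draws <- function(fit) {
  pnames <- names(fit$trans)
  xs <- lapply(fit$chains, `[[`, "x")
  d1 <- vapply(xs, function(x) dim(x)[1], 0)
  out <- array(NA_real_, c(sum(d1), dim(xs[[1]])[2], length(pnames)),
               dimnames = list(NULL, NULL, pnames))
  at <- 0
  for (x in xs) {
    for (j in seq_along(pnames))
      out[at + seq_len(dim(x)[1]), , j] <- .to_natural(x[, , j],
                                                       fit$trans[[pnames[j]]])
    at <- at + dim(x)[1]
  }
  out
}

.fit_lphi_draws <- function(fit) {
  do.call(rbind, lapply(fit$chains, `[[`, "lphi"))
}

#' Posterior summaries of subject- and group-level parameters
#'
#' Group-level values are posterior means of the across-subject average of
#' the natural-scale parameters.
#'
#' @param object an `lb_fit`.
#' @param ... unused.
#' @return list with `subject` (data frame of per-subject posterior means)
#'   and `group` (data frame with posterior mean and 95% HPD of the group
#'   average per parameter).
#' @export
summary.lb_fit <- function(object, ...) {
  arr <- .fit_natural_draws(object)
  pnames <- dimnames(arr)[[3]]
  subj <- as.data.frame(apply(arr, c(2, 3), mean))
  names(subj) <- pnames
  subj <- cbind(subject = object$subjects, subj,
                obs_precision = colMeans(exp(.fit_lphi_draws(object))))
  gd <- apply(arr, c(1, 3), mean)   # draws x P group average
  iv <- .hpd(gd)
  group <- data.frame(parameter = pnames, mean = colMeans(gd),
                      lower = iv[, "lower"], upper = iv[, "upper"],
                      row.names = NULL)
  list(subject = subj, group = group)
}

#' @export
print.lb_fit <- function(x, ...) {
  cat("hierarchical fit of model", x$model_id,
      if (x$omega_zero) "(omega fixed at 0)" else "", "\n")
  print(summary(x)$group, digits = 3)
  if (!is.null(x$waic)) cat(sprintf("WAIC %.1f (SE %.1f)\n", x$waic$waic,
                                    x$waic$se))
  d <- x$diagnostics
  cat(sprintf("max R-hat %.3f, group-level ESS %.0f\n", d$max_rhat, d$ess))
  if (is.finite(d$max_rhat) && d$max_rhat > 1.1)
    cat("warning: chains have not converged (R-hat > 1.1)\n")
  invisible(x)
}

.fit_diagnostics <- function(fit) {
  ml <- coda::mcmc.list(lapply(fit$chains, function(ch) coda::mcmc(ch$mu_g)))
  ess <- try(sum(coda::effectiveSize(ml)), silent = TRUE)
  rhat <- if (length(fit$chains) > 1) {
    gd <- try(coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE),
              silent = TRUE)
    if (inherits(gd, "try-error")) NA_real_ else max(gd$psrf[, 1], na.rm = TRUE)
  } else NA_real_
  list(max_rhat = rhat, ess = if (inherits(ess, "try-error")) NA_real_ else ess,
       converged = !is.finite(rhat) || rhat < 1.1)
}

# pointwise log-likelihood (draws x observations); observation order is
# (stimulus 1 trials, stimulus 2 trials) within subject, subjects stacked
.fit_pointwise_ll <- function(fit, max_draws = 400) {
  arr <- .fit_natural_draws(fit)
  lphi <- .fit_lphi_draws(fit)
  nd <- dim(arr)[1]
  keep <- unique(round(seq(1, nd, length.out = min(max_draws, nd))))
  wide <- fit$wide
  pnames <- dimnames(arr)[[3]]
  ll <- matrix(NA_real_, length(keep), 2 * wide$S * wide$T)
  for (i in seq_along(keep)) {
    d <- keep[i]
    pm <- matrix(0, wide$S, length(.PAR_NAMES),
                 dimnames = list(NULL, .PAR_NAMES))
    for (p in pnames) pm[, p] <- arr[d, , p]
    tr <- .traj_engine(fit$model_id, pm, wide$o1, wide$o2, wide$block,
                       fit$f$f1, fit$f$f2, full = FALSE)
    phi <- exp(lphi[d, ])
    g1 <- .guard_mu(tr$mu_pre1); g2 <- .guard_mu(tr$mu_pre2)
    l1 <- dbeta(wide$cy1, g1 * phi, (1 - g1) * phi, log = TRUE)
    l2 <- dbeta(wide$cy2, g2 * phi, (1 - g2) * phi, log = TRUE)
    ll[i, ] <- as.vector(t(cbind(l1, l2)))
  }
  ll
}

#' Compare fitted models by WAIC
#'
#' @param fits named list of `lb_fit` (or `lb_reg_fit`) objects fitted to
#'   the same observations.
#' @return data frame sorted by WAIC (lower is better).
#' @export
compare_models <- function(fits) {
  w <- lapply(fits, function(f) if (!is.null(f$waic)) f$waic else
    compute_waic(f))
  out <- data.frame(model = names(fits),
                    waic = vapply(w, `[[`, 0, "waic"),
                    se = vapply(w, `[[`, 0, "se"),
                    p_waic = vapply(w, `[[`, 0, "p_waic"),
                    row.names = NULL)
  out[order(out$waic), ]
}
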