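# Hierarchical regressions: maximum-likelihood and Gibbs-sampler oracles,
# WAIC comparison behaviour, the parameter-influence regression, the
# interference statistic, and split-half stability.

# maximum-likelihood beta regression (logit link, common precision) used as
# an independent oracle
ml_beta_reg <- function(y, X) {
  nll <- function(par) {
    eta <- X %*% par[seq_len(ncol(X))]
    m <- plogis(eta)
    phi <- exp(par[ncol(X) + 1])
    -sum(dbeta(y, m * phi, (1 - m) * phi, log = TRUE))
  }
  fit <- optim(c(rep(0, ncol(X)), log(5)), nll, method = "BFGS",
               hessian = TRUE)
  se <- sqrt(diag(solve(fit$hessian)))
  list(coef = fit$par[seq_len(ncol(X))], se = se[seq_len(ncol(X))])
}

test_that("beta-regression posterior matches a maximum-likelihood oracle", {
  set.seed(21)
  S <- 3; n <- 1500
  subj <- rep(1:S, each = n)
  X <- cbind(1, rnorm(S * n), rnorm(S * n))
  b_true <- c(0.1, 0.25, -0.1)
  m <- plogis(X %*% b_true)
  y <- rbeta(S * n, m * 12, (1 - m) * 12)
  y <- leakybeta:::.squeeze01(y)
  rows <- data.frame(subject = subj, y_bias = y, dV = X[, 2], dU = X[, 3])
  fit <- fit_fixation_beta_regression(rows, "pre_outcome",
                                      sampler = sampler_config(1, 400, 500),
                                      seed = 3)
  ml <- ml_beta_reg(y, X)
  g <- summary(fit)
  for (k in 1:3)
    expect_lt(abs(g$mean[k] - ml$coef[k]), 2 * ml$se[k] + 0.01)
})

test_that("beta-regression posterior matches an independent Gibbs sampler", {
  skip_if_not_installed("rjags")
  set.seed(22)
  S <- 6; n <- 40
  subj <- rep(1:S, each = n)
  bs <- cbind(rnorm(S, 0, 0.1), rnorm(S, 0.3, 0.1))
  X <- cbind(1, rnorm(S * n))
  m <- plogis(rowSums(X * bs[subj, ]))
  y <- leakybeta:::.squeeze01(rbeta(S * n, m * 10, (1 - m) * 10))
  rows <- data.frame(subject = subj, y_bias = y, dV = X[, 2])
  fit <- fit_fixation_beta_regression(rows, "no_uncertainty",
                                      sampler = sampler_config(2, 600, 800),
                                      seed = 4)
  g <- summary(fit)
  code <- "model {
    for (i in 1:N) {
      y[i] ~ dbeta(m[i] * phi[subj[i]], (1 - m[i]) * phi[subj[i]])
      logit(m[i]) <- b[subj[i], 1] + b[subj[i], 2] * x[i]
    }
    for (s in 1:S) {
      for (k in 1:2) { b[s, k] ~ dnorm(mu_b[k], pow(sigma_b[k], -2)) }
      lphi[s] ~ dnorm(mu_d, pow(sigma_d, -2))
      phi[s] <- exp(lphi[s])
    }
    for (k in 1:2) {
      mu_b[k] ~ dnorm(0, pow(2.5, -2))
      sigma_b[k] ~ dnorm(0, 1) T(0,)
    }
    mu_d ~ dnorm(log(10), pow(1.5, -2))
    sigma_d ~ dnorm(0, 1) T(0,)
  }"
  jm <- rjags::jags.model(textConnection(code),
                          data = list(y = y, x = X[, 2], subj = subj,
                                      N = length(y), S = S),
                          n.chains = 2, n.adapt = 500, quiet = TRUE,
                          inits = list(
                            list(.RNG.name = "base::Mersenne-Twister",
                                 .RNG.seed = 1),
                            list(.RNG.name = "base::Mersenne-Twister",
                                 .RNG.seed = 2)))
  stats::update(jm, 500)
  sm <- rjags::coda.samples(jm, "mu_b", n.iter = 2000)
  ref <- summary(sm)$statistics
  for (k in 1:2) {
    tol <- 3 * ref[k, "SD"] / sqrt(S) + 4 * ref[k, "Time-series SE"] + 0.01
    expect_lt(abs(g$mean[k] - ref[k, "Mean"]), tol)
  }
})

test_that("estimation-error regression matches an OLS oracle on shared data", {
  set.seed(23)
  co <- generate_cohort(6, "6", seed = 101)
  rows <- simulate_estimation_errors(co$trials, co$fixations,
                                     coef_sd = rep(1e-6, 5), seed = 5)
  fit <- fit_estimation_error_regression(rows = rows,
                                         sampler = sampler_config(1, 300, 400),
                                         seed = 6)
  ols <- lm(y ~ x_p_own + x_p_other + x_outcome + x_prev_fix, data = rows)
  se <- coef(summary(ols))[, "Std. Error"]
  g <- summary(fit)
  expect_lt(max(abs(g$mean - coef(ols))), max(2 * se, 0.01))
})

test_that("uncertainty-free model comparison follows the generative truth", {
  set.seed(24)
  co <- generate_cohort(8, "6", seed = 102)
  pl <- lapply(1:8, function(s) {
    p <- agent_params("6")
    for (nm in c("tau_pos", "tau_neg", "lam", "omega"))
      p[[nm]] <- co$params[[nm]][s]
    p
  })
  tj <- run_trajectory(co$trials, pl)
  sc <- sampler_config(1, 300, 400)
  # truly zero uncertainty effect in every subject: reduced model preferred
  gb0 <- leakybeta:::.DEFAULT_GEN_BETAS
  gb0$pre["uncertainty"] <- 0
  gb0$coef_sd_pre[3] <- 1e-6
  fx0 <- simulate_fixations(co$trials, tj, gb0, seed = 6)
  rows0 <- build_predictors(co$trials, tj, fx0, "pre_outcome")
  f_full <- fit_fixation_beta_regression(rows0, "pre_outcome", sampler = sc,
                                         seed = 7)
  f_red <- fit_fixation_beta_regression(rows0, "no_uncertainty", sampler = sc,
                                        seed = 8)
  cmp0 <- compare_regression_waic(f_full, f_red)
  expect_equal(cmp0$preferred, "reduced")
  # identical fits give a zero difference
  self <- compare_regression_waic(f_full, f_full)
  expect_equal(self$diff, 0)
  # strong true uncertainty effect: full model preferred
  gbU <- leakybeta:::.DEFAULT_GEN_BETAS
  gbU$pre["uncertainty"] <- 0.4
  fxU <- simulate_fixations(co$trials, tj, gbU, seed = 9)
  rowsU <- build_predictors(co$trials, tj, fxU, "pre_outcome")
  fU_full <- fit_fixation_beta_regression(rowsU, "pre_outcome", sampler = sc,
                                          seed = 10)
  fU_red <- fit_fixation_beta_regression(rowsU, "no_uncertainty",
                                         sampler = sc, seed = 11)
  expect_equal(compare_regression_waic(fU_full, fU_red)$preferred, "full")
  # mismatched rows are rejected
  expect_error(compare_regression_waic(f_full, fU_red), "identical")
})

test_that("parameter-influence regression has the expected sign pattern", {
  co <- generate_cohort(48, "6", seed = 103)
  mr <- aggregate(co$trials$rating, by = list(subject = co$trials$subject),
                  FUN = mean)
  fit <- fit_parameter_influence_regression(co$params, mr$x, seed = 12)
  cf <- fit$coef
  expect_gt(cf$mean[cf$predictor == "tau_pos"], 0)
  expect_lt(cf$lower[cf$predictor == "tau_pos"], cf$mean[2])
  expect_lt(cf$mean[cf$predictor == "tau_neg"], 0)
  expect_lt(abs(cf$mean[cf$predictor == "lam"]), 0.05)   # near-null leak effect
  # flat-prior posterior means equal the least-squares solution
  X <- cbind(1, scale(co$params$tau_pos), scale(co$params$tau_neg),
             scale(co$params$lam))
  expect_equal(unname(cf$ml), unname(qr.coef(qr(X), mr$x)), tolerance = 1e-10)
  expect_lt(max(abs(cf$mean - cf$ml)), 0.005)
  # constructed case: only tau_pos varies
  set.seed(13)
  prm <- data.frame(tau_pos = runif(30, 0.3, 1.2), tau_neg = 0.4, lam = 0.3)
  yy <- 0.3 + 0.2 * scale(prm$tau_pos)[, 1] + rnorm(30, 0, 0.01)
  f2 <- fit_parameter_influence_regression(prm, yy, seed = 14)
  expect_gt(f2$coef$lower[f2$coef$predictor == "tau_pos"], 0)
  expect_error(fit_parameter_influence_regression(prm[1:4, ], yy[1:4]),
               "at least 5")
})

test_that("interference statistic detects cross-stimulus learning", {
  co0 <- generate_cohort(10, "6",
                         group = list(omega = list(mean = 1e-6, sd = 0.01,
                                                   scale = "log")),
                         seed = 104)
  i0 <- interference_statistic(co0$trials, n_perm = 400, seed = 15)
  # the stable/volatile asymmetry makes label exchange only approximate, so
  # the null check asserts the statistic is not deep in the tail
  expect_gt(i0$p_value, 0.01)
  coO <- generate_cohort(10, "6",
                         group = list(omega = list(mean = 0.2, sd = 0.2,
                                                   scale = "log")),
                         seed = 105)
  iO <- interference_statistic(coO$trials, n_perm = 400,
                               omega = coO$params$omega, seed = 16)
  expect_lt(iO$p_value, 0.05)
  # across a cohort spanning omega values, the statistic tracks omega
  coM <- generate_cohort(24, "6",
                         group = list(omega = list(mean = 0.08, sd = 0.9,
                                                   scale = "log")),
                         seed = 106)
  iM <- interference_statistic(coM$trials, n_perm = 200,
                               omega = coM$params$omega, seed = 17)
  expect_gt(iM$omega_correlation, 0.3)
})

test_that("coefficients are stable across split halves", {
  co <- generate_cohort(10, "6", seed = 107)
  pl <- lapply(1:10, function(s) {
    p <- agent_params("6")
    for (nm in c("tau_pos", "tau_neg", "lam", "omega"))
      p[[nm]] <- co$params[[nm]][s]
    p
  })
  tj <- run_trajectory(co$trials, pl)
  rows <- build_predictors(co$trials, tj, co$fixations, "pre_outcome")
  sc <- sampler_config(1, 300, 400)
  f_odd <- fit_fixation_beta_regression(rows[rows$trial %% 2 == 1, ],
                                        "pre_outcome", sampler = sc, seed = 18)
  f_even <- fit_fixation_beta_regression(rows[rows$trial %% 2 == 0, ],
                                         "pre_outcome", sampler = sc, seed = 19)
  so <- summary(f_odd); se <- summary(f_even)
  k <- so$predictor == "dV"
  expect_lt(se$mean[k], so$upper[k] + (so$upper[k] - so$lower[k]))
  expect_gt(se$mean[k], so$lower[k] - (so$upper[k] - so$lower[k]))
})
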