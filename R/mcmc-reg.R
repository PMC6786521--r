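# Hierarchical Bayesian regression engine for beta-distributed proportions
# (logit link) and Gaussian outcomes. Subject-level coefficient vectors are
# drawn from group-level normal distributions; dispersion (beta precision /
# residual SD) is log-normal across subjects. Sampling is blocked adaptive
# Metropolis-within-Gibbs, vectorised across subjects: each sweep proposes
# one coefficient for every subject simultaneously and accepts per subject,
# group means are updated by conjugate Gibbs steps, and group SDs by
# random-walk Metropolis on the log scale. Warmup adapts per-subject
# proposal scales towards a 0.44 acceptance rate.

.rowsum_by <- function(v, subj, S) {
  as.vector(rowsum(v, subj, reorder = TRUE))[seq_len(S)]
}

.hier_reg_chain <- function(y, X, subj, family, n_warmup, n_iter, thin,
                            prior, chain_seed, init) {
  set.seed(chain_seed)
  N <- length(y); S <- max(subj); K <- ncol(X)
  b <- init$b + matrix(rnorm(S * K, 0, 0.02), S, K)
  ldisp <- init$ldisp + rnorm(S, 0, 0.05)
  mu_b <- colMeans(b); sigma_b <- pmax(apply(b, 2, sd), 0.02)
  mu_d <- mean(ldisp); sigma_d <- max(sd(ldisp), 0.05)

  loglik_vec <- if (family == "beta") {
    function(eta, disp) {
      m <- .guard_mu(plogis(eta))
      dbeta(y, m * disp, (1 - m) * disp, log = TRUE)
    }
  } else {
    function(eta, disp) dnorm(y, eta, disp, log = TRUE)
  }
  eta <- rowSums(X * b[subj, , drop = FALSE])
  disp <- exp(ldisp)[subj]
  ll_s <- .rowsum_by(loglik_vec(eta, disp), subj, S)

  # per-subject design-aligned proposal directions: Cholesky factors of
  # (X_s' X_s + ridge)^-1 so joint steps move along collinear ridges
  Lchol <- lapply(seq_len(S), function(s) {
    Xs <- X[subj == s, , drop = FALSE]
    xtx <- crossprod(Xs) + diag(1e-8 + 1e-6 * max(diag(crossprod(Xs))), K)
    t(chol(chol2inv(chol(xtx))))
  })
  # pooled geometry for global (group-level) translations along the ridge
  Lglob <- {
    xtx <- crossprod(X) + diag(1e-8 + 1e-6 * max(diag(crossprod(X))), K)
    t(chol(chol2inv(chol(xtx)))) * sqrt(S)
  }
  lstep_b <- matrix(log(0.1), S, K)
  lstep_joint <- rep(log(1), S)
  lstep_glob <- log(1)
  lstep_d <- rep(log(0.2), S)
  lstep_sig <- rep(log(0.3), K + 1)

  n_keep <- floor(n_iter / thin)
  out <- list(mu_b = matrix(NA_real_, n_keep, K),
              sigma_b = matrix(NA_real_, n_keep, K),
              mu_d = numeric(n_keep), sigma_d = numeric(n_keep),
              b = array(NA_real_, c(n_keep, S, K)),
              ldisp = matrix(NA_real_, n_keep, S))
  acc_b <- matrix(0, S, K); n_tot <- 0
  half_sd <- prior$sigma_half

  for (it in seq_len(n_warmup + n_iter)) {
    adapting <- it <= n_warmup
    g <- if (adapting) min(0.25, 3 / sqrt(it)) else 0
    for (k in seq_len(K)) {
      prop <- b[, k] + exp(lstep_b[, k]) * rnorm(S)
      eta_new <- eta + X[, k] * (prop - b[, k])[subj]
      ll_new <- .rowsum_by(loglik_vec(eta_new, disp), subj, S)
      lr <- ll_new - ll_s +
        dnorm(prop, mu_b[k], sigma_b[k], log = TRUE) -
        dnorm(b[, k], mu_b[k], sigma_b[k], log = TRUE)
      acc <- log(runif(S)) < lr
      if (any(acc)) {
        rows <- acc[subj]
        eta[rows] <- eta_new[rows]
        ll_s[acc] <- ll_new[acc]
        b[acc, k] <- prop[acc]
      }
      if (adapting) lstep_b[, k] <- lstep_b[, k] + g * (acc - 0.44)
      if (!adapting) acc_b[, k] <- acc_b[, k] + acc
    }
    # joint sweeps along the per-subject design geometry
    for (rep_j in 1:2) {
      db <- t(vapply(seq_len(S), function(s)
        exp(lstep_joint[s]) * as.vector(Lchol[[s]] %*% rnorm(K)),
        numeric(K)))
      bn <- b + db
      eta_new <- eta + rowSums(X * db[subj, , drop = FALSE])
      ll_new <- .rowsum_by(loglik_vec(eta_new, disp), subj, S)
      lpr <- rowSums(dnorm(bn, rep(mu_b, each = S),
                           rep(sigma_b, each = S), log = TRUE) -
                     dnorm(b, rep(mu_b, each = S),
                           rep(sigma_b, each = S), log = TRUE))
      acc <- log(runif(S)) < ll_new - ll_s + lpr
      if (any(acc)) {
        rows <- acc[subj]
        eta[rows] <- eta_new[rows]
        ll_s[acc] <- ll_new[acc]
        b[acc, ] <- bn[acc, ]
      }
      if (adapting) lstep_joint <- lstep_joint + g * (acc - 0.25)
    }
    # global translation: move the group mean and every subject together,
    # which decorrelates the group level from the subject level on
    # collinear designs
    for (rep_g in 1:2) {
      dglob <- exp(lstep_glob) * as.vector(Lglob %*% rnorm(K))
      eta_new <- eta + as.vector(X %*% dglob)
      ll_new <- .rowsum_by(loglik_vec(eta_new, disp), subj, S)
      mu_bn <- mu_b + dglob
      lr1 <- sum(ll_new) - sum(ll_s) +
        sum(dnorm(mu_bn, 0, prior$mu_sd, log = TRUE) -
            dnorm(mu_b, 0, prior$mu_sd, log = TRUE))
      if (log(runif(1)) < lr1) {
        eta <- eta_new; ll_s <- ll_new
        b <- sweep(b, 2, dglob, "+"); mu_b <- mu_bn
        okg <- 1
      } else okg <- 0
      if (adapting) lstep_glob <- lstep_glob + g * (okg - 0.25)
    }
    # dispersion sweep
    prop <- ldisp + exp(lstep_d) * rnorm(S)
    disp_new <- exp(prop)[subj]
    ll_new <- .rowsum_by(loglik_vec(eta, disp_new), subj, S)
    lr <- ll_new - ll_s +
      dnorm(prop, mu_d, sigma_d, log = TRUE) -
      dnorm(ldisp, mu_d, sigma_d, log = TRUE)
    acc <- log(runif(S)) < lr
    if (any(acc)) {
      ldisp[acc] <- prop[acc]
      ll_s[acc] <- ll_new[acc]
      disp <- exp(ldisp)[subj]
    }
    if (adapting) lstep_d <- lstep_d + g * (acc - 0.44)
    # group-level: conjugate means, Metropolis log-SDs
    upd_sigma <- function(sig, vals, mu, j) {
      lp <- function(s) sum(dnorm(vals, mu, s, log = TRUE)) +
        dnorm(s, 0, half_sd, log = TRUE) + log(s)
      sp <- sig * exp(exp(lstep_sig[j]) * rnorm(1))
      a <- lp(sp) - lp(sig)
      ok <- log(runif(1)) < a
      if (adapting) lstep_sig[j] <<- lstep_sig[j] + g * ((if (ok) 1 else 0) - 0.44)
      if (ok) sp else sig
    }
    for (k in seq_len(K)) {
      pv <- 1 / (S / sigma_b[k]^2 + 1 / prior$mu_sd^2)
      mu_b[k] <- rnorm(1, pv * sum(b[, k]) / sigma_b[k]^2, sqrt(pv))
      sigma_b[k] <- upd_sigma(sigma_b[k], b[, k], mu_b[k], k)
    }
    pv <- 1 / (S / sigma_d^2 + 1 / prior$mu_d_sd^2)
    mu_d <- rnorm(1, pv * (sum(ldisp) / sigma_d^2 +
                             prior$mu_d0 / prior$mu_d_sd^2), sqrt(pv))
    sigma_d <- upd_sigma(sigma_d, ldisp, mu_d, K + 1)

    if (!adapting) {
      n_tot <- n_tot + 1
      j <- it - n_warmup
      if (j %% thin == 0) {
        i <- j %/% thin
        out$mu_b[i, ] <- mu_b; out$sigma_b[i, ] <- sigma_b
        out$mu_d[i] <- mu_d; out$sigma_d[i] <- sigma_d
        out$b[i, , ] <- b; out$ldisp[i, ] <- ldisp
      }
    }
  }
  out$acc_rate <- acc_b / max(n_tot, 1)
  out
}

.reg_init <- function(y, X, subj, family) {
  S <- max(subj); K <- ncol(X)
  z <- if (family == "beta") qlogis(.squeeze01(y)) else y
  b <- matrix(0, S, K); ldisp <- numeric(S)
  for (s in seq_len(S)) {
    rows <- subj == s
    fit <- tryCatch(lm.fit(X[rows, , drop = FALSE], z[rows]),
                    error = function(e) NULL)
    cf <- if (is.null(fit)) rep(0, K) else ifelse(is.na(fit$coefficients), 0,
                                                  fit$coefficients)
    b[s, ] <- cf
    if (family == "beta") {
      m <- .guard_mu(plogis(X[rows, , drop = FALSE] %*% cf))
      v <- var(y[rows] - m)
      phi0 <- min(200, max(2, mean(m * (1 - m)) / max(v, 1e-6) - 1))
      ldisp[s] <- log(phi0)
    } else {
      ldisp[s] <- log(max(sd(z[rows] - X[rows, , drop = FALSE] %*% cf,
                             na.rm = TRUE), 1e-3))
    }
  }
  list(b = b, ldisp = ldisp)
}

# Fit the hierarchical regression; returns an object of class "lb_reg_fit".
.hier_reg_mcmc <- function(y, X, subj_id, family = c("beta", "gaussian"),
                           n_chains = 2, n_warmup = 500, n_iter = 500,
                           thin = 1, seed = 1, prior_scale = 1) {
  family <- match.arg(family)
  if (family == "beta" && (any(y <= 0) || any(y >= 1)))
    stop("beta-family outcomes must lie strictly in (0, 1) after compression",
         call. = FALSE)
  subjects <- sort(unique(subj_id))
  subj <- match(subj_id, subjects)
  K <- ncol(X)
  prior <- list(mu_sd = 2.5 * prior_scale, sigma_half = 1 * prior_scale,
                mu_d0 = if (family == "beta") log(10) else log(sd(y)),
                mu_d_sd = 1.5 * prior_scale)
  init <- .reg_init(y, X, subj, family)
  chains <- lapply(seq_len(n_chains), function(ch) {
    .hier_reg_chain(y, X, subj, family, n_warmup, n_iter, thin, prior,
                    .child_seed(seed, ch), init)
  })
  structure(list(family = family, chains = chains, y = y, X = X,
                 subj = subj, subjects = subjects,
                 coef_names = colnames(X),
                 settings = list(n_chains = n_chains, n_warmup = n_warmup,
                                 n_iter = n_iter, thin = thin, seed = seed,
                                 prior_scale = prior_scale)),
            class = "lb_reg_fit")
}

# pooled draws of the group-level coefficients (matrix draws x K)
.group_draws <- function(fit) {
  m <- do.call(rbind, lapply(fit$chains, `[[`, "mu_b"))
  colnames(m) <- fit$coef_names
  m
}

# pooled subject-level coefficient draws (array draws x S x K)
.subject_draws <- function(fit) {
  arrs <- lapply(fit$chains, `[[`, "b")
  d1 <- vapply(arrs, function(x) dim(x)[1], 0)
  out <- array(NA_real_, c(sum(d1), dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
  at <- 0
  for (x in arrs) { out[at + seq_len(dim(x)[1]), , ] <- x; at <- at + dim(x)[1] }
  out
}

#' Summarise a hierarchical regression fit
#'
#' @param object an `lb_reg_fit`.
#' @param prob mass of the highest-posterior-density interval.
#' @param ... unused.
#' @return data frame with posterior mean and HPD bounds per group-level
#'   coefficient, mirroring a coefficient table with columns
#'   (predictor, mean, lower, upper).
#' @export
summary.lb_reg_fit <- function(object, prob = 0.95, ...) {
  g <- .group_draws(object)
  iv <- .hpd(g, prob)
  data.frame(predictor = object$coef_names, mean = colMeans(g),
             lower = iv[, "lower"], upper = iv[, "upper"],
             row.names = NULL)
}

#' @export
print.lb_reg_fit <- function(x, ...) {
  cat("hierarchical", x$family, "regression:",
      length(x$subjects), "subjects,", length(x$y), "observations\n")
  print(summary(x), digits = 3)
  invisible(x)
}

# convergence diagnostics on the group-level draws
.reg_diagnostics <- function(fit) {
  ml <- coda::mcmc.list(lapply(fit$chains, function(ch) {
    coda::mcmc(cbind(ch$mu_b, ch$mu_d))
  }))
  ess <- try(sum(coda::effectiveSize(ml)), silent = TRUE)
  rhat <- if (length(fit$chains) > 1) {
    gd <- try(coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE),
              silent = TRUE)
    if (inherits(gd, "try-error")) NA_real_ else max(gd$psrf[, 1], na.rm = TRUE)
  } else NA_real_
  list(max_rhat = rhat, ess = if (inherits(ess, "try-error")) NA_real_ else ess)
}

# pointwise log-likelihood matrix (draws x observations), thinned
.reg_pointwise_ll <- function(fit, max_draws = 400) {
  b <- .subject_draws(fit)
  ld <- do.call(rbind, lapply(fit$chains, `[[`, "ldisp"))
  nd <- dim(b)[1]
  keep <- unique(round(seq(1, nd, length.out = min(max_draws, nd))))
  X <- fit$X; subj <- fit$subj; y <- fit$y
  ll <- matrix(NA_real_, length(keep), length(y))
  for (i in seq_along(keep)) {
    d <- keep[i]
    bs <- matrix(b[d, , ], ncol = ncol(X))
    eta <- rowSums(X * bs[subj, , drop = FALSE])
    disp <- exp(ld[d, ])[subj]
    ll[i, ] <- if (fit$family == "beta") {
      m <- .guard_mu(plogis(eta))
      dbeta(y, m * disp, (1 - m) * disp, log = TRUE)
    } else dnorm(y, eta, disp, log = TRUE)
  }
  ll
}
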