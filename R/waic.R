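# Watanabe-Akaike information criterion from a pointwise log-likelihood
# matrix (posterior draws in rows, observations in columns). Reported on
# the deviance scale, so lower scores indicate better fit; the
# effective-parameter penalty is the posterior variance of the pointwise
# log-likelihood (pWAIC2).

.waic_from_ll <- function(ll) {
  cmax <- apply(ll, 2, max)
  lppd_i <- cmax + log(colMeans(exp(sweep(ll, 2, cmax, "-"))))
  p_i <- apply(ll, 2, var)
  elpd_i <- lppd_i - p_i
  n_unstable <- sum(p_i > 0.4)
  if (n_unstable > 0)
    warning(sprintf("WAIC penalty unstable for %d observation(s) (var > 0.4)",
                    n_unstable), call. = FALSE)
  list(waic = -2 * sum(elpd_i), se = 2 * sqrt(length(elpd_i) * var(elpd_i)),
       p_waic = sum(p_i), elpd = sum(elpd_i), pointwise = -2 * elpd_i,
       n_unstable = n_unstable)
}

#' Compute WAIC for a fitted model
#'
#' Works on learning-model fits ([fit_model()]) and hierarchical
#' regression fits; the pointwise log-likelihood matrix is computed from
#' the stored posterior draws if not cached.
#'
#' @param fit an `lb_fit` or `lb_reg_fit` object, or a draws x
#'   observations log-likelihood matrix.
#' @return list with elements `waic` (deviance scale), `se`, `p_waic`,
#'   `elpd`, and per-observation contributions.
#' @export
compute_waic <- function(fit) {
  ll <- if (is.matrix(fit)) fit
  else if (inherits(fit, "lb_reg_fit")) .reg_pointwise_ll(fit)
  else if (inherits(fit, "lb_fit")) .fit_pointwise_ll(fit)
  else stop("unsupported object", call. = FALSE)
  .waic_from_ll(ll)
}
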