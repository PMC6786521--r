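# Trajectory-level analyses: the value-variance independence check and the
# behavioural cross-stimulus interference statistic.

#' Within-subject correlation between value and uncertainty
#'
#' Pearson correlation across trials (both stimuli pooled) between the
#' model-derived estimate (beta mean) and its uncertainty (beta variance),
#' per subject; used to verify that the task design dissociates the two.
#' Subjects with fewer than `min_trials` usable trials or a constant
#' series are excluded from the summary.
#'
#' @param traj trajectory from [run_trajectory()] for a beta-family model.
#' @param min_trials minimum usable trials per subject.
#' @return list with `per_subject` (data frame of r), `mean_r`, `sd_r`,
#'   and a one-sample t-test of the correlations against zero.
#' @export
value_variance_independence <- function(traj, min_trials = 3) {
  ok <- is.finite(traj$mu_pre) & is.finite(traj$sigma2_pre)
  tj <- traj[ok, ]
  rs <- vapply(split(tj, tj$subject), function(d) {
    if (nrow(d) < min_trials || sd(d$mu_pre) == 0 || sd(d$sigma2_pre) == 0)
      return(NA_real_)
    cor(d$mu_pre, d$sigma2_pre)
  }, 0)
  per <- data.frame(subject = names(rs), r = as.vector(rs), row.names = NULL)
  rv <- rs[is.finite(rs)]
  tt <- if (length(rv) > 2) t.test(rv) else NULL
  list(per_subject = per, mean_r = mean(rv), sd_r = sd(rv), t_test = tt)
}

#' Behavioural cross-stimulus interference statistic
#'
#' For each subject, the mean rating update for a stimulus (next trial's
#' rating minus current trial's rating, within block) is contrasted
#' between trials on which the *other* stimulus was shocked and trials on
#' which it was not. A permutation null for the group mean of the absolute
#' statistic is built by randomly swapping the two stimuli's labels per
#' trial; optionally the per-subject statistic is correlated with a
#' supplied interference parameter (fitted or generative omega).
#'
#' @param trials tidy trial table with ratings.
#' @param n_perm permutation count.
#' @param omega optional per-subject values to correlate with the
#'   statistic (aligned with sorted subjects).
#' @param seed integer seed.
#' @return list with `per_subject` statistics, the group mean absolute
#'   statistic, its permutation p-value, and (if `omega` given) the
#'   correlation between statistic and omega.
#' @export
interference_statistic <- function(trials, n_perm = 5000, omega = NULL,
                                   seed = 1) {
  wide <- .trials_wide(trials)
  Tn <- wide$T
  nxt <- c(wide$block[-1] == wide$block[-Tn], FALSE)
  i0 <- which(nxt)                       # trials with a successor in-block
  u1 <- wide$y1[, i0 + 1L, drop = FALSE] - wide$y1[, i0, drop = FALSE]
  u2 <- wide$y2[, i0 + 1L, drop = FALSE] - wide$y2[, i0, drop = FALSE]
  o1 <- wide$o1[, i0, drop = FALSE]; o2 <- wide$o2[, i0, drop = FALSE]
  stat_fun <- function(u1, u2, o1, o2) {
    m <- function(u, w) {
      sw <- rowSums(u * w); nw <- rowSums(w)
      ifelse(nw > 0, sw / nw, NA_real_)
    }
    # update of each stimulus split by the other stimulus's outcome
    s1 <- m(u1, o2) - m(u1, 1 - o2)
    s2 <- m(u2, o1) - m(u2, 1 - o1)
    rowMeans(cbind(s1, s2), na.rm = TRUE)
  }
  obs <- stat_fun(u1, u2, o1, o2)
  grp <- mean(abs(obs), na.rm = TRUE)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(p) {
    sw <- matrix(runif(length(o1)) < 0.5, nrow(o1), ncol(o1))
    u1p <- ifelse(sw, u2, u1); u2p <- ifelse(sw, u1, u2)
    o1p <- ifelse(sw, o2, o1); o2p <- ifelse(sw, o1, o2)
    mean(abs(stat_fun(u1p, u2p, o1p, o2p)), na.rm = TRUE)
  }, 0)
  pval <- (1 + sum(null >= grp)) / (1 + n_perm)
  out <- list(per_subject = data.frame(subject = wide$subjects,
                                       interference = obs),
              group_abs_mean = grp, p_value = pval)
  if (!is.null(omega)) {
    ct <- suppressWarnings(stats::cor.test(obs, omega))
    out$omega_correlation <- unname(ct$estimate)
    out$omega_cor_p <- ct$p.value
  }
  out
}
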