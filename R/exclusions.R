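# Subject-exclusion rules applied before the gaze analyses.

#' Detect gambler's-fallacy learners
#'
#' Fits the Rescorla-Wagner model and its dual-rate variant with learning
#' rates allowed to range over \[-1, 1\] and flags subjects whose posterior
#' mean for any learning rate (`alpha`, `alpha_pos`, `alpha_neg`) is
#' negative — i.e. subjects who lower their probability rating after a
#' shock. If either fit fails the subject's flag is `NA` and reported, not
#' silently dropped.
#'
#' @param trials tidy trial table with ratings.
#' @param sampler a [sampler_config()]; the default here is deliberately
#'   light since only point estimates of the learning rates are needed.
#' @param seed integer seed.
#' @return data frame with `subject`, posterior-mean learning rates, and
#'   logical `gambler` flag.
#' @export
detect_gamblers_fallacy <- function(trials,
                                    sampler = sampler_config(n_chains = 1,
                                                             n_warmup = 400,
                                                             n_iter = 600),
                                    seed = 1) {
  f1 <- try(fit_model(trials, "1", sampler = sampler, seed = seed,
                      compute_loglik = FALSE), silent = TRUE)
  f2 <- try(fit_model(trials, "2", sampler = sampler,
                      seed = .child_seed(seed, 2), compute_loglik = FALSE),
            silent = TRUE)
  subjects <- sort(unique(trials$subject))
  out <- data.frame(subject = subjects, alpha = NA_real_,
                    alpha_pos = NA_real_, alpha_neg = NA_real_)
  if (!inherits(f1, "try-error")) out$alpha <- summary(f1)$subject$alpha
  if (!inherits(f2, "try-error")) {
    s2 <- summary(f2)$subject
    out$alpha_pos <- s2$alpha_pos
    out$alpha_neg <- s2$alpha_neg
  }
  est <- as.matrix(out[, c("alpha", "alpha_pos", "alpha_neg")])
  out$gambler <- apply(est, 1, function(v)
    if (all(is.na(v))) NA else any(v < 0, na.rm = TRUE))
  out
}

#' Detect limited responders
#'
#' Flags subjects whose every rating lies (within tolerance) in
#' \{0, 0.5, 1\}, i.e. who only ever used the scale endpoints and midpoint.
#'
#' @param trials tidy trial table with ratings.
#' @param tol rounding tolerance.
#' @return data frame with `subject` and logical `limited` flag.
#' @export
detect_limited_responses <- function(trials, tol = 1e-6) {
  near <- abs(outer(trials$rating, c(0, 0.5, 1), "-")) <= tol
  ok <- rowSums(near) > 0
  agg <- aggregate(ok, by = list(subject = trials$subject), FUN = all)
  data.frame(subject = agg$subject, limited = agg$x)
}

#' Gaze-based exclusion rule
#'
#' Flags subjects whose duration-weighted off-stimulus proportion in the
#' selected phase exceeds 80%.
#'
#' @param fixations tidy fixation table.
#' @param phase phase in which the rule is evaluated (pre-outcome by
#'   default, matching its use for the preparatory-attention analyses).
#' @param threshold off-stimulus proportion above which a subject is
#'   excluded.
#' @return data frame with `subject`, `off_prop`, and logical `excluded`.
#' @export
apply_gaze_exclusion <- function(fixations, phase = "pre_outcome",
                                 threshold = 0.8) {
  fx <- fixations[fixations$phase == phase, ]
  agg <- aggregate(cbind(off = fx$dur_off,
                         tot = fx$dur_left + fx$dur_right + fx$dur_off),
                   by = list(subject = fx$subject), FUN = sum)
  data.frame(subject = agg$subject, off_prop = agg$off / agg$tot,
             excluded = agg$off / agg$tot > threshold)
}

#' Block-wise cross-validated model fit
#'
#' For each of the four blocks in turn, the model is fitted on the
#' remaining blocks, the posterior-mean subject parameters generate
#' predicted ratings on the held-out block (belief state resets at block
#' boundaries, so no information leaks), and fit is scored as the R^2
#' between predicted and observed ratings pooled over subjects. The mean
#' across folds is returned.
#'
#' @param trials tidy trial table with ratings.
#' @param model_id model to evaluate.
#' @param fixations fixation table (attention-coupled models).
#' @param sampler a [sampler_config()].
#' @param seed integer seed.
#' @return list with `r2_cv` (mean across folds) and `folds` (per-fold R^2).
#' @export
cross_validate_blocks <- function(trials, model_id = "6", fixations = NULL,
                                  sampler = sampler_config(n_chains = 1,
                                                           n_warmup = 400,
                                                           n_iter = 600),
                                  seed = 1) {
  blocks <- sort(unique(trials$block))
  if (length(blocks) < 2) stop("need at least 2 blocks", call. = FALSE)
  r2 <- vapply(seq_along(blocks), function(i) {
    held <- blocks[i]
    train <- trials[trials$block != held, ]
    test <- trials[trials$block == held, ]
    fx_tr <- if (!is.null(fixations)) fixations[fixations$block != held, ]
    fx_te <- if (!is.null(fixations)) fixations[fixations$block == held, ]
    fit <- fit_model(train, model_id, fixations = fx_tr, sampler = sampler,
                     seed = .child_seed(seed, i), compute_loglik = FALSE)
    est <- summary(fit)$subject
    par_list <- lapply(seq_len(nrow(est)), function(s) {
      p <- agent_params(model_id = model_id)
      for (nm in intersect(names(est), .PAR_NAMES)) p[[nm]] <- est[[nm]][s]
      if (model_id %in% c("1", "2")) p$omega <- est$omega[s]
      p
    })
    tj <- run_trajectory(test, par_list, fixations = fx_te)
    key <- interaction(tj$subject, tj$block, tj$trial, tj$stimulus)
    tk <- interaction(test$subject, test$block, test$trial, test$stimulus)
    pred <- tj$mu_pre[match(tk, key)]
    obs <- test$rating
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }, 0)
  list(r2_cv = mean(r2), folds = setNames(r2, paste0("block", blocks)))
}
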