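# Task-schedule generator: two concurrently presented stimuli, one on a
# stable and one on a volatile (piecewise-constant) shock-probability
# schedule, over blocks of trials with randomised screen sides.

#' Generate a task schedule
#'
#' Each block assigns one stimulus a constant shock probability and the
#' other a piecewise-constant schedule with 3-5 change-points (minimum
#' segment length 5 trials). Levels are adjusted so that the grand mean
#' shock probability across all trials and stimuli hits `target_mean`
#' (default 0.36, biasing shocks towards absence) within `tol`. With
#' `high_prob_pair = TRUE` the final two blocks are instead constructed
#' with block means 0.45 and 0.55, giving a pair with combined mean 0.50
#' for analyses restricted to high-probability blocks; the remaining
#' blocks still satisfy `target_mean`.
#'
#' @param n_blocks,n_trials blocks and trials per block (defaults 4 x 40).
#' @param target_mean grand mean shock probability.
#' @param stable_levels candidate constant probabilities for the stable
#'   stimulus.
#' @param volatile_levels candidate segment probabilities for the volatile
#'   stimulus.
#' @param n_changepoints integer vector of admissible change-point counts.
#' @param min_segment minimum volatile segment length in trials.
#' @param high_prob_pair add a 45%/55% block pair (see above).
#' @param tol tolerance on the achieved mean.
#' @param seed integer seed; the schedule is a pure function of the
#'   configuration and seed.
#' @return tidy data frame: `block`, `trial`, `stimulus`, `p_shock`,
#'   `stability` (`"stable"`/`"volatile"`), `side` (`"left"`/`"right"`).
#' @export
generate_schedule <- function(n_blocks = 4, n_trials = 40, target_mean = 0.36,
                              stable_levels = c(0.2, 0.25, 0.3),
                              volatile_levels = c(0.05, 0.1, 0.2, 0.35, 0.5,
                                                  0.65, 0.8, 0.9),
                              n_changepoints = 3:5, min_segment = 5,
                              high_prob_pair = FALSE, tol = 0.01,
                              seed = 1) {
  if (n_blocks < 1 || n_trials < min_segment * (min(n_changepoints) + 1))
    stop("infeasible schedule configuration", call. = FALSE)
  set.seed(seed)
  sample1 <- function(x) x[sample.int(length(x), 1)]   # safe for scalars
  volatile_path <- function() {
    ncp <- sample1(n_changepoints)
    nseg <- ncp + 1
    spare <- n_trials - min_segment * nseg
    cuts <- sort(sample(0:spare, ncp, replace = TRUE))
    lens <- min_segment + diff(c(0, cuts, spare))
    lvl <- numeric(nseg)
    lvl[1] <- sample1(volatile_levels)
    for (i in seq_len(nseg - 1)) {
      cand <- setdiff(volatile_levels, lvl[i])
      lvl[i + 1] <- if (length(cand)) sample1(cand) else lvl[i]
    }
    rep(lvl, lens)
  }
  blocks <- lapply(seq_len(n_blocks), function(b) {
    stable_stim <- sample1(1:2)
    ps <- rep(sample1(stable_levels), n_trials)
    pv <- volatile_path()
    p <- if (stable_stim == 1) cbind(ps, pv) else cbind(pv, ps)
    stability <- if (stable_stim == 1) c("stable", "volatile") else
      c("volatile", "stable")
    side1 <- sample(c("left", "right"), n_trials, replace = TRUE)
    list(p = p, stability = stability, side1 = side1)
  })
  # shift a set of blocks so the mean over them reaches a target, keeping
  # the stable stimulus constant within block and probabilities in range
  adjust <- function(idx, tgt, shift_stable = TRUE) {
    for (iter in 1:100) {
      cur <- mean(unlist(lapply(blocks[idx], function(b) b$p)))
      if (abs(cur - tgt) <= tol * 0.5) break
      d <- tgt - cur
      for (b in idx) {
        vcol <- which(blocks[[b]]$stability == "volatile")
        blocks[[b]]$p[, vcol] <<- pmin(0.95, pmax(0.02,
          blocks[[b]]$p[, vcol] + d * (if (shift_stable) 1 else 2)))
        if (shift_stable) {
          scol <- 3 - vcol
          blocks[[b]]$p[, scol] <<- pmin(0.95, pmax(0.02,
            blocks[[b]]$p[, scol] + d))
        }
      }
    }
    cur <- mean(unlist(lapply(blocks[idx], function(b) b$p)))
    if (abs(cur - tgt) > tol)
      stop("could not reach target mean shock probability", call. = FALSE)
  }
  if (high_prob_pair) {
    if (n_blocks < 3) stop("high_prob_pair needs at least 3 blocks", call. = FALSE)
    hp <- c(n_blocks - 1, n_blocks)
    adjust(hp[1], 0.45); adjust(hp[2], 0.55)
    adjust(setdiff(seq_len(n_blocks), hp), target_mean, shift_stable = FALSE)
  } else {
    adjust(seq_len(n_blocks), target_mean, shift_stable = FALSE)
  }
  do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    bl <- blocks[[b]]
    data.frame(
      block = b,
      trial = rep(seq_len(n_trials), times = 2),
      stimulus = rep(1:2, each = n_trials),
      p_shock = c(bl$p[, 1], bl$p[, 2]),
      stability = rep(bl$stability, each = n_trials),
      side = c(bl$side1, ifelse(bl$side1 == "left", "right", "left")))
  }))
}

#' Sample binary shock outcomes from a schedule
#'
#' Outcomes are independent Bernoulli draws per stimulus per trial (any
#' combination of shocks can occur on a trial).
#'
#' @param schedule output of [generate_schedule()].
#' @param seed integer seed.
#' @return the schedule with an added binary `outcome` column.
#' @export
sample_outcomes <- function(schedule, seed = 1) {
  set.seed(seed)
  schedule$outcome <- rbinom(nrow(schedule), 1, schedule$p_shock)
  schedule
}
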