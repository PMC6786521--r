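# Trajectory runner over the vectorised engine, plus the long <-> wide
# conversions shared by the simulator and the fitting code.
#
# Tidy trial tables are long: one row per subject x block x trial x stimulus
# with columns subject, block, trial, stimulus (1/2), side ("left"/"right"),
# p_shock, outcome and (when available) rating. Fixation tables are one row
# per subject x block x trial x phase with per-side durations (ms).

# Convert a long trial table into subject x trial matrices. Requires every
# subject to share the block/trial layout (true for generated cohorts).
.trials_wide <- function(trials) {
  need <- c("subject", "block", "trial", "stimulus", "outcome")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  trials <- trials[order(trials$subject, trials$block, trials$trial,
                         trials$stimulus), ]
  subjects <- unique(trials$subject)
  S <- length(subjects)
  t1 <- trials[trials$subject == subjects[1] & trials$stimulus == 1, ]
  Tn <- nrow(t1)
  if (nrow(trials) != S * Tn * 2)
    stop("trial table must be balanced across subjects", call. = FALSE)
  pick <- function(col, stim) {
    m <- matrix(trials[[col]][trials$stimulus == stim], nrow = S, ncol = Tn,
                byrow = TRUE)
    rownames(m) <- as.character(subjects)
    m
  }
  out <- list(subjects = subjects, S = S, T = Tn,
              block = t1$block, trial = t1$trial,
              o1 = pick("outcome", 1), o2 = pick("outcome", 2))
  for (col in intersect(c("rating", "p_shock"), names(trials))) {
    nm <- c(rating = "y", p_shock = "p")[col]
    out[[paste0(nm, "1")]] <- pick(col, 1)
    out[[paste0(nm, "2")]] <- pick(col, 2)
  }
  if ("side" %in% names(trials)) {
    out$left1 <- pick("side", 1) == "left"   # TRUE if stimulus 1 on the left
  }
  out
}

# Outcome-phase fixation proportions (of total phase time) per stimulus,
# as S x T matrices aligned with a .trials_wide() layout.
.fixation_wide <- function(fixations, wide) {
  fx <- fixations[fixations$phase == "outcome", ]
  fx <- fx[order(fx$subject, fx$block, fx$trial), ]
  if (nrow(fx) != wide$S * wide$T)
    stop("fixation table must have one outcome-phase row per trial",
         call. = FALSE)
  tot <- fx$dur_left + fx$dur_right + fx$dur_off
  tot[tot <= 0] <- NA
  pl <- matrix(fx$dur_left / tot, wide$S, wide$T, byrow = TRUE)
  pr <- matrix(fx$dur_right / tot, wide$S, wide$T, byrow = TRUE)
  pl[is.na(pl)] <- 0; pr[is.na(pr)] <- 0
  if (is.null(wide$left1))
    stop("side mapping required to align fixations with stimuli", call. = FALSE)
  f1 <- ifelse(wide$left1, pl, pr)
  f2 <- ifelse(wide$left1, pr, pl)
  list(f1 = f1, f2 = f2)
}

# Engine wrapper: params is an S x 11 matrix in .PAR_NAMES order.
.traj_engine <- function(model_id, par_mat, o1, o2, block,
                         f1 = NULL, f2 = NULL, full = FALSE) {
  .traj_engine_cpp(.model_code(model_id), par_mat, o1, o2,
                   as.integer(block), f1, f2, full)
}

#' Run a belief trajectory over a trial sequence
#'
#' Iterates the per-trial update rule of `params$model_id` over a tidy
#' trial table, re-initialising the belief state at every block boundary
#' (subjects are instructed to disregard earlier blocks). For the
#' attention-coupled models the outcome-phase fixation proportions of the
#' *previous* trial enter each update, with a neutral 0.5/0.5 split on the
#' first trial of a block.
#'
#' @param trials tidy trial table (columns `subject`, `block`, `trial`,
#'   `stimulus`, `outcome`, optionally `side`, `p_shock`, `rating`).
#' @param params an [agent_params()] (applied to all subjects) or a list of
#'   one per subject.
#' @param fixations tidy fixation table with outcome-phase rows (required
#'   for models 6A/6B and their binary variants).
#' @return a tidy data frame with one row per subject x block x trial x
#'   stimulus: `mu_pre` (estimate at rating time), `mu_post`, `sigma2_pre`,
#'   `sigma2_post`, `delta`, `A`, `B`, `alpha_t` (`NA` where a field does
#'   not apply to the model family).
#' @export
run_trajectory <- function(trials, params, fixations = NULL) {
  if (nrow(trials) == 0) {
    return(data.frame(subject = integer(), block = integer(), trial = integer(),
                      stimulus = integer(), side = character(),
                      mu_pre = numeric(), mu_post = numeric(),
                      sigma2_pre = numeric(), sigma2_post = numeric(),
                      delta = numeric(), A = numeric(), B = numeric(),
                      alpha_t = numeric()))
  }
  wide <- .trials_wide(trials)
  single <- inherits(params, "agent_params")
  model_id <- if (single) params$model_id else params[[1]]$model_id
  par_mat <- if (single) {
    matrix(rep(.par_matrix(params), each = wide$S), nrow = wide$S,
           dimnames = list(NULL, .PAR_NAMES))
  } else {
    if (length(params) != wide$S)
      stop("need one parameter set per subject", call. = FALSE)
    do.call(rbind, lapply(params, .par_matrix))
  }
  f <- list(f1 = NULL, f2 = NULL)
  if (.model_code(model_id) >= 7) {
    if (is.null(fixations))
      stop("attention-coupled models require a fixation table", call. = FALSE)
    f <- .fixation_wide(fixations, wide)
  }
  tr <- .traj_engine(model_id, par_mat, wide$o1, wide$o2, wide$block,
                     f$f1, f$f2, full = TRUE)
  flat <- function(m) as.vector(t(m))   # subject-major, trial within subject
  base <- data.frame(
    subject = rep(wide$subjects, each = wide$T),
    block = rep(wide$block, times = wide$S),
    trial = rep(wide$trial, times = wide$S))
  one <- function(stim) {
    sfx <- as.character(stim)
    side <- if (!is.null(wide$left1)) {
      l1 <- flat(wide$left1)
      if (stim == 1) ifelse(l1, "left", "right") else ifelse(l1, "right", "left")
    } else NA_character_
    cbind(base, data.frame(
      stimulus = stim, side = side,
      mu_pre = flat(tr[[paste0("mu_pre", sfx)]]),
      mu_post = flat(tr[[paste0("mu_post", sfx)]]),
      sigma2_pre = flat(tr[[paste0("sigma2_pre", sfx)]]),
      sigma2_post = flat(tr[[paste0("sigma2_post", sfx)]]),
      delta = flat(tr[[paste0("delta", sfx)]]),
      A = flat(tr[[paste0("A", sfx)]]),
      B = flat(tr[[paste0("B", sfx)]]),
      alpha_t = flat(tr[[paste0("alpha_t", sfx)]])))
  }
  out <- rbind(one(1), one(2))
  out[order(out$subject, out$block, out$trial, out$stimulus), , drop = FALSE]
}
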