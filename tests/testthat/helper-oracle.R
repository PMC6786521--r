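# Independent literal transcription of every update equation, written as
# plain scalar arithmetic with no reference to the package's update
# functions or engine. Used as the ground-truth oracle.

oracle_models <- c("1", "2", "3", "4", "5", "6", "6A", "6B", "6A_bin", "6B_bin")

# one belief-update step for one stimulus; st is a plain list
oracle_step <- function(model, st, ox, oy, fx, fy, p) {
  clip <- function(v) min(1, max(0, v))
  if (model %in% c("1", "2", "3", "4")) {
    d <- ox - st$V
    if (model == "1") {
      V <- st$V + p$alpha * d + p$omega * (oy - st$V)
    } else if (model == "2") {
      a <- if (d > 0) p$alpha_pos else p$alpha_neg
      V <- st$V + a * d + p$omega * (oy - st$V)
    } else {
      V <- st$V + st$alpha_t * d
      mag <- if (model == "3") d^2 else abs(d)
      st$alpha_t <- st$alpha_t + p$k * (mag - st$alpha_t)
    }
    st$V <- clip(V)
    st$delta <- d
    return(st)
  }
  mu <- st$A / (st$A + st$B)
  d <- ox - mu
  tp <- if (model == "5") p$tau else p$tau_pos
  tn <- if (model == "5") p$tau else p$tau_neg
  if (model %in% c("5", "6")) {
    A <- (1 - p$lam) * st$A + tp * ox + p$omega * oy
    B <- (1 - p$lam) * st$B + tn * (1 - ox) + p$omega * (1 - oy)
  } else if (model == "6A") {
    pi_x <- fx * p$gamma + (1 - p$gamma)
    A <- (1 - p$lam) * st$A + tp * pi_x * ox + p$omega * fy * oy
    B <- (1 - p$lam) * st$B + tn * pi_x * (1 - ox) + p$omega * fy * (1 - oy)
  } else if (model == "6B") {
    A <- (1 - p$lam) * st$A + tp * ox + p$omega * fy * oy + p$theta * fx
    B <- (1 - p$lam) * st$B + tn * (1 - ox) + p$omega * fy * (1 - oy)
  } else if (model == "6A_bin") {
    pi_x <- if (fx > fy) 1 else 1 - (fx - fy) * p$gamma
    A <- (1 - p$lam) * st$A + tp * pi_x * ox + p$omega * fy * oy
    B <- (1 - p$lam) * st$B + tn * pi_x * (1 - ox) + p$omega * fy * (1 - oy)
  } else { # 6B_bin: cross-stimulus term not fixation-weighted
    A <- (1 - p$lam) * st$A + tp * ox + p$omega * oy +
      max(0, fx - fy) * p$theta
    B <- (1 - p$lam) * st$B + tn * (1 - ox) + p$omega * (1 - oy)
  }
  st$A <- max(A, 1e-6)
  st$B <- max(B, 1e-6)
  st$delta <- d
  st
}

# full two-stimulus trajectory with block resets and the one-trial fixation
# lag (neutral 0.5/0.5 at block starts); outcomes o1/o2 and fixations f1/f2
# are vectors over trials
oracle_trajectory <- function(model, p, o1, o2, block, f1 = NULL, f2 = NULL) {
  Tn <- length(o1)
  mu_pre <- matrix(NA_real_, Tn, 2)
  beta_fam <- model %in% c("5", "6", "6A", "6B", "6A_bin", "6B_bin")
  for (t in seq_len(Tn)) {
    if (t == 1 || block[t] != block[t - 1]) {
      s1 <- list(V = 0.5, A = 1, B = 1, alpha_t = min(1, max(0, p$alpha)))
      s2 <- s1
      fl <- c(0.5, 0.5)
    }
    mu_pre[t, 1] <- if (beta_fam) s1$A / (s1$A + s1$B) else s1$V
    mu_pre[t, 2] <- if (beta_fam) s2$A / (s2$A + s2$B) else s2$V
    ns1 <- oracle_step(model, s1, o1[t], o2[t], fl[1], fl[2], p)
    ns2 <- oracle_step(model, s2, o2[t], o1[t], fl[2], fl[1], p)
    s1 <- ns1; s2 <- ns2
    if (!is.null(f1)) fl <- c(f1[t], f2[t])
  }
  mu_pre
}

# random parameter set covering every field
random_params <- function() {
  list(alpha = runif(1, -1, 1), alpha_pos = runif(1, -1, 1),
       alpha_neg = runif(1, -1, 1), omega = runif(1, 0, 0.3),
       k = runif(1), tau = runif(1, 0.05, 2), tau_pos = runif(1, 0.05, 2),
       tau_neg = runif(1, 0.05, 2), lam = runif(1), gamma = runif(1),
       theta = runif(1, 0, 1))
}

as_agent <- function(p, model) {
  ap <- agent_params(model_id = model)
  for (nm in names(p)) ap[[nm]] <- p[[nm]]
  if (model %in% c("3", "4")) ap$alpha <- abs(ap$alpha)
  ap
}

# small tidy trial table for one subject from outcome vectors
make_trials <- function(o1, o2, block, sides = NULL) {
  Tn <- length(o1)
  if (is.null(sides)) sides <- rep("left", Tn)
  data.frame(subject = 1, block = rep(block, 2),
             trial = rep(seq_len(Tn), 2),
             stimulus = rep(1:2, each = Tn),
             side = c(sides, ifelse(sides == "left", "right", "left")),
             outcome = c(o1, o2))
}

make_fixations <- function(f1, f2, block, sides = NULL) {
  Tn <- length(f1)
  if (is.null(sides)) sides <- rep("left", Tn)
  fl <- ifelse(sides == "left", f1, f2)
  fr <- ifelse(sides == "left", f2, f1)
  rbind(
    data.frame(subject = 1, block = block, trial = seq_len(Tn),
               phase = "outcome", dur_left = fl * 1000, dur_right = fr * 1000,
               dur_off = pmax(0, 1 - fl - fr) * 1000,
               first_fix_side = "left", first_fix_dur_left = 100,
               first_fix_dur_right = 100),
    data.frame(subject = 1, block = block, trial = seq_len(Tn),
               phase = "pre_outcome", dur_left = 400, dur_right = 400,
               dur_off = 200, first_fix_side = "left",
               first_fix_dur_left = 100, first_fix_dur_right = 100))
}
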