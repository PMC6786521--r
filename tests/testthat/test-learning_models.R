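# Update rules: stated examples, equivalence with the literal oracle
# transcription, nesting identities, and state-boundedness.

test_that("Rescorla-Wagner updates match direct arithmetic", {
  st <- belief_state(V = 0.5)
  p <- agent_params("1", alpha = 0.3, omega = 0)
  expect_equal(rw_update(st, trial_input(1, 0), p)$V, 0.65)
  p0 <- agent_params("1", alpha = 0, omega = 0)
  expect_equal(rw_update(st, trial_input(1, 1), p0)$V, 0.5)
  expect_equal(rw_update(st, trial_input(0, 0), p0)$V, 0.5)
  # dual-rate with cross-stimulus term, against hand evaluation
  st2 <- belief_state(V = 0.2)
  p2 <- agent_params("2", alpha_pos = 0.4, alpha_neg = 0.1, omega = 0.05)
  got <- rw_update(st2, trial_input(1, 0), p2)
  expect_equal(got$V, 0.2 + 0.4 * 0.8 + 0.05 * (0 - 0.2))
  expect_equal(got$delta, 0.8)
  expect_error(rw_update(st, trial_input(1, 0), agent_params("5")), "model_id")
})

test_that("hybrid updates adapt the learning rate as specified", {
  p <- agent_params("3", alpha = 0.5, k = 1)
  st <- belief_state(V = 0)
  st$alpha_t <- 0.5
  got <- hybrid_update(st, trial_input(0, 0), p)   # delta = 0
  expect_equal(got$alpha_t, 0)
  p0 <- agent_params("4", alpha = 0.2, k = 0)
  st$alpha_t <- 0.2
  expect_equal(hybrid_update(st, trial_input(1, 0), p0)$alpha_t, 0.2)
  # 10-trial sequence against a brute-force loop of the two equations
  set.seed(7)
  for (model in c("3", "4")) {
    o <- rbinom(10, 1, 0.5)
    pp <- agent_params(model, alpha = 0.4, k = 0.3)
    st <- belief_state(V = 0.5); st$alpha_t <- 0.4
    V <- 0.5; a <- 0.4
    for (t in 1:10) {
      st <- hybrid_update(st, trial_input(o[t], 0), pp)
      d <- o[t] - V
      V <- min(1, max(0, V + a * d))
      a <- a + 0.3 * ((if (model == "3") d^2 else abs(d)) - a)
    }
    expect_equal(st$V, V, tolerance = 1e-12)
    expect_equal(st$alpha_t, a, tolerance = 1e-12)
  }
})

test_that("leaky beta updates accumulate, leak, and floor evidence", {
  p <- agent_params("5", tau = 1, lam = 0, omega = 0)
  got <- beta_update(belief_state(A = 1, B = 1), trial_input(1, 0), p)
  expect_equal(c(got$A, got$B, got$mu), c(2, 1, 2 / 3))
  pfull <- agent_params("6", tau_pos = 0, tau_neg = 0, lam = 1, omega = 0)
  got2 <- beta_update(belief_state(A = 4, B = 2), trial_input(0, 1), pfull)
  expect_equal(c(got2$A, got2$B, got2$mu), c(1e-6, 1e-6, 0.5))
  # asymmetric update with interference against hand evaluation
  p3 <- agent_params("6", tau_pos = 0.8, tau_neg = 0.4, lam = 0.1, omega = 0.1)
  got3 <- beta_update(belief_state(A = 2, B = 3), trial_input(0, 1), p3)
  expect_equal(got3$A, 0.9 * 2 + 0.1 * 1)
  expect_equal(got3$B, 0.9 * 3 + 0.4 * 1 + 0.1 * 0)
  pbad <- agent_params("6")
  pbad$lam <- 2
  expect_error(beta_update(belief_state(), trial_input(1, 0), pbad), "lam")
})

test_that("beta moments equal quadrature moments on a grid", {
  expect_equal(unname(beta_moments(1, 1)), c(0.5, 1 / 12))
  expect_equal(beta_moments(9, 1)[["mu"]], 0.9)
  expect_error(beta_moments(0, 1), "must be > 0")
  set.seed(1)
  grid <- cbind(runif(20, 0.3, 8), runif(20, 0.3, 8))
  for (i in 1:20) {
    a <- grid[i, 1]; b <- grid[i, 2]
    m1 <- integrate(function(x) x * dbeta(x, a, b), 0, 1,
                    rel.tol = 1e-10, subdivisions = 500L)$value
    m2 <- integrate(function(x) x^2 * dbeta(x, a, b), 0, 1,
                    rel.tol = 1e-10, subdivisions = 500L)$value
    mm <- beta_moments(a, b)
    expect_equal(mm[["mu"]], m1, tolerance = 1e-8)
    expect_equal(mm[["sigma2"]], m2 - m1^2, tolerance = 1e-8)
  }
})

test_that("attention-coupled updates weight evidence by fixation", {
  st <- belief_state(A = 2, B = 3)
  # gamma = 0 reduces to the asymmetric model with fixation-weighted omega
  pA0 <- agent_params("6A", tau_pos = 0.8, tau_neg = 0.4, lam = 0.1,
                      omega = 0.2, gamma = 0)
  got <- attention_update_6A(st, trial_input(1, 1, 0.3, 0.5), pA0)
  p6 <- agent_params("6", tau_pos = 0.8, tau_neg = 0.4, lam = 0.1,
                     omega = 0.2 * 0.5)
  ref <- beta_update(st, trial_input(1, 1), p6)
  expect_equal(c(got$A, got$B), c(ref$A, ref$B), tolerance = 1e-12)
  # full attention gives a full update regardless of gamma
  pA <- agent_params("6A", tau_pos = 1, tau_neg = 1, lam = 0, omega = 0,
                     gamma = 0.7)
  got2 <- attention_update_6A(belief_state(), trial_input(1, 0, 1, 0), pA)
  expect_equal(got2$A, 2)
  # gamma = 0.6, fixation 0.3: pi = 0.3 * 0.6 + 0.4 = 0.58, hand-evaluated
  pA2 <- agent_params("6A", tau_pos = 0.5, tau_neg = 0.2, lam = 0.1,
                      omega = 0.1, gamma = 0.6)
  got3 <- attention_update_6A(belief_state(A = 2, B = 3),
                              trial_input(0, 1, 0.3, 0.6), pA2)
  expect_equal(got3$A, 0.9 * 2 + 0.1 * 0.6 * 1)
  expect_equal(got3$B, 0.9 * 3 + 0.2 * 0.58 * 1 + 0.1 * 0.6 * 0)
  # 6B: theta = 0 equals model 6 with fixation-weighted omega
  pB0 <- agent_params("6B", tau_pos = 0.8, tau_neg = 0.4, lam = 0.1,
                      omega = 0.2, theta = 0)
  gotB <- attention_update_6B(st, trial_input(1, 1, 0.3, 0.5), pB0)
  expect_equal(c(gotB$A, gotB$B), c(ref$A, ref$B), tolerance = 1e-12)
  # no fixation, no value bonus
  pB <- agent_params("6B", tau_pos = 0.8, tau_neg = 0.4, lam = 0.1,
                     omega = 0, theta = 0.9)
  gotB2 <- attention_update_6B(st, trial_input(1, 0, 0, 0.4), pB)
  expect_equal(gotB2$A, 0.9 * 2 + 0.8)
  # theta bonus scales with fixation
  gotB3 <- attention_update_6B(belief_state(A = 2, B = 2),
                               trial_input(0, 0, 0.8, 0.1),
                               agent_params("6B", tau_pos = 0, tau_neg = 0,
                                            lam = 0, omega = 0, theta = 0.5))
  expect_equal(gotB3$A, 2 + 0.4)
})

test_that("binary attention variants follow their stated rules", {
  st <- belief_state(A = 2, B = 2)
  pB <- agent_params("6B_bin", tau_pos = 0, tau_neg = 0, lam = 0, omega = 0,
                     theta = 1)
  eq <- binary_attention_update(st, trial_input(0, 0, 0.4, 0.4), pB, "6B_bin")
  expect_equal(eq$A, 2)   # equal fixation, no bonus
  win <- binary_attention_update(st, trial_input(0, 0, 0.7, 0.2), pB, "6B_bin")
  expect_equal(win$A, 2.5)
  # 6A_bin: winner gets pi = 1; loser's printed expression exceeds 1
  pA <- agent_params("6A_bin", tau_pos = 1, tau_neg = 0, lam = 0, omega = 0,
                     gamma = 0.5)
  w <- binary_attention_update(st, trial_input(1, 0, 0.6, 0.2), pA, "6A_bin")
  expect_equal(w$A, 3)
  l <- binary_attention_update(st, trial_input(1, 0, 0.2, 0.6), pA, "6A_bin")
  expect_equal(l$A, 2 + (1 - (0.2 - 0.6) * 0.5))   # pi = 1.2 as printed
})

test_that("trajectory runner agrees exactly with the literal oracle", {
  set.seed(42)
  for (rep in 1:100) {
    model <- sample(oracle_models, 1)
    Tn <- sample(c(10, 25, 40), 1)
    block <- sort(sample(1:2, Tn, replace = TRUE))
    o1 <- rbinom(Tn, 1, 0.4); o2 <- rbinom(Tn, 1, 0.4)
    f1 <- runif(Tn, 0, 0.6); f2 <- pmin(runif(Tn, 0, 0.6), 1 - f1)
    p <- random_params()
    ref <- oracle_trajectory(model, p, o1, o2, block, f1, f2)
    tj <- run_trajectory(make_trials(o1, o2, block), as_agent(p, model),
                         fixations = make_fixations(f1, f2, block))
    got <- cbind(tj$mu_pre[tj$stimulus == 1], tj$mu_pre[tj$stimulus == 2])
    if (model %in% c("3", "4")) ref <- oracle_trajectory(model,
      utils::modifyList(p, list(alpha = abs(p$alpha))), o1, o2, block, f1, f2)
    expect_equal(got, ref, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("single-step updates agree with the oracle across models", {
  set.seed(11)
  for (rep in 1:2000) {
    model <- sample(oracle_models, 1)
    p <- random_params()
    if (model %in% c("3", "4")) p$alpha <- abs(p$alpha)
    st0 <- list(V = runif(1), A = runif(1, 0.01, 6), B = runif(1, 0.01, 6),
                alpha_t = runif(1))
    ox <- rbinom(1, 1, 0.5); oy <- rbinom(1, 1, 0.5)
    fx <- runif(1, 0, 0.7); fy <- min(runif(1, 0, 0.7), 1 - fx)
    ref <- oracle_step(model, st0, ox, oy, fx, fy, p)
    st <- belief_state(V = st0$V, A = st0$A, B = st0$B, alpha_t = st0$alpha_t)
    got <- update_belief(st, trial_input(ox, oy, fx, fy), as_agent(p, model))
    if (model %in% c("1", "2", "3", "4")) {
      expect_equal(got$V, min(1, max(0, ref$V)), tolerance = 1e-12)
    } else {
      expect_equal(c(got$A, got$B), c(ref$A, ref$B), tolerance = 1e-12)
    }
    # state stays finite and within bounds
    expect_true(all(is.finite(c(got$V, got$A, got$B, got$mu, got$sigma2)),
                    na.rm = TRUE))
    expect_true(got$mu >= 0 && got$mu <= 1)
    # beta variance is bounded by 1/4 (attained as both masses shrink to
    # the floor) and by 1/12 once total evidence reaches 2
    if (!model %in% c("1", "2", "3", "4")) {
      expect_true(got$sigma2 > 0 && got$sigma2 <= 0.25 + 1e-9)
      if (got$A + got$B >= 2) expect_lte(got$sigma2, 1 / 12 + 1e-9)
    }
  }
})

test_that("nesting identities hold across the model family", {
  set.seed(3)
  Tn <- 40; block <- rep(1:2, each = 20)
  o1 <- rbinom(Tn, 1, 0.4); o2 <- rbinom(Tn, 1, 0.4)
  trials <- make_trials(o1, o2, block)
  fx <- make_fixations(runif(Tn, 0, 0.5), runif(Tn, 0, 0.5), block)
  # model 2 with equal rates reproduces model 1
  t1 <- run_trajectory(trials, agent_params("1", alpha = 0.35, omega = 0.1))
  t2 <- run_trajectory(trials, agent_params("2", alpha_pos = 0.35,
                                            alpha_neg = 0.35, omega = 0.1))
  expect_equal(t1$mu_pre, t2$mu_pre, tolerance = 1e-12)
  # model 6 with equal increments reproduces model 5
  t5 <- run_trajectory(trials, agent_params("5", tau = 0.7, lam = 0.2,
                                            omega = 0.1))
  t6 <- run_trajectory(trials, agent_params("6", tau_pos = 0.7,
                                            tau_neg = 0.7, lam = 0.2,
                                            omega = 0.1))
  expect_equal(t5$mu_pre, t6$mu_pre, tolerance = 1e-12)
  # 6A with gamma = 0 and 6B with theta = 0 reduce to model 6 only up to
  # the fixation weighting of the cross-stimulus term: exact once omega = 0
  tA <- run_trajectory(trials, agent_params("6A", tau_pos = 0.7,
                                            tau_neg = 0.3, lam = 0.2,
                                            omega = 0, gamma = 0),
                       fixations = fx)
  tB <- run_trajectory(trials, agent_params("6B", tau_pos = 0.7,
                                            tau_neg = 0.3, lam = 0.2,
                                            omega = 0, theta = 0),
                       fixations = fx)
  t6b <- run_trajectory(trials, agent_params("6", tau_pos = 0.7,
                                             tau_neg = 0.3, lam = 0.2,
                                             omega = 0))
  expect_equal(tA$mu_pre, t6b$mu_pre, tolerance = 1e-12)
  expect_equal(tB$mu_pre, t6b$mu_pre, tolerance = 1e-12)
  # with omega > 0 they differ (the cross term is fixation-weighted)
  tAo <- run_trajectory(trials, agent_params("6A", tau_pos = 0.7,
                                             tau_neg = 0.3, lam = 0.2,
                                             omega = 0.2, gamma = 0),
                        fixations = fx)
  t6o <- run_trajectory(trials, agent_params("6", tau_pos = 0.7,
                                             tau_neg = 0.3, lam = 0.2,
                                             omega = 0.2))
  expect_gt(max(abs(tAo$mu_pre - t6o$mu_pre)), 1e-6)
})

test_that("mean estimate moves monotonically with outcomes when leak-free", {
  set.seed(5)
  for (rep in 1:50) {
    p <- agent_params("6", tau_pos = runif(1, 0.1, 2),
                      tau_neg = runif(1, 0.1, 2), lam = 0, omega = 0)
    st <- belief_state(A = runif(1, 0.2, 5), B = runif(1, 0.2, 5))
    up <- beta_update(st, trial_input(1, 0), p)
    dn <- beta_update(st, trial_input(0, 0), p)
    expect_gte(up$mu, st$mu)
    expect_lte(dn$mu, st$mu)
  }
})

test_that("trajectory handles degenerate inputs", {
  expect_equal(nrow(run_trajectory(data.frame(), agent_params("6"))), 0)
  tr <- make_trials(c(1, 0), c(0, 1), c(1, 1))
  expect_error(run_trajectory(tr, agent_params("6A")), "fixation")
  expect_error(agent_params("6", lam = 1.5), "lam")
  expect_error(agent_params("6A", gamma = -0.1), "gamma")
  expect_error(agent_params("6B", theta = -1), "theta")
  expect_error(agent_params("6", obs_precision = 0), "obs_precision")
  expect_error(trial_input(1, 0, 0.8, 0.7), "sum to at most 1")
})
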