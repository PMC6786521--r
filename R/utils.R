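# Small shared numerical helpers.

# Smithson-Verkuilen compression of proportions away from {0, 1} so a beta
# likelihood is defined on every observation; n is the total sample size.
.squeeze01 <- function(y, n = length(y)) (y * (n - 1) + 0.5) / n

# guard a predicted mean strictly inside (0, 1) for beta shape parameters
.guard_mu <- function(m, eps = 1e-4) eps + (1 - 2 * eps) * m

# within-group z-scoring; constant columns map to 0
.zscore_by <- function(x, g) {
  mu <- ave(x, g, FUN = function(v) mean(v, na.rm = TRUE))
  s <- ave(x, g, FUN = function(v) sd(v, na.rm = TRUE))
  z <- (x - mu) / s
  z[!is.na(x) & !is.finite(z)] <- 0   # constant columns scale to 0
  z
}

# 95% highest-posterior-density interval from pooled draws
.hpd <- function(draws, prob = 0.95) {
  iv <- coda::HPDinterval(coda::as.mcmc(as.matrix(draws)), prob = prob)
  iv
}

# derive a bounded child seed from (seed, index) without overflowing
# 32-bit integers
.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483629) + 1L
}
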