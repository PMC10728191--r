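# Shared fixtures, built in code.

default_pool <- make_species_pool(3, 6)
default_pairs <- make_pairing_design(default_pool)

# a quiet configuration for deterministic structural checks
noiseless_config <- function(seed = 1) {
  psf_sim_config(seed = seed, dissimilarity_sd = 0, psf_noise_sd = 0,
                 covariate_effect = 0, pot_noise_sd = 0, biomass_cv = 0,
                 cover_noise_sd = 0)
}

# parametric dissimilarities + truth for a config
make_truth <- function(config, pool = default_pool) {
  dissims <- setNames(lapply(config$groups, function(g)
    simulate_dissimilarities(pool, config, g)), config$groups)
  list(dissims = dissims, truth = simulate_true_psf(dissims, config))
}

# symmetric PSF matrix from a truth table
truth_matrix <- function(truth) {
  sp <- unique(c(truth$a, truth$b))
  m <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  m[cbind(truth$a, truth$b)] <- truth$true_psf
  m[cbind(truth$b, truth$a)] <- truth$true_psf
  m
}

# brute-force Bray-Curtis for the oracle tests
bc_brute <- function(a, b) sum(abs(a - b)) / sum(a + b)

# random interior sigma matrices for property sweeps
random_sigma <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(n * n, -1, 0.7), n, n)
}

# central-difference Jacobian of the reduced replicator system
fd_jacobian <- function(sigma, P_hat, h = 1e-6) {
  N <- nrow(sigma)
  f <- function(p_red) {
    P <- c(p_red, 1 - sum(p_red))
    w <- as.numeric(sigma %*% P)
    (P * (w - sum(w * P)))[seq_len(N - 1)]
  }
  p0 <- P_hat[seq_len(N - 1)]
  J <- matrix(0, N - 1, N - 1)
  for (k in seq_len(N - 1)) {
    e <- rep(0, N - 1); e[k] <- h
    J[, k] <- (f(p0 + e) - f(p0 - e)) / (2 * h)
  }
  J
}
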