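test_that("conspecific fitness is half the fully-dissimilar prediction", {
  expect_equal(conspecific_sigma(psf_predictor()), -3.471 / 2)
  p <- psf_predictor(c(a = -1.2, b = -0.8), intercept = 0)
  expect_equal(conspecific_sigma(p), -1)
  p0 <- psf_predictor(c(a = 0), intercept = 0)
  expect_equal(conspecific_sigma(p0), 0)
})

test_that("interaction matrices reproduce pairwise feedback exactly", {
  cfg <- psf_sim_config(seed = 51)
  tr <- make_truth(cfg)
  p <- psf_predictor()
  pm <- predict(p, tr$dissims)
  sub <- default_pool$species[c(1, 7, 13)]
  A <- build_interaction_matrix(p, tr$dissims, sub)
  expect_equal(diag(A$sigma), setNames(rep(A$w_mono, 3), sub))
  for (i in 1:2) for (j in (i + 1):3) {
    Is <- A$sigma[i, i] + A$sigma[j, j] - A$sigma[i, j] - A$sigma[j, i]
    expect_equal(Is, unname(pm[sub[i], sub[j]]), tolerance = 1e-12)
  }
  # fully dissimilar pair sits at the zero heterospecific baseline
  ones <- lapply(tr$dissims, function(x) { x$d[] <- 1; diag(x$d) <- 0; x })
  A1 <- build_interaction_matrix(p, ones, sub[1:2])
  expect_equal(unname(A1$sigma[1, 2]), 0, tolerance = 1e-12)
  expect_error(build_interaction_matrix(p, tr$dissims, c(sub, "nope")),
               "without predicted PSF")
})

test_that("Cramer equilibrium matches hand results and the direct solve", {
  eq <- equilibrium(matrix(c(-1, 0, 0, -1), 2, 2,
                           dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(unname(eq$P_hat), c(0.5, 0.5))
  expect_equal(eq$w_hat, -0.5)
  expect_true(eq$feasible)
  eq2 <- equilibrium(diag(2))
  expect_equal(unname(eq2$P_hat), c(0.5, 0.5))
  expect_equal(eq2$w_hat, 0.5)
  expect_true(eq2$feasible)
  # dominated species -> some frequency leaves (0, 1) -> infeasible
  sig <- matrix(c(-1, -0.5, -0.2,
                  -0.5, -1, -0.2,
                  -2, -2, -1), 3, 3)
  eq3 <- equilibrium(sig)
  expect_false(eq3$feasible)
  # Cramer equals the direct linear solve on random matrices
  for (s in 1:20) {
    sigma <- random_sigma(sample(2:6, 1), s)
    eq <- equilibrium(sigma)
    if (eq$degenerate) next
    x <- solve(sigma, rep(1, nrow(sigma)))
    expect_equal(unname(eq$P_hat), x / sum(x), tolerance = 1e-10)
    expect_equal(eq$w_hat, 1 / sum(x), tolerance = 1e-10)
  }
})

test_that("stability matches sign expectations and finite differences", {
  st_neg <- stability(-diag(2), c(0.5, 0.5))
  expect_true(st_neg$stable)
  st_pos <- stability(diag(2), c(0.5, 0.5))
  expect_false(st_pos$stable)
  expect_error(stability(diag(2), c(1.2, -0.2)), "interior")
  for (s in 1:10) {
    sigma <- random_sigma(sample(2:5, 1), 100 + s)
    eq <- equilibrium(sigma)
    if (!isTRUE(eq$feasible)) next
    st <- stability(sigma, eq$P_hat)
    expect_equal(st$jacobian, fd_jacobian(sigma, unname(eq$P_hat)),
                 tolerance = 1e-5)
    # shift invariance of the dominant eigenvalue
    st_c <- stability(sigma + 0.37, eq$P_hat)
    expect_equal(st_c$dominant_eig, st$dominant_eig, tolerance = 1e-8)
  }
})

test_that("community feedback reduces to the pairwise sign at N = 2", {
  for (s in 1:25) {
    sigma <- random_sigma(2, 200 + s)
    Is <- sigma[1, 1] + sigma[2, 2] - sigma[1, 2] - sigma[2, 1]
    Ic <- community_feedback(sigma)
    expect_equal(Ic, Is / 2, tolerance = 1e-10)
  }
  expect_equal(community_feedback(-diag(4)), -1, tolerance = 1e-12)
  expect_equal(community_feedback(matrix(0.3, 3, 3)), 0, tolerance = 1e-12)
})

test_that("model complementarity follows N (w_hat - w_mono)", {
  eq <- equilibrium(-diag(2))
  expect_equal(model_complementarity(eq, -1), 1)
  # shift property: equilibrium fitness and w_mono move together, CE fixed
  for (s in 1:10) {
    sigma <- random_sigma(3, 300 + s)
    eq <- equilibrium(sigma)
    if (!isTRUE(eq$feasible)) next
    ce <- model_complementarity(eq, -1)
    eq_c <- equilibrium(sigma + 0.9)
    expect_equal(unname(eq_c$P_hat), unname(eq$P_hat), tolerance = 1e-8)
    expect_equal(model_complementarity(eq_c, -1 + 0.9), ce, tolerance = 1e-8)
  }
})

test_that("replicator dynamics conserve the simplex and reach equilibrium", {
  sigma <- matrix(c(-1, 0, 0, -1), 2, 2)
  tr <- integrate_dynamics(sigma, c(0.9, 0.1), t_max = 60, dt = 0.5)
  P_end <- tr[nrow(tr), -1]
  expect_equal(unname(P_end), c(0.5, 0.5), tolerance = 1e-6)
  expect_lt(max(abs(rowSums(tr[, -1]) - 1)), 1e-8)
  # starting at the equilibrium stays there
  tr0 <- integrate_dynamics(sigma, c(0.5, 0.5), t_max = 10, dt = 0.5)
  expect_lt(max(abs(tr0[, -1] - 0.5)), 1e-8)
  expect_error(integrate_dynamics(sigma, c(0.7, 0.7)), "simplex")
})

test_that("compiled screen agrees with the pure-R reference", {
  cfg <- psf_sim_config(seed = 52)
  tr <- make_truth(cfg)
  p <- psf_predictor()
  pm <- predict(p, tr$dissims)
  pool5 <- make_species_pool(1, 5)
  # reuse the first five pool species under the small pool's names
  sp5 <- default_pool$species[seq_len(5)]
  pm5 <- pm[sp5, sp5]
  dimnames(pm5) <- list(pool5$species, pool5$species)
  scr_c <- screen_pool(p, pool = pool5, psf_matrix = pm5, compiled = TRUE)
  scr_r <- screen_pool(p, pool = pool5, psf_matrix = pm5, compiled = FALSE)
  for (col in c("feasible", "stable", "passes"))
    expect_equal(scr_c[[col]], scr_r[[col]])
  for (col in c("I_c", "w_hat", "CE_model", "predicted_psf", "dilution"))
    expect_equal(scr_c[[col]], scr_r[[col]], tolerance = 1e-9)
})

test_that("screen end-members behave as the theory dictates", {
  pool4 <- make_species_pool(2, 2)
  sp <- pool4$species
  # all pairs fully dissimilar under a neutral-intercept predictor:
  # sigma = w_mono I shifted; with w_mono < 0 every community passes
  p_neg <- psf_predictor(c(g = -2), intercept = 0)
  pm_neg <- matrix(-2, 4, 4, dimnames = list(sp, sp)); diag(pm_neg) <- 0
  scr_neg <- screen_pool(p_neg, pool = pool4, psf_matrix = pm_neg)
  expect_true(all(scr_neg$passes))
  expect_true(all(scr_neg$CE_model > 0))
  # mirrored positive-feedback pool: nothing passes
  p_pos <- psf_predictor(c(g = 2), intercept = 0)
  pm_pos <- -pm_neg
  scr_pos <- screen_pool(p_pos, pool = pool4, psf_matrix = pm_pos)
  expect_false(any(scr_pos$passes))
})
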