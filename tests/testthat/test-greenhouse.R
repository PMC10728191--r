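# small hand-built pot tables for the estimator tests
toy_pots <- function(cell_means, reps = 3, height_slope = 0, noise = 0,
                     seed = 1, constant_height = FALSE) {
  set.seed(seed)
  sp <- rownames(cell_means)
  rows <- list()
  for (p in sp) for (s in colnames(cell_means)) {
    h <- if (constant_height) rep(10, reps) else rnorm(reps, 10, 2)
    rows[[paste(p, s)]] <- data.frame(
      plant = p, inoculum = s, replicate = seq_len(reps), height_cm = h,
      cell = cell_means[p, s], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  # centre heights within plant species so the generator cell value is the
  # expectation at each species' own mean height (the estimator's target)
  hbar <- tapply(out$height_cm, out$plant, mean)
  logb <- out$cell + height_slope * (out$height_cm - hbar[out$plant]) +
    rnorm(nrow(out), 0, noise)
  out$shoot_g <- 0.7 * exp(logb)
  out$root_g <- 0.3 * exp(logb)
  rownames(out) <- NULL
  out[, c("plant", "inoculum", "replicate", "height_cm", "shoot_g", "root_g")]
}

test_that("cell means reduce to raw means without a covariate effect", {
  cm <- matrix(c(0.5, 0.1, -0.2, 0.8), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  pots <- toy_pots(cm, reps = 4, noise = 0.3, constant_height = TRUE)
  cells <- fit_cell_means(pots)
  raw <- tapply(log(pots$shoot_g + pots$root_g),
                list(pots$plant, pots$inoculum), mean)
  # no height variation: the covariate drops out and the adjusted means are
  # exactly the raw cell means
  expect_equal(unclass(cells$m), unclass(raw), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unname(cells$n), matrix(4, 2, 2))
})

test_that("noiseless balanced data recovers generator cell values exactly", {
  cm <- matrix(c(0.5, 0.1, -0.2, 0.8), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  pots <- toy_pots(cm, reps = 3, height_slope = 0.05, noise = 0)
  cells <- suppressWarnings(fit_cell_means(pots))
  # adjusted to each species' mean height: cm + slope * 0 = cm
  expect_equal(unclass(cells$m)[rownames(cm), colnames(cm)], unclass(cm),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("cell means are invariant to a constant height shift", {
  cm <- matrix(c(0.5, 0.1, -0.2, 0.8), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  pots <- toy_pots(cm, reps = 5, height_slope = 0.05, noise = 0.1)
  shifted <- pots
  shifted$height_cm <- shifted$height_cm + 7
  c1 <- fit_cell_means(pots)
  c2 <- fit_cell_means(shifted)
  expect_equal(c1$m, c2$m, tolerance = 1e-10)
})

test_that("missing designed cells are reported", {
  cm <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  pots <- toy_pots(cm)
  cells <- suppressWarnings(fit_cell_means(pots))
  expect_error(pairwise_psf(cells, "A", "C"), "missing cell")
})

test_that("pairwise PSF is the symmetric four-cell log contrast", {
  cells <- list(m = matrix(c(log(2), 0, 0, log(2)), 2, 2,
                           dimnames = list(c("A", "B"), c("A", "B"))))
  # alpha_A = 2, beta_B = 2, alpha_B = 1, beta_A = 1
  expect_equal(pairwise_psf(cells, "A", "B"), 2 * log(2))
  expect_equal(pairwise_psf(cells, "B", "A"), pairwise_psf(cells, "A", "B"))
  # equal cells -> zero feedback
  cells0 <- list(m = matrix(0.4, 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(pairwise_psf(cells0, "A", "B"), 0)
  # adding a constant to every log cell mean changes nothing
  cells_c <- list(m = cells$m + 3)
  expect_equal(pairwise_psf(cells_c, "A", "B"), pairwise_psf(cells, "A", "B"))
})

test_that("PSF variance applies the conspecific sample-size adjustment", {
  nm <- list(c("A", "B"), c("A", "B"))
  cells <- list(m = matrix(0, 2, 2, dimnames = nm),
                mean_raw = matrix(1, 2, 2, dimnames = nm),
                var_raw = matrix(0.04, 2, 2, dimnames = nm),
                n = matrix(c(9, 3, 3, 9), 2, 2, dimnames = nm))
  v1 <- psf_variance(cells, "A", "B", conspecific_effective_n = 1)
  expect_equal(v1, 0.04 + 0.04 + 0.04 / 3 + 0.04 / 3, tolerance = 1e-12)
  v9 <- psf_variance(cells, "A", "B", conspecific_effective_n = 9)
  expect_equal(v9, 2 * 0.04 / 9 + 2 * 0.04 / 3, tolerance = 1e-12)
  # zero variance everywhere -> zero PSF variance
  cells0 <- cells
  cells0$var_raw[] <- 0
  expect_equal(psf_variance(cells0, "A", "B"), 0)
  # variance decreases when any cell gains replicates
  cells_n <- cells
  cells_n$n[1, 2] <- 6
  expect_lt(psf_variance(cells_n, "A", "B", 9),
            psf_variance(cells, "A", "B", 9))
})

test_that("random-effects pooling behaves on degenerate inputs", {
  # identical estimates: pooled value equals them, no heterogeneity
  psfs <- data.frame(psf = rep(-0.5, 6), var_psf = rep(0.04, 6))
  m <- meta_analyze(psfs)
  expect_equal(m$estimate, -0.5, tolerance = 1e-8)
  expect_equal(m$tau2, 0, tolerance = 1e-8)
  expect_equal(m$se, sqrt(0.04 / 6), tolerance = 1e-6)
  expect_true(m$significant)
  # symmetric estimates pool to zero with a symmetric CI
  psfs2 <- data.frame(psf = c(-1, 0, 1), var_psf = rep(0.1, 3))
  m2 <- meta_analyze(psfs2)
  expect_equal(m2$estimate, 0, tolerance = 1e-8)
  expect_equal(m2$ci_low, -m2$ci_high, tolerance = 1e-8)
  expect_false(m2$significant)
  expect_error(meta_analyze(psfs2[1, , drop = FALSE]), "at least 2")
})

test_that("meta-analysis recovers a simulated common mean", {
  cfg <- psf_sim_config(seed = 21)
  tr <- make_truth(cfg)
  pots <- simulate_greenhouse(default_pool, default_pairs, tr$truth, cfg)
  est <- estimate_pairwise_psf(pots, default_pairs)
  m <- meta_analyze(est)
  true_mean <- mean(truth_matrix(tr$truth)[cbind(est$a, est$b)])
  expect_gt(true_mean, m$ci_low)
  expect_lt(true_mean, m$ci_high)
})

test_that("group summary reports 6 family combinations plus overall", {
  cfg <- psf_sim_config(seed = 22)
  tr <- make_truth(cfg)
  pots <- simulate_greenhouse(default_pool, default_pairs, tr$truth, cfg)
  est <- estimate_pairwise_psf(pots, default_pairs)
  gs <- group_summary(est)
  expect_equal(nrow(gs), 7)
  expect_equal(sort(gs$k[gs$group != "overall"]), c(9L, 9L, 9L, rep(18L, 3)))
  expect_equal(gs$k[gs$group == "overall"], 81L)
  # the configured legume-legume pattern (least dissimilar soil communities)
  # gives the least negative pooled feedback
  expect_equal(gs$group[which.max(gs$estimate[1:6])], "F2:F2")
})
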