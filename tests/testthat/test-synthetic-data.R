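test_that("simulated dissimilarities are symmetric block matrices", {
  cfg <- psf_sim_config(seed = 2)
  d <- simulate_dissimilarities(default_pool, cfg, "soil_fungal_pathogen")
  expect_s3_class(d, "dissimilarity_matrix")
  expect_equal(diag(d$d), setNames(rep(0, 18), default_pool$species))
  expect_identical(d$d, t(d$d))
  expect_true(all(d$d >= 0 & d$d <= 1))
  # determinism
  d2 <- simulate_dissimilarities(default_pool, cfg, "soil_fungal_pathogen")
  expect_identical(d$d, d2$d)
  expect_error(simulate_dissimilarities(default_pool, cfg, "nope"),
               "unknown group")
})

test_that("zero-sd dissimilarities reproduce the configured block values", {
  means <- lapply(psf_sim_config()$dissimilarity_means, function(m) m)
  means[["soil_fungal_pathogen"]][] <- 0.7
  means[["soil_fungal_pathogen"]]["F2:F2"] <- 0.3
  cfg <- psf_sim_config(seed = 1, dissimilarity_sd = 0,
                        dissimilarity_means = means)
  d <- simulate_dissimilarities(default_pool, cfg, "soil_fungal_pathogen")$d
  legumes <- names(default_pool$family)[default_pool$family == "F2"]
  off <- d[legumes, legumes][upper.tri(diag(6))]
  expect_equal(unname(off), rep(0.3, 15))
  others <- d[legumes, setdiff(default_pool$species, legumes)]
  expect_true(all(others == 0.7))
})

test_that("ground-truth PSF evaluates the calibrated predictor", {
  cfg0 <- noiseless_config()
  # all dissimilarities forced to 0 / 1 via degenerate means
  for (v in c(0, 1)) {
    means <- lapply(cfg0$dissimilarity_means, function(m) { m[] <- v; m })
    cfg <- psf_sim_config(seed = 1, dissimilarity_sd = 0, psf_noise_sd = 0,
                          dissimilarity_means = means)
    tr <- make_truth(cfg)$truth
    expected <- if (v == 0) 1.589 else -1.52 - 2.27 - 1.27 + 1.589
    expect_equal(unique(round(tr$true_psf, 10)), round(expected, 10))
  }
  # determinism with noise off
  tr1 <- make_truth(noiseless_config(5))$truth
  tr2 <- make_truth(noiseless_config(5))$truth
  expect_identical(tr1, tr2)
  # missing predictor group errors
  cfg <- psf_sim_config(seed = 1)
  d <- make_truth(cfg)$dissims
  expect_error(simulate_true_psf(d[1:2], cfg), "missing predictor group")
})

test_that("greenhouse design has 702 pots with the stated replication", {
  cfg <- psf_sim_config(seed = 3)
  tr <- make_truth(cfg)
  pots <- simulate_greenhouse(default_pool, default_pairs, tr$truth, cfg)
  expect_equal(nrow(pots), 702)
  per_species <- table(pots$plant)
  expect_equal(as.vector(per_species), rep(39L, 18))  # 9 + 27 + 3
  one <- pots[pots$plant == default_pool$species[1], ]
  expect_equal(sum(one$inoculum == one$plant), 9)
  expect_equal(sum(one$inoculum == "sterile"), 3)
  expect_equal(as.vector(table(one$inoculum[!(one$inoculum %in%
    c(one$plant[1], "sterile"))])), rep(3L, 9))
})

test_that("noiseless greenhouse data round-trips the true PSF", {
  cfg <- noiseless_config(4)
  tr <- make_truth(cfg)
  pots <- simulate_greenhouse(default_pool, default_pairs, tr$truth, cfg)
  est <- suppressWarnings(estimate_pairwise_psf(pots, default_pairs))
  tm <- truth_matrix(tr$truth)
  expect_equal(est$psf, unname(tm[cbind(est$a, est$b)]), tolerance = 1e-10)
})

test_that("field design reproduces the 240-plot layout", {
  design <- make_field_design(default_pool)
  expect_equal(nrow(design), 240)
  expect_equal(sum(design$richness >= 2), 168)
  expect_equal(as.vector(table(design$richness)), c(72L, 72L, 48L, 48L))
  mono <- design[design$richness == 1, ]
  expect_equal(as.vector(table(unlist(plot_species(mono)))), rep(4L, 18))
  # paired shelters share compositions within a subblock
  for (b in 1:6) {
    sub <- design[design$subblock == b, ]
    sh <- split(sub$species, sub$shelter)
    expect_equal(sort(sh[[1]]), sort(sh[[2]]))
    expect_equal(lengths(sh), setNames(c(20L, 20L), names(sh)))
  }
  # under-dispersed mixtures are single-family
  fam_of <- default_pool$family
  for (k in which(design$dispersion == "under")) {
    fams <- unique(fam_of[plot_species(design)[[k]]])
    expect_length(fams, 1)
  }
})

test_that("null field generator yields no biodiversity effects", {
  cfg <- psf_sim_config(seed = 6, biomass_cv = 0, cover_noise_sd = 0,
                        dilution_gain = 0, psf_noise_sd = 0,
                        dissimilarity_sd = 0)
  tr <- make_truth(cfg)
  design <- make_field_design(default_pool, cfg)
  bio <- simulate_field_biomass(design, tr$truth, cfg)
  eff <- biodiversity_effects(bio, monoculture_reference(bio))
  expect_equal(max(abs(eff$CE)), 0, tolerance = 1e-9)
  expect_equal(max(abs(eff$SE)), 0, tolerance = 1e-9)
  expect_equal(eff$RYT, rep(1, nrow(eff)), tolerance = 1e-12)
})

test_that("positive dilution gain with negative PSF forces CE > 0", {
  cfg <- psf_sim_config(seed = 6, biomass_cv = 0, cover_noise_sd = 0,
                        dilution_gain = 0.5)
  tr <- make_truth(cfg)
  design <- make_field_design(default_pool, cfg)
  bio <- simulate_field_biomass(design, tr$truth, cfg)
  eff <- biodiversity_effects(bio, monoculture_reference(bio))
  # CE is strictly positive exactly in plots with negative plot-level PSF
  # (positive dilution score) under the noiseless generator
  tm <- truth_matrix(tr$truth)
  comp <- setNames(plot_species(design), design$plot_id)
  planted_psf <- vapply(eff$plot_id, function(p) {
    sp <- comp[[p]]
    plot_predicted_psf(sp, rep(1 / length(sp), length(sp)), tm)
  }, 0)
  expect_true(all(eff$CE[planted_psf < 0] > 0))
  expect_true(all(eff$CE[planted_psf > 0] < 0))
  # fixed seed => identical tables
  expect_identical(bio, simulate_field_biomass(design, tr$truth, cfg))
})

test_that("ASV overlap controls Bray-Curtis structure", {
  cfg <- psf_sim_config(seed = 8, asv_richness = 120)
  pool2 <- make_species_pool(1, 2)
  # full overlap -> identical compositions -> zero dissimilarity
  ov1 <- list(g = list(within = c(F1 = 1), between = 1))
  cfg1 <- psf_sim_config(seed = 8, asv_richness = 120, asv_overlap = ov1,
                         read_depth_range = c(3000L, 3000L),
                         dissimilarity_means = list(g = c("F1:F1" = 0)))
  t1 <- simulate_asv_tables(pool2, cfg1, "g", sampling = FALSE)
  d1 <- species_pair_dissimilarity(t1, "g")
  expect_equal(max(d1$d), 0, tolerance = 1e-6)
  # zero overlap -> disjoint features -> dissimilarity 1 even after rarefying
  ov0 <- list(g = list(within = c(F1 = 0), between = 0))
  cfg0 <- psf_sim_config(seed = 8, asv_richness = 120, asv_overlap = ov0,
                         dissimilarity_means = list(g = c("F1:F1" = 1)))
  t0 <- simulate_asv_tables(pool2, cfg0, "g")
  d0 <- species_pair_dissimilarity(rarefy_table(t0, "min", seed = 1), "g")
  expect_equal(min(d0$d[1, 2]), 1)
  # monotone: lower overlap => higher mean dissimilarity
  mean_bc <- vapply(c(0.8, 0.5, 0.2), function(o) {
    ov <- list(g = list(within = c(F1 = o), between = o))
    cfgo <- psf_sim_config(seed = 8, asv_richness = 120, asv_overlap = ov,
                           dissimilarity_means = list(g = c("F1:F1" = 1 - o)))
    tab <- simulate_asv_tables(pool2, cfgo, "g")
    mean(species_pair_dissimilarity(tab, "g")$d[1, 2])
  }, 0)
  expect_true(all(diff(mean_bc) > 0))
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- psf_sim_config(seed = 9)
  s1 <- simulate_study(cfg, asv = FALSE)
  s2 <- simulate_study(cfg, asv = FALSE)
  expect_identical(s1, s2)
})
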