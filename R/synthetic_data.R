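## Synthetic-data generators.  Each generator draws from its own seeded
## substream (stage_seed) so stages can be re-run independently and the whole
## chain is byte-identical under a fixed config seed.

#' Simulate a species-pair dissimilarity matrix for one microbial group
#'
#' Draws a symmetric Bray-Curtis-like dissimilarity matrix whose entry means
#' depend only on the microbial group and the unordered family combination of
#' the two species, emulating family-structured pathogen communities (with
#' legume-legume pairs most similar under the default configuration).
#'
#' @param pool A [make_species_pool()] pool.
#' @param config A [psf_sim_config()] configuration.
#' @param group Microbial group label; must be present in
#'   `config$dissimilarity_means`.
#' @return A `dissimilarity_matrix` object (see [as_dissimilarity_matrix()]).
#' @export
simulate_dissimilarities <- function(pool, config, group) {
  stopifnot(inherits(pool, "species_pool"), inherits(config, "psf_sim_config"))
  means <- config$dissimilarity_means[[group]]
  if (is.null(means))
    stop("unknown group `", group, "`: not in config$dissimilarity_means",
         call. = FALSE)
  sp <- pool$species
  set.seed(stage_seed(config$seed, 10 + match(group, names(config$dissimilarity_means))))
  n <- length(sp)
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    g <- family_group(pool$family[[sp[i]]], pool$family[[sp[j]]])
    val <- means[[g]] + stats::rnorm(1, 0, config$dissimilarity_sd)
    d[i, j] <- d[j, i] <- min(max(val, 0), 1)
  }
  as_dissimilarity_matrix(d, group = group)
}

#' Simulate ground-truth pairwise PSF from dissimilarities
#'
#' Evaluates the ground-truth linear dissimilarity-to-PSF predictor
#' (coefficients `config$psf_coef`, intercept `config$psf_intercept`) at the
#' simulated dissimilarities for every unordered species pair and adds
#' pair-level Gaussian noise of SD `config$psf_noise_sd`.
#'
#' @param dissims Named list of `dissimilarity_matrix` objects covering at
#'   least the predictor groups in `names(config$psf_coef)`.
#' @param config A [psf_sim_config()].
#' @return Data frame with columns `a`, `b` (species pair, pool order) and
#'   `true_psf` (log-response-ratio units).
#' @export
simulate_true_psf <- function(dissims, config) {
  need <- names(config$psf_coef)
  missing <- setdiff(need, names(dissims))
  if (length(missing))
    stop("missing predictor group(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sp <- rownames(dissims[[need[1]]]$d)
  set.seed(stage_seed(config$seed, 20))
  idx <- utils::combn(length(sp), 2)
  a <- sp[idx[1, ]]; b <- sp[idx[2, ]]
  psf <- rep(config$psf_intercept, ncol(idx))
  for (g in need) {
    dg <- dissims[[g]]$d
    psf <- psf + config$psf_coef[[g]] * dg[cbind(a, b)]
  }
  if (config$psf_noise_sd > 0)
    psf <- psf + stats::rnorm(length(psf), 0, config$psf_noise_sd)
  data.frame(a = a, b = b, true_psf = psf, stringsAsFactors = FALSE)
}

## look up true PSF as a symmetric matrix
true_psf_matrix <- function(truth) {
  sp <- unique(c(truth$a, truth$b))
  m <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  m[cbind(truth$a, truth$b)] <- truth$true_psf
  m[cbind(truth$b, truth$a)] <- truth$true_psf
  m
}

#' Simulate the greenhouse pot experiment
#'
#' Generates one row per pot for the pairwise feedback design: per species, 9
#' conspecific pots, 3 pots for each of its 9 designed heterospecific soil
#' inocula, and 3 sterile controls (39 pots per species; 702 in the default
#' design).  Log dry biomass is species effect + inoculum effect +
#' plant-by-inoculum interaction + `covariate_effect` x seedling height +
#' Gaussian noise, with interactions chosen so that the pairwise PSF
#' log-response contrast on noiseless cell means equals the ground-truth PSF
#' for every designed pair.
#'
#' @param pool,config As elsewhere.
#' @param pairs A [make_pairing_design()] table.
#' @param truth A [simulate_true_psf()] table.
#' @return Data frame with columns `pot_id`, `plant`, `inoculum`,
#'   `replicate`, `height_cm`, `shoot_g`, `root_g`.
#' @export
simulate_greenhouse <- function(pool, pairs, truth, config) {
  stopifnot(inherits(pool, "species_pool"))
  sp <- pool$species
  psf_m <- true_psf_matrix(truth)
  set.seed(stage_seed(config$seed, 30))
  ## deterministic species and inoculum main effects (log-gram scale)
  sp_eff <- stats::setNames(seq(log(2), log(6), length.out = length(sp)), sp)
  in_eff <- stats::setNames(seq(-0.05, 0.05, length.out = length(sp)), sp)
  partner <- partner_map(pairs, sp)
  rows <- list()
  for (p in sp) {
    soils <- c(rep(p, 9L), rep(partner[[p]], each = 3L), rep("sterile", 3L))
    reps <- c(seq_len(9L), rep(seq_len(3L), times = length(partner[[p]])),
              seq_len(3L))
    rows[[p]] <- data.frame(plant = p, inoculum = soils, replicate = reps,
                            stringsAsFactors = FALSE)
  }
  pots <- do.call(rbind, rows)
  rownames(pots) <- NULL
  n <- nrow(pots)
  pots$pot_id <- sprintf("pot_%03d", seq_len(n))
  pots$height_cm <- stats::rnorm(n, 10, 2)
  gamma <- ifelse(pots$inoculum == "sterile", 0.10,
                  ifelse(pots$inoculum == pots$plant, 0,
                         -psf_m[cbind(pots$plant,
                                      ifelse(pots$inoculum == "sterile",
                                             pots$plant, pots$inoculum))] / 2))
  log_b <- sp_eff[pots$plant] +
    ifelse(pots$inoculum == "sterile", 0, in_eff[pots$inoculum]) + gamma +
    config$covariate_effect * (pots$height_cm - 10) +
    stats::rnorm(n, 0, config$pot_noise_sd)
  total <- exp(unname(log_b))
  pots$shoot_g <- 0.7 * total
  pots$root_g <- 0.3 * total
  pots[, c("pot_id", "plant", "inoculum", "replicate", "height_cm",
           "shoot_g", "root_g")]
}

## species -> character vector of its designed heterospecific soil partners
partner_map <- function(pairs, species) {
  out <- stats::setNames(vector("list", length(species)), species)
  for (k in seq_len(nrow(pairs))) {
    out[[pairs$a[k]]] <- c(out[[pairs$a[k]]], pairs$b[k])
    out[[pairs$b[k]]] <- c(out[[pairs$b[k]]], pairs$a[k])
  }
  lapply(out, sort)
}

#' Build the field plot design
#'
#' Deterministically lays out 240 plots: six subblocks of paired 20-plot
#' shelters with matched plant compositions (the two shelters of a pair carry
#' the two precipitation labels).  Each shelter holds 6 monocultures, 3 + 3
#' under/over-dispersed two-species mixtures, 2 + 2 three-species mixtures
#' and 2 + 2 six-species mixtures.  Under-dispersed mixtures draw species
#' from a single family; over-dispersed mixtures span families.  Compositions
#' rotate round-robin so every species appears in near-equal plot counts per
#' treatment (each species appears in exactly 4 monoculture plots).
#'
#' @param pool,config As elsewhere; the pool must have the default 3 x 6
#'   shape.
#' @return Data frame with one row per plot: `plot_id`, `subblock`,
#'   `shelter`, `precip`, `richness`, `dispersion` (`"mono"`, `"under"` or
#'   `"over"`), and `species` (semicolon-joined species list).
#' @export
make_field_design <- function(pool, config = psf_sim_config()) {
  stopifnot(inherits(pool, "species_pool"))
  if (pool$n_families != 3 || pool$n_per_family != 6)
    stop("the field design requires the default 3-family x 6-species pool",
         call. = FALSE)
  fams <- unique(pool$family)
  by_fam <- split(pool$species, factor(pool$family[pool$species], levels = fams))
  sp <- pool$species
  m <- 6L
  ## candidate composition lists, interleaved across families so that
  ## consecutive draws spread over families
  within_pairs <- interleave(lapply(fams, function(f) {
    s <- by_fam[[f]]
    idx <- utils::combn(m, 2)
    lapply(seq_len(ncol(idx)), function(k) s[idx[, k]])
  }))
  fam_pairs <- utils::combn(fams, 2)
  between_pairs <- interleave(lapply(seq_len(ncol(fam_pairs)), function(cc) {
    sA <- by_fam[[fam_pairs[1, cc]]]; sB <- by_fam[[fam_pairs[2, cc]]]
    lapply(seq_len(2 * m), function(k)
      c(sA[((k - 1) %% m) + 1], sB[((k + (k - 1) %/% m) - 1) %% m + 1]))
  }))
  within_triples <- interleave(lapply(fams, function(f) {
    s <- by_fam[[f]]
    idx <- utils::combn(m, 3)
    lapply(seq_len(ncol(idx)), function(k) s[idx[, k]])
  }))
  over_triples <- lapply(seq_len(12L), function(t)
    c(by_fam[[1]][((t - 1) %% m) + 1],
      by_fam[[2]][((t) %% m) + 1],
      by_fam[[3]][((t + 1) %% m) + 1]))
  under_six <- lapply(seq_len(12L), function(t) by_fam[[((t - 1) %% 3) + 1]])
  over_six <- lapply(seq_len(12L), function(t)
    unlist(lapply(seq_along(fams), function(fi)
      by_fam[[fi]][c(((t - 1) %% m) + 1, ((t + 2) %% m) + 1)])))
  plots <- list()
  for (b in seq_len(6L)) {
    comp <- c(
      lapply(((b - 1) * 6 + 0:5) %% 18 + 1, function(i) sp[i]),   # 6 mono
      within_pairs[(b - 1) * 3 + 1:3],                            # 3 under-2
      between_pairs[(b - 1) * 3 + 1:3],                           # 3 over-2
      within_triples[(b - 1) * 2 + 1:2],                          # 2 under-3
      over_triples[(b - 1) * 2 + 1:2],                            # 2 over-3
      under_six[(b - 1) * 2 + 1:2],                               # 2 under-6
      over_six[(b - 1) * 2 + 1:2])                                # 2 over-6
    disp <- c(rep("mono", 6), rep("under", 3), rep("over", 3),
              rep("under", 2), rep("over", 2), rep("under", 2), rep("over", 2))
    for (sh in 1:2) {
      precip <- if (sh == 1) "50%" else "150%"
      for (k in seq_along(comp)) {
        plots[[length(plots) + 1L]] <- data.frame(
          subblock = b, shelter = (b - 1) * 2 + sh, precip = precip,
          richness = length(comp[[k]]), dispersion = disp[k],
          species = paste(comp[[k]], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, plots)
  out$plot_id <- sprintf("plot_%03d", seq_len(nrow(out)))
  out[, c("plot_id", "subblock", "shelter", "precip", "richness",
          "dispersion", "species")]
}

interleave <- function(lists) {
  k <- max(lengths(lists))
  out <- list()
  for (i in seq_len(k)) for (l in lists)
    if (i <= length(l)) out[[length(out) + 1L]] <- l[[i]]
  out
}

#' Split the semicolon-joined species column of a field design
#' @param design A [make_field_design()] table (or any table with a
#'   `species` column of semicolon-joined lists).
#' @return List of character vectors, one per row.
#' @export
plot_species <- function(design) strsplit(design$species, ";", fixed = TRUE)

#' Simulate field biomass and cover
#'
#' Monoculture plots yield the species' configured monoculture mean times
#' lognormal noise.  In mixtures, each member yields `M_i / N` scaled by
#' `1 + dilution_gain x dilution score`, where the dilution score is the
#' plot-level predicted pathogen dilution computed from the ground-truth PSF
#' matrix at equal planted proportions.  Percent cover is an affine function
#' of biomass plus Gaussian noise, to exercise the cover-to-biomass
#' regression.
#'
#' @param design A [make_field_design()] table.
#' @param truth A [simulate_true_psf()] table covering all pool pairs.
#' @param config A [psf_sim_config()].
#' @return Data frame: `plot_id`, `species`, `biomass_g`, `cover_pct`,
#'   plus the plot's `richness` and `dispersion`.
#' @export
simulate_field_biomass <- function(design, truth, config) {
  psf_m <- true_psf_matrix(truth)
  sp_all <- rownames(psf_m)
  M <- config$monoculture_means
  if (is.null(M)) M <- default_monoculture_means(sp_all)
  missing <- setdiff(unique(unlist(plot_species(design))), names(M))
  if (length(missing))
    stop("no monoculture mean configured for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  set.seed(stage_seed(config$seed, 40))
  sdlog <- sqrt(log(1 + config$biomass_cv^2))
  comp <- plot_species(design)
  rows <- vector("list", nrow(design))
  for (k in seq_len(nrow(design))) {
    members <- comp[[k]]
    N <- length(members)
    if (N == 1) {
      b <- M[members] * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    } else {
      p <- rep(1 / N, N)
      pred <- plot_predicted_psf(members, p, psf_m)
      dil <- pathogen_dilution(pred, N)
      b <- (M[members] / N) * (1 + config$dilution_gain * dil) *
        stats::rlnorm(N, -sdlog^2 / 2, sdlog)
    }
    cover <- config$cover_intercept + config$cover_slope * b +
      stats::rnorm(N, 0, config$cover_noise_sd)
    rows[[k]] <- data.frame(plot_id = design$plot_id[k], species = members,
                            biomass_g = unname(b),
                            cover_pct = pmax(unname(cover), 0),
                            richness = N, dispersion = design$dispersion[k],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## deterministic species monoculture means, decoupled from family order
default_monoculture_means <- function(species) {
  n <- length(species)
  vals <- seq(150, 450, length.out = n)
  ord <- ((seq_len(n) - 1) * 7) %% n + 1
  stats::setNames(vals[order(ord)], species)
}

#' Simulate ASV count tables for one microbial group
#'
#' Builds integer feature-count tables over a pool of shared,
#' family-specific and species-private features.  Each species allocates
#' compositional mass `between-overlap` to the shared block,
#' `within-overlap - between-overlap` to its family block and
#' `1 - within-overlap` to its private block, so the expected Bray-Curtis
#' dissimilarity between two monocultures is approximately
#' `1 - within-overlap` within a family and `1 - between-overlap` between
#' families.  Library sizes vary across `config$read_depth_range` to exercise
#' rarefaction; two monoculture samples are generated per species (paired
#' plots of matched composition pooled into one sample).  If a field design
#' is supplied, one sample per mixture plot is added with composition equal
#' to the mean of the member species' profiles, so the dominant pathogen of
#' each species is diluted in proportion to richness.
#'
#' @param pool,config,group As elsewhere.
#' @param design Optional [make_field_design()] table; mixture plots get
#'   samples.
#' @param sampling If `TRUE` (default) counts are multinomial draws; if
#'   `FALSE` counts are the rounded expected values (noise-free).
#' @return A `feature_table` object: list with `counts` (features x samples
#'   integer matrix), `samples` (data.frame: `sample`, `species`, `plot`,
#'   `richness`) and `features` (data.frame: `feature`, `primary_lifestyle`,
#'   `secondary_lifestyle`).
#' @export
simulate_asv_tables <- function(pool, config, group, design = NULL,
                                sampling = TRUE) {
  stopifnot(inherits(pool, "species_pool"))
  ov <- config$asv_overlap
  if (is.null(ov)) ov <- default_asv_overlap(config, pool)
  if (is.null(ov[[group]]))
    stop("no overlap configuration for group `", group, "`", call. = FALSE)
  ovg <- ov[[group]]
  fams <- unique(pool$family)
  if (any(ovg$within[fams] < ovg$between - 1e-12))
    stop("within-family overlap must be >= between-family overlap",
         call. = FALSE)
  sp <- pool$species
  R <- config$asv_richness
  nG <- max(2L, round(0.4 * R))
  nFam <- max(2L, round(0.3 * R / length(fams)))
  nSp <- max(2L, round(0.3 * R / length(sp)))
  feat_G <- sprintf("%s_shared_%03d", group, seq_len(nG))
  feat_F <- lapply(fams, function(f) sprintf("%s_%s_%03d", group, f, seq_len(nFam)))
  names(feat_F) <- fams
  feat_S <- lapply(sp, function(s) sprintf("%s_%s_%03d", group, s, seq_len(nSp)))
  names(feat_S) <- sp
  features <- c(feat_G, unlist(feat_F, use.names = FALSE),
                unlist(feat_S, use.names = FALSE))
  geo <- function(n) { w <- 0.65^(seq_len(n) - 1); w / sum(w) }
  profile <- function(s) {
    f <- pool$family[[s]]
    a <- ovg$between
    c_ <- 1 - ovg$within[[f]]
    b <- ovg$within[[f]] - a
    p <- stats::setNames(numeric(length(features)), features)
    p[feat_G] <- a * geo(nG)
    p[feat_F[[f]]] <- b * geo(nFam)
    p[feat_S[[s]]] <- c_ * geo(nSp)
    p
  }
  profiles <- vapply(sp, profile, numeric(length(features)))
  set.seed(stage_seed(config$seed, 50 + nchar(group)))
  samples <- data.frame(sample = character(0), species = character(0),
                        plot = character(0), richness = integer(0),
                        stringsAsFactors = FALSE)
  cols <- list()
  draw <- function(p) {
    rng <- config$read_depth_range
    depth <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    if (sampling) stats::rmultinom(1, depth, p)[, 1] else round(depth * p)
  }
  for (s in sp) for (r in 1:2) {
    id <- sprintf("mono_%s_%d", s, r)
    cols[[id]] <- draw(profiles[, s])
    samples[nrow(samples) + 1L, ] <- list(id, s, NA_character_, 1L)
  }
  if (!is.null(design)) {
    comp <- plot_species(design)
    for (k in which(design$richness > 1)) {
      id <- sprintf("mix_%s", design$plot_id[k])
      p <- rowMeans(profiles[, comp[[k]], drop = FALSE])
      cols[[id]] <- draw(p)
      samples[nrow(samples) + 1L, ] <-
        list(id, NA_character_, design$plot_id[k], design$richness[k])
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- features
  ## guild labels spread evenly over all blocks (cycle of 20 features:
  ## pathogen_frac primary pathogens, then 15% pathogen-in-secondary-only,
  ## rest saprotrophs) so filtering keeps every block's structure
  nfeat <- length(features)
  slot <- (seq_len(nfeat) - 1) %% 20
  primary <- ifelse(slot < 20 * config$asv_pathogen_frac,
                    "plant_pathogen", "soil_saprotroph")
  secondary <- ifelse(slot >= 20 * config$asv_pathogen_frac &
                        slot < 20 * (config$asv_pathogen_frac + 0.15),
                      "plant_pathogen", NA_character_)
  feature_table(counts, samples,
                data.frame(feature = features, primary_lifestyle = primary,
                           secondary_lifestyle = secondary,
                           stringsAsFactors = FALSE))
}

## default per-group overlap derived from the configured dissimilarity means
default_asv_overlap <- function(config, pool) {
  fams <- unique(pool$family)
  out <- list()
  for (g in names(config$dissimilarity_means)) {
    dm <- config$dissimilarity_means[[g]]
    within <- stats::setNames(
      vapply(fams, function(f) 1 - dm[[paste(f, f, sep = ":")]], 0), fams)
    between_labels <- setdiff(names(dm), paste(fams, fams, sep = ":"))
    out[[g]] <- list(within = within, between = 1 - mean(dm[between_labels]))
  }
  out
}

#' Write all synthetic inputs of one simulated study to TSV files
#'
#' Runs the full generator chain (pool, pairing design, dissimilarities,
#' ground-truth PSF, greenhouse pots, field design, field biomass, ASV
#' tables) and writes TSV files to a directory.
#'
#' @param config A [psf_sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of generated objects.
#' @export
write_synthetic_study <- function(config = psf_sim_config(), dir = ".") {
  study <- simulate_study(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(study$pairs, "pairing_design.tsv")
  tsv(study$truth, "true_psf.tsv")
  tsv(study$pots, "pots.tsv")
  tsv(study$design, "plots.tsv")
  tsv(study$biomass, "plot_biomass.tsv")
  for (g in names(study$dissims)) {
    d <- study$dissims[[g]]$d
    utils::write.table(data.frame(species = rownames(d), d,
                                  check.names = FALSE),
                       file.path(dir, paste0("dissim_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (g in names(study$asv)) {
    tab <- study$asv[[g]]
    utils::write.table(data.frame(feature = rownames(tab$counts), tab$counts,
                                  check.names = FALSE),
                       file.path(dir, paste0("asv_counts_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tsv(tab$samples, paste0("samples_", g, ".tsv"))
    tsv(tab$features, paste0("features_", g, ".tsv"))
  }
  invisible(study)
}

#' Generate one full synthetic study in memory
#'
#' @param config A [psf_sim_config()].
#' @param asv Also generate ASV tables (slowest stage); default `TRUE`.
#' @return Named list: `pool`, `pairs`, `dissims`, `truth`, `pots`,
#'   `design`, `biomass`, `asv`.
#' @export
simulate_study <- function(config = psf_sim_config(), asv = TRUE) {
  pool <- make_species_pool(config$n_families, config$n_per_family)
  pairs <- make_pairing_design(pool)
  dissims <- stats::setNames(
    lapply(config$groups, function(g) simulate_dissimilarities(pool, config, g)),
    config$groups)
  truth <- simulate_true_psf(dissims, config)
  pots <- simulate_greenhouse(pool, pairs, truth, config)
  design <- make_field_design(pool, config)
  biomass <- simulate_field_biomass(design, truth, config)
  asv_tabs <- if (asv) stats::setNames(
    lapply(config$groups, function(g)
      simulate_asv_tables(pool, config, g, design = design)),
    config$groups) else NULL
  list(pool = pool, pairs = pairs, dissims = dissims, truth = truth,
       pots = pots, design = design, biomass = biomass, asv = asv_tabs)
}
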