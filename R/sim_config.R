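#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  Defaults encode
#' the study conditions of the prairie experiment the package emulates:
#' 3 plant families x 6 species, 81 pairwise greenhouse feedback tests, 240
#' field plots, family-structured pathogen dissimilarities with the
#' legume-legume combinations lowest, and pairwise PSF values generated from
#' the calibrated dissimilarity-to-PSF linear predictor plus Gaussian noise.
#'
#' @param seed Integer seed; all generators are deterministic given the seed.
#' @param n_families,n_per_family Pool shape (default 3 x 6).
#' @param groups Microbial groups to simulate dissimilarities for.  The first
#'   three defaults are the predictor groups required by
#'   [simulate_true_psf()].
#' @param dissimilarity_means Named list: for each group, a named numeric
#'   vector of mean Bray-Curtis dissimilarity per unordered family
#'   combination (names like `"F1:F2"`), all in \[0, 1\].  `NULL` uses a
#'   default in which the legume family (`F2`) has the lowest within-family
#'   pathogen dissimilarity.
#' @param dissimilarity_sd SD of Gaussian jitter around the group/family-pair
#'   mean dissimilarity.
#' @param psf_coef Named slopes of the dissimilarity-to-PSF predictor used as
#'   ground truth (PSF units per unit dissimilarity).
#' @param psf_intercept Intercept of the ground-truth predictor (PSF units).
#' @param psf_noise_sd SD of the pair-level Gaussian noise added to the
#'   ground-truth PSF.
#' @param covariate_effect Slope of log biomass on initial seedling height
#'   (per cm).
#' @param pot_noise_sd Pot-level residual SD of log dry biomass.
#' @param biomass_cv Coefficient of variation of the multiplicative
#'   (lognormal) noise on field biomass.
#' @param dilution_gain Dimensionless effect of the plot pathogen-dilution
#'   score on per-species mixture yield.
#' @param monoculture_means Named vector of mean monoculture biomass
#'   (g m^-2) per species; `NULL` spreads species over 150-450 g m^-2.
#' @param cover_intercept,cover_slope,cover_noise_sd Affine map from biomass
#'   to percent cover (plus Gaussian noise) used to exercise the
#'   cover-to-biomass regression.
#' @param asv_richness Number of ASV features per simulated group table.
#' @param read_depth_range Length-2 integer range of library sizes.
#' @param asv_overlap Named list per group with elements `within` (named by
#'   family) and `between` (scalar): expected compositional overlap
#'   (1 - Bray-Curtis) for species pairs of each kind.  `NULL` derives it
#'   from `dissimilarity_means`.  Requires `within >= between`.
#' @param asv_pathogen_frac Fraction of features labelled plant pathogens in
#'   the primary lifestyle; a further 15% carry the label in the secondary
#'   lifestyle only.
#' @return A list of class `psf_sim_config`.
#' @export
psf_sim_config <- function(seed = 1L,
                           n_families = 3L,
                           n_per_family = 6L,
                           groups = c("soil_fungal_pathogen", "soil_oomycete",
                                      "root_fungal_pathogen"),
                           dissimilarity_means = NULL,
                           dissimilarity_sd = 0.15,
                           psf_coef = c(soil_fungal_pathogen = -1.52,
                                        soil_oomycete = -2.27,
                                        root_fungal_pathogen = -1.27),
                           psf_intercept = 1.589,
                           psf_noise_sd = 0.4,
                           covariate_effect = 0.02,
                           pot_noise_sd = 0.15,
                           biomass_cv = 0.2,
                           dilution_gain = 0.5,
                           monoculture_means = NULL,
                           cover_intercept = 2,
                           cover_slope = 0.15,
                           cover_noise_sd = 2,
                           asv_richness = 240L,
                           read_depth_range = c(2000L, 5000L),
                           asv_overlap = NULL,
                           asv_pathogen_frac = 0.7) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  fams <- paste0("F", seq_len(n_families))
  if (is.null(dissimilarity_means))
    dissimilarity_means <- default_dissim_means(groups, fams)
  for (g in names(dissimilarity_means)) {
    dm <- dissimilarity_means[[g]]
    if (any(dm < 0 | dm > 1))
      stop("dissimilarity means must lie in [0, 1]", call. = FALSE)
  }
  if (dissimilarity_sd < 0 || psf_noise_sd < 0 || pot_noise_sd < 0 ||
      biomass_cv < 0 || cover_noise_sd < 0)
    stop("all standard deviations must be >= 0", call. = FALSE)
  if (length(read_depth_range) != 2 || any(read_depth_range < 1) ||
      read_depth_range[1] > read_depth_range[2])
    stop("`read_depth_range` must be an increasing positive pair", call. = FALSE)
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              n_per_family = as.integer(n_per_family), groups = groups,
              dissimilarity_means = dissimilarity_means,
              dissimilarity_sd = dissimilarity_sd,
              psf_coef = psf_coef, psf_intercept = psf_intercept,
              psf_noise_sd = psf_noise_sd,
              covariate_effect = covariate_effect,
              pot_noise_sd = pot_noise_sd,
              biomass_cv = biomass_cv, dilution_gain = dilution_gain,
              monoculture_means = monoculture_means,
              cover_intercept = cover_intercept, cover_slope = cover_slope,
              cover_noise_sd = cover_noise_sd,
              asv_richness = as.integer(asv_richness),
              read_depth_range = as.integer(read_depth_range),
              asv_overlap = asv_overlap,
              asv_pathogen_frac = asv_pathogen_frac)
  class(cfg) <- "psf_sim_config"
  cfg
}

## default family-combination dissimilarity means: legume (F2) within-family
## pathogen communities are most similar, between-family pairs most distinct
default_dissim_means <- function(groups, fams) {
  labels <- unique(c(outer(fams, fams, function(a, b)
    paste(pmin(a, b), pmax(a, b), sep = ":"))))
  base <- c(soil_fungal_pathogen = 0.85, soil_oomycete = 0.80,
            root_fungal_pathogen = 0.82)
  within <- c(soil_fungal_pathogen = 0.72, soil_oomycete = 0.68,
              root_fungal_pathogen = 0.70)
  legume <- c(soil_fungal_pathogen = 0.45, soil_oomycete = 0.52,
              root_fungal_pathogen = 0.48)
  out <- list()
  for (g in groups) {
    bg <- if (g %in% names(base)) base[[g]] else 0.8
    wg <- if (g %in% names(within)) within[[g]] else 0.7
    lg <- if (g %in% names(legume)) legume[[g]] else 0.5
    m <- setNames(rep(bg, length(labels)), labels)
    for (f in fams) m[paste(f, f, sep = ":")] <- wg
    if ("F2" %in% fams) m["F2:F2"] <- lg
    out[[g]] <- m
  }
  out
}

## deterministic sub-seed for a generator stage, kept inside 32-bit range
stage_seed <- function(seed, stage) {
  (as.double(seed) * 7919 + stage) %% 2147483629
}
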