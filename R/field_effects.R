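## Biodiversity effects from field biomass: the additive (Loreau-Hector)
## partition of the net biodiversity effect into complementarity and
## selection, relative yield totals, overyielding tests and the regressions
## of complementarity on predicted PSF / pathogen dilution.

#' Species-specific cover-to-biomass conversion
#'
#' Fits a simple linear regression of biomass on percent cover per species
#' from paired calibration observations, and predicts plot-level per-species
#' biomass from cover surveys.  Species with fewer than 3 calibration pairs
#' (or zero cover variance) fall back to a pooled all-species regression
#' with a warning.
#'
#' @param calibration Data frame with columns `species`, `cover_pct`,
#'   `biomass_g` (paired strip observations).
#' @param surveys Data frame with columns `species` and `cover_pct` to
#'   predict biomass for (e.g. one row per plot x species); optional.
#' @return List: `fits` (per-species intercept/slope/n and whether the
#'   pooled fallback was used), `r` (overall Pearson correlation between
#'   cover and biomass), and if `surveys` given, `predicted` (the surveys
#'   with a `biomass_g` column appended, floored at 0).
#' @export
cover_to_biomass <- function(calibration, surveys = NULL) {
  pooled <- stats::lm(biomass_g ~ cover_pct, data = calibration)
  fits <- list()
  for (s in sort(unique(calibration$species))) {
    d <- calibration[calibration$species == s, , drop = FALSE]
    fallback <- nrow(d) < 3 || stats::sd(d$cover_pct) == 0
    if (fallback) {
      warning("species ", s, ": ", nrow(d),
              " calibration pair(s) or zero cover variance; pooled fit used")
      cf <- stats::coef(pooled)
    } else {
      cf <- stats::coef(stats::lm(biomass_g ~ cover_pct, data = d))
    }
    fits[[s]] <- data.frame(species = s, intercept = cf[[1]], slope = cf[[2]],
                            n = nrow(d), pooled = fallback,
                            stringsAsFactors = FALSE)
  }
  fits <- do.call(rbind, fits)
  rownames(fits) <- NULL
  out <- list(fits = fits,
              r = stats::cor(calibration$cover_pct, calibration$biomass_g))
  if (!is.null(surveys)) {
    idx <- match(surveys$species, fits$species)
    if (anyNA(idx)) stop("survey species without calibration: ",
                         paste(unique(surveys$species[is.na(idx)]),
                               collapse = ", "), call. = FALSE)
    surveys$biomass_g <- pmax(
      fits$intercept[idx] + fits$slope[idx] * surveys$cover_pct, 0)
    out$predicted <- surveys
  }
  out
}

#' Mean monoculture biomass per species
#'
#' @param biomass Long plot x species biomass table with `plot_id`,
#'   `species`, `biomass_g` and `richness`.
#' @return List of class `monoculture_reference`: `M` (named means, g m^-2)
#'   and `n_plots` (named counts).
#' @export
monoculture_reference <- function(biomass) {
  mono <- biomass[biomass$richness == 1, , drop = FALSE]
  if (!nrow(mono)) stop("no monoculture plots in table", call. = FALSE)
  M <- tapply(mono$biomass_g, mono$species, mean)
  structure(list(M = c(M), n_plots = c(table(mono$species))),
            class = "monoculture_reference")
}

#' Biodiversity effects per mixture plot
#'
#' For each mixture, computes per-species relative yields
#' `RY_i = B_i_mix / M_i`, deviations `dRY_i = RY_i - 1/N` from the equal
#' planting expectation, and the additive partition
#' `CE = N x mean(dRY) x mean(M)`, `SE = N x cov(dRY, M)` (population
#' covariance, so `CE + SE` equals the net biodiversity effect exactly),
#' the relative yield total `RYT = sum RY_i`, and the net effect
#' `sum B_i_mix - sum M_i / N`.  Species planted but absent at harvest must
#' appear with biomass 0 in the table to contribute `RY = 0`.
#'
#' @param biomass Long plot x species biomass table (`plot_id`, `species`,
#'   `biomass_g`; mixture plots = plots with >= 2 rows).
#' @param ref A [monoculture_reference()] (or any list with named `M`).
#' @return Data frame of class `biodiversity_effects`: `plot_id`, `richness`,
#'   `CE`, `SE`, `net`, `RYT` (one row per mixture plot), with the
#'   per-species deviations in attribute `"delta_ry"`.
#' @export
biodiversity_effects <- function(biomass, ref) {
  M_all <- ref$M
  rows <- list()
  dry <- list()
  for (d in split(biomass, biomass$plot_id)) {
    N <- nrow(d)
    if (N < 2) next
    if (anyNA(match(d$species, names(M_all))) ||
        any(M_all[d$species] <= 0)) {
      bad <- d$species[is.na(match(d$species, names(M_all))) |
                         !(M_all[d$species] > 0)]
      stop("no positive monoculture mean for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    M <- M_all[d$species]
    ry <- d$biomass_g / M
    dRY <- ry - 1 / N
    ## population covariance makes CE + SE = net exactly
    covp <- mean(dRY * M) - mean(dRY) * mean(M)
    CE <- N * mean(dRY) * mean(M)
    SE <- N * covp
    rows[[d$plot_id[1]]] <- data.frame(
      plot_id = d$plot_id[1], richness = N, CE = CE, SE = SE,
      net = sum(d$biomass_g) - sum(M) / N, RYT = sum(ry),
      stringsAsFactors = FALSE)
    dry[[d$plot_id[1]]] <- stats::setNames(dRY, d$species)
  }
  if (!length(rows)) stop("no mixture plots (>= 2 species) found",
                          call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "delta_ry") <- dry
  class(out) <- c("biodiversity_effects", "data.frame")
  out
}

#' Regress biodiversity effects on predicted PSF and dilution
#'
#' Simple OLS regressions of complementarity and relative yield total on the
#' plot-level predicted PSF effect and predicted pathogen dilution, with the
#' overall F-test and adjusted R-squared per regression.
#'
#' @param effects A [biodiversity_effects()] table.
#' @param scores A [plot_scores()] table (matched by `plot_id`).
#' @param min_plots Minimum number of mixture plots (default 10).
#' @return Data frame: `response`, `predictor`, `slope`, `intercept`,
#'   `adj_r_squared`, `f_p`, `n`.
#' @export
effects_regression <- function(effects, scores, min_plots = 10) {
  d <- merge(effects, scores[, c("plot_id", "predicted_psf", "dilution")],
             by = "plot_id")
  if (nrow(d) < min_plots)
    stop("need >= ", min_plots, " mixture plots", call. = FALSE)
  out <- list()
  for (resp in c("CE", "RYT")) for (pred in c("predicted_psf", "dilution")) {
    if (stats::sd(d[[pred]]) == 0)
      stop("zero-variance predictor: ", pred, call. = FALSE)
    fit <- fit_ols(d[, pred, drop = FALSE], d[[resp]])
    out[[paste(resp, pred)]] <- data.frame(
      response = resp, predictor = pred,
      slope = fit$coefficients[[pred]],
      intercept = fit$coefficients[["(Intercept)"]],
      adj_r_squared = fit$adj_r_squared, f_p = fit$f_p, n = fit$n,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' One-sided overyielding tests per richness level
#'
#' One-sample t-tests of complementarity > 0 and relative yield total > 1
#' within each mixture richness level.
#'
#' @param effects A [biodiversity_effects()] table.
#' @return Data frame: `richness`, `n`, `mean_CE`, `p_CE` (H1: CE > 0),
#'   `mean_RYT`, `p_RYT` (H1: RYT > 1).  Levels with a single plot are
#'   skipped with a warning; zero-variance samples report `NA`.
#' @export
overyielding_tests <- function(effects) {
  out <- list()
  for (N in sort(unique(effects$richness))) {
    d <- effects[effects$richness == N, , drop = FALSE]
    if (nrow(d) < 2) {
      warning("richness ", N, ": single plot, test skipped")
      next
    }
    p1 <- if (stats::sd(d$CE) == 0) NA_real_ else
      stats::t.test(d$CE, mu = 0, alternative = "greater")$p.value
    p2 <- if (stats::sd(d$RYT) == 0) NA_real_ else
      stats::t.test(d$RYT, mu = 1, alternative = "greater")$p.value
    out[[as.character(N)]] <- data.frame(
      richness = N, n = nrow(d), mean_CE = mean(d$CE), p_CE = p1,
      mean_RYT = mean(d$RYT), p_RYT = p2, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
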