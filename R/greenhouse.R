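## Pairwise plant-soil feedback from greenhouse pot data: covariate-adjusted
## cell means of log biomass, the log-response-ratio PSF contrast, its
## delta-method variance, and random-effects meta-analysis of the pair set.

#' Covariate-adjusted plant x inoculum cell means
#'
#' Fits log dry biomass on the plant x inoculum cells plus a per-species
#' slope on initial seedling height (centred within plant species), so each
#' cell mean is the fitted value at that species' mean height.  Sterile
#' controls are excluded.  Also records, per cell, the raw-scale mean,
#' within-cell sample variance and replicate count used by the Eq.-(2)-style
#' variance.
#'
#' @param pots Pot table with columns `plant`, `inoculum`, `height_cm` and
#'   biomass columns `shoot_g`, `root_g`.
#' @param biomass `"total"` (shoot + root, default) or `"shoot"`.
#' @return Object of class `psf_cell_means`: list of matrices `m` (log-scale
#'   adjusted cell mean), `se` (its standard error), `mean_raw`, `var_raw`,
#'   `n` (rows = plant species, columns = soil/inoculum species).
#' @export
fit_cell_means <- function(pots, biomass = c("total", "shoot")) {
  biomass <- match.arg(biomass)
  pots <- pots[pots$inoculum != "sterile", , drop = FALSE]
  b <- if (biomass == "total") pots$shoot_g + pots$root_g else pots$shoot_g
  if (any(b <= 0)) stop("biomass must be positive for the log transform",
                        call. = FALSE)
  plants <- sort(unique(pots$plant))
  soils <- sort(unique(pots$inoculum))
  cell <- interaction(factor(pots$plant, plants),
                      factor(pots$inoculum, soils), drop = TRUE, sep = "\r")
  counts <- table(cell)
  if (any(counts < 1)) stop("designed cell without pots", call. = FALSE)
  ## centre height within plant species: cell coefficients then equal the
  ## adjusted mean at each species' own mean height
  hbar <- tapply(pots$height_cm, pots$plant, mean)
  hc <- pots$height_cm - hbar[pots$plant]
  log_b <- log(b)
  fit <- stats::lm(log_b ~ 0 + cell + factor(plant, plants):hc, data =
                     data.frame(cell = cell, plant = pots$plant, hc = hc))
  cf <- stats::coef(fit)
  vc <- diag(stats::vcov(fit))
  m <- se <- mean_raw <- var_raw <- nmat <-
    matrix(NA_real_, length(plants), length(soils),
           dimnames = list(plants, soils))
  for (lv in levels(cell)) {
    ps <- strsplit(lv, "\r", fixed = TRUE)[[1]]
    cn <- paste0("cell", lv)
    m[ps[1], ps[2]] <- cf[[cn]]
    se[ps[1], ps[2]] <- sqrt(vc[[cn]])
    in_cell <- cell == lv
    raw <- b[in_cell]
    mean_raw[ps[1], ps[2]] <- mean(raw)
    var_raw[ps[1], ps[2]] <- if (length(raw) > 1) stats::var(raw) else 0
    nmat[ps[1], ps[2]] <- length(raw)
  }
  structure(list(m = m, se = se, mean_raw = mean_raw, var_raw = var_raw,
                 n = nmat, biomass = biomass),
            class = "psf_cell_means")
}

#' @export
print.psf_cell_means <- function(x, ...) {
  cat("Adjusted cell means (", x$biomass, " log biomass): ",
      nrow(x$m), " plant species x ", ncol(x$m), " inocula, ",
      sum(!is.na(x$m)), " filled cells\n", sep = "")
  invisible(x)
}

## the four cells of a pair; errors if any is missing
pair_cells <- function(cells, a, b) {
  need <- rbind(c(a, a), c(b, b), c(a, b), c(b, a))
  known <- need[, 1] %in% rownames(cells$m) & need[, 2] %in% colnames(cells$m)
  miss <- !known
  miss[known] <- is.na(cells$m[need[known, , drop = FALSE]])
  if (any(miss))
    stop("missing cell(s): ",
         paste(apply(need[miss, , drop = FALSE], 1, paste, collapse = " in "),
               collapse = "; "), call. = FALSE)
  need
}

#' Pairwise plant-soil feedback (log response ratio)
#'
#' The PSF between species A and B is the log-scale contrast
#' `m[A,A] + m[B,B] - m[A,B] - m[B,A]` of adjusted cell means (plant in
#' rows, soil in columns): the performance of each species on conspecific
#' soil relative to the partner's soil.  Negative values favour coexistence.
#'
#' @param cells A [fit_cell_means()] object.
#' @param a,b The two species.
#' @return The PSF estimate (dimensionless, log-response-ratio units).
#' @export
pairwise_psf <- function(cells, a, b) {
  idx <- pair_cells(cells, a, b)
  sum(cells$m[idx] * c(1, 1, -1, -1))
}

#' Variance of a pairwise PSF estimate
#'
#' Delta-method variance of the four-term log contrast: the sum over the
#' four cells of `Var / (N x mean^2)` on the raw biomass scale.  Because each
#' conspecific cell mean is reused in all nine pairwise feedbacks involving
#' that species, the conspecific sample sizes are deflated to
#' `conspecific_effective_n` (default 1 = 9 replicates / 9 feedback
#' estimates).
#'
#' @param cells A [fit_cell_means()] object.
#' @param a,b The two species.
#' @param conspecific_effective_n Effective N for the two conspecific cells.
#' @return The variance of [pairwise_psf()].
#' @export
psf_variance <- function(cells, a, b, conspecific_effective_n = 1) {
  idx <- pair_cells(cells, a, b)
  mu <- cells$mean_raw[idx]
  v <- cells$var_raw[idx]
  n <- cells$n[idx]
  if (any(mu == 0)) stop("zero raw-scale cell mean", call. = FALSE)
  n[1:2] <- conspecific_effective_n
  sum(v / (n * mu^2))
}

#' Estimate all designed pairwise PSFs from a pot table
#'
#' @param pots Pot table (see [fit_cell_means()]).
#' @param pairs A [make_pairing_design()] table giving the designed pairs
#'   and their family-combination labels.
#' @param biomass Passed to [fit_cell_means()].
#' @param conspecific_effective_n Passed to [psf_variance()].
#' @return Data frame of class `pairwise_psf_table`: `a`, `b`, `group`,
#'   `psf`, `var_psf`.
#' @export
estimate_pairwise_psf <- function(pots, pairs, biomass = "total",
                                  conspecific_effective_n = 1) {
  cells <- fit_cell_means(pots, biomass)
  out <- pairs[, c("a", "b", "group")]
  out$psf <- mapply(function(a, b) pairwise_psf(cells, a, b),
                    pairs$a, pairs$b)
  out$var_psf <- mapply(function(a, b)
    psf_variance(cells, a, b, conspecific_effective_n), pairs$a, pairs$b)
  class(out) <- c("pairwise_psf_table", "data.frame")
  out
}

#' Random-effects pooling of pairwise PSF estimates
#'
#' Pools the pairwise estimates with a random-effects model (REML via
#' [metafor::rma.mv()], pairwise combination as the random effect, the
#' per-pair delta-method variance as the sampling variance).  The pooled
#' PSF is significantly different from zero when the 95% confidence
#' interval excludes zero.
#'
#' @param psfs A data frame with columns `psf` and `var_psf` (e.g. from
#'   [estimate_pairwise_psf()]), optionally filtered to one family
#'   combination.
#' @return Object of class `psf_meta`: list with `estimate`, `se`,
#'   `ci_low`, `ci_high`, `tau2`, `k`, `significant`.
#' @export
meta_analyze <- function(psfs) {
  if (nrow(psfs) < 2)
    stop("need at least 2 pairwise estimates to pool", call. = FALSE)
  dat <- data.frame(yi = psfs$psf, vi = psfs$var_psf,
                    pair = seq_len(nrow(psfs)))
  fit <- metafor::rma.mv(yi, vi, random = ~ 1 | pair, data = dat)
  est <- as.numeric(fit$beta)
  structure(list(estimate = est, se = fit$se,
                 ci_low = fit$ci.lb, ci_high = fit$ci.ub,
                 tau2 = sum(fit$sigma2), k = nrow(psfs),
                 significant = fit$ci.lb > 0 | fit$ci.ub < 0),
            class = "psf_meta")
}

#' @export
print.psf_meta <- function(x, ...) {
  cat(sprintf("Pooled PSF: %.3f [%.3f, %.3f] (k = %d, tau^2 = %.4f)%s\n",
              x$estimate, x$ci_low, x$ci_high, x$k, x$tau2,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pooled PSF per family combination and overall
#'
#' @param psfs A `pairwise_psf_table` with a `group` column.
#' @return Data frame with one row per family combination plus `"overall"`:
#'   `group`, `k`, `estimate`, `ci_low`, `ci_high`, `tau2`, `significant`.
#' @export
group_summary <- function(psfs) {
  groups <- sort(unique(psfs$group))
  res <- list()
  for (g in c(groups, "overall")) {
    sub <- if (g == "overall") psfs else psfs[psfs$group == g, , drop = FALSE]
    if (nrow(sub) < 2) {
      warning("group ", g, " has < 2 pairs; omitted")
      next
    }
    m <- meta_analyze(sub)
    res[[g]] <- data.frame(group = g, k = m$k, estimate = m$estimate,
                           ci_low = m$ci_low, ci_high = m$ci_high,
                           tau2 = m$tau2, significant = m$significant,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
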