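## The dissimilarity-to-PSF linear predictor: exhaustive AICc model
## selection over main-effect subsets, Akaike-weight model averaging,
## predictor importance, and plot-level predicted PSF / pathogen dilution.

#' Ordinary least squares with fit statistics
#'
#' Thin wrapper around [stats::lm()] returning the quantities the selection
#' machinery needs: coefficients, residual sum of squares, adjusted R-squared
#' and the overall F-test p-value.
#'
#' @param X Numeric matrix or data frame of predictor columns (may have zero
#'   columns for the intercept-only model).
#' @param y Numeric response.
#' @return List: `coefficients` (named, incl. `(Intercept)`), `rss`,
#'   `r_squared`, `adj_r_squared`, `f_p`, `n`, `p` (number of slopes).
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need more rows than parameters", call. = FALSE)
  Xf <- cbind(`(Intercept)` = 1, X)
  q <- qr(Xf)
  if (q$rank < ncol(Xf))
    stop("collinear predictors: rank ", q$rank, " < ", ncol(Xf),
         call. = FALSE)
  cf <- qr.coef(q, y)
  res <- y - Xf %*% cf
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  f_p <- if (p > 0 && tss > rss) {
    f <- ((tss - rss) / p) / (rss / (n - p - 1))
    stats::pf(f, p, n - p - 1, lower.tail = FALSE)
  } else NA_real_
  list(coefficients = stats::setNames(as.numeric(cf), colnames(Xf)),
       rss = rss, r_squared = r2, adj_r_squared = adj, f_p = f_p,
       n = n, p = p)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = n log(RSS / n) + 2k + 2k(k + 1)/(n - k - 1)` for a Gaussian
#' model, with the additive constant dropped (it is common to all models of
#' the same data, so AICc differences are unaffected).  `k` counts all
#' estimated parameters including the intercept and the residual variance.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param k Parameter count (slopes + intercept + variance).
#' @return The AICc value.
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  ## floor the RSS so an exact (zero-residual) fit stays finite; ties among
  ## exact fits are then broken by the parameter-count penalty
  rss <- max(rss, n * 1e-300)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Exhaustive AICc model selection over predictor subsets
#'
#' Fits every main-effects subset of the predictors (including the
#' intercept-only model), ranks models by AICc, converts AICc differences to
#' Akaike weights `w_m = exp(-Delta_m / 2) / sum exp(-Delta / 2)`, scores
#' each predictor's importance as the summed weight of the models containing
#' it, and averages the intercept over all models by weight.
#'
#' @param data Data frame containing the response and predictor columns.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names (at most
#'   15).
#' @param importance_cutoff Importance level above which a predictor is
#'   flagged important (default 0.7).
#' @return Object of class `psf_selection`: list with `models` (data frame:
#'   one row per subset with `formula`, `k`, `rss`, `aicc`, `delta`,
#'   `weight`, `adj_r_squared`), `coefficients` (list of named coefficient
#'   vectors), `importance` (named, sorted decreasing), `important`
#'   (names with importance >= cutoff), `averaged_intercept`, `best`
#'   (index of the lowest-AICc model), `response`, `predictors`.
#' @export
exhaustive_selection <- function(data, response, predictors,
                                 importance_cutoff = 0.7) {
  p <- length(predictors)
  if (p > 15) stop("more than 15 predictors: 2^p subsets not enumerable",
                   call. = FALSE)
  miss <- setdiff(c(response, predictors), names(data))
  if (length(miss)) stop("columns not in data: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  y <- data[[response]]
  n <- length(y)
  nm <- 2^p
  rows <- vector("list", nm)
  coefs <- vector("list", nm)
  kept <- logical(nm)
  for (m in seq_len(nm)) {
    in_model <- as.logical(bitwAnd(m - 1L, bitwShiftL(1L, seq_len(p) - 1L)))
    vars <- predictors[in_model]
    fit <- tryCatch(fit_ols(data[, vars, drop = FALSE], y),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("subset {", paste(vars, collapse = ", "), "} skipped: ",
              conditionMessage(fit))
      next
    }
    k <- length(vars) + 2  # slopes + intercept + residual variance
    rows[[m]] <- data.frame(
      formula = paste(response, "~", if (length(vars))
        paste(vars, collapse = " + ") else "1"),
      k = k, rss = fit$rss, aicc = aicc(fit$rss, n, k),
      adj_r_squared = fit$adj_r_squared, stringsAsFactors = FALSE)
    coefs[[m]] <- fit$coefficients
    kept[m] <- TRUE
  }
  models <- do.call(rbind, rows[kept])
  coefs <- coefs[kept]
  models$delta <- models$aicc - min(models$aicc)
  w <- exp(-models$delta / 2)
  models$weight <- w / sum(w)
  imp <- stats::setNames(numeric(p), predictors)
  for (i in seq_along(coefs))
    for (v in intersect(names(coefs[[i]]), predictors))
      imp[v] <- imp[v] + models$weight[i]
  imp <- sort(imp, decreasing = TRUE)
  avg_int <- sum(models$weight * vapply(coefs, `[[`, 0, "(Intercept)"))
  structure(list(models = models, coefficients = coefs, importance = imp,
                 important = names(imp)[imp >= importance_cutoff],
                 averaged_intercept = avg_int,
                 best = which.min(models$aicc),
                 response = response, predictors = predictors,
                 importance_cutoff = importance_cutoff),
            class = "psf_selection")
}

#' @export
print.psf_selection <- function(x, ...) {
  cat("Exhaustive AICc selection:", nrow(x$models), "models over",
      length(x$predictors), "predictors\n")
  cat("Best model:", x$models$formula[x$best], "\n")
  cat("Importance (cutoff ", x$importance_cutoff, "):\n", sep = "")
  print(round(x$importance, 3))
  cat("Weight-averaged intercept:", round(x$averaged_intercept, 4), "\n")
  invisible(x)
}

#' Construct a dissimilarity-to-PSF predictor from known coefficients
#'
#' The default coefficients are the field-calibrated values for the three
#' retained microbial predictors of the prairie experiment (soil fungal
#' pathogen, soil oomycete and root fungal pathogen Bray-Curtis
#' dissimilarities), with the model-averaged intercept:
#' `PSF_ij = -1.52 d_sfp - 2.27 d_so - 1.27 d_rfp + 1.589`.
#'
#' @param coefficients Named numeric vector of slopes (PSF units per unit
#'   dissimilarity).
#' @param intercept Intercept (PSF units).
#' @return Object of class `psf_predictor`.
#' @export
psf_predictor <- function(coefficients = c(soil_fungal_pathogen = -1.52,
                                           soil_oomycete = -2.27,
                                           root_fungal_pathogen = -1.27),
                          intercept = 1.589) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            is.numeric(intercept), length(intercept) == 1,
            all(is.finite(c(coefficients, intercept))))
  structure(list(coefficients = coefficients, intercept = intercept,
                 selection = NULL, data = NULL, fitted = NULL),
            class = "psf_predictor")
}

#' Fit the dissimilarity-to-PSF predictor
#'
#' The central fitting function of the package: given measured pairwise PSF
#' values and per-pair microbial dissimilarities, runs exhaustive AICc model
#' selection over all main-effect subsets ([exhaustive_selection()]), and
#' assembles the final linear predictor with slopes taken from the
#' best-AICc model restricted to the chosen predictor set and the
#' weight-averaged intercept.
#'
#' @param data Data frame with the response column and one column per
#'   candidate dissimilarity predictor.
#' @param response Response column name (default `"psf"`).
#' @param predictors Candidate predictor columns; default all numeric
#'   columns except the response.
#' @param use Which predictors enter the final model: `"best"` (those of the
#'   lowest-AICc model, default) or a character vector of predictor names
#'   (each must appear in the best model containing it; slopes are then
#'   refit by OLS on exactly that subset).
#' @param importance_cutoff Importance threshold (default 0.7).
#' @return Object of class `psf_predictor` with the selection results
#'   attached; supports `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals` and `simulate`.
#' @seealso [psf_predictor()] to build a predictor from fixed coefficients.
#' @export
fit_psf_predictor <- function(data, response = "psf", predictors = NULL,
                              use = "best", importance_cutoff = 0.7) {
  if (is.null(predictors)) {
    num <- vapply(data, is.numeric, TRUE)
    predictors <- setdiff(names(data)[num], response)
  }
  sel <- exhaustive_selection(data, response, predictors, importance_cutoff)
  best_cf <- sel$coefficients[[sel$best]]
  if (identical(use, "best")) {
    chosen <- setdiff(names(best_cf), "(Intercept)")
  } else {
    chosen <- use
    bad <- setdiff(chosen, setdiff(names(best_cf), "(Intercept)"))
    if (length(bad)) stop("predictor(s) not in the best model: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  slopes <- best_cf[chosen]
  obj <- psf_predictor(coefficients = slopes,
                       intercept = sel$averaged_intercept)
  obj$selection <- sel
  obj$data <- data[, c(response, predictors), drop = FALSE]
  obj$response <- response
  obj$fitted <- as.numeric(obj$intercept +
    as.matrix(data[, chosen, drop = FALSE]) %*% slopes)
  obj$sigma <- sqrt(sum((data[[response]] - obj$fitted)^2) /
                      max(nrow(data) - length(chosen) - 1, 1))
  obj
}

#' @export
print.psf_predictor <- function(x, ...) {
  cat("Dissimilarity-to-PSF predictor\n")
  cat("  PSF_ij =", paste(sprintf("%+.4g * %s", x$coefficients,
                                  names(x$coefficients)), collapse = " "),
      sprintf("%+.4g", x$intercept), "\n")
  if (!is.null(x$selection))
    cat("  fitted by exhaustive AICc selection over",
        length(x$selection$predictors), "candidate predictors\n")
  invisible(x)
}

#' @export
coef.psf_predictor <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.psf_predictor <- function(object, ...) {
  print(object)
  if (!is.null(object$selection)) {
    sel <- object$selection
    cat("\nTop models by AICc:\n")
    ord <- order(sel$models$aicc)[seq_len(min(5, nrow(sel$models)))]
    print(sel$models[ord, c("formula", "k", "aicc", "delta", "weight",
                            "adj_r_squared")], row.names = FALSE,
          digits = 4)
    cat("\nPredictor importance (summed Akaike weights):\n")
    print(round(sel$importance, 3))
  }
  invisible(object)
}

#' @export
residuals.psf_predictor <- function(object, ...) {
  if (is.null(object$fitted)) stop("predictor was not fitted to data",
                                   call. = FALSE)
  object$data[[object$response]] - object$fitted
}

#' Predict pairwise PSF from dissimilarities
#'
#' @param object A `psf_predictor`.
#' @param newdata Either a data frame with one column per predictor (rows =
#'   pairs), or a named list of `dissimilarity_matrix` objects covering the
#'   predictor groups, in which case a full symmetric species x species
#'   matrix of predicted PSF is returned.
#' @param ... Unused.
#' @return Numeric vector (data-frame input) or symmetric matrix
#'   (dissimilarity-matrix input).
#' @export
predict.psf_predictor <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fitted)) stop("no data to predict from", call. = FALSE)
    return(object$fitted)
  }
  vars <- names(object$coefficients)
  if (is.data.frame(newdata)) {
    miss <- setdiff(vars, names(newdata))
    if (length(miss)) stop("newdata lacks predictor(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    return(as.numeric(object$intercept +
      as.matrix(newdata[, vars, drop = FALSE]) %*% object$coefficients))
  }
  ## list of dissimilarity matrices -> full pairwise matrix
  miss <- setdiff(vars, names(newdata))
  if (length(miss)) stop("missing dissimilarity matrix for: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  mats <- lapply(newdata[vars], function(x)
    if (inherits(x, "dissimilarity_matrix")) x$d else as.matrix(x))
  sp <- rownames(mats[[1]])
  out <- matrix(object$intercept, length(sp), length(sp),
                dimnames = list(sp, sp))
  for (v in vars) {
    mv <- mats[[v]]
    if (!identical(rownames(mv), sp))
      stop("dissimilarity matrices have mismatched species", call. = FALSE)
    out <- out + object$coefficients[[v]] * mv
  }
  diag(out) <- 0
  out
}

#' @export
plot.psf_predictor <- function(x, ...) {
  if (is.null(x$fitted)) stop("predictor was not fitted to data", call. = FALSE)
  obs <- x$data[[x$response]]
  graphics::plot(x$fitted, obs, xlab = "predicted PSF",
                 ylab = "measured PSF",
                 main = "Dissimilarity-to-PSF predictor", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.psf_predictor <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$fitted)) stop("predictor was not fitted to data",
                                   call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  out <- as.data.frame(replicate(
    nsim, object$fitted + stats::rnorm(n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot-level predicted PSF effect
#'
#' Sums `p_i p_j PSF_ij` over the unordered heterospecific species pairs of
#' a plot, where `p` are realized densities (biomass proportions summing to
#' 1).  Monocultures score 0.
#'
#' @param species Character vector of plot members.
#' @param p Realized densities, same length, summing to 1.
#' @param psf_matrix Symmetric species x species predicted-PSF matrix (e.g.
#'   from [predict.psf_predictor()]).
#' @return Predicted PSF effect (PSF units).
#' @export
plot_predicted_psf <- function(species, p, psf_matrix) {
  if (length(species) != length(p))
    stop("`species` and `p` differ in length", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("densities must sum to 1", call. = FALSE)
  miss <- setdiff(species, rownames(psf_matrix))
  if (length(miss)) stop("species missing from PSF matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  N <- length(species)
  if (N < 2) return(0)
  tot <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    tot <- tot + p[i] * p[j] * psf_matrix[species[i], species[j]]
  unname(tot)
}

#' Predicted pathogen dilution of a plot
#'
#' `- predicted PSF x (1 - 1/N)`: the expected release from specialist
#' pathogens when a fraction `(N - 1)/N` of neighbours are heterospecific.
#' Positive when the predicted PSF is negative; 0 in monoculture.
#'
#' @param predicted_psf Plot-level predicted PSF ([plot_predicted_psf()]).
#' @param N Planted species richness (>= 1).
#' @return Dilution score (PSF units, sign-flipped).
#' @export
pathogen_dilution <- function(predicted_psf, N) {
  if (any(N < 1)) stop("richness must be >= 1", call. = FALSE)
  -predicted_psf * (1 - 1 / N)
}

#' Predicted PSF and dilution scores for every plot
#'
#' @param biomass Long plot x species biomass table (columns `plot_id`,
#'   `species`, `biomass_g`).
#' @param psf_matrix Symmetric predicted-PSF matrix.
#' @return Data frame: `plot_id`, `richness` (species with biomass rows),
#'   `predicted_psf`, `dilution`.
#' @export
plot_scores <- function(biomass, psf_matrix) {
  out <- lapply(split(biomass, biomass$plot_id), function(d) {
    tot <- sum(d$biomass_g)
    p <- if (tot > 0) d$biomass_g / tot else rep(1 / nrow(d), nrow(d))
    pred <- plot_predicted_psf(d$species, p, psf_matrix)
    data.frame(plot_id = d$plot_id[1], richness = nrow(d),
               predicted_psf = pred,
               dilution = pathogen_dilution(pred, nrow(d)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
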