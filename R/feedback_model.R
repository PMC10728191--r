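## Frequency-dependent host-environment feedback model: replicator dynamics
## on the simplex with fitness w = sigma %*% P.  Interaction matrices are
## built from predicted pairwise PSF; communities are screened for
## feasibility (Cramer's rule), local stability (reduced Jacobian) and
## negative community-level feedback, and a model complementarity effect is
## computed at the coexistence equilibrium.

#' Common conspecific fitness from a PSF predictor
#'
#' Assuming (i) equal conspecific effect strength across species, (ii) a
#' zero fitness baseline for a fully dissimilar heterospecific pair, and
#' (iii) that the pairwise feedback of a fully dissimilar pair is the sum of
#' the two conspecific effects, the common monoculture fitness is half the
#' predicted PSF at all dissimilarities equal to 1.
#'
#' @param predictor A [psf_predictor()].
#' @return `w_mono` (dimensionless fitness units).
#' @export
conspecific_sigma <- function(predictor) {
  (predictor$intercept + sum(predictor$coefficients)) / 2
}

#' Interaction matrix for a community subset
#'
#' Builds the sigma matrix of the feedback model: `sigma[i, i] = w_mono` and
#' `sigma[i, j] = w_mono - PSF_ij / 2` for a heterospecific pair, so the
#' pairwise feedback recomputed from sigma
#' (`sigma_ii + sigma_jj - sigma_ij - sigma_ji`) equals the predicted
#' `PSF_ij` exactly and a fully dissimilar pair sits at the zero baseline.
#'
#' @param predictor A [psf_predictor()].
#' @param dissims Named list of `dissimilarity_matrix` objects covering the
#'   predictor groups (or a precomputed symmetric PSF matrix via
#'   `psf_matrix`).
#' @param species Character vector of community members (>= 2).
#' @param psf_matrix Optional precomputed symmetric predicted-PSF matrix;
#'   when supplied, `dissims` is ignored.
#' @return Object of class `interaction_matrix`: list with `sigma`,
#'   `species`, `w_mono`.
#' @export
build_interaction_matrix <- function(predictor, dissims = NULL, species,
                                     psf_matrix = NULL) {
  if (is.null(psf_matrix)) psf_matrix <- predict(predictor, dissims)
  miss <- setdiff(species, rownames(psf_matrix))
  if (length(miss)) stop("species without predicted PSF: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  w_mono <- conspecific_sigma(predictor)
  P <- psf_matrix[species, species, drop = FALSE]
  sigma <- w_mono - P / 2
  diag(sigma) <- w_mono
  structure(list(sigma = sigma, species = species, w_mono = w_mono),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("Interaction matrix:", length(x$species), "species, w_mono =",
      round(x$w_mono, 4), "\n")
  invisible(x)
}

as_sigma <- function(A) {
  if (inherits(A, "interaction_matrix")) A$sigma else as.matrix(A)
}

#' Coexistence equilibrium by Cramer's rule
#'
#' Solves the interior equilibrium of the feedback model: equal fitness
#' `sigma %*% P = w 1` with frequencies on the simplex.  By Cramer's rule
#' `P_i = det(A_i) / sum_j det(A_j)` with `A_i` the sigma matrix whose i-th
#' column is replaced by ones, and the equilibrium fitness is
#' `w = det(A) / sum_j det(A_j)`.  The community is feasible when every
#' frequency lies strictly inside (0, 1) (tolerance 1e-9).
#'
#' @param A An `interaction_matrix` or plain sigma matrix.
#' @return List of class `feedback_equilibrium`: `P_hat`, `w_hat`,
#'   `feasible`, `degenerate` (singular system flag).
#' @export
equilibrium <- function(A) {
  sigma <- as_sigma(A)
  N <- nrow(sigma)
  if (N < 2) stop("need at least 2 species", call. = FALSE)
  dets <- vapply(seq_len(N), function(i) {
    Ai <- sigma
    Ai[, i] <- 1
    det(Ai)
  }, 0)
  tot <- sum(dets)
  scale <- max(abs(dets), abs(det(sigma)), 1)
  if (abs(tot) < 1e-12 * scale) {
    return(structure(list(P_hat = rep(NA_real_, N), w_hat = NA_real_,
                          feasible = FALSE, degenerate = TRUE),
                     class = "feedback_equilibrium"))
  }
  P <- dets / tot
  w <- det(sigma) / tot
  eps <- 1e-9
  structure(list(P_hat = stats::setNames(P, rownames(sigma)), w_hat = w,
                 feasible = all(P > eps & P < 1 - eps), degenerate = FALSE),
            class = "feedback_equilibrium")
}

#' @export
print.feedback_equilibrium <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate equilibrium (singular system)\n")
  } else {
    cat("Equilibrium frequencies:",
        paste(round(x$P_hat, 4), collapse = ", "), "\n")
    cat("Equilibrium fitness:", round(x$w_hat, 4),
        if (x$feasible) "(feasible)" else "(not feasible)", "\n")
  }
  invisible(x)
}

#' Reduced Jacobian and local stability at the equilibrium
#'
#' Substitutes `P_N = 1 - sum(P_i)` into the replicator dynamics and
#' evaluates the (N-1) x (N-1) Jacobian analytically at the interior
#' equilibrium:
#' `J_ik = P_i (sigma_ik - sigma_iN - ((P' sigma)_k - (P' sigma)_N))`.
#' The equilibrium is locally stable when the dominant eigenvalue's real
#' part is below -1e-9.
#'
#' @param A An `interaction_matrix` or sigma matrix.
#' @param P_hat Feasible interior equilibrium frequencies.
#' @return List: `dominant_eig` (max real part), `stable`, `jacobian`.
#' @export
stability <- function(A, P_hat) {
  sigma <- as_sigma(A)
  N <- nrow(sigma)
  if (any(!is.finite(P_hat)) || any(P_hat <= 0) || any(P_hat >= 1))
    stop("`P_hat` must be a feasible interior equilibrium", call. = FALSE)
  v <- as.numeric(P_hat %*% sigma)       # (P' sigma)_k
  J <- matrix(0, N - 1, N - 1)
  for (i in seq_len(N - 1)) for (k in seq_len(N - 1))
    J[i, k] <- P_hat[i] * (sigma[i, k] - sigma[i, N] - (v[k] - v[N]))
  lam <- max(Re(eigen(J, only.values = TRUE)$values))
  list(dominant_eig = lam, stable = lam < -1e-9, jacobian = J)
}

#' Community-level feedback
#'
#' The dominant eigenvalue of the symmetrized sigma matrix restricted to the
#' zero-sum tangent space of the simplex.  Negative values mean every
#' frequency perturbation is self-correcting through the soil community
#' (negative community-level feedback); at N = 2 the sign equals the sign of
#' the classic pairwise feedback
#' `sigma_11 + sigma_22 - sigma_12 - sigma_21`.
#'
#' @param A An `interaction_matrix` or sigma matrix.
#' @return `I_c` (fitness units).
#' @export
community_feedback <- function(A) {
  sigma <- as_sigma(A)
  N <- nrow(sigma)
  S <- (sigma + t(sigma)) / 2
  ## orthonormal basis of {x : sum(x) = 0}: drop the constant column of a
  ## QR completion of 1
  B <- qr.Q(qr(cbind(rep(1, N), diag(N))))[, 2:N, drop = FALSE]
  max(eigen(t(B) %*% S %*% B, symmetric = TRUE, only.values = TRUE)$values)
}

#' Model complementarity at the coexistence equilibrium
#'
#' `CE_model = N x (w_hat - w_mono)`: with relative fitness standing in for
#' biomass, the mean relative-yield deviation is
#' `(w_hat - w_mono) / w_mono` and the mean "monoculture biomass" is
#' `w_mono`, so the additive-partition complementarity reduces to this
#' difference.
#'
#' @param eq A [equilibrium()] result (feasible).
#' @param w_mono The common conspecific fitness.
#' @return `CE_model` (fitness units).
#' @export
model_complementarity <- function(eq, w_mono) {
  if (!isTRUE(eq$feasible)) stop("equilibrium is not feasible", call. = FALSE)
  length(eq$P_hat) * (eq$w_hat - w_mono)
}

#' Integrate the replicator dynamics
#'
#' Numerically integrates `dP_i/dt = P_i (w_i - sum_j w_j P_j)` with
#' `w = sigma %*% P` from a simplex start, using [deSolve::ode()] (lsoda).
#'
#' @param A An `interaction_matrix` or sigma matrix.
#' @param P0 Initial frequencies on the simplex (tolerance 1e-9).
#' @param t_max Integration horizon (1/fitness time units).
#' @param dt Output time step.
#' @return Matrix of class `deSolve`: time column plus one frequency column
#'   per species.
#' @export
integrate_dynamics <- function(A, P0, t_max = 100, dt = 0.1) {
  sigma <- as_sigma(A)
  N <- nrow(sigma)
  if (abs(sum(P0) - 1) > 1e-9 || any(P0 < 0))
    stop("`P0` must lie on the simplex", call. = FALSE)
  ## integrate the reduced system with P_N = 1 - sum(P_i): the simplex sum
  ## is then conserved exactly (the full-coordinate form lets roundoff grow
  ## along the sum direction whenever the equilibrium fitness is negative)
  rhs <- function(t, p, parms) {
    P <- c(p, 1 - sum(p))
    w <- as.numeric(sigma %*% P)
    list((P * (w - sum(w * P)))[seq_len(N - 1)])
  }
  red <- deSolve::ode(y = P0[seq_len(N - 1)], times = seq(0, t_max, by = dt),
                      func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
  full <- cbind(red, 1 - rowSums(red[, -1, drop = FALSE]))
  colnames(full) <- c("time", if (!is.null(names(P0))) names(P0) else
    paste0("P", seq_len(N)))
  class(full) <- class(red)
  full
}

#' Screen every community from a pool through the feedback model
#'
#' Enumerates all subsets of size >= 2 ([enumerate_communities()]), solves
#' each community's equilibrium, and records feasibility, local stability,
#' community-level feedback, model complementarity, and the predicted PSF
#' effect and pathogen dilution evaluated at the equilibrium frequencies.  A
#' community passes the screen when it is feasible, locally stable and has
#' negative community-level feedback.  Uses a compiled path; the pure-R
#' functions [equilibrium()], [stability()] and [community_feedback()]
#' define the same quantities and are cross-checked in the package tests.
#'
#' @param predictor A [psf_predictor()].
#' @param dissims Named list of dissimilarity matrices (or `psf_matrix`).
#' @param pool A [make_species_pool()] pool.
#' @param psf_matrix Optional precomputed predicted-PSF matrix.
#' @param max_richness Largest community size to screen (default: whole
#'   pool).
#' @param compiled Use the compiled screening loop (default `TRUE`).
#' @return Data frame of class `community_screen`: `community`
#'   (semicolon-joined species), `N`, `feasible`, `stable`, `I_c`,
#'   `passes`, `w_hat`, `CE_model`, `predicted_psf`, `dilution` (model
#'   quantities are `NA` for infeasible communities).
#' @export
screen_pool <- function(predictor, dissims = NULL, pool,
                        psf_matrix = NULL, max_richness = NULL,
                        compiled = TRUE) {
  if (is.null(psf_matrix)) psf_matrix <- predict(predictor, dissims)
  sp <- pool$species
  if (!all(sp %in% rownames(psf_matrix)))
    stop("PSF matrix does not cover the pool", call. = FALSE)
  w_mono <- conspecific_sigma(predictor)
  sigma_full <- w_mono - psf_matrix[sp, sp] / 2
  diag(sigma_full) <- w_mono
  subsets <- enumerate_communities(pool)
  if (!is.null(max_richness))
    subsets <- subsets[lengths(subsets) <= max_richness]
  if (compiled) {
    res <- screen_subsets_cpp(sigma_full, psf_matrix[sp, sp], subsets, w_mono)
  } else {
    res <- t(vapply(subsets, function(idx)
      screen_one_r(sigma_full, psf_matrix[sp, sp], idx, w_mono),
      numeric(8)))
  }
  colnames(res) <- c("feasible", "stable", "I_c", "w_hat", "CE_model",
                     "predicted_psf", "dilution", "degenerate")
  out <- data.frame(
    community = vapply(subsets, function(i) paste(sp[i], collapse = ";"), ""),
    N = lengths(subsets), res[, c("feasible", "stable", "I_c", "w_hat",
                                  "CE_model", "predicted_psf", "dilution")],
    stringsAsFactors = FALSE)
  out$feasible <- out$feasible > 0.5
  out$stable <- out$stable > 0.5
  out$passes <- out$feasible & out$stable & out$I_c < 0
  class(out) <- c("community_screen", "data.frame")
  out
}

## reference R implementation of one screening step (mirrors the compiled
## path; used as its oracle in tests)
screen_one_r <- function(sigma_full, psf_full, idx, w_mono) {
  sigma <- sigma_full[idx, idx, drop = FALSE]
  eq <- equilibrium(sigma)
  if (eq$degenerate || !eq$feasible) {
    return(c(feasible = 0, stable = 0, I_c = community_feedback(sigma),
             w_hat = NA, CE_model = NA, predicted_psf = NA, dilution = NA,
             degenerate = as.numeric(isTRUE(eq$degenerate))))
  }
  st <- stability(sigma, eq$P_hat)
  N <- length(idx)
  pred <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    pred <- pred + eq$P_hat[i] * eq$P_hat[j] * psf_full[idx[i], idx[j]]
  c(feasible = 1, stable = as.numeric(st$stable),
    I_c = community_feedback(sigma), w_hat = eq$w_hat,
    CE_model = model_complementarity(eq, w_mono),
    predicted_psf = unname(pred),
    dilution = -unname(pred) * (1 - 1 / N), degenerate = 0)
}

#' Per-richness summary of a community screen
#'
#' @param screen A [screen_pool()] table.
#' @return Data frame: `N`, `n_communities`, `n_passing`, `median_CE_model`,
#'   `median_predicted_psf`, `median_dilution` (medians over passing
#'   communities).
#' @export
screen_summary <- function(screen) {
  out <- lapply(split(screen, screen$N), function(d) {
    pass <- d[d$passes, , drop = FALSE]
    data.frame(N = d$N[1], n_communities = nrow(d), n_passing = nrow(pass),
               median_CE_model = stats::median(pass$CE_model),
               median_predicted_psf = stats::median(pass$predicted_psf),
               median_dilution = stats::median(pass$dilution))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
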