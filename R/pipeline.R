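## End-to-end orchestration: simulate -> dissimilarity -> greenhouse PSF ->
## predictor -> field effects -> feedback model, with a machine-readable
## report.

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the whole chain at the configured study conditions: generates
#' the synthetic study, computes guild-filtered rarefied Bray-Curtis
#' species-pair dissimilarities, estimates pairwise PSF from the greenhouse
#' pots and pools them meta-analytically, fits the dissimilarity-to-PSF
#' predictor by exhaustive AICc selection, scores every field plot
#' (predicted PSF, pathogen dilution), computes biodiversity effects and
#' their regressions, and screens all multispecies communities through the
#' feedback model.  All stage outputs are written as TSV plus a
#' `report.json` when `out_dir` is given.
#'
#' @param config A [psf_sim_config()]; its seed drives every stage.
#' @param out_dir Optional output directory for TSV stage outputs and
#'   `report.json`.
#' @param max_richness Cap on screened community size (default: whole
#'   pool).
#' @param stages Character vector of stages to run (dependency order is
#'   enforced; later stages require the earlier ones): subset of
#'   `c("simulate", "dissimilarity", "greenhouse", "predictor", "effects",
#'   "feedback")`.
#' @return List of class `psf_pipeline`: all stage outputs plus `report`.
#' @export
run_psf_pipeline <- function(config = psf_sim_config(), out_dir = NULL,
                             max_richness = NULL,
                             stages = c("simulate", "dissimilarity",
                                        "greenhouse", "predictor",
                                        "effects", "feedback")) {
  all_stages <- c("simulate", "dissimilarity", "greenhouse", "predictor",
                  "effects", "feedback")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- function(s, dep) if (s %in% stages && !(dep %in% stages))
    stop("stage `", s, "` requires stage `", dep, "`", call. = FALSE)
  need("dissimilarity", "simulate"); need("greenhouse", "simulate")
  need("predictor", "dissimilarity"); need("predictor", "greenhouse")
  need("effects", "predictor"); need("feedback", "predictor")
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage `", stage, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- list(config = config)
  message("stage simulate")
  out$study <- run("simulate", simulate_study(config))
  study <- out$study
  if ("dissimilarity" %in% stages) {
    ## ASV route: guild filter -> rarefy to minimum depth -> mean pairwise
    ## Bray-Curtis.  The drawn matrices in study$dissims are the "measured"
    ## assay dissimilarities driving the rest of the chain; the ASV-derived
    ## matrices reproduce their family-combination structure and the report
    ## records the agreement of the class means.
    message("stage dissimilarity")
    out$dissims_asv <- run("dissimilarity", stats::setNames(lapply(
      config$groups, function(g) {
        tab <- guild_filter(study$asv[[g]], "plant_pathogen")
        tab <- rarefy_table(tab, "min", seed = stage_seed(config$seed, 60))
        species_pair_dissimilarity(tab, group = g)
      }), config$groups))
    out$dissims <- study$dissims
  }
  if ("greenhouse" %in% stages) {
    message("stage greenhouse")
    out$pairwise_psf <- run("greenhouse",
                            estimate_pairwise_psf(study$pots, study$pairs))
    out$meta <- run("greenhouse", group_summary(out$pairwise_psf))
  }
  if ("predictor" %in% stages) {
    message("stage predictor")
    out$predictor <- run("predictor", {
      dat <- out$pairwise_psf
      for (g in config$groups)
        dat[[g]] <- out$dissims[[g]]$d[cbind(dat$a, dat$b)]
      fit_psf_predictor(dat, response = "psf", predictors = config$groups)
    })
    out$psf_matrix <- predict(out$predictor, out$dissims)
  }
  if ("effects" %in% stages) {
    message("stage effects")
    out$scores <- run("effects", plot_scores(study$biomass, out$psf_matrix))
    out$effects <- run("effects", biodiversity_effects(
      study$biomass, monoculture_reference(study$biomass)))
    out$regressions <- run("effects",
                           effects_regression(out$effects, out$scores))
    out$overyielding <- run("effects", overyielding_tests(out$effects))
  }
  if ("feedback" %in% stages) {
    message("stage feedback")
    out$screen <- run("feedback", screen_pool(
      out$predictor, pool = study$pool, psf_matrix = out$psf_matrix,
      max_richness = max_richness))
    out$screen_by_richness <- screen_summary(out$screen)
  }
  out$report <- pipeline_report(out)
  class(out) <- "psf_pipeline"
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

pipeline_report <- function(out) {
  study <- out$study
  rep <- list(
    seed = out$config$seed,
    design = list(
      n_species = length(study$pool$species),
      n_pairs = nrow(study$pairs),
      n_pots = nrow(study$pots),
      n_plots = nrow(study$design),
      n_mixtures = sum(study$design$richness >= 2)))
  if (!is.null(out$dissims_asv)) {
    fam <- study$pool$family
    rep$dissimilarity <- lapply(names(out$dissims_asv), function(g) {
      d <- out$dissims_asv[[g]]$d
      sp <- rownames(d)
      iu <- which(upper.tri(d), arr.ind = TRUE)
      grp <- family_group(fam[sp[iu[, 1]]], fam[sp[iu[, 2]]])
      list(group = g,
           class_means = as.list(tapply(d[iu], grp, mean)),
           configured = as.list(out$config$dissimilarity_means[[g]]))
    })
  }
  if (!is.null(out$meta)) rep$psf_meta <- out$meta
  if (!is.null(out$predictor)) rep$predictor <- list(
    coefficients = as.list(out$predictor$coefficients),
    intercept = out$predictor$intercept,
    importance = as.list(out$predictor$selection$importance))
  if (!is.null(out$regressions)) {
    rep$regressions <- out$regressions
    rep$overyielding <- out$overyielding
  }
  if (!is.null(out$screen)) rep$feedback_screen <- list(
    n_communities = nrow(out$screen),
    n_passing = sum(out$screen$passes),
    by_richness = out$screen_by_richness)
  rep
}

write_pipeline <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(out$study$pots, "pots.tsv")
  tsv(out$study$design, "plots.tsv")
  tsv(out$study$biomass, "plot_biomass.tsv")
  if (!is.null(out$pairwise_psf)) tsv(out$pairwise_psf, "pairwise_psf.tsv")
  if (!is.null(out$meta)) tsv(out$meta, "psf_meta.tsv")
  if (!is.null(out$predictor)) {
    tsv(out$predictor$selection$models, "model_selection.tsv")
    jsonlite::write_json(list(coefficients =
                                as.list(out$predictor$coefficients),
                              intercept = out$predictor$intercept),
                         file.path(dir, "predictor.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out$scores)) tsv(out$scores, "plot_scores.tsv")
  if (!is.null(out$effects)) tsv(as.data.frame(out$effects), "effects.tsv")
  if (!is.null(out$regressions)) tsv(out$regressions, "regressions.tsv")
  if (!is.null(out$screen)) {
    tsv(as.data.frame(out$screen), "community_screen.tsv")
    tsv(out$screen_by_richness, "screen_summary.tsv")
  }
  jsonlite::write_json(out$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' @export
print.psf_pipeline <- function(x, ...) {
  d <- x$report$design
  cat("PSF pipeline run (seed ", x$report$seed, ")\n", sep = "")
  cat("  design:", d$n_plots, "plots (", d$n_mixtures, "mixtures ),",
      d$n_pots, "pots,", d$n_pairs, "pairwise feedback tests\n")
  if (!is.null(x$predictor)) {
    cat("  predictor: ")
    print(x$predictor)
  }
  if (!is.null(x$screen))
    cat("  feedback screen:", nrow(x$screen), "communities,",
        sum(x$screen$passes), "passing\n")
  invisible(x)
}

#' Validate pipeline input tables
#'
#' Schema checks for the TSV inputs of the pipeline: required columns,
#' nonnegative counts, symmetric dissimilarity matrices with zero diagonal
#' and entries in \[0, 1\], and plot density vectors summing to 1.
#'
#' @param pots,plots,biomass Optional data frames (as produced by the
#'   synthetic generators or read from TSV).
#' @param dissim Optional named list of square dissimilarity data
#'   frames/matrices.
#' @param densities Optional named list of plot density vectors.
#' @return Data frame of violations (`input`, `message`); zero rows when
#'   everything checks out.
#' @export
validate_psf_inputs <- function(pots = NULL, plots = NULL, biomass = NULL,
                                dissim = NULL, densities = NULL) {
  bad <- list()
  flag <- function(input, msg)
    bad[[length(bad) + 1L]] <<- data.frame(input = input, message = msg,
                                           stringsAsFactors = FALSE)
  need_cols <- function(d, cols, input) {
    miss <- setdiff(cols, names(d))
    if (length(miss)) flag(input, paste("missing column(s):",
                                        paste(miss, collapse = ", ")))
    length(miss) == 0
  }
  if (!is.null(pots) &&
      need_cols(pots, c("plant", "inoculum", "height_cm", "shoot_g",
                        "root_g"), "pots")) {
    if (any(pots$shoot_g + pots$root_g <= 0))
      flag("pots", "nonpositive biomass")
  }
  if (!is.null(plots))
    need_cols(plots, c("plot_id", "richness", "species"), "plots")
  if (!is.null(biomass) &&
      need_cols(biomass, c("plot_id", "species", "biomass_g"), "biomass")) {
    if (any(biomass$biomass_g < 0)) flag("biomass", "negative biomass")
  }
  for (g in names(dissim)) {
    d <- as.matrix(dissim[[g]])
    if (nrow(d) != ncol(d)) { flag(g, "not square"); next }
    if (max(abs(d - t(d))) > 1e-9) flag(g, "not symmetric")
    if (any(abs(diag(d)) > 1e-12)) flag(g, "nonzero diagonal")
    if (any(d < -1e-12 | d > 1 + 1e-12)) flag(g, "entries outside [0, 1]")
  }
  for (p in names(densities)) {
    if (abs(sum(densities[[p]]) - 1) > 1e-9)
      flag(p, "densities do not sum to 1")
    if (any(densities[[p]] < 0)) flag(p, "negative density")
  }
  if (!length(bad)) return(data.frame(input = character(0),
                                      message = character(0)))
  do.call(rbind, bad)
}
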