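## Feature-count tables and Bray-Curtis species-pair dissimilarity.

#' Construct a feature-count table
#'
#' @param counts Nonnegative integer matrix, features x samples, with unique
#'   dimnames.
#' @param samples Data frame with at least columns `sample` (matching the
#'   column names of `counts`) and `species` (species of origin; `NA` for
#'   mixture samples).
#' @param features Optional data frame of per-feature metadata (e.g. guild
#'   lifestyles); must have a `feature` column matching the row names.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(counts, samples, features = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("feature and sample identifiers must be unique", call. = FALSE)
  if (!all(colnames(counts) %in% samples$sample))
    stop("every count column needs a row in `samples`", call. = FALSE)
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(features)) {
    if (!all(rownames(counts) %in% features$feature))
      stop("every count row needs a row in `features`", call. = FALSE)
    features <- features[match(rownames(counts), features$feature), ,
                         drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(counts = counts, samples = samples, features = features),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature-count table:", nrow(x$counts), "features x",
      ncol(x$counts), "samples\n")
  cat("  library sizes:", paste(range(colSums(x$counts)), collapse = "-"),
      "\n")
  invisible(x)
}

#' Rarefy a feature-count table to even depth
#'
#' Subsamples each sample without replacement to exactly `depth` reads
#' (the vegan `rrarefy` draw).  Samples whose library size is below the
#' target depth are dropped with a warning.
#'
#' @param table A [feature_table()].
#' @param depth Target depth, or `"min"` for the smallest library size.
#' @param seed Integer seed making the draw reproducible.
#' @return A rarefied `feature_table`.
#' @export
rarefy_table <- function(table, depth = "min", seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  totals <- colSums(table$counts)
  if (identical(depth, "min")) depth <- min(totals)
  if (!is.numeric(depth) || depth <= 0)
    stop("`depth` must be a positive count or \"min\"", call. = FALSE)
  keep <- totals >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(table$counts)[!keep], collapse = ", "))
  counts <- table$counts[, keep, drop = FALSE]
  set.seed(seed)
  rare <- t(suppressWarnings(vegan::rrarefy(t(counts), depth)))
  feature_table(rare, table$samples[keep, , drop = FALSE], table$features)
}

#' Restrict a feature table to one guild
#'
#' Keeps features whose primary or secondary lifestyle matches the guild
#' label (the union rule: a feature listed as e.g. `plant_pathogen` in the
#' secondary lifestyle only is retained).
#'
#' @param table A [feature_table()] with `primary_lifestyle` /
#'   `secondary_lifestyle` feature metadata.
#' @param guild Guild label, default `"plant_pathogen"`.
#' @return A `feature_table` restricted to the guild; all samples preserved.
#' @export
guild_filter <- function(table, guild = "plant_pathogen") {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$features))
    stop("table has no feature metadata with guild labels", call. = FALSE)
  f <- table$features
  keep <- (!is.na(f$primary_lifestyle) & f$primary_lifestyle == guild) |
    (!is.na(f$secondary_lifestyle) & f$secondary_lifestyle == guild)
  if (!any(keep))
    warning("no features matched guild `", guild, "`; returning empty table")
  feature_table(table$counts[keep, , drop = FALSE], table$samples,
                f[keep, , drop = FALSE])
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `sum(|a - b|) / sum(a + b)`: 0 for identical compositions, 1 for disjoint
#' ones.  Delegates to [vegan::vegdist()].
#'
#' @param a,b Nonnegative count vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length", call. = FALSE)
  if (sum(a) + sum(b) == 0)
    stop("Bray-Curtis undefined: both vectors are all-zero", call. = FALSE)
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Species-pair dissimilarity matrix from monoculture samples
#'
#' For every unordered species pair, averages the Bray-Curtis dissimilarity
#' over all cross pairs of one species-i sample and one species-j sample
#' (monoculture samples only).  The diagonal is 0 by definition.
#'
#' @param table A [feature_table()]; samples with non-`NA` `species` are
#'   used.
#' @param group Label stored on the result.
#' @return A `dissimilarity_matrix`.
#' @export
species_pair_dissimilarity <- function(table, group = "unknown") {
  stopifnot(inherits(table, "feature_table"))
  mono <- !is.na(table$samples$species)
  counts <- table$counts[, mono, drop = FALSE]
  species <- table$samples$species[mono]
  empty <- tapply(colSums(counts), species, sum) == 0
  sp <- sort(unique(species))
  if (any(empty)) {
    warning("species with all-zero samples excluded: ",
            paste(names(empty)[empty], collapse = ", "))
    sp <- setdiff(sp, names(empty)[empty])
  }
  full <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  d <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i >= j) next
    ci <- which(species == sp[i]); cj <- which(species == sp[j])
    d[i, j] <- d[j, i] <- mean(full[ci, cj])
  }
  as_dissimilarity_matrix(d, group = group)
}

#' Validate and label a dissimilarity matrix
#'
#' @param d Symmetric numeric matrix in \[0, 1\] with zero diagonal and
#'   species dimnames.
#' @param group Microbial group label.
#' @return An object of class `dissimilarity_matrix` (list with `d` and
#'   `group`).
#' @export
as_dissimilarity_matrix <- function(d, group = "unknown") {
  d <- as.matrix(d)
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("dissimilarity matrix needs matching species dimnames", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-9) stop("matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
  if (any(d < -1e-12 | d > 1 + 1e-12))
    stop("dissimilarities must lie in [0, 1]", call. = FALSE)
  structure(list(d = d, group = group), class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat("Dissimilarity matrix (", x$group, "): ", nrow(x$d), " species, ",
      "mean off-diagonal ", round(mean(x$d[upper.tri(x$d)]), 3), "\n", sep = "")
  invisible(x)
}

#' Dilution signature of the dominant pathogens
#'
#' For each species, identifies the most abundant pathogen feature in its
#' monoculture samples (ties broken towards the lexicographically smallest
#' feature id) and reports, for every mixture sample containing that
#' species, the change in the feature's relative abundance relative to the
#' monoculture.
#'
#' @param table A [feature_table()] containing monoculture samples (non-`NA`
#'   `species`) and mixture samples (non-`NA` `plot`); features should
#'   already be guild-filtered to pathogens.
#' @param plot_members Named list mapping plot id to its member species
#'   (e.g. from [plot_species()] keyed by `plot_id`).
#' @return Data frame: `species`, `plot`, `richness`, `feature`,
#'   `mono_rel`, `mix_rel`, `change` (`mix_rel - mono_rel`).
#' @export
dilution_signature <- function(table, plot_members) {
  stopifnot(inherits(table, "feature_table"))
  rel <- sweep(table$counts, 2, pmax(colSums(table$counts), 1), "/")
  smp <- table$samples
  mono <- !is.na(smp$species)
  species <- sort(unique(smp$species[mono]))
  top <- character(0)
  for (s in species) {
    pr <- rowMeans(rel[, smp$sample[mono & smp$species == s], drop = FALSE])
    if (sum(pr) == 0) {
      warning("species ", s, " has no pathogen reads; omitted")
      next
    }
    ## deterministic tie-break: first (lexicographically smallest) feature id
    ord <- order(-pr, rownames(rel))
    top[s] <- rownames(rel)[ord[1]]
  }
  mix <- which(!is.na(smp$plot))
  rows <- list()
  for (k in mix) {
    members <- plot_members[[smp$plot[k]]]
    for (s in intersect(members, names(top))) {
      mono_rel <- mean(rel[top[[s]], smp$sample[mono & smp$species == s]])
      mix_rel <- rel[top[[s]], smp$sample[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, plot = smp$plot[k], richness = smp$richness[k],
        feature = top[[s]], mono_rel = mono_rel, mix_rel = mix_rel,
        change = mix_rel - mono_rel, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
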