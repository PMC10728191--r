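#' Build a family-structured species pool
#'
#' Creates the pool of plant species used throughout the package: a set of
#' species identifiers grouped into plant families.  The default experiment
#' uses 18 native prairie species, six each from three families (grasses,
#' legumes and composites).
#'
#' @param n_families Number of plant families (>= 1).
#' @param n_per_family Number of species per family (>= 2).
#' @param family_names Optional character vector of family labels; defaults to
#'   `"F1"`, `"F2"`, ... Species are named `"<family>_S<k>"`.
#' @return An object of class `species_pool`: a list with elements
#'   `species` (character vector) and `family` (named character vector mapping
#'   species to family label).
#' @examples
#' pool <- make_species_pool(3, 6)
#' length(pool$species)  # 18
#' table(pool$family)
#' @export
make_species_pool <- function(n_families = 3, n_per_family = 6,
                              family_names = NULL) {
  if (!is.numeric(n_families) || n_families < 1 ||
      n_families != round(n_families))
    stop("`n_families` must be a positive integer", call. = FALSE)
  if (!is.numeric(n_per_family) || n_per_family < 2 ||
      n_per_family != round(n_per_family))
    stop("`n_per_family` must be an integer >= 2", call. = FALSE)
  if (is.null(family_names)) family_names <- paste0("F", seq_len(n_families))
  if (length(family_names) != n_families)
    stop("`family_names` must have length `n_families`", call. = FALSE)
  species <- as.vector(t(outer(family_names, paste0("_S", seq_len(n_per_family)),
                               paste0)))
  family <- rep(family_names, each = n_per_family)
  names(family) <- species
  structure(list(species = species, family = family,
                 n_families = n_families, n_per_family = n_per_family),
            class = "species_pool")
}

#' @export
print.species_pool <- function(x, ...) {
  cat("Species pool:", length(x$species), "species in",
      x$n_families, "families\n")
  fams <- split(x$species, x$family[x$species])
  for (f in names(fams))
    cat("  ", f, ": ", paste(fams[[f]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pairwise feedback test design
#'
#' Builds the set of unordered species pairs entering the greenhouse pairwise
#' feedback tests: every species is paired with exactly three heterospecific
#' species from each family (its own family excluded of itself).  The
#' construction is deterministic: within a family the circulant graph with
#' offsets 1, 3 and 5 on the species indices (3-regular); between families A
#' and B, species k of A is paired with species k, k+1 and k+2 (mod size) of
#' B.  For the default 18-species pool this yields 81 pairs: 9 within-family
#' pairs per family and 18 pairs per family pair.
#'
#' @param pool A [make_species_pool()] object; every family needs >= 4
#'   species so that 3 heterospecific same-family partners exist.
#' @return A data.frame with columns `a`, `b` (species, `a < b` by pool
#'   order), `family_a`, `family_b` and `group` (the unordered family
#'   combination label, e.g. `"F1:F2"`).
#' @examples
#' design <- make_pairing_design(make_species_pool())
#' nrow(design)  # 81
#' table(design$group)
#' @export
make_pairing_design <- function(pool) {
  stopifnot(inherits(pool, "species_pool"))
  m <- pool$n_per_family
  if (m < 4)
    stop("every family needs >= 4 species for the 3-regular within-family design",
         call. = FALSE)
  fams <- unique(pool$family)
  by_fam <- split(pool$species, factor(pool$family[pool$species], levels = fams))
  pairs <- list()
  ## within-family: circulant graph, offsets {1, 3, 5} for families of >= 6
  ## (3-regular on 6 nodes), {1, 2, 3} for smaller families
  offs <- if (m >= 6) c(1L, 3L, 5L) else c(1L, 2L, 3L)
  for (f in fams) {
    sp <- by_fam[[f]]
    for (i in seq_len(m)) for (o in offs) {
      j <- ((i - 1L + o) %% m) + 1L
      if (j != i)
        pairs[[length(pairs) + 1L]] <- c(sp[min(i, j)], sp[max(i, j)])
    }
  }
  pairs <- unique(pairs)
  ## between-family: k of A with k, k+1, k+2 of B
  if (length(fams) > 1) {
    cmb <- utils::combn(fams, 2)
    for (cc in seq_len(ncol(cmb))) {
      spA <- by_fam[[cmb[1, cc]]]; spB <- by_fam[[cmb[2, cc]]]
      for (k in seq_len(m)) for (o in 0:2) {
        j <- ((k - 1L + o) %% m) + 1L
        pairs[[length(pairs) + 1L]] <- c(spA[k], spB[j])
      }
    }
  }
  pairs <- unique(pairs)
  a <- vapply(pairs, `[`, "", 1L)
  b <- vapply(pairs, `[`, "", 2L)
  fa <- unname(pool$family[a]); fb <- unname(pool$family[b])
  data.frame(a = a, b = b, family_a = fa, family_b = fb,
             group = family_group(fa, fb), stringsAsFactors = FALSE)
}

## unordered family-combination label, stable order from first appearance
family_group <- function(fa, fb) {
  paste(pmin(fa, fb), pmax(fa, fb), sep = ":")
}

#' Enumerate all multispecies communities from a pool
#'
#' Lists every subset of the pool with at least two species, in lexicographic
#' order by species index.  For the default 18-species pool this is
#' 2^18 - 18 - 1 = 262,125 communities.
#'
#' @param pool A [make_species_pool()] object, or an integer pool size.
#' @param min_size Smallest subset size to return (default 2).
#' @return A list of integer vectors (indices into `pool$species`).
#' @export
enumerate_communities <- function(pool, min_size = 2) {
  S <- if (inherits(pool, "species_pool")) length(pool$species) else as.integer(pool)
  if (S > 22)
    stop("pool too large for exhaustive enumeration (> 22 species); ",
         "sample subsets instead", call. = FALSE)
  out <- vector("list", 2^S)
  n <- 0L
  ## lexicographic order by species index: recursive prefix enumeration
  rec <- function(prefix, start) {
    for (i in start:S) {
      sub <- c(prefix, i)
      if (length(sub) >= min_size) {
        n <<- n + 1L
        out[[n]] <<- sub
      }
      if (i < S) rec(sub, i + 1L)
    }
  }
  rec(integer(0), 1L)
  out[seq_len(n)]
}
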