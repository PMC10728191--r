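---
title: "From soil pathogen dissimilarity to biodiversity effects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From soil pathogen dissimilarity to biodiversity effects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific chain

`psfdilution` implements, as one tested pipeline, the chain of analyses that
links the composition of soil pathogen communities to the productivity
advantage of diverse plant communities:

1. **Microbial dissimilarity.** Guild-filtered ASV count tables from
   monoculture soils are rarefied to the minimum library size and turned
   into species-pair Bray-Curtis dissimilarity matrices, one per microbial
   group (soil fungal pathogens, soil oomycetes, root fungal pathogens,
   ...).
2. **Pairwise plant-soil feedback (PSF).** A greenhouse experiment grows
   every species on conspecific and heterospecific soil inocula.  The PSF
   of a pair (A, B) is the log-response contrast
   `ln(alpha_A) + ln(beta_B) - ln(beta_A) - ln(alpha_B)` of
   covariate-adjusted cell means; negative values mean each species does
   relatively worse on its own soil, the precondition for coexistence
   through pathogen dilution.
3. **The dissimilarity-to-PSF predictor.** Measured pairwise PSF is
   regressed on the candidate microbial dissimilarities by exhaustive AICc
   model selection with Akaike-weight model averaging; the fitted linear
   predictor extends PSF estimates to every species pair in the pool.
4. **Plot scores and biodiversity effects.** Each field mixture gets a
   predicted PSF effect (density-weighted sum over its species pairs) and a
   predicted pathogen dilution `-PSF x (1 - 1/N)`; observed biomass gives
   the additive partition into complementarity (CE) and selection (SE) and
   the relative yield total (RYT), which are then regressed on the scores.
5. **The feedback model.** A frequency-dependent (replicator) model built
   from the same predicted PSF values is screened over every community
   assembled from the pool for feasibility, local stability and negative
   community-level feedback, yielding a model complementarity effect at the
   coexistence equilibrium.

A synthetic-data generator stands in for the field, greenhouse and
sequencing data so that every stage is testable end to end without any
download.

# The models and their assumptions

## Pairwise PSF and its variance

Pot-level log dry biomass is modelled as plant x inoculum cell means plus a
per-species slope on initial seedling height (centred within species, so
each adjusted mean sits at that species' own mean height).  Working on the
log scale makes the four-cell PSF contrast exactly the log response ratio of
geometric-mean performances and makes PSF invariant to any constant shift of
the cell means.  The delta-method variance of the contrast sums
`Var / (N m^2)` over the four cells on the raw scale.  Because each
conspecific cell mean is reused by all nine feedback estimates involving
that species, the conspecific cells' sample sizes are deflated to an
effective `N = 1` (9 replicates / 9 estimates) by default — a conservative
inflation of the per-pair variance that prevents the shared conspecific
means from making the 81 estimates look more independent than they are.

Pooling uses a random-effects model fitted by REML through
`metafor::rma.mv()` with the pairwise combination as the random effect and
the delta-method variance as the sampling variance; an effect is declared
nonzero when the 95% Wald interval excludes zero.  Performance defaults to
total (shoot + root) dry biomass and can be switched to shoot only; the
contrast itself is unchanged up to the constant log shoot fraction whenever
allocation is proportional.

## Exhaustive selection and the averaged intercept

With `p` candidate dissimilarity predictors all `2^p` main-effects subsets
are fitted (interactions are never considered: dissimilarities already
summarize whole-community differences, and the candidate count keeps the
search exact rather than heuristic).  AICc is computed as
`n log(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with `k` counting slopes, intercept
and residual variance; the Gaussian additive constant is dropped since only
differences matter.  Akaike weights give each predictor an importance (the
summed weight of models containing it) with 0.7 as the default threshold
separating important from unimportant predictors.  The final predictor
takes its slopes from the lowest-AICc model and its intercept from the
weight-average over all models — the intercept is well defined in every
model, while averaging slopes over models that omit them is not.  A
numerical floor on RSS keeps an exact (zero-residual) fit finite, in which
case the parameter-count penalty breaks ties toward parsimony.

The packaged default coefficients (`psf_predictor()`) are the
field-calibrated values for the three retained predictors:

```
PSF_ij = -1.52 d_soil_fungal_pathogen - 2.27 d_soil_oomycete
         - 1.27 d_root_fungal_pathogen + 1.589
```

## Plot scores

The plot-level predicted PSF sums `p_i p_j PSF_ij` over *unordered*
heterospecific pairs, with `p` the realized biomass proportions.  The
unordered convention halves the value an ordered sum would give; it only
rescales the regressions' slopes, never their signs or tests, and is the
convention under which the two-species closed form `p_1 p_2 PSF_12`
matches the pairwise definition directly.  Pathogen dilution is
`-PSF x (1 - 1/N)`: the sign flip converts suppression into expected
release, and `(N - 1)/N` is the chance that a neighbour is heterospecific
under even mixing.

## The additive partition

Relative yields use the equal-proportion expectation `1/N` (the layout
plants mixtures evenly, and the convention makes monoculture plots the
natural reference).  The selection effect uses the *population* covariance
(divide by `N`); this is what makes `CE + SE` equal the net biodiversity
effect identically, which the tests assert on every simulated plot.
Species planted but absent at harvest enter with relative yield 0 rather
than being dropped — the shortfall is part of the deviation from
expectation.  Monoculture reference biomass `M_i` is the mean over that
species' monoculture plots (4 per species in the default design), pooled
across blocks.

## The feedback model

Frequencies follow `dP_i/dt = P_i (w_i - sum_j w_j P_j)` with fitness
`w = sigma P`.  The interaction matrix is built from predicted PSF with two
conventions: the conspecific fitness is the same for all species
(`w_mono = PSF(d = 1) / 2`, i.e. the feedback of a fully dissimilar pair is
the sum of two equal conspecific effects), and a fully dissimilar
heterospecific pair sits at fitness 0.  The zero baseline is free: adding
any constant to the whole matrix leaves equilibrium frequencies, stability
and the model complementarity unchanged (a tested invariance), so only the
contrast `sigma_ii + sigma_jj - sigma_ij - sigma_ji = PSF_ij` carries
information.  The off-diagonal is split symmetrically because the
dissimilarities carry no directional information.

Equilibria come from Cramer's rule (`P_i = det A_i / sum_j det A_j`, the
column-replacement form forced by `A P = w 1`), cross-checked against the
direct linear solve; feasibility requires all frequencies strictly inside
(0, 1) with tolerance `1e-9`.  Stability is the dominant eigenvalue of the
analytically reduced `(N-1)`-dimensional Jacobian (threshold `-1e-9`), with
a finite-difference Jacobian retained as a test oracle.  Community-level
feedback is the dominant eigenvalue of the symmetrized matrix restricted to
the zero-sum tangent space of the simplex.  That definition was chosen
because it reduces exactly to the sign of the classic pairwise feedback at
`N = 2` and coincides with the stability criterion for symmetric matrices;
other multispecies feedback indices exist, and counts of passing
communities (though not the qualitative richness gradients) can depend on
that choice.  Numerical integration of the dynamics uses the reduced
system with `P_N = 1 - sum P_i`: in full coordinates the simplex sum is a
neutrally unstable direction whenever equilibrium fitness is negative, and
roundoff grows exponentially along it.

# What the synthetic generator emulates

The generator reproduces the experimental design at the combinatorial
level: 18 species in 3 families; 81 pairwise feedback tests laid out as
fixed circulant partner graphs (each species meets 3 partners per family;
the real layout is not published, and any symmetric 3-regular choice gives
the same counts); 702 pots (9 conspecific, 3 x 9 heterospecific, 3 sterile
per species); 240 field plots in six subblocks of paired 20-plot shelters
with matched compositions and richness 1/2/3/6 in counts 72/72/48/48.  A
precipitation label is generated but never used downstream.

Dissimilarities are drawn per microbial group around family-combination
means (legume-legume lowest), jittered with SD 0.15 — the spread one sees
among Bray-Curtis values of pairs sharing a family combination in amplicon
data sets of this kind — and clipped to [0, 1].  True pairwise PSF is the
calibrated linear predictor evaluated at those dissimilarities plus
Gaussian noise (SD 0.4).  Greenhouse interactions are constructed so that
the four-cell contrast of noiseless cell means reproduces the true PSF
exactly (a machine-precision round-trip in the tests); pot noise (log-SD
0.15) and a height covariate (0.02 per cm) are layered on top.  Field
mixtures yield `M_i / N` scaled by `1 + gain x dilution score` with
lognormal noise (CV 0.2, so that the log transform of the analysis matches
the generator) — so overyielding is, by construction, driven entirely by
pathogen dilution, and the null configuration (`dilution_gain = 0`, no
noise) yields exactly CE = SE = 0 and RYT = 1.  Monoculture means spread
species over 150-450 g m^-2 in an order decorrelated from family
membership.  ASV tables draw multinomial reads over shared,
family-specific and species-private feature blocks whose mass fractions
are set by within/between-family overlap targets; libraries vary over
2000-5000 reads to exercise rarefaction, a deliberately scaled-down depth
that keeps the full pipeline fast while preserving the compositional
structure.

What the generator does *not* emulate: pair-level idiosyncrasy in the ASV
layer (the count tables reproduce the family-block structure of the
dissimilarities, not the pair-level jitter, so the pipeline treats the
drawn matrices as the measured assay dissimilarities and validates the ASV
route against the class means); spatial or block effects; temporal
dynamics of the field communities; taxonomy and guild inference, which are
upstream of the package's inputs.  Passing tests therefore demonstrate the
correctness and statistical behaviour of the analysis chain under the
assumed generative structure, not the field realism of that structure.

# Numerical choices and degenerate inputs

- Rarefaction is a single seeded draw without replacement
  (`vegan::rrarefy`); samples below the target depth are dropped with a
  warning.
- Dissimilarity aggregation across replicate samples is the arithmetic mean
  over all cross pairs — unbiased and order-free.
- The dominant-pathogen tie-break is lexicographic in the feature id, for
  determinism.
- Cells with a single pot contribute zero raw-scale variance (their
  delta-method term vanishes rather than erroring).
- Singular interaction matrices or a vanishing determinant sum are flagged
  degenerate and recorded as infeasible rather than erroring, so pool-wide
  screens never abort.
- The compiled screening loop (RcppArmadillo) mirrors the pure-R
  definitional functions; the tests assert agreement between the two routes
  on random subsets to `1e-9`.

# Problem sizes

The default study conditions are used throughout: 18 species, 81 pairs,
702 pots, 240 plots, and the full enumeration of all 262,125 communities
of size >= 2 (the compiled screen handles the enumeration in seconds).
Recovery-style checks use 20 generator seeds for the predictor-importance
and regression-sign properties and 10 seeds for the community-screen shape
property.

# Known limitations

- The meta-analytic pooling assumes independent sampling errors across
  pairs; the shared conspecific cells induce covariance that is only
  approximated by the effective-sample-size deflation.
- Model-averaged intercept plus best-model slopes is one of several
  defensible averaging conventions; full coefficient averaging with
  shrinkage would give slightly different predictors.
- The community screen is conservative: communities failing feasibility or
  stability under the equal-conspecific-fitness parameterization might
  coexist under relaxed assumptions.
- Cover-to-biomass conversion is a per-species simple regression with a
  pooled fallback; it is exercised by the generator but not used by the
  default pipeline, which simulates biomass directly.
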