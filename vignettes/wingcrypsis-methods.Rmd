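---
title: "Methods: wing colorimetry and background-choice inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wing colorimetry and background-choice inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingcrypsis)
```

`wingcrypsis` measures how cryptic a butterfly wing is against a known
background, and whether individuals behaviourally prefer the background
that matches them. This vignette documents the models, the numerical
choices, and the limits of what the synthetic-data tests can show.

## Colorimetric model

Scanned wings are assumed to be (or to have been linearized to) linear
reflectance RGB. The chain is:

1. **Calibration.** Gray standards of known reflectance are fitted per
   channel with a least-squares polynomial mapping raw scanner value to
   reflectance (`fit_calibration`). The default degree is 1, reflecting a
   scanner with a linear response; higher degrees handle gamma-encoded
   devices. A fitted mapping whose cumulative decrease on a 256-point grid
   exceeds 0.005 (0.5 % of full scale) is rejected as non-monotone; dips
   below that threshold are least-squares wiggle at the range ends, not a
   physically decreasing response.
2. **Transect sampling.** Five landmarks define two contiguous polyline
   segments through the eyespot centre (the shared centre landmark is
   sampled once). The transect is rasterized 8-connected (Bresenham), and
   each transect pixel contributes the unweighted mean linear RGB of its
   3×3 neighbourhood. Landmarks and every transect pixel must lie at least
   one pixel from the border so the window fits.
3. **Chromaticity.** Linear RGB maps to CIE XYZ with the sRGB/Rec.709
   primary matrix and D65 white (2° observer), then to chromaticity
   `x = X/(X+Y+Z)`, `y = Y/(X+Y+Z)` with relative luminance `Y` carried
   alongside. The source protocol names neither primaries nor illuminant;
   sRGB/D65 is the de facto assumption for consumer scanners, and the
   matrix is a single isolated constant should another device space be
   needed. Pure black has no chromaticity; it is mapped by convention to
   the white point with `Y = 0`, flagged, and excluded from score means.
4. **Scores.** *Internal contrast* is the (x, y) Euclidean distance
   between an element's mean colour and the wing background's mean colour.
   The *crypsis score* is the mean (x, y) distance of all transect samples
   to a reference patch chromaticity (brown HSB 25°/60%/50% or green
   130°/60%/50%, converted by the standard HSB→RGB formula). Luminance is
   deliberately excluded from both: the scores live in the chromaticity
   diagram, and luminance means are available separately from
   `element_mean_colors`.

**Mean-then-convert.** Element colours are averaged in linear RGB first
and converted to chromaticity second. Averaging chromaticities directly
would weight dark pixels equally with bright ones and is unstable near
black (where x, y are undefined); averaging in linear RGB corresponds to
mixing light. The opposite order is easy to substitute since conversion is
a pure function, but it is not exposed as an option to keep scores
comparable across analyses.

## Synthetic wings

The generator (`generate_wing_image`) draws a stylized wing: a flat
background field, a pale transverse band, and a concentric eyespot (outer
ring, dark disc, pale focus), plus i.i.d. Gaussian pixel noise in linear
RGB clipped to [0, 1] (no noise model is given in the source protocol;
independent Gaussian noise is the standard first-order model for sensor
noise on a linear scale). Geometry beyond landmark and boundary placement
is irrelevant to the pipeline, which only reads colours along the
transect. Per developmental temperature the defaults encode the two
seasonal forms: at Td 19 the element radii are smaller and the element
colours sit close to the wing background and to the brown assay patch; at
Td 27 they are larger and more contrasting. Colour values are stylized
browns/ochres chosen once to reproduce the qualitative orderings (lower
internal contrast and better brown matching at Td 19), not measurements of
real wings.

Ground-truth boundary intervals annotate only *pure* transect pixels —
those whose whole 3×3 sampling window lies inside a single element.
Transition pixels between elements remain unannotated, so a noise-free
wing reproduces each element's target colour exactly (to machine
precision) through the full sampling path; the crypsis score still uses
every transect sample, pure or not.

What the synthetic wings do **not** emulate: real scale texture,
vignetting and lighting gradients, specular reflection, morphological
variation in landmark placement, or non-circular eyespots. Passing the
zero-noise identity and ordering tests therefore demonstrates correctness
of the measurement chain, not robustness to real-scan artifacts — the
calibration module addresses device response, nothing corrects placement
error.

## Synthetic cohorts

`generate_cohort_series` simulates the flight-cage assay: cohorts of 20
same-sex individuals from each Td × Ta × Sex cell observed over 15 photos.
All individuals are perched at every photo. At each step every individual
relocates with probability `plogis(η_act)`; movers depart uniformly from
the currently perched (a hypergeometric split across brown/green — the
protocol never describes departures, and the uniform rule is the simplest
one that keeps occupancy, arrivals and relocations mutually consistent)
and re-alight on brown with probability `plogis(η_pref)`. Both linear
predictors contain treatment fixed effects (indicator coding `Td19`,
`Ta19`, `SexF`, baseline Td 27 / Ta 27 / male) and crossed Gaussian random
intercepts for cohort and time point. Photo 1 has no previous photo, so
its arrivals and relocations are undefined (`NA`) and excluded from the
responses.

The protocol leaves open whether individuals could be off-patch (on the
mesh front) between photos. The simulator keeps everyone perched: an
"unobserved" pool would add a third state with no observable consequence
for the two-vector responses, at the cost of an arbitrary extra rate
parameter, so it was left out.

Default effect sizes are the package's study conditions, fixed once:
preference intercept 0.2, `Td19` +0.7, `SexF` +1.1, `Ta19:SexF` +0.6;
activity `Td19` +0.45, `Ta19` +0.8, `Td19:SexF` −0.45, `Ta19:SexF` −0.8,
on top of a baseline activity of 6 expected relocations per photo per 20
individuals; random-intercept standard deviations 0.5 (cohort) and 0.3
(time point). The magnitudes were back-solved so that, at the study design
size (8 cohorts per cell, i.e. 16 per temperature treatment), the Wald
z-statistics approximate the reported strength of the corresponding
effects in the study this package operationalizes — strong Td and Sex
preference effects, a clear adult-temperature × sex interaction, and male-
but not female-limited activity responses. They were not adjusted after
seeing any test outcome.

## Mixed-model inference

Both behavioural responses are binomial two-vector outcomes fitted by
ML with the Laplace approximation (`lme4::glmer`, bobyqa optimizer) with
crossed random intercepts for cohort and time point — crossed rather than
nested because both factors index the same observation grid and neither
nests the other. ML (not REML) is used throughout, including the Gaussian
pigmentation models, so that likelihood-ratio tests and BIC are comparable
across fixed-effect structures. With no random term the fits degenerate to
`glm`/`lm`, and the test suite checks that degenerate path against an
independently hand-rolled IRLS and against closed-form one-way ANOVA.

`fit_glmm` exposes lme4's `nAGQ`. The default (1) is the Laplace
approximation; `nAGQ = 0` drops the final fixed-effect profiling step and
is roughly an order of magnitude faster. At the cluster sizes used here
the two agree to about 0.02 on the logit scale, so the large Monte-Carlo
recovery studies in the test suite (hundreds of fits on thousands of
cohorts) use `nAGQ = 0`; single analyses use the default.

- **BIC backward elimination** (`backward_select_bic`) starts from main
  effects plus all two-way interactions (the three-way interaction is
  excluded from the starting model) and removes, per step, the removable
  term whose deletion lowers `BIC = −2ℓ + k log n` most, respecting
  marginality; ties break deterministically (higher order first, then
  alphabetically). Elimination operates on fixed terms only — the random
  structure is part of the design, not a hypothesis under selection.
  `n` is the number of (cohort × photo) rows, and `k` counts fixed
  coefficients plus variance components.
- **LRT and parametric bootstrap.** P-values come from the χ² upper tail
  and, where requested, from a parametric bootstrap: `nsim` response
  tables simulated from the fitted reduced model (fresh random-effect
  draws included), both models refitted per table, and
  `p = (1 + #{sim ≥ obs}) / (n_ok + 1)`. Failed refits are dropped and
  counted; more than 10 % failures aborts. The add-one formula bounds p
  below by `1/(nsim+1)`; 999 simulations is the routine setting, and the
  calibration tests use 199 to keep the Monte-Carlo study tractable.
- **Post hoc contrasts** use estimated marginal means on the link scale
  (emmeans) with Tukey-style multivariate-t adjustment. The compact letter
  display is computed in-package by the standard insert-and-absorb
  algorithm, with letters ordered by group means.
- **Pigmentation models** default to ordinary least squares (no random
  term): each wing contributes one score per response, so there is no
  repeated-measures structure to absorb; this choice is flagged in the
  model spec and a random term can be added if wings were measured
  repeatedly. Per-term Wald F statistics use residual degrees of freedom
  `n − p`; the df rule is isolated in `f_tests` for substitution.
- **1:1 preference tests** are exact two-sided binomial tests on
  cell-aggregated arrival counts. Whether the original asterisks derived
  from an exact test or from the GLMM intercept is not stated in the
  protocol; the exact test is implemented and labelled as this package's
  interpretation.

## Numerical and reproducibility choices

- One master seed derives per-purpose sub-stream seeds through a small
  deterministic hash (`derive_seed`), so images, cohorts, calibration
  standards and bootstrap draws are independently reproducible; generator
  functions save and restore the caller's RNG state.
- Coordinates are 0-based `(row, col)`; boundary intervals are half-open
  `[start, end)`. All external JSON uses the same convention.
- 8-bit images are normalized by 255, 16-bit by 65535, before calibration.
- Zero-trial response rows (no arrivals at a photo) are dropped with a
  logged count rather than imputed; complete separation in a binomial fit
  is flagged (`divergent`), never silently returned; boundary (zero)
  variance estimates are reported with a flag.
- The pipeline writes a manifest with md5 checksums of every output and
  never overwrites differing outputs without `force`.

## Problem sizes used in the test suite

The Monte-Carlo studies run at sizes chosen to make their conclusions
statistically meaningful while remaining desk-scale: coefficient recovery
at 300 cohorts per cell × 100 replicates (`nAGQ = 0`); bootstrap
calibration at 200 null replicates × 199 simulations with GLM-backed fits;
LRT size at 500 null replicates; effect-direction reproduction at the
study design size (8 cohorts and 16 wings per cell) × 50 replicates.

## Known limitations

- Chromaticity distances are device-referred, not receiver-referred: no
  predator visual model, receptor noise, or JND scaling — distances are
  comparable within a study, not across instruments.
- Landmarks and segment boundaries are inputs; nothing detects them from
  pixels.
- The Wald F for mixed models uses a simple residual-df rule; for small
  designs a Satterthwaite or Kenward-Roger approximation would be more
  accurate.
- The activity and preference processes are simulated independently given
  the random effects; real butterflies presumably couple them.
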