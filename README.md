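# wingcrypsis

Quantifying seasonal crypsis in butterfly wings, and testing whether the
cryptic seasonal form also behaves more cryptically.

Many satyrid butterflies, *Bicyclus anynana* among them, develop discrete
seasonal wing forms keyed by developmental temperature (Td): cool-reared
(19 °C, dry-season-like) adults carry small, dull pattern elements on a
brown ground; warm-reared (27 °C, wet-season-like) adults carry large,
contrasting eyespots. `wingcrypsis` implements a complete, tested pipeline
for the two halves of that story:

1. **Wing colorimetry.** Calibrated wing scans are sampled along a
   two-segment transect defined by five landmarks through the eyespot
   centre; each sample is the mean linear RGB of its 3×3 pixel
   neighbourhood. Colours are converted to CIE xyY (sRGB primaries, D65
   white point) and scored in the chromaticity plane:

   - *internal contrast* of a pattern element
     `d(element, background) = sqrt((x_e - x_b)^2 + (y_e - y_b)^2)`,
     the Euclidean distance in CIE (x, y) between the element's mean
     colour and the wing-background's mean colour;
   - *crypsis score*: the mean (x, y) distance of **all** transect samples
     to a reference assay patch — brown HSB(25°, 60%, 50%) or green
     HSB(130°, 60%, 50%) — an inverse proxy for background matching.

2. **Behavioural inference.** Cohorts of 20 same-sex adults are observed
   over 15 time-lapse photos on a brown/green patch mosaic. Perching
   preference (arrivals to brown vs green) and activity (relocated vs
   stationary) are modelled as two-vector binomial responses in logit-link
   GLMMs with crossed random intercepts for cohort and time point,
   ML/Laplace estimation (lme4 underneath), backward BIC model selection,
   likelihood-ratio and parametric-bootstrap p-values, Tukey-adjusted
   post hoc contrasts with compact letter display, and exact binomial
   tests against a 1:1 ratio.

Because the original raw data are not deposited, the package ships a
first-class synthetic-data module — wing images with known element colours
and geometry, and cohort series with known logit-scale effects — so every
stage can be exercised end to end against ground truth.

## Worked example

```r
library(wingcrypsis)

# a noise-free synthetic wing of each seasonal form
p   <- wing_sim_params(pixel_noise_sd = 0)
w19 <- generate_wing_image(p, 19, "F")
prof <- sample_transect(w19$image, w19$annotation$landmarks)
internal_contrast(prof, w19$annotation$boundaries)
#>              element     distance
#> 1       central_band 0.0161146699
#> 2 eyespot_outer_ring 0.0020703189
#> 3  eyespot_dark_disc 0.0007502255
#> 4      eyespot_focus 0.0154911058

crypsis_score(prof, reference_patch("brown"))
#> Crypsis score: 0.0099 (mean CIE-xy distance over 143 samples)
```

The cool-reared wing's elements sit within ~0.016 chromaticity units of
its own background (low internal contrast) and the whole transect averages
~0.010 units from the brown assay patch; the warm-reared form scores
roughly two to four times higher on both, i.e. it is more conspicuous and
less brown-matching.

```r
# behavioural arm at the study design size (8 cohorts per Td x Ta x Sex cell)
obs  <- generate_cohort_series(cohort_sim_params(seed = 1))
pref <- build_preference_response(obs)
sel  <- backward_select_bic(pref, mixed_model_spec("preference"))
sel$spec$fixed
#> [1] "Td"  "Ta"  "Sex" "Ta:Sex"
coef(sel$fit)[["Td19"]]
#> [1] 0.718
```

The selected preference model retains the developmental-temperature
effect: cool-reared cohorts arrive on brown with ~0.72 higher log-odds,
matching the injected simulation truth of 0.7.

A full run (`run_full_pipeline(pipeline_config("out", seed = 1))`) chains
calibration, scoring, model selection, bootstrap tests, post hoc letters
and 1:1 tests, and writes tidy CSVs plus a provenance manifest;
`make_figures("out")` draws the summary figures. The same pipeline is
scriptable from a shell via `inst/cli/wingcrypsis.R`.

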