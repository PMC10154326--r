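---
title: "Mechanistic invasion-risk modelling with thermorange: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic invasion-risk modelling with thermorange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermorange)
```

## What the package models

`thermorange` asks a single mechanistic question per map pixel: can a bird
of known morphology and physiology balance its heat budget there in every
month of the year, and for long enough in a row to breed? The pipeline has
four layers:

1. **Microclimate**: monthly climate normals (min/max temperature, wind,
   cloud, snow) are downscaled to 24 hourly records for one mid-month
   model day per month, at the animal's height above ground.
2. **Endotherm heat balance**: for each hour, a steady-state energy
   balance returns the metabolic rate `M` that holds the core temperature
   `Tb`, after a thermoregulatory cascade (physiological adjustments
   first, then behaviour) tries to bring `M` within ±5% of the hour's
   target rate.
3. **Suitability**: months pass when the daily mean requirement stays at
   or below the intake ceiling (4.6 × BMR) and no hour forces the
   allowable rate below BMR; a pixel is at risk of invasion when all
   twelve months are survivable and a sufficiently long circular run of
   breeding-suitable months exists.
4. **Inference and evaluation**: an iterative Latin-Hypercube sensitivity
   workflow trims trait ranges against occurrence data, a 100-variant
   ensemble maps intraspecific variation, and niche-dynamics and
   forecast-evaluation statistics quantify how realized niches moved and
   how well maps predict occurrences.

Everything runs on seeded synthetic worlds, so all behaviour is testable
offline against closed-form expectations.

## The heat balance and its closed form

Each body part (torso, neck, head, legs, beak) is a cylinder or ellipsoid
sharing one core temperature; parts exchange no heat with each other. Per
part, heat flows through a series chain — flesh (conductivity `k_flesh`,
0.41–2.80 W/m/C for vasoconstriction to vasodilation), subcutaneous fat
(neck and torso), plumage (depth × ptiloerection multiplier over an
effective conductivity interpolated between still air and keratin by a
packing fraction built from feather diameter, length and depth) — and
leaves through a boundary layer combining convection (forced
Nusselt–Reynolds power law `Nu = 0.615 Re^0.5`, floored by `Nu = 3`) and
linearized longwave radiation.

Two deliberate simplifications keep every hourly solve closed form:

* **Longwave linearization at a fixed reference temperature** (10 °C).
  The radiative coefficient `h_r = 4 ε σ T_ref³` is a constant rather
  than a function of surface temperature. Over the −40…+45 °C range this
  misstates the radiative conductance by at most a few percent, and in
  exchange the solver is exact, fast, and identical between the per-hour
  R path and the compiled grid kernel — the package tests assert
  bit-level agreement between the two.
* **Operative temperature formulation.** Air, sky/ground radiant
  temperature and absorbed solar combine into one driving temperature per
  part, so the required rate is
  `M = (Σ_p A_p (Tb − Te_p) / (R_p + 1/h_p) + E_cut) / (1 − η − f_resp)`,
  with `η` the 25% muscle work export during active hours and `f_resp`
  the respiratory loss fraction (proportional to the inhaled–exhaled air
  temperature difference). Cutaneous evaporation is a free-water-surface
  term on 1–5% of the skin, attenuated by a plumage vapor-resistance
  factor, with the skin vapor density evaluated at `Tb` (the skin sits
  within a degree or two of the core in the regimes where evaporation
  matters).

The thermoregulatory cascade evaluates a fixed, ordered state list: from
the neutral state (mid-range `k_flesh`, no ptiloerection, 1% wet skin, no
shade), cold stress proceeds to full vasoconstriction and then stepwise
ptiloerection (plumage depth ×1.1 … ×1.5 in 0.1 steps); heat stress to
full vasodilation, 5% wet skin, then shade (which removes solar gain
only). The first state within ±5% of the target is kept; otherwise the
extreme state is returned, and a bird whose allowable rate still sits
below BMR is scored as dying of heat. Death from cold is not decided per
hour: it emerges from the monthly intake-ceiling check.

## Aggregation windows and conventions

The intake ceiling is applied to the *daily mean* requirement (an energy
budget over the model day), while the overheating check is *hourly* (heat
death is acute). Both windows are configuration options with these
defaults. The breeding multiplier (1.5) composes multiplicatively with
the activity target (active hours: 2.5 × 1.5 × BMR); the alternative
additive reading is not supported. Activity spans daylight plus civil
twilight (sun no lower than 6° below the horizon). Breeding durations are
integer months, rounded up.

## The microclimate reference curves

The diurnal temperature course is a declared convention: minimum at
sunrise, maximum at solar noon + 2 h, half-cosine branches between, which
guarantees every hourly value stays inside `[tmin, tmax]`. Humidity
assumes constant water mass over the day, pinned to saturation at `tmin`
— the implied vapor pressure is constant until the 100% cap binds, and a
property test checks this to 10⁻⁹ relative. Clear-sky solar uses a
broadband transmittance of 0.70 per Kasten–Young air mass with a 30%
diffuse coefficient; cloud attenuates linearly down to an overcast floor
of 0.25. Wind is reduced by land-cover shelter factors (forest 0.50,
shrub/herbaceous 0.90, urban 0.75) and then moved from the 2 m reference
to animal height along a neutral log profile with a 1 cm roughness
length. Sky temperature blends a clear-sky emissivity with an overcast
sky radiating at air temperature; ground temperature is air temperature
plus 0.012 °C per W/m² of solar, clamped to 0 °C over snow. There is no
transient soil heat conduction, no horizon shading and no within-month
weather variability.

## The synthetic world and the analytic truth map

The generator emulates the statistical structure of gridded normals, not
any real product: temperature is a deterministic function of latitude
(0.6 °C/deg), elevation (6.5 °C/km lapse over smoothed seeded-noise
topography) and a seasonal cosine peaking in July; wind and cloud are
constants; snow follows freezing monthly maxima. Grids are
northern-hemisphere by convention. The default gradient
(26 °C sea-level annual mean at the southern border, 35–65° latitude,
amplitude 6 °C, diurnal range 8 °C) was chosen once so that the
packaged archetypes' cold edges fall inside the grid — pheasants hardy
nearly everywhere, the parakeet edging mid-grid, the waxbill confined to
the warm margin — mirroring the qualitative ordering seen in real
invasions. What the generator does *not* emulate: spatially structured
sampling noise in climate, ocean masks, microhabitat buffering, and
species interactions; passing tests therefore demonstrate internal
consistency of the method, not fidelity to any real landscape.

The truth map is an independent closed form, not a re-run of the model:
per cell it evaluates the cold-extreme series conductance at the
coldest-month `tmin` (no solar, no evaporation, no cascade) times the
activity-weighted work-export factor, and thresholds at 4.6 × BMR. It is
exact for the hourly model only under its stated preconditions — flat
terrain, uniform land cover, zero diurnal range, solar and evaporation
disabled — because then every hour of the coldest month reproduces the
same closed form. Oracle-based tests (cold-edge agreement, parameter
recovery) therefore run under those preconditions with a sea-level
temperature of 21.5 °C, which bisects the grid with the parakeet's edge;
this is an experiment-design choice, fixed here once.

## Sensitivity workflow and ensemble

The Latin-Hypercube design varies twelve traits (BMR, activity
multiplier, mass, body density, fat fraction, core temperature,
core–skin differential, feather diameter, feather length, feather depth,
feather reflectivity, exhaled-air temperature difference). Mass rescales
all geometry and, isometrically, feather depths and lengths. Designs are
1000 variants at the species level and 100 for the intraspecific
ensemble. Variable importance comes from a 500-tree random-forest
permutation importance (clamped nonnegative, normalized to sum 1);
ranges of parameters above 5% importance are trimmed to the envelope of
variants with TSS > 0.3, and iteration stops when the largest relative
range reduction falls below 5% (measured per parameter, max over
parameters — the norm is a declared choice). The intraspecific map takes,
per pixel, the *minimum BMR-normalized* requirement across variants, so
the ensemble at-risk set is exactly the union of the per-variant sets;
the breeding requirement is evaluated per variant and not relaxed. The
alternative (minimum in absolute watts) is not the default because
normalization makes variants with different BMRs comparable against the
same 4.6 × ceiling.

## Niche metrics and evaluation

Climate space is the first two axes of a centered, scaled PCA of the
pooled backgrounds, with a sign convention (dominant loading positive)
for determinism. Occurrence and availability densities are Gaussian-kernel
smoothed (normal-reference plug-in bandwidth per axis) on a 100 × 100
grid bounded by the background extent. Expansion/stability/unfilling are
computed inside the intersection of each range's 75th-percentile
available-climate region, on "occupied" cells defined as those carrying
95% of a range's occurrence density — the cut the package documents,
since kernel densities have no natural zero. Schoener's D on
availability-corrected densities is the overlap statistic; the
equivalency null pools and resplits occurrences, the similarity null
redraws one range's occurrences from its background, with p-values of
the form `(1 + #null beyond observed)/(1 + reps)`. The truncation index
(PNTI) counts occupied-boundary cells abutting or exceeding the
available-space margin on a 4-neighbourhood.

Forecast evaluation thins occurrences greedily in a seeded order (50 km
default, 10 km variant), derives background radii from mean pairwise
great-circle distances (Earth radius 6371.0088 km), thresholds scores at
the 2.5%/5% training-omission quantile (lower interpolation), and
computes TSS, bootstrap partial ROC (50% presence resampling, ratio of
model to diagonal partial AUC restricted to the acceptable omission
band) and MOP extrapolation masks (strict extrapolation outside the
calibration min–max; similarity from the mean distance to the nearest
10% of calibration points). Binary mechanistic maps get the continuous
score `−max_monthly_multiple` for ROC purposes: a lower requirement means
more suitable.

## Numerical choices and problem sizes

The gridded kernel is compiled (Rcpp) and is the production path for
maps, variant sweeps and the ensemble; the per-hour R path is the
reference implementation, and tests pin the two together to machine
precision. Test-suite experiments run at desk scale chosen for
reproducibility on one CPU: 20 × 20 oracle landscapes, 20 seeded
replicates of the 1000-variant recovery workflow, 200-run null
calibrations at reduced kernel-grid resolution (R = 30), and 1000
bootstrap iterations for partial ROC. The acceptance script uses the
full 60 × 60 default world. Degenerate inputs are defined: zero diurnal
range yields a flat day course; polar day/night fall back to a 6 h
sunrise convention for the temperature curve; equal-score thresholds
return the common value; LHS ranges of zero width are legal and sample
the point.

## Known limitations

The model is steady-state per hour: no heat storage between hours (the
flesh specific heat is carried as a constant but unused by the solver),
no torpor, no water budget, no rain wetting, no nest microclimate or
juvenile development. Shade removes solar gain only, leaving longwave
exchange untouched. Whole-bird conductance is somewhat higher than
empirical minimal conductances for the smallest archetype, which makes
the synthetic waxbill more cold-limited than its real counterpart; all
package-level claims are therefore comparative (orderings,
monotonicities, edge agreement) rather than absolute-value predictions
for any real species.
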