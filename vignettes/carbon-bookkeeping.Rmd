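---
title: "A Tier 3 carbon bookkeeping model for land-use change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Tier 3 carbon bookkeeping model for land-use change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonbook)
```

## The accounting problem

Committed-emissions accounting treats forest as either intact or cleared
and books the whole carbon stock the moment a pixel is deforested. Real
landscapes are messier: land is cleared gradually, used, abandoned and
regrown; forests are degraded without being cleared; soil carbon leaks
out over decades and seeps back even more slowly. A bookkeeping model
tracks all of these states explicitly: every pixel is split into
**cohorts** — sub-pixel area fractions sharing a land class, conversion
year and regrowth age — and the net CO₂ flux is the year-on-year change in
total carbon stock times 44/12. Emissions are positive, absorption
negative, everywhere in the package.

## Carbon pools and curves

**Mature aboveground carbon (CAP).** Per forest type, CAP is a percentile
of aboveground biomass over nearly intact pixels, times a biomass carbon
fraction of 0.5. The central analysis uses the median; the
"clearing less dense forest first" sensitivity uses the 25th percentile,
reflecting evidence that less dense forest tends to be cleared first.
Percentiles interpolate linearly between closest order statistics
(`stats::quantile` type 7); the choice is recorded in the configuration so
alternative conventions remain switchable. "Nearly intact" is an input
flag on the biomass table — selecting those pixels from imagery is
upstream of this package.

**Regrowth.** Aboveground carbon of regrowth of age $a$ follows a logistic
curve $CAR(a) = CAP/(1+e^{\alpha-\beta a})$, rising quickly while pioneer
species dominate and converging to CAP. Rather than taking $\alpha,\beta$
as free parameters, `calibrate_logistic()` solves them from two boundary
conditions: carbon equals the agricultural level (5 tC/ha) at age 0, and
99 % of CAP at the type's recovery time — 40 years for humid, 35 for
dry/seasonal forest. Both conditions then hold to machine precision, and
the curve at age 25 sits at about 85 % of CAP. Published coefficient
tables can be dropped in through `alpha_override`/`beta_override`; this
matters because a severe-degradation anchor of 41 % of CAP at 15 years is
sometimes quoted, whereas the two-point calibration at CAP = 114 gives
about 45 % — the difference is inherited from the coefficients, not from
the curve shape.

**Roots.** No root carbon map exists at this scale, so root carbon tracks
aboveground carbon through a per-type root:shoot ratio (defaults around
0.24 for moist and 0.28 for dry forest, overridable). Roots are released
with AGC on clearing and rebuilt along the logistic. A gradual root-decay
curve would be a configuration extension; nothing in the data available to
the model constrains it.

**Soil.** Soil organic carbon (top 100 cm, tC/ha) declines only under
agriculture: linearly, losing 25 % of the reference stock over 20 years,
then no further. Recovery after abandonment runs at half the
decomposition slope, so a 20-year spell takes 40 years to undo. Re-cleared
land resumes decomposition from its current level, not from the reference.
Conversion of forest to pasture or to other natural vegetation leaves soil
carbon intact, consistent with field evidence that soil carbon is
resilient unless the soil is actually tilled.

**Degraded forest.** Forest that is disturbed without prior clearing
(selective logging, fire, river course changes) is assigned the
aboveground carbon of fixed-age regrowth — 25 years by default, 15 in the
severe sensitivity — with soil carbon untouched. The loss is booked once;
while the plot stays observed as regrowth its equivalent age is held, and
if it is later observed as forest again it recovers along the curve.

## From decadal maps to annual cohorts

Observations are land-cover classes at 1990, 2000 and 2010; the timing of
a change within a decade is unobserved. The default rule converts one
tenth of the transitioning area in each year — unbiased under no
information — with a midpoint rule available in the configuration.
Within a simulated year, dynamics run first (aging, soil steps) and
conversions apply at year end, so an area cleared in year $k$ accrues
$10-k$ years of soil decomposition by the decade's close. This makes the
engine's decade emission for a uniform clearing exactly the closed-form
sum $\sum_{k=1}^{10}\tfrac1{10}[\Delta AGC\,(1+rs) + \text{SOC loss over }
(10-k)\text{ years}]\cdot\tfrac{44}{12}$, which the tests verify.

Initial conditions at 1990 are not observed either. Regrowth pixels start
as ten equal cohorts aged 1–10; agricultural pixels assume a 10-year prior
spell (soil at 87.5 % of reference). Both are configurable. Land already
agricultural at 1990 was cleared before the ledger opens: it emits nothing
further while it stays in use — the central estimate books no emissions
from land with no observed use change, which is also why a fully static
landscape of forest, agriculture and bare classes produces exactly zero
flux. Static regrowth, by contrast, keeps absorbing: that regeneration
uptake is a central part of the net estimate. Abandoning old agricultural
land later still recovers its soil deficit as absorption.

Odd transitions the maps do produce are handled without fictitious jumps:
never-cleared forest observed as regrowth is degradation (one
reclassification event); other vegetation observed later as forest seeds a
regrowth cohort at the equivalent age of its current carbon, absorbing
along the curve. Never-forested and nonvegetated pixels carry zero
land-use-change flux.

## Scenarios

`scenario_spec()` describes a named deviation set; `preset_scenarios()`
bundles the standard eight runs: baseline, the four land-use-change
sensitivities (25th percentile; 20 % pasture with intact soil on the
pasture fraction of each clearing; 35 % soil loss; 15-year degraded
forest), the two static-land adjustments, and a combined static-land run
(the published sensitivity set defines the two static adjustments
separately; the combined run completes the set by showing their joint
effect). The static-land adjustments are:

* **Erosion** — on 80 % of land that is non-forested throughout a period,
  1 % of the soil stock erodes annually and 1.5 % of the eroded carbon is
  oxidised to CO₂ (the rest is assumed redeposited downslope). Whether the
  soil stock is depleted year-on-year or held constant is not a settled
  convention; both modes are provided (`mode = "depleting"` is the
  default; the two differ by under 5 % over a decade).
* **Mature-forest sink** — pixels forest at both ends of a period gain
  4 % of CAP (plus the root share) per decade, linearly per year, as a
  negative flux.

On any landscape containing the relevant transitions the scenario
ordering is monotone in the expected directions: 25th percentile, pasture
and mature sink reduce net emissions; higher soil loss, severe degradation
and erosion increase them. The tests assert exactly this ordering rather
than absolute national totals, which depend on the (unreleased) national
grid.

## The synthetic landscape generator

`gen_landscape()` emulates the statistical structure of the national
inputs: nine forest types with right-skewed (lognormal) biomass around
type medians, department-level soil carbon in a 30–140 tC/ha range,
cover classes sampled from configured 1990 shares and two decadal
transition matrices (sampled independently per pixel), and an
administrative partition with population and GDP per period. Rare types
are guaranteed a minimal intact reference sample (30 draws) so percentile
estimation is always defined at small grids. `gen_national_like()` solves
the forest rows of the transition matrices so the expected forest areas
scale exactly to the 56.8 / 55.0 / 52.6 Mha national trajectory on a
108.4 Mha territory, rescales the type medians so the share-weighted
mature carbon is exactly 114 tC/ha, and carries the published national
mid-period population and GDP.

What the generator does **not** emulate: spatial autocorrelation of
deforestation, sub-pixel mixed transitions (the engine's cohort fractions
exercise those paths instead), classification error, and the correlation
between biomass density and clearing probability. Passing tests therefore
demonstrate the accounting machinery — conservation, curve calibration,
scenario directions, parameter recovery — not fidelity to any real
national total.

## Numerical choices and problem sizes

Time is discrete in whole years, matching the decadal observation
granularity. Cohort fractions must sum to 1 within 1e-9 at every step and
each pixel-period is checked against the mass-balance identity
(stock change × 44/12 = booked flux) at 1e-6 relative tolerance; both are
hard errors, not warnings. The inverse curve clamps below the age-0 level
to age 0 and above 99 % of CAP to the recovery time. Identical cohorts
are merged on exact state to keep the per-pixel state small. Everything is
deterministic given the seed; reruns are bit-identical.

The test suite and examples use grids of 60–6,000 pixels (0.6–60 Mha
equivalent): large enough for sampling checks (share recovery within
binomial standard errors, percentile recovery within a few percent) while
a full run stays in seconds. A full national grid (~10,800 pixels) runs
in well under a minute per scenario.

## Known limitations

* No litter or deadwood pools, and no sub-annual dynamics — the model
  books what its five pools (AGC, roots, SOC; agricultural and
  other-vegetation stand-ins) can express.
* Root release on clearing is instantaneous; a gradual alternative is a
  configuration extension point.
* One predominant forest type per pixel; within-pixel type mixtures are
  not represented.
* Degradation attribution (fire vs logging) and permanence of the
  mature-forest sink are outside the model's scope.
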