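---
title: "Model, calibration and optimizer: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, calibration and optimizer: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriopt)
```

This vignette documents the epidemiological model, its calibration, the
intervention and costing layers, and the budget optimizer, together with
the design decisions taken where more than one reasonable construction
exists. It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The compartmental engine

Children are tracked from birth to 59 months across five age bands
(widths 1, 5, 6, 12 and 36 months), each stratified by four
height-for-age categories and four breastfeeding categories — an 80-way
state. The timestep is one month. Within a month the engine applies, in a
fixed order:

1. **births** into the `<1m` band, with entry stunting odds driven by the
   birth-outcome mix (term/preterm × AGA/SGA) and the under-6-month
   breastfeeding distribution;
2. **deaths**, at stratum- and cause-specific monthly rates;
3. **aging**, modelled as a `1/width` outflow from each band. Outflows
   are computed from the post-death counts *before* any transfers are
   added, so a child can cross at most one band boundary per month.

The `1/width` outflow (an exponential sojourn approximation) was chosen
over explicit month-of-age cohorts: it conserves mass exactly, keeps the
state small, and makes within-band dynamics diagonal, which gives
closed-form per-cohort flows used by the calibration. Its cost is a
dispersed residence time per band rather than a fixed one; the
band-advance survival closed form in `band_advance_probability()`
accounts for this exactly. The within-month order births → deaths → aging
is a convention; the monthly rates are calibrated under the same
convention, so no bias is introduced at baseline.

One consequence of the order convention is that the state snapshot
between months holds the `<1m` band empty (its single monthly cohort has
just aged out). Reported populations and prevalences therefore use the
*mid-month* population (after births and deaths, before aging), and
`projected_u5mr()` discards a 60-month burn-in so that the one-off
transient from initializing at a cross-sectional population snapshot does
not contaminate the stationary rate.

Mortality for stratum $(s, b)$ of band $a$ and cause $c$ is

$$\mu_{a,c,s,b} = m_{a,c} \; \frac{RR^{HA}_{c,s}\,RR^{BF}_{c,a,b}}{Z_{a,c}} \;
\pi_{a,c}(\text{coverage}),$$

where $Z_{a,c}$ is the baseline-distribution-weighted mean of the product
of relative risks and $\pi$ the intervention multiplier. Dividing by $Z$
makes the population-average baseline rate equal $m_{a,c}$ exactly: risk
factors redistribute deaths across strata but never change their total at
the baseline risk distribution. Whether breastfeeding relative risks act
on all causes or specific causes in the older bands is not settled in the
literature we emulate; the effects table supports both (an `"all"` entry
and per-cause entries per band), with the shipped defaults using
cause-specific values.

Stunting is reassigned only at band transitions. A child leaving band
$a$ enters band $a{+}1$ stunted with odds

$$o_{a+1} \cdot OR_{\text{prev}}^{[\text{was stunted}]} \cdot
OR_{\text{dia}}^{e_b} \cdot OR_{\text{programs}},$$

where $e_b$ is the excess diarrhea episodes accumulated over the band in
breastfeeding category $b$, relative to the age-appropriate reference
practice — exclusive breastfeeding under 6 months, partial (continued
breastfeeding with complementary foods) thereafter; the reference
category by construction accrues zero excess. Diarrhea is a flow
modifier, not a compartment: incidence enters only through this
odds-ratio channel and through vitamin A's effect on diarrhea mortality.
The resulting stunted/non-stunted split is mapped onto the four
height-for-age categories proportionally to the target band's baseline
within-group shape, and the breastfeeding category is redrawn from the
target band's (intervention-adjusted) distribution. Birth-outcome strata
are collapsed into the entry odds at birth and not tracked afterwards.

At initialization the stunting and breastfeeding axes are taken
independent within each band (joint distributions are essentially never
published); correlations develop through the dynamics.

## Calibration

`calibrate()` solves two nested problems at the databook's *baseline*
coverages and risk distributions:

- **Mortality.** The under-5 mortality target $q_5 = U5MR/1000$ is split
  into a neonatal share (the `<1m` band) and a constant post-neonatal
  monthly hazard shared by the four older bands. Named-cause rates are
  proportional to the databook's cause-of-death fractions, with the
  scale solved against the engine's exact per-cohort death flows so that
  named-cause deaths match their share of the target; the *other* cause
  absorbs the residual needed to hit the total. A negative residual is
  an explicit calibration error (the named causes alone already exceed
  observed mortality), never silently clipped.
- **Stunting.** Per band, the entry odds $o_a$ are solved (monotone
  one-dimensional roots) so that the mixture of previously-stunted and
  non-stunted arrivals, with their diarrhea and program odds ratios at
  baseline coverage, reproduces the databook's stunted fraction. Two
  alternating passes with the mortality solve suffice, since mortality
  perturbs the arrival mix only at second order.

Because within-band dynamics are diagonal, a birth cohort's band-by-band
exposure, deaths and advancement have closed forms
(`nutriopt:::cohort_flows()`), making calibration exact rather than
simulation-fitted; the acceptance tests verify the closed loop through
the actual monthly projection (U5MR within 0.5%, per-band stunting within
1% absolute, prevalence drift under 1% over the 15-year horizon).

Program effects are *absolute*: a multiplier of 1 at zero coverage.
Calibration at baseline coverage therefore interprets the calibrated
rates as the no-program hazards scaled such that current programs
reproduce current statistics; scaling coverage below baseline worsens
outcomes, above baseline improves them.

## Interventions

Coverage is population coverage of each program's own target group.
AMS/BEP multiply the odds of SGA birth outcomes (BEP only within the
below-poverty stratum, with independent coverage overlap); BFP moves
exclusive-breastfeeding prevalence linearly around the anchor point
(baseline coverage, baseline prevalence) toward an attainable ceiling of
0.90 at full coverage — the ceiling and a linear efficacy knob (default
1) are exposed because no published mapping from promotion coverage to
prevalence exists; IYCF lowers stunting odds and all-cause mortality
among covered 6–23-month children above the poverty line; CFS (which
bundles the education component) is the only channel for the
below-poverty stratum, so joint IYCF+CFS exposure is not double-counted;
VAS reduces diarrhea incidence and diarrhea mortality from 6 months.
All multipliers are monotone in coverage and bounded in $(0, 1]$.

## Costing

The unit-cost curve $c(S) = \mathrm{sat}\cdot\tanh(S/(\mathrm{sat}\,P\,u))$
was chosen because it satisfies the two stated anchors exactly — it passes
through the origin and its marginal cost at zero spending equals the unit
cost — while saturating smoothly; saturation defaults to 0.95 with
per-program overrides. Target-population denominators come from the
databook's target rules (pregnancies approximated by annual births), with
explicit overrides where a program's coverage indicator implies its own
denominator (e.g. vitamin A campaign doses delivered twice yearly); the
synthetic fixture uses such overrides so the published 2014 spending
arithmetic (unit cost × beneficiaries) is reproduced exactly. Estimated
current spending deliberately uses that product, not the curve inverse,
matching how such estimates are produced in practice; the small
discrepancy between the product and the curve at baseline coverage is a
property of the estimate, not of the model. Start-up costs are excluded.

## Optimizer

Adaptive stochastic descent proposes single-program steps (projected back
onto the budget simplex with iterative bound clamping), samples the
(program, direction) pair with probability proportional to a learned
weight, and doubles/halves the direction's step size and weight on
acceptance/rejection. Hyperparameters (initial step 10% of budget,
growth 2.0, decay 0.5, stall window 100 evaluations, cap 2000
evaluations) follow the conventions of the published algorithm family and
are configurable. `optimize_allocation()` restarts from the status quo
plus random simplex points (default 3 starts) and never returns worse
than the status quo; maximization objectives are negated so the optimizer
is single-sense. Budget scans warm-start each budget from the previous
optimum rescaled, which — because every program is beneficial and
coverage is monotone in spending — makes the optimal objective sequence
monotone non-worsening by construction.

Budget-outcome curves interpolate optimized grid objectives with a
monotone shape-preserving cubic (Hyman filtering) after enforcing
monotonicity on the grid (optimizer noise cannot oscillate the curve);
extrapolation clamps to the end values. The default grid
$\{0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4\}\times$ current regional spending
adds two low points to the published scenario set for curve shape.
Regions are independent (no migration), so the national objective is the
sum of regional objectives. `geospatial_optimize()` always evaluates the
current split (and any caller-supplied reference splits/allocations) as
refined candidates, so geographic targeting cannot report worse than the
references it was given — mirroring the status-quo guarantee of the
single-region optimizer.

## The synthetic fixtures

`generate_demo_databook()` emulates a national Bangladesh-like setting:
3 million births/year at the engine's own stationary age profile (≈14.4 M
under-5 children), U5MR 46/1000 with half neonatal, aggregate stunting
scaled to 36% over an age-increasing profile, 61% exclusive breastfeeding
under 6 months, published unit costs and 2014 coverages, and plausible
Bangladesh-like cause-of-death and birth-outcome mixes. Populations are
set from the calibrated stationary cohort flows precisely so that
baseline projections start at equilibrium — the stationarity the
acceptance tests check is a genuine closed loop (distributions →
calibration → projection), not an assertion of the inputs. The seven
region fixtures encode only the published qualitative structure: Sylhet
the highest prevalence (with a steeper age profile approaching the
published ~70%/~35% oldest-band contrast with Khulna in ordering, though
not magnitude), highest poverty and lowest coverage; Dhaka the largest
population and hence the most stunted children; regional populations
summing to the national fixture within 1%; AMS unit costs $1.78–$1.82.

Effect sizes are placeholders with literature-scale magnitudes
(e.g. not-breastfed diarrhea mortality RR ≈ 10 under 6 months, IYCF
stunting OR 0.67, VAS diarrhea mortality reduction 0.28), flagged in the
databook and logged at every calibration. What passing tests show is that
the machinery — calibration, projection, costing, optimization —
reproduces the published *arithmetic and orderings* under these
conditions; they do not validate the placeholder effect sizes against
real data, and headline national projections that depend on the original
survey databooks are deliberately out of scope. Under the placeholders,
optimizing "alive and not stunted" at the current budget concentrates
funding on IYCF (with vitamin A's marginal value close behind but below
IYCF's), and complementary food provision enters the expanding envelope
well before antenatal supplementation — the published qualitative
ordering.

## Numerical choices and degenerate inputs

Monthly rates are capped at 0.99/month with a logged warning (and the
cap is silenced during calibration's root bracketing, which deliberately
probes extreme hazards). Root solves use `uniroot` at tolerance 1e-13/1e-14
on monotone scalar functions. The person ledger (births − deaths −
graduates = stock change) holds to 1e-9 relative every month and is
tested on randomized databooks. Zero-month horizons return empty
trajectories with zero cumulatives; empty multiplier lists return empty
scans; an all-zero allocation is feasible and simply buys no coverage.
Distribution sums are validated to 1e-9; YAML serialization is canonical
at 15 significant digits so write→read→write is byte-stable.

Problem sizes in the shipped tests and acceptance script (projection
horizons of 60–180 months, optimizer budgets of a few hundred to a few
thousand evaluations, curve grids of 4–8 points) were chosen as the
smallest sizes at which the checked properties are stable; all are
configurable upward for production analyses.

## Known limitations

Uniform mixing within bands; no wasting or anaemia states; no flow-on of
early breastfeeding promotion onto later feeding practices; no start-up
costs or time-varying unit costs; no uncertainty propagation — results
are deterministic given inputs, and the optimizer's stochasticity is
fully seeded. The placeholder effect sizes make every quantitative output
illustrative rather than predictive.
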