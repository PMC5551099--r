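---
title: "Performance surfaces, net production, and trophic tipping points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Performance surfaces, net production, and trophic tipping points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(phasetip)
```

## The question the package answers

Whether a grazed ecosystem stays "green" or collapses to a barren state
depends not on either species' tolerance in isolation but on the *balance*
between primary production and consumption. Because physiological
performance responds nonlinearly — and differently per species — to
temperature and to seawater pCO2, that balance can flip sign under driver
combinations where both species are individually well within their limits.
`phasetip` models this for one producer and one consumer: it builds each
species' performance surface over a temperature × pCO2 grid, subtracts
demand from supply, and locates the tipping boundary.

## Curve families and their assumptions

**Thermal performance curve (TPC).** Gaussian rise below the optimum,
quadratic fall above it, hard zero outside `(CT_min, CT_max)`:

$$
P(T) = \begin{cases}
P_{max}\, e^{-\left(\frac{T - T_{opt}}{2\sigma_{rise}}\right)^2} & CT_{min} < T \le T_{opt}\\[2pt]
P_{max}\left(1 - \left(\frac{T - T_{opt}}{CT_{max} - T_{opt}}\right)^2\right) & T_{opt} < T < CT_{max}\\[2pt]
0 & \text{otherwise.}
\end{cases}
$$

This is one of the standard unimodal TPC forms: it peaks exactly at
`T_opt`, reaches zero exactly at `CT_max`, and is left-skewed whenever the
fall span `CT_max − T_opt` is shorter than the rise scale `2σ_rise` — a
condition every preset satisfies, reflecting the near-universal observation
that performance collapses faster above the optimum than it builds below
it. Two numerical caveats are accepted by design: the Gaussian limb is not
exactly zero at `CT_min`, so performance drops discontinuously to zero
there (the jump is small whenever `T_opt − CT_min ≳ 2σ_rise`); and the two
limbs meet with a slope break at `T_opt`.

**pCO2 responses.** Producers can use added inorganic carbon, so their
multiplier is a saturating Michaelis–Menten curve with a `baseline` at zero
pCO2 and asymptote 1 (`k_half` µatm is the half-saturation level).
Consumers are harmed past a threshold, so their multiplier is a descending
logistic from 1 toward `floor`, inflecting at `c_mid` µatm with slope
`steepness` (per µatm). These are the simplest shapes with the right
qualitative behavior: negligible effect at small doses, increasingly severe
effects past a threshold for the stressor case.

**Hormesis.** `(1 + α·d)·e^{−(d/λ)^κ}` is exactly 1 at zero dose,
stimulated above 1 at small doses when `α > 0`, and declines to zero at
high dose; `α = 0` nests the monotone-toxin case. It stands alongside the
other families for dose–response fitting and is not used by the scenario
presets.

**Driver interaction.** The default combination of the two drivers is
multiplicative — the accepted null expectation for independent stressors.
The `fig8` preset adds the one interactive mechanism the framework
develops: co-driver stress shifts the consumer's thermal curve downward,
by `d_topt` (optimum) and `d_ctmax` (foraging-stop temperature, identified
with `CT_max` of the consumer TPC — the natural reading, since both mark
where thermally driven activity ceases). The stress weight is a linear
ramp from 0 at the lowest modeled pCO2 to 1 at the highest; linear is the
minimal assumption given only two stated endpoints, and the ramp is
isolated in `stress_weight()` for substitution.

## From curves to surfaces

`species_surface()` evaluates `TPC(T) × m(c)` on the grid;
`scale_to_max()` rescales each species to its own grid maximum, so both
surfaces run 0–1 (scaling is per species, not joint — each panel of a
scenario is its own relative map). Net production is `N = P − ρ·G`. The
capacity ratio `ρ` (maximum potential consumption : maximum potential
production) defaults to 1, which is what direct comparison of two
individually 0–1-scaled surfaces implies, but real systems differ, so it
is an explicit parameter. Realized secondary production is

$$ S = e \cdot \min(\rho G, \max(P, 0)), $$

the consumer getting the lesser of its physiological capacity and the food
actually produced, floored at zero (starting consumer biomass is zero, so
there is no biomass to lose), times a transfer efficiency `e ∈ (0, 1]`
defaulting to 1. This min-of-capacity-and-supply form is this package's
construction — the framework names the quantity without a formula — and is
kept in one function so an alternative (e.g. a saturating functional
response) can be swapped in. `limitation_map()` reports which constraint
binds per cell, ties going to `physiology_limited`.

Surfaces are instantaneous-rate maps: there is no time stepping and no
feedback of consumption onto consumer biomass. The state space is
memoryless — no hysteresis or alternative-stable-state dynamics.

## Phase structure and numerical choices

`classify_regions()` labels cells by `N > 0`; exact zeros are classed
depleted, so the boundary belongs to the barren region.
`extract_isocline()` runs marching squares on the net matrix with linear
interpolation along cell edges; each vertex therefore satisfies
`|interpolated N| ≤ 1e−9`. Saddle cells (both diagonals crossing) are
resolved by the sign of the bilinear interpolant at the cell center — the
standard deterministic rule. The test suite checks every vertex against an
independent brute-force edge scan on randomly generated smooth fields.

`steepness_map()` uses central differences (one-sided at edges) after
rescaling each axis to `[0, 1]` by its grid range, because °C and µatm are
incommensurable; users with a physically motivated scaling can rescale the
axes themselves before gridding.

`classify_perturbation()` works on exact coordinates, not grid cells. A
perturbation is `state_shifting` iff the sign of net flips;
otherwise it is `parallel` when the log balance `log(P / ρG)` moves by at
most `tol` (default 0.05 — the arrow taxonomy is qualitative, so the
threshold is exposed), `reinforcing` when the balance diverges *and* `|N|`
grows, and `parallel` otherwise. When `P` or `ρG` is zero at an endpoint
the log balance is undefined and classification falls back to the
sign-and-magnitude rules alone. The log-balance criterion is one defensible
quantification of "equivalent benefit to both species"; it is a package
choice, flagged as such.

## Preset parameterization

The scenario-defining constants are the thermal optima (and the `fig8`
shifts of 2 °C and 4 °C); everything else is a frozen repository constant
chosen so each scenario's qualitative geometry holds on the default grid.
Changing any of them is a breaking change.

| preset | producer TPC (T_opt, CT_min, CT_max, σ) | consumer TPC (T_opt, CT_min, CT_max, σ) | extra |
|---|---|---|---|
| fig4 | 24, 5, 32, 8 | 20, 6, 26, 3.5 | — |
| fig5 | 20, 2, 30, 6 | 24, 6, 30, 4 | — |
| fig6 | 20, 2, 30, 7 | 20, 6, 25, 3 | producer broader |
| fig7 | 20, 6, 25, 3 | 20, 2, 30, 7 | consumer broader |
| fig8 | 24, 5, 32, 8 | 20, 6, 26, 3.5 | interaction (2, 4) °C |

All presets share the pCO2 responses — producer
`saturating(k_half = 800 µatm, baseline = 0.2)`, consumer
`threshold(c_mid = 1200 µatm, steepness = 0.012 /µatm, floor = 0.3)` —
and `ρ = 1`, efficiency 1, on the default grid: 111 temperatures over
[10, 32] °C (0.2 °C steps) × 62 pCO2 levels over [280, 1500] µatm (20 µatm
steps). Units are °C and µatm throughout, the standard units of the ocean
acidification literature; the pCO2 span runs from the pre-industrial
atmosphere to a high-emission coastal scenario. The grid resolves the
preset geometry while keeping a full scenario run around a second.

```{r scenario}
res <- run_scenario(build_preset("fig4"))
glance(res)
```

```{r panels, fig.height = 6}
autoplot(res)
```

## Synthetic observations and curve fitting

`simulate_observations()` draws driver values uniformly over the curve's
support (for a TPC, `[CT_min, CT_max]`; for the pCO2 and hormetic
families, a span wide enough to show both limbs) and adds Gaussian noise
truncated at zero — the simplest observation model for non-negative rate
data. Determinism is by explicit seed.

`fit_curve()` minimizes the residual sum of squares with Nelder–Mead from
8 deterministic starts spread over the observation range, on transformed
parameters that enforce each family's invariants; the winner gets a second
polishing round. A derivative-free search is used deliberately: the TPC is
piecewise, and its critical temperatures enter only through clipping, so
their derivatives vanish almost everywhere and gradient-based least
squares stalls. Multi-start matters because the quadratic limb can trap a
single start on the wrong side of the peak.

```{r recovery}
obs <- simulate_observations(tpc(24, 5, 32, 6), n = 200,
                             noise_sd = 0.02, seed = 1)
fit <- fit_curve(obs, "tpc")
glance(fit)
```

One identifiability caveat: when the Gaussian limb is still shallow at
`CT_min` (rise scale comparable to the span below the optimum), the
likelihood is nearly flat in `CT_min` — the fitted value can wander far
below the data while `T_opt`, `σ_rise`, and `CT_max` remain sharply
determined. Parameter-recovery claims in the test suite are therefore
about `T_opt` (median absolute error under 0.5 °C at n = 200, noise sd
0.02, across 20 seeds), the parameter the phase geometry depends on most.

## What the synthetic generator does and does not emulate

The generator produces independent, homoscedastic, truncated-Gaussian
errors around a known curve with uniform driver coverage. Real performance
data have none of these luxuries: error variance typically grows with the
rate, driver coverage is clustered at experimentally convenient levels,
acclimation and measurement order induce correlation, and the true curve
family is unknown. Passing the recovery tests therefore shows the
estimator is correct and well-conditioned under the stated observation
model — not that field TPCs are this easy. Likewise the preset scenarios
demonstrate the framework's qualitative geometry, not calibrated
predictions for any real species pair.

## Known limitations

- Two species, two drivers, one interaction mechanism; no population
  dynamics, no feedback of consumption on consumer biomass, no
  multi-trophic extension.
- Surfaces are memoryless snapshots; no hysteresis.
- The secondary-production and perturbation-classification formulas are
  package constructions where the conceptual framework is verbal; both are
  isolated in single functions for substitution.
- Light and nutrient axes are covered conceptually by the same four curve
  families but have no dedicated types.
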