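---
title: "Methods: personal thermal stress assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personal thermal stress assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermindex)
```

## What the package computes

thermindex turns a standard 3-hourly weather forecast plus a personal
context (body, activity, clothing, heat acclimatisation, indoor/outdoor
situation) into a single personal thermal stress index on a −4 (extreme
cold) to +4 (extreme heat) scale, with |index| ≤ 1 meaning low stress.
The index is a translation layer over four established occupational
models:

* **Heat (outdoor)** — the Liljegren outdoor WBGT model feeds an
  ISO 7243-style screening: the modelled WBGT is corrected by a clothing
  adjustment value (CAV) and divided by an acclimatisation- and
  metabolism-dependent reference limit to give the Heat Risk Level
  (HRL); a piecewise-linear map places HRL on the positive index scale.
  A Predicted Heat Strain (ISO 7933) minute-by-minute simulation
  supplies the duration limit until rectal temperature reaches 38 °C and
  the expected sweat loss.
* **Cold (outdoor)** — the IREQ model (ISO 11079) solves the whole-body
  heat balance for the clothing insulation required at a thermoneutral
  and a minimal (high-strain) criterion; the index scales the worn
  insulation against those two requirements (one index unit per Clo of
  deficit/excess outside the band). The JAG/TI windchill index covers
  local cooling of exposed skin.
* **Indoor** — Fanger's PMV/PPD (ISO 7730); the indoor index *is* the
  PMV.

## Derived meteorology

Forecast fields are normalised at the boundary (pressure hPa → kPa,
percent cloud cover → nearest octa) and the model-grade variables are
derived per sample:

* vapour pressure from the Antoine relation
  `0.1 · (rh/100) · exp(18.965 − 4030/(t+235))` kPa;
* 2 m wind from the 10 m forecast wind by the neutral-stability profile
  `v2 = v10 · (2/10)^0.25`. We use the exact power form; the factor is
  often quoted rounded to 0.67. The windchill formula is the one
  exception that consumes the 10 m wind directly — its 0.16 exponent
  already performs the height scaling, so no pre-scaling is applied;
* solar position from the low-precision astronomical-almanac ephemeris
  (mean anomaly, mean longitude, declination, sidereal hour angle) —
  accurate to a fraction of a degree, which is ample since radiation
  enters the models only through `cza`. Top-of-atmosphere irradiance is
  `1367 · max(0, cza)/d²` W m⁻² and clear-sky surface irradiance is 0.85
  of it; cloud cover attenuates by the transmittance `1 − 0.75(N/8)^3.4`.

**Worst-case radiation policy.** The heat path deliberately ignores
cloud attenuation (advice should hold for the sunlit intervals of a
partly cloudy day); the cold path forces a full 8-octa overcast
(transmittance 0.25) so radiative input is minimal. Both live in the
engine — the meteorology module exposes attenuated and unattenuated
radiation side by side.

## The globe models

Black-globe and natural wet-bulb temperatures are solved from the
Liljegren energy balances (radiative gain vs convective loss; plus
evaporation for the wick), with a 50 mm globe per the input convention,
surface albedo 0.45, wick dimensions 7 × 25.4 mm, and the reference
direct-beam parameterisation
`fdir = clip(exp(3 − 1.34·ns − 1.65/ns), 0, 0.9)` where `ns` is surface
irradiance normalised by top-of-atmosphere. Solvers are damped
fixed-point iterations started at air temperature (wet bulb: at the dew
point), tolerance 0.02 °C, capped at 500 iterations with a hard error on
non-convergence; wind speed is floored at 0.13 m s⁻¹ inside the solvers
as in the reference implementation. Note a physical subtlety the tests
acknowledge: under a clear, dry night sky the globe equilibrates up to
about 2 °C *below* air temperature because sky emissivity is well below
one.

Mean radiant temperature inverts the globe reading with
`t_mr = 100·[((t_g+273)/100)⁴ + h_c·(t_g − t_air)]^{1/4} − 273`,
`h_c = max(0.4·|Δt|^{0.25}, 2.5·v₂^{0.6})`; the form is fixed by the
requirement `t_mr = t_air` when `t_g = t_air`. A negative bracket
(possible only in pathological inputs) is clamped to zero with a
warning.

## Personal factors

Resting metabolic rate uses the sex-specific Harris–Benedict equations
(kcal day⁻¹, converted to Watts with the thermochemical calorie,
4184 J kcal⁻¹). Working levels carry fixed ISO 8996 class values (low
180 W, moderate 300 W, high 415 W, very high 520 W); areal rates divide
by the Du Bois surface area `0.007184·w^0.425·h^0.725`. Walking speed is
0.8 m s⁻¹ for every non-rest level (air-pumping approximation) and zero
at rest; external work is zero throughout. The clothing catalogue holds
six stock ensembles from summer (0.078 m² K W⁻¹, i.e. 0.5 Clo) to
extreme winter (0.388 m² K W⁻¹ = 2.5 Clo), each with a static vapour
permeability index and an air permeability; all three values are
user-tunable. 1 Clo = 0.155 m² K W⁻¹ throughout.

## Heat branch details

`CAV = 5.81·ln(R_{e,T,s}) + 20.7` °C with
`R_{e,T,s} = 0.16·(I_a/f_cl + I_cl)`, `I_a = 0.085` m² K W⁻¹. We read
the total insulation as basic insulation plus the air layer *divided* by
the clothing area factor — the ISO 9920 convention: enlarging the outer
surface dilutes the boundary-layer resistance. The clothing area factor
is `1 + 1.81·I_cl` below 2 Clo and `1.2424·clo^0.1546` above; the two
published branches do not meet at any single threshold, so the branch
point is a convention (we place it at 2 Clo with the linear branch
below) — it only matters for very heavy ensembles. The reference limit
is `56.7 − 11.5·log10(M)` °C for acclimatised and `59.9 − 14.1·log10(M)`
for unacclimatised workers, with M the whole-body heat production in
Watts. The HRL → index map has slopes 1.25, 5, 5, 1 across the bands
(<0.8, 0.8–1.0, 1.0–1.2, >1.2); we clamp the index at +4 since the scale
is defined on [−4, 4].

## PHS and IREQ internals

Both follow the published standard algorithms since the source models
are defined by those listings. PHS integrates minute by minute
(equilibrium core temperature with a 10-min time constant, clothed/nude
skin-temperature blend with a 3-min constant, dynamic clothing
corrections for wind and walking, sweat-rate prediction with
acclimatisation-dependent maxima — wettedness cap 1.0 vs 0.85 and a 25 %
higher maximum sweat rate when acclimatised). Out-of-envelope inputs
(t_air outside 15–50 °C, metabolic rate outside 100–450 W m⁻²) attach a
validity note rather than failing, because the engine intentionally
stretches model ranges at the heat/cold handover.

IREQ solves the heat balance at two (skin temperature, skin wetness)
criteria — neutral `(35.7 − 0.0285 M, 0.001 M)` with thermoregulatory
sweating, minimal `(33.34 − 0.0354 M, 0.06)` without — for the required
*resultant* insulation, then converts to required *basic* insulation by
undoing the wind/motion penalty
`0.54·e^{−0.15v−0.22w}·p^{0.075} − 0.06·ln p + 0.5` (p = ensemble air
permeability in L m⁻² s⁻¹). The package solves the balance residual by
`uniroot` (the residual is monotone in insulation); the exposure limit
solves the residual for the steady heat-debt rate S at the worn clothing
and converts the permissible debt of 40 Wh m⁻² into minutes, capped at
480 (an 8 h shift). Inputs are clamped to the standard's validity ranges
(M to [58, 290] W m⁻², v to [0.4, 18] m s⁻¹); note the Harris–Benedict
resting rate (~45 W m⁻²) sits below the floor and is clamped up to 58.

## Windchill

We keep the published JAG/TI coefficients with the 10 m wind in m s⁻¹,
matching the source convention of this tool family (the worked value
−15.2 °C at −12 °C and 5 m s⁻¹ pins this reading down). Two boundary
choices are ours: below a validity floor of 1.34 m s⁻¹ the function
returns the air temperature, and above it the result is capped at the
air temperature — with wind in m s⁻¹ the raw polynomial exceeds `t_air`
for winds up to about 3 m s⁻¹, and a windchill "warmer than the air"
would be physically meaningless for exposed-skin risk. Frostbite is
flagged exactly when the windchill is below 0 °C, and wind-stopping
clothing is advised exactly when the windchill sits at least 2 °C below
air temperature.

## Engine policy

Mode dispatch is total and deterministic: indoor contexts take the PMV
path; otherwise the heat path runs first and heat mode is entered iff
HRL ≥ 0.8 (the first WBGT alert band — the handover threshold is
configurable in `engine_settings()`); below it the cold path rules, with
IREQ deliberately stretched above its nominal +10 °C ceiling until the
WBGT threshold takes over. This yields exactly one mode per sample and
no gap in the sweep over air temperature. The cold-path index can be
*positive* (overdressed), which is how the well-known paradox arises of
simultaneous overdressing advice and frostbite warnings in windy cold.
Advice is emitted as stable machine-readable codes plus a text
catalogue; caregiver profiles (senior/child) only swap texts and never
affect the index. Self-reported thermal perception is echoed in reports
and never enters any computation.

A 24 h forecast is assessed sample by sample and contiguous windows with
|index| > 2 are flagged. Because wind and radiation enter the index,
the flagged peak need not coincide with the air-temperature extreme —
the test suite constructs an evening-gale series where peak cold strain
occurs hours after the coldest hour.

## Synthetic weather and what it does not emulate

`synthetic_forecast()` generates deterministic (seeded) 9-sample series:
`heatwave` confines air temperature to 28–38 °C (dry, sunny, Madrid
coordinates in July), `arctic` to −25…−5 °C (windy, overcast, Tromsø in
January), `temperate` is a mild spring day, and `diurnal-cycle` is a
clean sinusoid whose phase follows local solar time (coolest before
sunrise, warmest mid-afternoon). These reproduce the *ranges and
diurnal structure* the scenarios require; they do not emulate fronts,
precipitation physics, autocorrelated forecast error or humidity-wind
coupling, so passing tests demonstrate correct model translation, not
meteorological realism.

## Sensitivity grid

`sensitivity_grid()` fixes the experiment design used for the tool's
sensitivity analysis: vapour pressure frozen at the 20 °C / 50 % value
(1.18 kPa) with RH capped at 100 % at low temperatures, wind 1 m s⁻¹, no
solar irradiation (implemented by assessing at a mid-latitude winter
midnight), a 1.80 m / 80 kg person. Age and sex are not part of the
stated design; we fix them once at 40 y, male (they only enter through
the resting metabolic rate, which the grid's working levels bypass).
The default temperature axis is −20…45 °C in 5 °C steps — fine enough
to locate the band boundaries the qualitative claims are about.

## Verification strategy

Every model translation is cross-checked in the test suite against an
independent reference route: a flat transcription of the published
Liljegren listing (agreement within 0.5 °C over a
temperature–humidity–wind–sun grid), an independently structured
ISO 7933 minute loop with `uniroot` inner solves (DLE and sweat within
5 %), the published stepwise-march IREQ solver (insulation and exposure
limit within 10 %), a `uniroot` solution of the Fanger balance plus the
classic 22 °C/60 %/1.2 met/0.5 clo ≈ −0.75 validation row (PMV within
0.1), and the Spencer Fourier-series ephemeris (solar elevation within
2°). Mapping breakpoints are tested for continuity and monotonicity,
and the index is property-tested to stay inside [−4, 4] across weather
sweeps.

## Known limitations

* Altitude/barometric corrections beyond the forecast pressure field are
  not modelled; high-altitude use is out of scope.
* No exposure history: every assessment starts from a thermally neutral
  person.
* Local extremity cooling is handled only through windchill advice, not
  through limb-specific insulation modelling.
* The indoor temperature suggestion is an advisory adaptive-comfort
  stand-in (`0.33·t_out + 18.8` °C, ±1 °C per thermostat step); the
  assessment itself always uses the user-entered values.
* Medication, disease and age-specific threshold shifts are not
  modelled; caregiver profiles adapt wording only.
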