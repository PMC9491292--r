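---
title: "Modelling vegetation uptake of atmospheric mercury with hgdep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vegetation uptake of atmospheric mercury with hgdep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgdep)
library(dplyr)
```

## The problem

Vegetation is one of the largest sinks of atmospheric elemental mercury
(Hg⁰): foliage takes up Hg⁰ through stomata and leaf surfaces, and that
mercury reaches soils through litterfall and throughfall. The magnitude of
this sink is uncertain by a factor of several, and it matters: a weaker land
sink routes more mercury to the ocean, where it bioaccumulates as
methylmercury. `hgdep` provides the pieces needed to study this sink at desk
scale:

1. an offline **resistance-in-series dry-deposition velocity model** with
   compound-specific scaling (`drydep` functions, `velocity_field()`);
2. **land-surface handling**: fractional land-use composition per grid cell,
   73→11 category aggregation, weekly leaf-area-index (LAI) cycles, the
   site land-type override used for model–observation comparison, and a
   rainforest→savanna conversion (`savannize()`);
3. an **observation pipeline** turning litterfall / throughfall /
   wet-deposition fluxes and STP-referenced Hg⁰ concentrations into annual
   dry-deposition velocities (`derive_velocities()`);
4. a **three-box atmospheric Hg⁰/Hg²⁺ model** for tuning the aqueous Hg²⁺
   reduction coefficient against observed Hg⁰ concentrations
   (`tune_alpha()`);
5. **budget bookkeeping**: velocity × concentration → deposition flux maps,
   regional Mg yr⁻¹ integrals, and scenario deltas (`scenario_delta()`);
6. **synthetic generators** for meteorology, land surface and site
   databases, so every stage runs and is testable without external data.

## The deposition model

Dry deposition is modelled as three resistances in series,

$$ v_d = \frac{1}{R_a + R_b + R_c}, $$

with the aerodynamic resistance
$R_a = [\ln(z_{ref}/z_0) - \Psi_h(\zeta)]/(k u_*)$ (von Kármán constant
$k = 0.4$; Businger–Dyer $\Psi_h$, neutral $\Psi_h = 0$ when no stability
information is available), the quasi-laminar boundary resistance
$R_b = (2/k u_*)\,(Sc/Pr)^{2/3}$, and a bulk surface resistance $R_c$
combining four parallel pathways:

$$ \frac{1}{R_c} = \frac{1}{R_s + R_m} + \frac{1}{R_{lu}} +
   \frac{1}{R_{dc} + R_{cl}} + \frac{1}{R_{ac} + R_{gs}} $$

(stomata+mesophyll, cuticles, lower canopy, ground). Compound specificity
enters through the effective Henry's law constant $H^*$ and the biological
reactivity $f_0 \in [0, 1]$: dissolution and surface reaction are parallel
uptake routes, so e.g.

$$ R_m = \frac{1}{H^*/3000 + 100 f_0}, \qquad
   R_{lu} = \frac{R_{lu,base}}{10^{-5} H^* + f_0}\cdot\frac{1}{\mathrm{LAI}}, $$

and ground / lower-canopy resistances interpolate between baselines
tabulated for a highly soluble (SO₂-like) and a highly reactive (O₃-like)
reference gas, $R = [H^*/(10^5 R_{SO_2}) + f_0/R_{O_3}]^{-1}$. For Hg⁰,
$H^* = 0.11$ M atm⁻¹ and $f_0$ is the key uncertain parameter: $10^{-5}$
reproduces the historical North-American calibration, $3\times10^{-5}$
matches the Harvard Forest flux-tower net exchange, and $9\times10^{-5}$ /
$0.2$ match Amazon litterfall / total foliar uptake. Gaseous Hg²⁺
($f_0 = 0$, $H^* = 10^{14}$ M atm⁻¹) collapses $R_c$ to essentially zero.
Velocity is monotone non-decreasing in $H^*$, $f_0$ and LAI, and bounded by
$1/(R_a + R_b)$; the test suite asserts all of these as properties.

Blocked pathways (night-time stomata, zero LAI, inert+insoluble gas,
non-vegetated baselines) are represented by a single infinite-resistance
sentinel (`Inf`), never by division errors: `1/Inf = 0` makes the harmonic
combination exact.

### The baseline resistance table

The five-season × eleven-category baseline table
(`land_category_params()`) ships as an editable CSV
(`inst/extdata/surface_resistance_baselines.csv`), in the style of the
classic big-leaf parameterisations, so corrections are one-file edits. The
package's own category set includes *tropical rainforest* and
*savanna/grassland* as distinct categories so that land-conversion
scenarios are expressible. Over the *water* category the resistance scheme
is not applied: ocean Hg⁰ uptake belongs to air–sea exchange modelling,
outside this package's scope, and scenario runs use a configurable constant
(`ocean_vd`, default 0).

### Seasonal class and LAI

The seasonal class is a fixed month+hemisphere lookup (tropics, |lat| ≤
20°, are always "midsummer lush"; the snow class is never assigned — the
package models dry, snow-free surfaces only). Weekly LAI series are
interpolated linearly to the hour with wrap-around
(`lai_at()`). The stomatal leaf resistance is divided by LAI (a canopy of
parallel leaves) and the cuticular baseline likewise; at LAI = 0 both
pathways are blocked rather than divided by zero. These scalings are the
package's own choice where the level of detail is genuinely open; each is
isolated in one documented function so alternatives are one-line edits.

Whether an offline velocity model should apply stability corrections is
also genuinely open; the met generator emits neutral stability by default,
and `aerodynamic_resistance()` accepts a Monin–Obukhov parameter when the
caller has one.

## From field measurements to velocities

Site studies report litterfall, throughfall, and open-field wet deposition
(µg m⁻² yr⁻¹), plus Hg⁰ air concentrations at STP (273 K, 1 atm). The
pipeline computes, per record,

* total foliar uptake = litterfall + throughfall − open-field wet
  deposition (the total dry-deposited Hg to foliage);
* the local-condition concentration
  $C_{local} = C_{STP}\,(273/T)(P/1\,\mathrm{atm})$ — typically a 3–40 %
  decrease at warm or high-altitude sites;
* $v_d = F/C_{local}$ with a 365-day year (3.1536×10⁷ s), reported in
  cm s⁻¹.

Conventions (documented because the choices are open): quartiles use the
linear-interpolation rule (`stats::quantile` type 7); records lacking a
usable concentration are excluded from velocity statistics but retained as
flux records; negative foliar-uptake fluxes are retained and flagged rather
than dropped — transparency over silent filtering. Litterfall-based
velocities under-sample total uptake (woody tissues, mosses, lichens and
the throughfall component are missed), which is why litterfall and
total-foliar medians differ by ~36 % in the literature; the synthetic site
generator reproduces exactly this structure with its `litterfall_frac`
(default 0.73 ≈ 1/1.37).

## The three-box model and reduction tuning

Strengthening the Hg⁰ land sink in a chemistry-transport model depletes
atmospheric Hg⁰ unless the aqueous reduction of Hg²⁺ back to Hg⁰ is
retuned. The expensive part of that retuning can be done offline with a
three-box (NH extratropics / tropics / SH extratropics) linear mass
balance: emissions in; first-order oxidation, reduction (bulk rate
$\alpha k_{red}$, with the NO₂-photolysis and organic-aerosol dependence of
the full parameterisation folded into $k_{red}$), Hg⁰ dry deposition to
land, Hg²⁺ wet+dry deposition; 20 % of terrestrial Hg²⁺ deposition
promptly re-emitted as Hg⁰; inter-box exchange on fixed timescales. The
steady state is one dense linear solve; `tune_alpha()` brackets and
root-finds the $\alpha$ that matches a target NH surface Hg⁰ concentration
(default target in examples: 1.4 ng m⁻³), with self-recovery accurate to
better than 10⁻⁶ relative.

The default box construction (air masses 1.0/2.05/1.0 ×10¹⁸ kg, emissions
4000/3000/1000 Mg yr⁻¹, $k_{ox} = 4$ yr⁻¹, $k_{red} = 70$ yr⁻¹,
$k_{dep,Hg^0}$ = 0.6/0.8/0.15 yr⁻¹, $k_{dep,Hg^{2+}}$ = 25 yr⁻¹, exchange
0.3 yr) is configuration, not code, and was chosen once to sit at the
global scales of the modern mercury cycle: ~8000 Mg yr⁻¹ emitted, a Hg⁰
burden of a few thousand Mg, a land Hg⁰ sink of order 2000 Mg yr⁻¹ and an
Hg²⁺ lifetime of weeks. It is illustrative: the package makes no claim to
reproduce any specific transport model's tuned coefficients, only the
procedure and its directional behaviour (a doubled land sink forces
$\alpha$ up, by about a factor of 2 in our configuration).

## Scenarios and budgets

`savannize()` reassigns all tropical-rainforest coverage within a mask to
the savanna category, replacing its LAI with the mean weekly LAI of current
savanna reference cells; `scenario_delta()` recomputes velocities for both
surfaces under identical meteorology, converts to deposition at a fixed
prescribed concentration field, and reports regional budget deltas
(antisymmetric by construction). The concentration field is *prescribed* —
the package contains no transport — so budget magnitudes of
chemistry-transport scale (global land sinks in thousands of Mg yr⁻¹,
ocean transfers of hundreds of Mg yr⁻¹) are documented context, not
reproducible outputs. The optional box-model closure translates a weakened
land sink into a re-equilibrated global state, reporting the implied extra
ocean deposition and Hg⁰ burden increase — directionally the same
land-to-ocean shift the full-model scenario shows.

## What the synthetic data emulate — and what they do not

The generators (all seeded, Mersenne–Twister, bit-reproducible) emulate:
diurnal solar geometry with cloud attenuation and zero night-time
radiation; latitudinal, seasonal and diurnal temperature structure;
lognormal friction velocity; a mixed land-use map with an Amazon-like
rainforest block, a savanna reference block, coastal water/land cells and
all 11 categories present; and site databases with multiplicative
lognormal flux noise (σ = 0.3 by default, a visual match to the spread of
published litterfall compilations — a modelling choice, not a measured
value) around a known true velocity. They do **not** emulate realistic
geography, spatial covariance of meteorology, measurement-method biases
beyond litterfall undersampling, or inter-annual trends. Passing tests
therefore demonstrate correctness of the algorithms and their documented
structure on data of the assumed form, not agreement with any particular
field campaign.

## Numerical choices and problem sizes

* Internal units are SI (m s⁻¹, s m⁻¹, K, Pa); cm s⁻¹, ng m⁻³, µg m⁻²
  yr⁻¹ and Mg yr⁻¹ appear only at I/O boundaries; unit conversions are
  exact (tested to 10⁻¹² relative, round-trip).
* Fraction normalisation is enforced to 10⁻⁶ everywhere; area of the
  sphere partitions exactly (closed form).
* The steady-state solve uses LAPACK through `solve()`; the transient
  integrator (`deSolve::ode`) is used only for diagnostics and as an
  independent oracle in tests.
* Examples and tests use one-cell annual runs (8760 h, ~1 s) and small
  multi-week gridded runs (6×6 cells × 2 weeks) — sizes chosen so the
  whole analysis re-runs comfortably on a laptop; all magnitudes quoted in
  the README come from exactly these runs.

## Known limitations

Dry, snow-free surfaces only; no wet/snow surface modifications. No
atmospheric transport, oxidation-mechanism detail, aerosol (particulate
Hg) deposition or air–sea exchange. No foliar re-emission parameterisation
(derived velocities are net uptake, as are the measurements). The baseline
resistance table is a literature-style reconstruction and intentionally
lives in one editable CSV.
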