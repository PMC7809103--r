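---
title: "Modelling seasonal competition and parasitism in the maize pest complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seasonal competition and parasitism in the maize pest complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestdyn)
```

## The system

Maize fields in Kenya host an interacting complex of four lepidopteran
pests — the stemborers *Busseola fusca* (Bf), *Sesamia calamistis* (Sc) and
*Chilo partellus* (Cp), and the invasive fall armyworm *Spodoptera
frugiperda* (Sf) — each attacked by a guild of parasitoid species. pestdyn
simulates the joint dynamics of any subset of these pests and their guilds
as a stock-and-flow system: one pest stock $N_i(t)$ and one lumped
parasitoid stock $P_i(t)$ per species, in individuals per hectare, with
time in months.

## Model structure

**Pest growth.** Each pest grows by Lotka–Volterra interspecific
competition against a shared, season-switching carrying capacity $K(t)$:

$$G_i = \frac{r_i N_i}{K(t)} \Big( K(t) - N_i - \sum_{j \neq i} a_{ij} N_j \Big),$$

where $r_i$ is the intrinsic monthly growth rate and $a_{ij}$ the
per-individual effect of species $j$ on species $i$. The coefficient
matrices were estimated from density-dependent larval-survival experiments
separately for every 2-, 3- and 4-species combination; `competition_matrix()`
therefore keys the lookup by the *exact* species subset, never by pair.

**Seasonality.** Time 0 is the April planting. A 3-month maize variety is
grown April–June and October–December; the remaining months the pests
persist on wild alternative hosts. This gives $K(t)$ two levels: 62,500
individuals/ha in the field (31,250 plants/ha at a reference density of 2
pests per plant) and 625 in the refuge. Three delays/discounts shape each
year:

* pests are first recorded in the field one month after planting, so
  $K(t)$ stays at the refuge level for the first month of each cropping
  block (`pest_entry_delay`);
* parasitism is recorded only from the pest's second field generation, so
  the crop-level parasitism fraction $\varphi_i$ activates two months after
  planting (`parasitism_onset_delay`), with $\varphi_i = 0$ in the gap and
  a low wild fraction (0.05) during non-cropping months;
* at the instant a cropping season ends, only 10% of each pest stock
  survives onto alternative hosts (`carryover_fraction`); the haircut is
  instantaneous, applied once per boundary, and affects pests only —
  parasitoid guilds decline through their own decrease rate.

The published constants table prints two readings for the wild parasitism
row (0.05 and "0.055%"); the package adopts 0.05, which matches the row's
value column, and keeps 0.055 as `wild_parasitism_preset("high")`.
Similarly the non-cropping capacity row prints both "625" and "10%"
(inconsistent with 62,500); the explicit value cell 625 is used, as a plain
config field.

**Parasitism.** The parasitism loss flow is a pluggable strategy
(`parasitism_forms()`). Two forms are registered, both built from the
printed constants ($\varphi_i$, the meeting probability $p = 0.035$, and
the capacity):

* `"saturating"` (default): $L_i = \varphi_i(t)\, N_i \,(1 - e^{-p P_i})$.
  Per-capita parasitism rises with parasitoid density and saturates at the
  recorded fraction $\varphi_i$, so the published parasitism rates are the
  high-parasitoid limit.
* `"mass_action"`: $L_i = \varphi_i(t)\, p\, N_i P_i / K(t)$, the bilinear
  form normalized by capacity.

The default was chosen on dynamical grounds. Each parasitized host yields
$5 \times 0.46 = 2.3$ female parasitoids and guilds decline at 0.7 per
month, so a guild persists only where $2.3 L_i / P_i > 0.7$. Under the
bilinear form $2.3 L_i / P_i = 2.3\varphi_i p N_i / K \le 2.3 \times 0.3
\times 0.035 \approx 0.024$ for any feasible stock ($N_i \le K$), two
orders of magnitude short: parasitoids decay monotonically to zero and no
host–parasitoid cycling is possible at the printed constants. The
saturating form sustains the guilds and reproduces the qualitative
behaviour the system is described to have — populations growing from low
stocks, then a cyclical host–parasitoid relationship from about month 4,
with every parasitoid peak trailing its host peak. Custom forms can be
supplied as a function via the `parasitism_form` field.

**Parasitoid flows.** $R_i = 2.3\, L_i$ (emergence times sex ratio) and
$D_i = 0.7\, P_i$, with the bookkeeping identity $R_i = 2.3 L_i$ holding
exactly at every recorded step.

## Integration and numerical choices

The integrator is fixed-step forward Euler at $\Delta t = 0.25$ months
(weekly), matching the recording interval and the fixed-step scheme of the
stock-and-flow platform the model family comes from:
$N_i \leftarrow \max(0, N_i + \Delta t (G_i - L_i))$ and likewise for
$P_i$. Negative excursions are clipped at zero and logged in the
trajectory's `clip_events` attribute. The choice is deliberate: the
overshoot-and-oscillate behaviour around the capacity is part of the
modelled dynamics, and a higher-order adaptive solver would smooth it away.

Euler at this step is not a precise ODE solver. In the parasitism-free,
constant-capacity limit the trajectory is logistic with closed form
$N(t) = K / (1 + ((K - N_0)/N_0) e^{-rt})$; at $r = 0.83$ and $\Delta t =
0.25$ the discrete growth factor per step is $1.2075$ against the exact
$e^{0.2075} \approx 1.2305$, which compounds to a maximum pointwise
relative error near 28% during the exponential phase (around 2% would
require $\Delta t \approx 0.01$). The error decreases monotonically as the
step halves, which the test suite asserts; simulations at different `dt`
should only be compared qualitatively.

Season boundaries are detected at exact sample times (the horizon must be
a multiple of `dt`), the carryover is applied before the boundary state is
recorded, and `t` is recomputed as `k * dt` each step so no floating-point
drift accumulates.

**Initial conditions** are not printed anywhere; the package defaults to
$N_i(0) =$ `reference_density_wild` $\times K_{wild}/2 = 156.25$
individuals/ha per species (half the refuge reference density, i.e. growth
from a near-empty refuge) and $P_i(0) = 0.1 N_i(0)$, identical across
species since no species-specific seeding is given. Both are plain config
fields; dominance *shares* are insensitive to moderate changes because all
species are seeded equally, but absolute peak sizes scale with them.
Stocks are continuous densities per hectare; no integer rounding is
applied. The published reference pest densities (2 per plant in crop, 0.5
in the wild) enter only through these initial-condition defaults, not the
flow equations.

## Metrics

* `dominance_shares()` — each species' fraction of the summed pest stocks.
  The published percentages are stated "after 6 months" without saying
  whether they are instantaneous or averaged; the package computes both
  and treats the time-average over months 6–24 as the headline number,
  since it is stable against the phase jitter of the fixed-step
  integrator. Samples where the total is zero are dropped from the
  average.
* `mean_total_pests()` / `cross_system_ratio()` — the time-mean of the
  summed pest stocks, and the percentage ratio of its average across one
  collection of systems to another (sole vs pairs, pairs vs triples,
  triples vs quad), averaging across all systems of a given cardinality.
* `detect_cycles()` — interior local maxima (strict sign change of the
  first difference) of a pest stock and its guild after a 4-month burn-in
  (the published runs become cyclical after month 4), plus the lag of each
  parasitoid peak behind the nearest preceding host peak.
* `phase_diagram()` — all pests compiled into one host total and all
  guilds into one parasitoid total, the standard two-stock validation
  view. The final 6 months (one cropping plus one non-cropping block, the
  period of the seasonal attractor) are treated as the final loop; the
  closure gap between its first and last point, relative to the loop
  diameter, measures how closed the orbit is. The quad-system default run
  closes to well under 1% of the loop diameter.

## Coefficient estimation

`fit_competition()` inverts the equilibrium relation
$K_i = N_i + \sum_{j \neq i} a_{ij} N_j$, where $K_i$ is the total larval
survival a habitat supports and $N_i$ the focal survivors: for each focal
species the response $K_i^{obs} - N_i$ is regressed on the competitor
densities by intercept-free ordinary least squares — the literal
rearrangement of the equilibrium line, since no intercept appears in it.
Negative estimates are retained but flagged rather than constrained,
because a non-negativity constraint would invalidate the reported standard
errors; designs with collinear or constant competitor densities are
rejected with the focal species named. `solve_equilibrium()` and
`equilibrium_residual()` expose the same linear system for feasibility
analysis, and equilibrium states are exact fixed points of the
competition-only growth flow.

## Synthetic data

`generate_density_experiment()` emulates the structure of the
density-dependence experiments behind the coefficient tables: a factorial
grid of larval densities with additive Gaussian noise on the survival
response, truncated at zero. Defaults are laboratory-scale — density
levels 0/10/20/40 larvae per arena, 3 replicates, noise sd 0.5 larvae. The
focal species' density takes only positive levels (an arena without focal
larvae records no survival), while competitor densities include 0 as
controls; this also keeps the zero-truncation inactive at realistic noise
levels, so the estimator is unbiased on generated data. The generator is a
pure function of the design and its seed.

What these fixtures do *not* emulate: count-valued (e.g. binomial)
survival noise, arena-scale crowding nonlinearities, or the unpublished
empirical noise level of the original experiments. Passing the recovery
tests therefore shows the estimator is correct for the stated linear
additive-error model, not that field data would be as well behaved.

`generate_trajectory_fixture()` provides analytic trajectories (logistic,
lagged sine pair, closed circle, flat) with ground truth attached, so the
metrics are tested independently of the simulator. `perturb_parameters()`
builds lognormally jittered scenario ensembles for robustness checks of
the dominance orderings.

## Problem sizes

Default runs are 96 Euler steps (24 months at $\Delta t = 0.25$); the full
15-system gallery plus the aggregated validation run completes in about a
second, and the whole test suite — including a 100-repeat Monte-Carlo
bias check of the estimator — in a few seconds.

## Known limitations

* The exact flow equations of the original stock-and-flow implementation
  are not published in the main text; the parasitism form here is a
  documented, swappable surrogate chosen as described above. Quantitative
  reproduction of the published percentages is therefore not guaranteed,
  and the package's own results differ in level while agreeing in most
  orderings.
* Under the literal competition equation, coefficients of order $10^{-4}$
  per individual are negligible against field-scale stocks
  ($a_{ij} N_j \ll K$), so simulated dominance is driven almost entirely
  by the growth-rate and parasitism differences between species and the
  shares of coexisting species are far closer to symmetric than the
  published ones. The coefficient units/scale are not stated; they are
  treated as dimensionless per-individual effects at field scale.
* No stochastic demography, no spatial structure, no
  temperature/phenology dependence, and no competition between parasitoid
  guilds (excluded by assumption).
* Whether parasitoids should also take a between-season haircut is not
  stated; the package applies it to pests only.

## A minimal session

```{r example, eval = FALSE}
traj <- simulate(pest_scenario(c("Bf", "Cp")))
dominance_shares(traj)
detect_cycles(traj, "Cp")
phase_diagram(simulate(pest_scenario(pest_species_ids())))
```
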