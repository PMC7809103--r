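# pestdyn

Stock-and-flow simulation of the maize pest complex of Kenya: the
stemborers *Busseola fusca* (Bf), *Sesamia calamistis* (Sc) and *Chilo
partellus* (Cp), the invasive fall armyworm *Spodoptera frugiperda* (Sf),
and the lumped parasitoid guild attacking each of them. The package is for
ecologists and IPM modellers who want a scriptable, tested version of this
class of seasonal competition/host–parasitoid models: it builds every
single- and multi-species scenario from published constants, simulates
them deterministically, and computes the summaries by which such systems
are compared (dominance shares, peaks, cross-system population ratios,
cycle detection, phase portraits).

## The model

For each pest species *i* in the system, with stocks in individuals/ha and
time in months:

```
dN_i/dt = (r_i N_i / K(t)) (K(t) - N_i - Σ_{j≠i} a_ij N_j)  -  L_i     (pest)
dP_i/dt = 2.3 L_i - 0.7 P_i                                 (parasitoids)
L_i     = φ_i(t) N_i (1 - exp(-0.035 P_i))                   (parasitism)
```

* `r_i` — intrinsic growth rate; `a_ij` — per-individual competition
  coefficient of species *j* on *i*, estimated separately for every 2-,
  3- and 4-species combination (lookup is by exact subset).
* `K(t)` switches between 62,500 individuals/ha in the maize field and
  625 in the wild refuge. Maize is in the field April–June and
  October–December; pests enter the field 1 month after planting,
  crop-level parasitism `φ_i` activates 2 months after planting (wild
  level 0.05 during non-cropping months), and only 10% of each pest stock
  survives each cropping→non-cropping transition.
* Each parasitized host yields 5 × 0.46 = 2.3 female parasitoids; guilds
  decline at 0.7/month.

Integration is fixed-step forward Euler at dt = 0.25 months over 24
months, with stocks clipped at zero (and the clipping logged). The
parasitism form is a swappable strategy (`parasitism_forms()`); the
methods vignette (`vignettes/maize-pest-dynamics.Rmd`) explains why the
saturating default is used and every other numerical choice.

The package also implements the estimation side: `fit_competition()`
recovers the `a_ij` from density-dependent larval-survival tables by
intercept-free multiple regression on the equilibrium relation
`K_i = N_i + Σ_{j≠i} a_ij N_j`, and `generate_density_experiment()`
produces synthetic experiments with known coefficients for validating it.

## Worked example

```r
library(pestdyn)

traj <- simulate(pest_scenario(c("Bf", "Cp")))   # two-species system
dominance_shares(traj)
#> Dominance shares (instantaneous at month 6; averaged over [6, 24]):
#>                  Bf    Cp
#> instantaneous 48.91 51.09
#> averaged      49.17 50.83

detect_cycles(traj, "Cp")
#> Cycles of Cp after month 4: 3 pest peaks, 3 parasitoid peaks
#> Parasitoid lags behind host peaks (months): 0.25, 0.25, 0.25

peak_summary(traj)$table
#>   stock       max t_max
#> 1  N_Bf 1705.9167 20.75
#> 2  N_Cp 1751.3578 20.75
#> 3  P_Bf  617.2175 21.00
#> 4  P_Cp  770.7581 21.00

phase_diagram(simulate(pest_scenario(pest_species_ids())))
#> Phase portrait: 97 points; final 6-month loop closure gap 12.16 (0.2% of loop diameter 6225)
```

Reading the numbers: *C. partellus* holds a slightly larger averaged share
of the pair's total pest stock than *B. fusca* (its higher growth rate
outweighs its higher parasitism), both species peak near the end of the
final cropping season, each parasitoid guild peaks one time step after its
host, and the aggregated four-species run traces an essentially closed
host–parasitoid loop — the classic cyclical signature of a sustained
host–parasitoid interaction.

`run_gallery(dir)` reproduces the full study layout: all 15 systems (4
sole, 6 pairwise, 4 three-species, 1 four-species) plus the aggregated
two-stock validation run, writing per-system trajectory/metrics CSVs, a
combined dominance-share table and a manifest, byte-identically on every
rerun.

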