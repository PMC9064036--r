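# mmgrowth

Single-cell growth analysis for mother-machine microfluidic
cultivations. The package takes tables of division events (one row per
observed cell life: birth time and generation time τ), and turns them
into population growth rates, growth-kinetic parameters and
heterogeneity measures — handling the statistical trap of finite
recordings: long generation times are systematically undercounted.

It is written for microbiologists and biostatisticians analysing
time-lapse lineage data, with *Corynebacterium glutamicum* growing on
protocatechuic acid (PCA, 0–100 mmol L⁻¹) as the motivating system.

## What it computes

**Censoring-corrected generation-time distributions.** In a window
`[t_start, t_end]` a cell with generation time τ can only start within
`t_end − t_start − τ`, so raw histograms are biased short. Counts are
reweighted by

    c_τ = (t_end − t_start) / (t_end − t_start − τ)

and normalized into a discrete distribution f(τᵢ) on the 5-min imaging
grid.

**Population growth rate** by inverting the Euler–Lotka relation for
binary fission,

    1 = 2 Σᵢ f(τᵢ) exp(−µ τᵢ),

solved to machine tolerance on a provable bracket. Experiments with
fewer than 5 usable events are assigned µ = 0; those with 5–49 are
excluded as unrepresentative; 50+ are analysed.

**Growth kinetics across concentrations.** Replicate-level (c, µ) pairs
are fitted by bounded multi-start least squares to
Monod-with-Hill-inhibition models,

    µ(c) = µ_max · c/(K + c) · 1/(1 + (c/K_I)^n_I)          (single-step)
    µ(c) = (µ₁ c/(K₁+c) + µ₂ c/(K₂+c)) · 1/(1 + (c/K_I)^n_I)  (two-step)

plus plain Monod and Teissier comparators.

**Transport limits of the device.** From diffusivity, penetration
depth, cell density and chamber geometry: the per-cell uptake
u = D·ḡ·h/(ρ·l_g²), the volumetric uptake Û = u·ρ/h, the parabolic
channel concentration profile, and the critical inlet concentration
Û·l²/(4D) below which the channel centre starves.

**A synthetic-data generator** simulates whole studies (mother lineages
per channel, imaging-grid discretization, natural censoring,
concentration-dependent kinetics, all-or-nothing replicate failure) with
a ground-truth manifest, so every pipeline stage is verifiable end to
end.

## Worked example

```r
library(mmgrowth)

study <- simulate_study(simulation_config(seed = 1))   # 12 conc x 5 reps
out <- run_analysis(study$events,
                    analysis_config(models = "single"),
                    experiments = study$truth,
                    transport = transport_params())
out
#> <mm_analysis>
#>   events read: 12620 rows, 44 experiment(s)
#>   events inside [15, 40] h window: 7428
#>   experiments: 35 analyzed, 20 zero_growth, 5 excluded
#>   fit 'single': RSS 0.010737 on 55 observations
```

Per-concentration replicate means show the growth optimum at
6 mmol L⁻¹ and the collapse at inhibitory concentrations:

```r
summarize_concentrations(out$results)
#>    concentration_mmol_per_L n_replicates mean_mu_per_h sd_mu_per_h
#>  4                     0.1             5        0.1293     0.00314
#>  7                     1               5        0.3107     0.00212
#>  8                     6               5        0.3594     0.00189
#>  9                    20               5        0.2413     0.00147
#> 11                    50               5        0.0000     0.00000
```

The fitted kinetic parameters come back near the generating values
(µ_max 0.37, K 0.185, K_I 23.37):

```r
tidy(out$fits$single)
#>   term   estimate std.error
#> 1 mu_max    0.372   0.00600
#> 2 K         0.192   0.0108
#> 3 K_I      21.5     0.245
#> 4 n_I       8.71    0.893
```

and the transport report puts the diffusion-limitation threshold at
`out$transport$c_crit_mmol_per_L` ≈ 0.139 mmol L⁻¹ for a 20 µm channel
(0.070 with the centre-drop convention) — the same order as the
concentration below which spatial heterogeneity appears in such devices.

Plot helpers: `autoplot()` on distributions and fits,
`plot_heterogeneity()` for the variance-vs-mean generation-time view.
A thin CLI over the same functions ships in `inst/scripts/mmgrowth`
(subcommands `simulate`, `analyze`, `fit`, `transport`).

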