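# mitowave

Quantitative analysis and modelling of the **mitotic wave** in rows of
*Drosophila* sensory organ progenitors (SOPs).

On the pupal notum, bristle precursors sit G2-arrested in rows until one
anteromedial cell per row — SOP0 — resumes mitosis; its neighbours follow,
and divisions propagate as a centrifugal wave toward both row ends. The
wave is thought to arise from contact inhibition: each undivided SOP
inhibits its neighbours' mitotic entry (via protrusion-mediated
Delta/Notch/Scabrous signalling), and dividing switches that inhibition
off. `mitowave` provides, for anyone analysing such division-timing data:

* **Wave metrics** — SOP0 identification, signed metric ranks
  (rank × mean inter-SOP distance, µm; anterior negative), rank–time
  regressions per wave arm, and the wave rate: mean |1/slope| in µm/min.
* **The contagion model** — per undivided cell *i*,

  dA\_i/dt = r/(1 + I\_i) − A\_i/ρ,  dI\_i/dt = μ·m\_i(t) − I\_i/δ,

  where m\_i(t) counts undivided immediate neighbours; the cell divides
  when A reaches a threshold θ, releasing its neighbours. Simulated with a
  compiled fixed-step integrator with interpolated event times;
  non-dimensionalised (r = δ = θ = 1) so ρ and μ are the free parameters.
* **Parameter estimation** — deterministic least-squares fitting of
  (ρ, μ) with the data/model time scale profiled in closed form, plus a
  fit-comparison predicate for the "inhibition down, ρ stable" signature.
* **Synthetic nota** — genotype presets (control, *sca* null, Rac1
  dominant-negative, *Dl/sca* het) generating realistic record tables so
  the whole pipeline is testable end to end.
* **I/O** — delimited-text record tables (`notum_id, row_id, side,
  position_um, division_time_min, genotype`), auto-detected delimiter,
  dual `.`/`,` decimal parsing, column-name mapping for foreign layouts.

## Worked example

```r
library(mitowave)

# one model row: 4 anterior + 8 posterior cells around the seed
p <- contagion_params(rho = 20, mu = 0.65)
sim <- simulate_row(p, n_ant = 4, n_post = 8, spacing_um = 30,
                    time_scale = 55)
head(as.data.frame(sim), 7)
#>   rank metric_rank_um time_min
#> 1   -4           -120 134.3508
#> 2   -3            -90 134.3481
#> 3   -2            -60 133.0691
#> 4   -1            -30 110.6099
#> 5    0              0   0.0000
#> 6    1             30 110.6099
#> 7    2             60 133.0691

# a synthetic control cohort, analysed like a recording
cohort <- bind_cohort(generate_cohort(genotype_preset("control", seed = 1),
                                      n_nota = 16))
analyze_cohort(cohort)
#> <wave_analysis>
#>   48 row series, 96 per-row regressions
#>   wave rate: 2.425 um/min (per-row), 3.117 um/min (aggregate)
```

The model row shows the wave's signature shape: symmetric arms, a large
first step (SOP0 is the origin, not a mean), then flattening as distant
cells approach their own division schedule. The cohort analysis reports
the wave rate under both documented regression granularities — per-row
series or cross-nota aggregate curves (here 2.4 and 3.1 µm/min; a faster,
more synchronous wave gives larger values).

Fitting the model back to the cohort's mean curve recovers the inhibition
parameter and illustrates a documented caveat:

```r
fit <- fit_params(aggregate_series(analyze_cohort(cohort)$series))
fit
#> <contagion_fit>
#>   rho_hat = 499.8, mu_hat = 0.5276, time_scale = 55.79 min/unit
#>   loss = 15.7211 min^2 over 15 points (1844 evaluations)
```

μ̂ = 0.528 against a generating μ of 0.52; ρ̂, by contrast, is essentially
unconstrained by noisy curves (the generating value was 40) — see the
methods vignette (`vignettes/mitotic-wave-model.Rmd`) for the
identifiability analysis.

A thin command-line wrapper covers the same pipeline
(`inst/scripts/mitowave`): `synth`, `analyze`, `simulate`, `fit` and
`recover` subcommands over CSV tables, each run writing a provenance
record.

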