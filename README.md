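# gqunfold

Single-molecule quantification of helicase-mediated G-quadruplex (GQ)
unfolding, and of how GQ-stabilizing small-molecule ligands inhibit it.

G-quadruplexes are four-stranded structures formed by guanine-rich DNA
(e.g. human telomeric repeats). Helicases such as Bloom helicase (BLM)
unfold them during replication and repair; GQ-stabilizing ligands are
usually ranked by the thermal stabilization they confer, but the
physiologically relevant question is how much they slow *helicase-mediated*
unfolding. gqunfold implements the analysis for the two single-molecule
readouts of that quantity, for researchers analyzing smFRET trajectories
and TIRF spot-count time-lapses:

- **Dynamic smFRET assay.** Per-frame FRET efficiency is the raw proximity
  ratio E = I_A / (I_D + I_A). Each helicase-mediated unfolding shows as a
  dip from a folded level (E ≈ 0.70 parallel, ≈ 0.59 antiparallel) to
  E ≤ 0.45 followed by a rise to E ≥ 0.55. A hysteresis state machine
  counts events (single-point dips excluded); the condition-level rate
  pools molecules, k = Σ events / Σ observation time, with observation
  windows bounded at photobleaching. Uncertainty is a molecule-level
  bootstrap (20 000 resampled sets; Gaussian-fit SD and 2.5–97.5%
  percentile CI), and ligand conditions are normalized to a matched
  no-ligand reference.
- **Cumulative spot assay.** Surface-bound donor-labelled molecules leave
  the surface once the GQ has been unfolded and the adjacent duplex
  unwound; spots are counted per time-lapse frame (robust-background local
  maxima detection), normalized to percent remaining, and the removed
  fraction at 600 s is expressed relative to the reference.
- **Synthetic-data module.** A two-state continuous-time Markov trace
  simulator (frame integration, channel noise, exponential photobleaching,
  donor-only subpopulation) and a spot time-lapse simulator carry full
  ground truth, so every estimator is validated by parameter recovery.

FRET histograms of pooled early frames are fitted with least-squares
Gaussian mixtures to characterize folded-state populations. All
user-facing functions take data frames and return tibbles; fitted objects
have broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()`
views.

## Worked example

Simulate a no-ligand reference and a ligand condition in which unfolding is
slowed 2.5-fold, then run the full trace pipeline:

```r
library(gqunfold)

ref_cfg <- trace_sim_config(n_molecules = 150, n_frames = 3000,
                            k_unfold = 0.05, seed = 1)
lig_cfg <- trace_sim_config(n_molecules = 150, n_frames = 3000,
                            k_unfold = 0.02, seed = 2)

analyze <- function(cfg, name, boot_seed) {
  sim <- simulate_condition(cfg)
  fret <- compute_fret(sim$traces)
  windows <- detect_observation_window(fret)
  records <- count_unfolding_events(fret, windows = windows)
  list(estimate = summarize_condition(records, name),
       boot = bootstrap_mean_rate(records, n_boot = 20000, seed = boot_seed))
}

ref <- analyze(ref_cfg, "BLM-only", 11)
lig <- analyze(lig_cfg, "BLM + ligand", 12)
ref$estimate
#> <rate_estimate> BLM-only: 96 events / 4325.2 s over 150 molecules -> 0.0222 /s (mean of per-molecule rates 0.03009 /s)
ref$boot
#> <rate_bootstrap> 20000 sets of 150 molecules: mean 0.02942 /s, sd 0.005645 /s, 95% CI [0.01996, 0.04265]
lig$estimate
#> <rate_estimate> BLM + ligand: 49 events / 4375.5 s over 150 molecules -> 0.0112 /s (mean of per-molecule rates 0.02368 /s)
relative_rate(lig$estimate, ref$estimate, lig$boot, ref$boot)
#> <relative_rate_result> BLM + ligand / BLM-only = 0.5045 (50%)
```

Reading the output: the reference condition yielded 96 unfolding events in
4325 s of pooled observation time over 150 molecules, a pooled rate of
0.0222 s⁻¹ with a bootstrap SD of 0.0056 s⁻¹ (the mean-of-rates statistic
the bootstrap resamples differs from the pooled rate because observation
times vary per molecule). The ligand condition's pooled rate is normalized
to the reference: 0.50, i.e. unfolding slowed to 50% — consistent with the
2.5-fold generative slowdown given that short dwells below the detector's
minimum are censored in both conditions.

The cumulative assay is analogous:

```r
ref <- simulate_spot_counts(spot_sim_config(n_spots = 400,
                                            removal_hazard = 2e-3, seed = 5))
lig <- simulate_spot_counts(spot_sim_config(n_spots = 400,
                                            removal_hazard = 8e-4, seed = 6))
relative_activity(lig$series, ref$series, t_ref = 600)
#> <relative_activity_result> condition vs condition at 600 s: removed 0.360 vs 0.722 -> relative activity 0.498
```

A command-line pipeline (`exec/gqunfold`, or `run_cli()` from R) wraps the
same functions as subcommands `simulate-traces`, `analyze-traces`,
`simulate-spots`, `analyze-spots` and `report`, writing per-molecule CSVs,
result JSONs, summary tables and a provenance record beside every output.

See the vignette `vignettes/gq-unfolding-kinetics.Rmd` for the model,
parameter meanings, numerical choices and limitations.

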