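---
title: "Quantifying helicase-mediated G-quadruplex unfolding from single-molecule data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying helicase-mediated G-quadruplex unfolding from single-molecule data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gqunfold)
```

## The measurement problem

G-quadruplexes (GQs) are four-stranded DNA structures formed by guanine-rich
sequences, notably at human telomeres (hGQ). Small-molecule (SM) ligands that
stabilize GQs are candidate anti-proliferative agents, and their efficacy is
conventionally summarized by the thermal stabilization they confer
(&Delta;T~m~). In cells, however, GQs are resolved not by heat but by
helicases such as Bloom helicase (BLM), so the physiologically relevant
question is how much a ligand slows *helicase-mediated* unfolding. gqunfold
implements the analysis for two complementary single-molecule readouts of
that quantity:

1. **Dynamic assay (smFRET).** A donor/acceptor pair spans the GQ of a
   surface-tethered construct. Folded GQ gives high FRET efficiency
   (E~FRET~ &asymp; 0.70 for the parallel conformer, &asymp; 0.59 for
   antiparallel/hybrid); each transient unfolding by the helicase appears as
   a dip to low E~FRET~ followed by refolding. Counting dips across hundreds
   of molecules yields an unfolding rate per condition, and ligand conditions
   are expressed relative to a matched no-ligand reference.

2. **Cumulative assay (spot counting).** The GQ sits between the surface
   tether and a short donor-labelled duplex. The helicase can only unwind
   the duplex — releasing the labelled strand from the surface — after
   unfolding the GQ, so the number of donor spots in the field decays with
   cumulative unfolding activity. The fraction of spots removed by a
   reference time (600 s), normalized to the no-ligand reference, is the
   second measure of inhibition.

Both analyses operate on tabular data (per-frame intensities, per-molecule
records, per-timepoint counts), so every user-facing function takes a data
frame and returns a tibble, chaining with the pipe.

## FRET traces and the observation window

The per-frame efficiency is the raw proximity ratio
$E = \frac{I_A}{I_D + I_A}$ after clamping negative (background-subtracted)
intensities to zero. No gamma or leakage correction is applied: thresholds
are calibrated on the uncorrected scale, and molecules lacking an active
acceptor form their own histogram peak at the leakage level
(E &asymp; 0.12) rather than being subtracted. Frames with non-positive
summed intensity are undefined and are skipped by every downstream step;
traces that are undefined throughout are dropped with a warning rather than
an error, since they are a routine feature of real fields of view.

Observation time runs from the start of recording until photobleaching or
the end of the movie, whichever comes first. Photobleaching detection is not
specified by any standard, so the package uses a deliberately simple,
configurable rule on running medians (window 5 frames, drop fraction 0.5,
both exposed as arguments and tuned against simulator ground truth):

* **Donor bleach** — the summed intensity is memoryless under unfolding
  (donor and acceptor trade intensity), so its first sustained drop below
  half the initial level marks the end of the window.
* **Acceptor-only bleach** — the acceptor channel *does* drop transiently
  during genuine unfolding dwells, so a first-crossing rule would truncate
  traces at their first event. The window therefore ends at the first frame
  from which the acceptor running median stays below half its initial level
  for the remainder of the trace (a permanence rule). A trace that ends
  during a real unfolded dwell loses at most that final dwell (~2 s at the
  default refolding hazard), which removes events and time in proportion and
  leaves the pooled rate essentially unbiased.

## Event counting: dual thresholds with hysteresis

An unfolding event is a dip from a folded level to E &le; 0.45 followed by a
rise to E &ge; 0.55. The detector is a three-state machine per molecule:

* **disarmed &rarr; armed** when the trace first reaches the high threshold
  (a trace that starts unfolded and never folds yields no events);
* **armed &rarr; unfolded** when E stays at or below the low threshold for
  at least `min_dwell_frames` consecutive defined frames (default 2 —
  single-point dips are indistinguishable from noise and are conservatively
  not counted);
* **unfolded &rarr; armed** when E returns to the high threshold.

Frames strictly between the thresholds never change the state (hysteresis),
so between-threshold wander is never double-counted; undefined frames are
skipped without resetting either the state or the dwell counter. Two
counting conventions are implemented because the event signature names a dip
*and* a rise while the rate arithmetic counts unfolding events: the default
`at_dip` increments when the qualifying dip is reached (an event interrupted
by bleaching still counts, consistent with worked traces whose windows end
at acceptor bleach), and `full_cycle` increments only on the completed rise.
The state machine is verified against an independently hand-specified DFA by
exhaustive enumeration of all threshold-symbol traces up to length 12, for
both modes and dwell requirements 1–3. No smoothing or hidden-Markov
idealization is applied: thresholding raw E~FRET~ is the method; HMM-style
idealizers are a documented non-goal because gradual unfolding transitions
and short dwells defeat their assumptions here.

## Rates, bootstrap uncertainty, and normalization

The condition-level rate pools all molecules:
$k = \frac{\sum_i n_i}{\sum_i T_i}$, with zero-event traces contributing
observation time only. This equals the observation-time-weighted mean of
per-molecule rates (asserted numerically in the tests). Uncertainty comes
from a molecule-level bootstrap: each of 20 000 sets resamples N
per-molecule rates with replacement and stores their unweighted mean. The
reported uncertainty is the SD of a least-squares Gaussian fit to the
histogram of resampled means (Freedman–Diaconis bin width), with the
empirical 2.5–97.5% percentile interval alongside. Two numerical
fallbacks guard the fit: an all-identical distribution reports SD 0 without
fitting, and fewer than five distinct resampled means (tiny-N enumeration
regimes, where the histogram is a few spikes) reports sample moments with a
note. Ligand conditions are normalized by dividing pooled rates; for
distributions, the ligand's resampled means are rescaled by the reference
distribution's Gaussian peak so the reference peaks at 1.0 (a rescaling, not
a ratio of paired resamples, matching how normalized rate distributions are
conventionally displayed).

One estimator subtlety is preserved deliberately: for one published
reference condition the printed event count and total time give a pooled
rate that rounds to 0.054 s^-1^ while the printed rate is 0.055 s^-1^
(which the unweighted mean of per-molecule rates could produce). Both
estimators are therefore computed and reported, and the acceptance test
asserts the discrepancy rather than hiding it.

## FRET histograms

Folded-state characterization pools the first 15 defined frames of each
molecule (one short movie; the exact pooled frame count is not standardized,
so it is an argument) into 0.02-wide bins spanning [-0.2, 1.2], and fits a
sum of Gaussians to the binned counts by Levenberg–Marquardt least squares —
matching how such histograms are conventionally presented and fitted, rather
than EM on raw samples. SDs and amplitudes are optimized on the log scale so
they stay positive; the fit is deterministic given the initial means, and
components are returned sorted by mean with area-fraction weights. Recovery
tests sample the three-peak generative model (means 0.12/0.59/0.70, SDs
0.02/0.05/0.03) at 10^5^ frames and require all means back within ±0.01.

## The spot assay

Spot detection is deliberately simple and is validated only on synthetic
frames (the counting programs used in practice are typically unpublished):
background level and noise are estimated by median and MAD over the frame;
candidates are local maxima within a PSF-sized neighborhood exceeding
background + 5 SD; maxima closer than `min_separation` merge, keeping the
brighter. Thresholding in SD multiples makes counts invariant to uniform
intensity rescaling. Counts are normalized so the first timepoint reads
100%; the removed fraction at t~ref~ = 600 s is interpolated linearly
between bracketing timepoints (time-lapse schedules need not hit 600 s
exactly), and relative activity is the ratio of removed fractions,
condition over reference. Replicates are independent series, paired by
position, summarized by mean and sample SD.

## The synthetic-data generator

The generator exists so that every stage has ground truth. Each molecule
carries a two-state continuous-time Markov chain (folded &harr; unfolded)
sampled in continuous time; per-frame efficiencies are occupancy-weighted
within the frame crossing a transition (frame integration), which is the
only nod to the gradual transitions seen in real data — transitions are
otherwise instantaneous. Intensities partition a constant total
(donor = total·(1−E), acceptor = total·E, the standard map when only FRET
levels, not absolute intensities, are constrained) with Gaussian noise both
on the FRET scale and per channel. Donor and acceptor bleach as independent
exponential clocks; bleaching is a hard step to background, after acceptor
bleach the trace reads at the leakage level. Donor-only molecules emit
constantly at E = 0.12; no blinking or spectral cross-talk matrix is
modelled.

Defaults are fixed once as the study conditions: 600 s at 50 ms frames
(200 ms for the spot time-lapse), unfolding hazard 0.05 s^-1^, refolding
0.5 s^-1^, 60% parallel conformer among FRET-active molecules, 20%
donor-only, bleach lifetimes 30 s (acceptor) and 60 s (donor) giving mean
per-molecule observation times near the ~22 s the published totals imply,
total intensity 1000 with channel noise 40 and FRET-scale noise 0.05. The
unfolded level defaults to E = 0.30 with the shared noise SD — an explicit
assumption, since the unfolded-state distribution is characterized only
against a supplementary unstructured-construct histogram not reproduced
here; it is chosen to sit clearly below the 0.45 threshold. The spot assay
defaults to a removal hazard of 1.2&times;10^-3^ s^-1^ (roughly half the
spots removed by 600 s, the scale of the no-ligand reference) and zero
bleach hazard, since the control series demonstrates negligible
photobleaching under time-lapse excitation.

The generator emulates the statistical structure the analysis assumes — not
surface heterogeneity, day-to-day protein-activity variation, ligand
adsorption, partial unfolding attempts, or conformer interconversion.
Passing recovery tests therefore demonstrates that the estimators are
correct and calibrated for data satisfying the model, not that real movies
satisfy it; on real data the published inter-analyst spread of ~25% in
absolute rates is the relevant caution, and it is why ligand effects are
always reported relative to a same-chamber reference.

"Ground-truth event rate" in the recovery tests means transitions whose
unfolded sojourn lasts at least `min_dwell_frames` frames within the
analysed window: the detector excludes shorter dips by design, so that is
the rate it estimates. With the default dwell of 2 frames at 50 ms and
refolding hazard 0.5 s^-1^, ~5% of true transitions fall below the cutoff;
comparing against the raw transition rate would conflate that deliberate
censoring with estimator error.

## Problem sizes and determinism

Tests and the acceptance script use 500 molecules × 12 000 frames for trace
recovery, 10^5^ frames for histogram recovery, 2 000 spots for survival
checks, 20 000 bootstrap sets, and exhaustive event-counter enumeration to
length 12 — sizes chosen so the full suite completes in well under a minute
per stage while keeping Monte-Carlo error far inside the asserted
tolerances. All randomness flows from explicit integer seeds:
`simulate_condition()` seeds once from its config, the bootstrap takes its
own seed, and the command-line pipeline derives per-condition substreams
from `--seed`, so simulate &rarr; analyze &rarr; report reproduces bit for
bit.

## Known limitations

* The photobleach detector is heuristic; traces whose acceptor bleaches
  during an unfolded dwell are truncated at the preceding fold, and
  windows are resolved only to about half the median window.
* The Gaussian-mixture fit is least squares on binned counts; for very low
  counts per bin a Poisson likelihood would be preferable.
* Spot detection has no sub-pixel localization or drift correction and
  merges genuinely overlapping molecules; it is a validated stand-in, not a
  reimplementation of any particular counting program.
* The two-state kinetic model ignores partial unfolding attempts and
  multi-state folding; dwell-time distribution fitting is out of scope.
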