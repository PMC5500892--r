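---
title: "Quantitative AP-MS interactomics and EPSC analysis with apmskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative AP-MS interactomics and EPSC analysis with apmskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmskit)
```

## The problem

Affinity purification coupled to mass spectrometry (AP-MS) identifies the
stable interaction partners of a membrane-protein target: antibodies pull
the target and its co-assembled complexes out of a solubilized membrane
fraction, and label-free quantification of the co-purified proteins tells
us *how much* of each partner travels with the target. The motivating
application is the proteome of AMPA-type glutamate receptors in rodent
brain, where serial purifications and knockout comparisons distinguish
receptor sub-populations (for example, assemblies organized around
biogenesis factors in the endoplasmic reticulum versus surface receptors
carrying TARP/CNIH/GSG1l core subunits). The same experiments motivate the
electrophysiology half of the package: when an assembly factor is knocked
down, the consequence is read out as a change in excitatory postsynaptic
current (EPSC) amplitudes, so the measurement conventions for those
currents are implemented alongside.

`apmskit` implements the full analysis chain downstream of peptide feature
extraction, together with synthetic-data generators so that every stage
can be tested against known ground truth without any raw spectra.

## From peak volumes to protein profiles

The elementary observation is the **peak volume** (PV): one peptide's
m/z signal intensity integrated over chromatographic time, arranged as a
peptides x datasets matrix (`pv_matrix`). Two nuisance factors separate a
PV from the protein amount of interest: the peptide's response factor
(ionization efficiency and detectability, easily spanning orders of
magnitude between peptides), and multiplicative measurement noise.

The quantification stage removes the first factor by **max-normalization**
(`normalize_peptide_profiles()`): each peptide's PVs are divided by that
peptide's maximum over all datasets. Because the response factor is a
property of the peptide, not of the dataset, it cancels exactly; what
remains is a relative profile in [0, 1] that all sibling peptides of a
protein should share.

Peptides that do *not* share it — false assignments, interfering features,
modified forms — are removed by **correlation ranking**
(`rank_and_select_peptides()`): peptides are scored by their mean pairwise
Pearson correlation against siblings (pairwise-complete, with at least
`min_shared = 3` shared datasets per pair; sparser pairs contribute r = 0
so undefined correlations cannot dominate), peptides with mean r below 0
are discarded, and the best `k = max(k_min, ceiling(fraction * n))`
peptides are kept, with `k = n` for proteins with `n <= k_min` peptides.
The defaults `k_min = 3`, `fraction = 0.5` reproduce the "50% best
correlating" convention for larger proteins while keeping a floor for
small ones; the published description of the rule ("at least 2–7 or, for
larger proteins, the 50% best") is ambiguous about the small-protein
floor, so the rule is exposed as three configurable parameters rather
than hard-coded. Ties in mean correlation are broken lexicographically by
peptide sequence to keep runs deterministic.

The protein's **relative abundance profile** is then the per-dataset
median over the selected peptide profiles (`protein_profile()`). The
median, combined with the selection step, absorbs a gross outlier peptide
completely: in the noiseless case the recovered profile is exact, which
is what the oracle tests assert to 1e-9.

Two absolute-scale estimators sit on top of the profiles:

* `calibrate_qconcat()` fits, per protein, one non-negative least-squares
  scale factor to calibration values from concatenated-standard
  (QconCAT-style) fusion-protein measurements, giving **molecular
  abundances**. The fit is global per protein rather than per dataset —
  the calibration standard measures the protein's response, which does
  not vary between datasets — and has the closed form
  `s = sum(profile * cal) / sum(profile^2)`.
* `abundance_spec()` provides the fallback for proteins without
  standards: summed isoform-specific PVs divided by the number of
  MS-accessible isoform-specific amino acids. It is linear in the PVs, so
  its rank order tracks true abundance even though its absolute scale is
  arbitrary.

`normalize_to_target()` finally divides every abundance by the dataset's
primary-target abundance, so values read as degree of association with
the bait, and computes the amount of co-purified AMPA receptors as the
sum of GluA1-4 abundances over 4 (four pore-forming subunits per
receptor tetramer).

## Specificity: ratios, thresholds, consensus

Specific interactors are separated from background by **enrichment
ratios** (rPV): each target-AP replicate's abundance over the mean of the
control replicates (`compute_rpv()`, mean-of-ratios across replicates,
reported mean ± s.e.m.). Proteins undetected in a control are given a
detection-floor abundance of half the smallest observed value in that
dataset — some floor is required for finite ratios, half the minimum is
the conventional choice, and every imputed cell is flagged.

The **specificity threshold** for one comparison is estimated from the
distribution of all proteins' log ratios (`estimate_threshold()`):
`exp(median + 3 * MAD)` with the scaled median absolute deviation
(consistency constant 1.4826). The published analyses derive thresholds
"from rPV histograms" without restating the procedure, so this robust
mode-plus-spread rule is a declared design choice: median and MAD ignore
the enriched minority, which gives the threshold its key property that
adding strongly enriched proteins never lowers it. Fewer than 20 finite
ratios make distribution estimation meaningless and raise an error
advising a manual threshold.

`call_specific()` applies the published consensus rule: a protein is
specific when it exceeds the threshold in at least two independent
antibody-versus-IgG comparisons *and* in every required depletion or
knockout control comparison. On simulated truth (5 prey among 200
background proteins) this yields precision 1.0 at recall about 1 under
the default multiplier.

**Two-step (serial) APs** measure co-assembly directly: an exhaustive
first AP captures a fraction F of each protein, the second AP of the
flow-through captures 1 − F. `twostep_partition()` computes
`F = rPV / (rPV + 1)` per replicate from the first/second ratio and
averages across replicates. The map rPV → F is a bijection from (0, ∞)
onto (0, 1) with the reflection identity F(1/x) = 1 − F(x), and
F + (1 − F) = 1 holds exactly by construction. A protein seen in only one
of the two steps is treated as fully captured there (F = 1 or 0) and
flagged, rather than floor-imputed, so the boundary cases are exact.

`compare_groups()` (e.g. knockout versus wild type) reports the ratio of
group means with a two-sided Student's t-test and the `**` / `***`
star convention at p < 0.01 / p < 0.001. No multiple-testing correction
is applied — the published analyses report per-protein p-values — so
p-values are per-protein statements, which the documentation states
explicitly. `cross_dataset_correlation()` implements the subunit
correlation analysis: a protein coupled to a whole receptor population
correlates better with the *sum* of that population's subunits than with
any single member, which the Monte-Carlo tests reproduce.

## EPSC measurement conventions

The electrophysiology module implements fixed measurement rules for
synaptic currents digitized at 20 kHz (the generators refuse sampling
below 10 kHz):

* **Peak**: extremum of the baseline-subtracted current within 2 ms after
  the presynaptic action potential. The baseline is the mean over the
  5 ms preceding the AP — the published conventions do not state a
  baseline window, and 5 ms is long enough to average noise but short
  enough to avoid preceding events. Events peaking later than the window
  are knowingly underestimated; a test documents this behavior.
* **Rise time**: interval between the 20% and 80% crossings of peak
  amplitude, linearly interpolated between samples. For a saturating
  exponential rise this equals `ln(4) * tau_rise`, which the tests check
  to within one sampling interval.
* **Latency**: AP to the 5%-of-peak onset crossing; evoked events outside
  0.2–2 ms are flagged.
* **Decay**: least-squares fit of `A * exp(-t / tau)` from the peak over
  the following 40 ms — exactly the segment the acceptance filters
  guarantee to be interference-free. Start values come from a log-linear
  regression and are refined by Levenberg–Marquardt; noiseless
  mono-exponentials are recovered to better than 0.1% across
  tau in [1, 100] ms.
* **Acceptance filters**: amplitude > 20 pA, no further event onset
  within 40 ms, rise time within 0.4–2.0 ms. Each violated rule is named
  in the rejection reasons, and each filter is individually necessary.
* **Paired pulse**: because at 50 Hz the second response rides on the
  first decay, `measure_paired_pulse()` subtracts the first event's
  fitted decay, extrapolated under the second peak, before reading the
  second amplitude — the standard overlap correction.
* **AMPA/NMDA ratio**: when only the total dual-component current and the
  pharmacologically isolated NMDA component are available, the AMPA
  component is their difference.

Group differences of EPSC statistics use the Mann–Whitney U test
(`mann_whitney_u()`): exact for combined n ≤ 20 without ties, normal
approximation with tie and continuity correction otherwise; an all-tied
input returns p = 1. The tests verify the exact branch against full
enumeration of rank assignments and the approximation's type-I error
against the exact null distribution of U.

The spontaneous-event detector (`detect_epsc_onsets()`, smoothed
derivative crossing 3 x noise s.d.) is a declared stand-in: only the
post-hoc acceptance filters are part of the published conventions, the
pre-detector is not, so it is kept simple and configurable.

## What the generators emulate — and what they do not

`simulate_apms()` generates
`PV = abundance * response(peptide) * noise(peptide, dataset)` with
log-normal response factors (sdlog 0.5), log-normal measurement noise
(the default CV of 0.2 is a typical label-free replicate CV; published
replicate variances are not available for this workflow, so defaults are
chosen for realism and testability), optional outlier peptides whose
values are scrambled by an independent per-dataset factor, and logistic
missingness in log-PV emulating a detection limit. Noise factors have
unit expectation, so noiseless limits reduce every generator to closed
forms and the two-step generator conserves `first + second = total` in
expectation.

`ap_scenario()` encodes the standard specificity design — two antibody
APs, an IgG control, a target-depletion control, 50-fold enrichment of
bait and prey over controls, background log-normal around 10 (sdlog 1) —
and `simulate_twostep()` the serial design with a configurable true
fraction; 0.175 is used throughout the tests as the mid-range of the
15–20% co-assembly finding the design mirrors. `simulate_epsc_train()`
sums difference-of-exponential events (tau_rise 0.5 ms, tau_decay
11.3 ms, the control decay constant) onto Gaussian noise, evoked at AP
markers plus 0.5 ms latency or as a Poisson train.

The generators deliberately do **not** emulate: retention-time
misalignment or feature-matching errors beyond the outlier mechanism,
correlated (batch-like) noise between datasets, isoform-shared peptides
(the flag exists but the generator emits only specific peptides),
chromatographic or spectral structure, and overlapping synaptic events
beyond Poisson timing. Passing recovery tests therefore show that the
estimators are correct and robust under the stated noise model, not that
they would be unbiased on any real acquisition; in particular the
specificity precision of 1.0 reflects independent noise between antibody
comparisons, which shared upstream processing could violate.

## Numerical choices and degenerate inputs

* Tables are tab-separated UTF-8, `.` decimal, empty string = missing;
  floats are serialized with 6 significant digits, below measurement
  precision, so read/write round-trips are stable.
* Missing PVs are distinct from zero; an all-missing peptide is dropped
  with a warning, a dataset whose target abundance is missing or zero is
  dropped from normalization with a message.
* Percentages round half away from zero (96.1 / 3.9 from 815 / 33 of
  848); pooled percent-of-control uses the unweighted mean of group
  means (conditions are summarized per group first), and
  `percent_remaining + percent_reduction = 100` exactly before rounding.
  Whether published "about 60%" summaries pool conditions or describe
  them singly is not always stated; pooling is the documented choice.
* All simulations are seed-deterministic, and the pipeline's outputs are
  a pure function of (inputs, config, seed); the run log echoes every
  parameter.

The test suite and the acceptance script run the recovery analyses at
deliberately desk-sized problems — 6–8 proteins, 5–6 peptides each, 8
datasets, 100 seeds for profile recovery; 206 proteins and 50 seeds for
specificity; 4 000-sample traces for kinetics — sizes at which the
Monte-Carlo bands in the tests are stable but a full run completes in
seconds.

## Worked example

```{r example, eval = FALSE}
model <- ap_scenario(seed = 1)
sim <- simulate_apms(model, noise_model(cv = 0.15), 6, seed = 2)
prof <- protein_profiles(sim$pv)$profiles

r1 <- compute_rpv(prof, "AB1", "IGG")
r1$threshold <- estimate_threshold(r1$rpv)
head(r1[order(-r1$rpv), ])
```

## Known limitations

* Protein inference stops at the isoform-specific flag; shared-peptide
  grouping is out of scope.
* The correlation-based outlier filter is a simple mean-r cutoff; the
  full published filter it stands in for is not restated in the source
  describing this workflow.
* rPV combination across replicates is mean-of-ratios (each first
  replicate versus the averaged controls); ratio-of-means would differ
  slightly for noisy low-abundance proteins.
* The EPSC decay fit window starts at the measured peak, where the rise
  term has not fully saturated; for tau_rise 0.5 ms and tau_decay about
  11 ms this biases tau by under 1%, which the recovery tests bound.
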