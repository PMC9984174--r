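---
title: "Methods: modeling single-cell JNK heterogeneity with jnknoise"
author: "jnknoise authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling single-cell JNK heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jnknoise)
```

This vignette is the package's own account of its science: the network
model and its assumptions, the calibration contract, the reporter model,
the trace-analysis rules, the synthetic-data generator, and the
numerical and design choices that were genuinely open.

## The network model

The model describes stress- or chemotherapy-induced activation of the
apoptotic JNK pathway in a single cell as a deterministic ODE system
with 16 species:

* **ZAK** (a MAP3K): inactive and active forms. The stress input `S`
  (arbitrary stress units, a sustained step from `t = 0`) drives
  activation at rate `kin * S * Z / (kmz + Z)`; deactivation is first
  order.
* **MKK4**: un-, mono- and bis-phosphorylated forms (the bis form is
  active) plus an Akt-inhibited form.
* **MKK7**: the same three phospho-forms, each also in a
  feedback-marked variant, plus an Akt-inhibited form (7 states).
* **JNK**: un-, mono- and bis-phosphorylated; bis-phosphorylated JNK
  (the T183/Y185 analogue) is the model's activity readout.

Kinase steps are distributive two-site Michaelis–Menten reactions;
constitutive phosphatases are first order. This is the standard MAPK
cascade idiom: the literature fixes the topology of this network (a
three-tiered cascade with positive feedback on MKK7 and inhibitory Akt
cross-talk on both MAP2Ks) but not its rate equations, so the
functional forms here are the package's own choice and no
correspondence with any previously fitted constants is claimed.

**Positive feedback.** Active JNK converts every MKK7 phospho-form into
a feedback-marked variant (mass action in active JNK, rate `kfb`;
reverse rate `pfb`). The marked bis-phosphorylated form phosphorylates
JNK with a `gfb`-fold catalytic gain (default 40). Setting `kfb = 0`
and `gfb = 1` (`disableFeedback()`) removes every feedback contribution
while leaving all other constants untouched — the in-silico knockout.

**Akt cross-talk.** Phospho-Akt acts as a fixed-concentration kinase
driving MKK4 and MKK7 into catalytically dead inhibited states with
first-order recovery. Only the direction and the existence of the
inhibitory sites are fixed by the biology; *which* forms are drained is
a free design choice. The package drains the **phosphorylated** (i.e.
signaling-engaged) forms: a drain on the unphosphorylated pool is
already equilibrated before stimulation and yields a monotone,
plateau-shaped response with no defined peak time, whereas the
engaged-form drain produces the observed transient — a rise to a peak
(anchored at 30 min, below) followed by slow adaptation — and gives
phospho-Akt its amplitude-limiting role.

**Per-cell parameterization.** A cell's relative abundances (reference
population mean 1) multiply the reference totals (100 concentration
units per pool) and the cross-talk flux. `buildNetwork()` +
`simulateCell()` integrate the system from the cell's pre-stimulus
steady state at the basal input.

## Calibration

`calibrateNominal()` fixes the free time scale of the hand-set base
constants against three constraints on the nominal (all-ones) cell:

1. the saturated response (1000 stress units) peaks at **30 min**, the
   peak time of anisomycin-induced JNK activity;
2. the basal input is **1/20th** of the saturating input — a
   physiological resting drive rather than a zero input;
3. the effective Hill coefficient of the peak-versus-stimulus response
   with feedback enabled is at least 2 (the cascade's ultrasensitivity).

Because constraint 1 is satisfied by a pure time rescaling (every
first-order and bimolecular rate is multiplied by one factor;
Michaelis constants, the gain and the totals are untouched), peak
*amplitudes* and all ensemble statistics are invariant under the
calibration — the time axis is the only thing it moves. The remaining
base constants were tuned, once, so that the reference synthetic
ensemble reproduces the study's printed emergent statistics (an
impaired fraction near 10% and a stimulated-peak CoV near 73% under
33–43% component noise, with the feedback knockout lowering amplitude
but *raising* CoV); `scripts/acceptance.R` and the acceptance tests
recompute these quantities from scratch.

## Where the ultrasensitivity lives

With the shipped constants the full model's dose response is not a
smooth sigmoid: it contains a near-discontinuous **ignition** of the
positive feedback (a jump of nearly two orders of magnitude between
adjacent stimuli), after which the response keeps growing along a
graded branch. Two consequences matter for interpretation:

* `doseResponse()` reports the spec-classical half-maximum log-slope
  estimate (`hill`, about 2.6 for the nominal cell) *and* the maximum
  local log-slope (`hillMax`, about 5–10 depending on the stimulus
  grid). Because the nominal cell ignites far below saturation — it
  must, for only ~10% of noisy cells to fail ignition at 1000 stress
  units — the half-maximum falls on the graded branch, where the local
  slope is comparable to the feedback-free cascade's (about 2.8). The
  switch itself is visible only in `hillMax`, which is the quantity the
  package's tests use for the feedback-ultrasensitivity ordering.
* The ensemble's bimodality (ignited vs non-ignited cells) is exactly
  the mechanism that produces the impaired subpopulation and the
  amplified output noise.

## The kinase translocation reporter

The KTR is modeled with four states (phosphorylated × compartment)
with first-order shuttling; phosphorylation is proportional to kinase
activity. The default constants put half-phosphorylation near 75
activity units so the cytoplasmic:nuclear ratio (range 0.2–2.0) spans
its dynamic range across activities 0–200; shuttling operates on the
minutes scale, so the reporter tracks the hours-scale activity
transients with negligible lag. `ratioToActivity()` inverts the
steady-state map by bracketed root finding (tolerance 1e-9) and clips
at the 200-unit saturation cap, so measurement imprecision at
saturating ratios cannot explode into the activity estimate: beyond the
cap the derivative of the estimate with respect to the ratio is exactly
zero. Single-time-point conversion uses the steady-state inverse; the
dynamic reporter model is used only to *generate* synthetic traces.
The concentration units of the cap are the reporter model's native
units; no mapping to the network model's totals is implied.

## Trace analysis rules

* **Expression bounds**: tracks with mean reporter MFI strictly below
  10 or strictly above 200 are excluded; boundary values are retained.
  Every exclusion is logged with a reason code.
* **Coverage**: either the full imaging period (`full_period`) or a
  contiguous first `minMinutes` (default 480 min = 8 h).
* **Caspase onset**: the first sample time with caspase intensity
  strictly above 50 MFI. The per-time-point reading (first crossing) is
  used rather than a whole-track mean, because onset *times* are the
  quantity of interest downstream; a series sitting exactly at 50 never
  fires.
* **Peak window**: default 0–240 min (the early activity phase);
  `smooth = "median3"` (used by the pipeline) applies a 3-point running
  median before peak picking — the usual high-content denoising step —
  while the function default leaves the raw maximum untouched.
* **Normalization anchor**: the pipeline expresses peak activities
  relative to the highest activity recorded across **all** tracks,
  before QC exclusion, so that dropping the single brightest cell
  cannot rescale the activity axis.
* **Commitment curve**: per-bin apoptotic fractions over equal-width
  peak bins; the 50% midpoint is interpolated on a weighted
  monotone (pool-adjacent-violators) regularization of the binned
  fractions. Monotonicity of commitment in peak activity is the only
  assumption; the generator's logistic form is never used on the
  analysis side.
* **Onset-curve regression**: within each condition's cumulative
  caspase curve, the linear portion is selected automatically as the
  maximal-R² contiguous window of at least 4 samples starting at or
  after the first nonzero fraction; pairwise slope differences use a
  Welch-type t on the slope standard errors.

## Statistics layer

Cohen's d is the absolute mean difference over the pooled
(group-size-weighted) SD. The reporting classes follow the figure
convention: d < 0.2 inconsequential (even when statistically
significant), 0.2–0.5 small, > 0.5 large; the textbook 0.8 anchor for
"large" is noted in the documentation. Gating applies when both groups
exceed 1000 cells (`gatedComparison()`, Welch's t by default). The
cumulative-distribution discrepancy Z (`cdfDiscrepancyZ()`) compares a
simulated sample set to observed replicates: D is the mean absolute
difference of pooled empirical CDFs on a fixed unit-interval grid, and
Z standardizes D against leave-one-out replicate-vs-rest
discrepancies. The published Z values for this comparison were computed
from experimental replicates that are not redistributable, so the
construction here is a documented, testable choice — ordering and sign
behavior are guaranteed by tests, numerical agreement with any printed
value is not claimed.

## The synthetic generator

`generatorConfig()` freezes the study conditions: n = 2000 cells;
independent log-normal abundances with mean 1 and per-component CoV
targets of 43/35/39/33/41% for ZAK/MKK4/MKK7/JNK/phospho-Akt (spread
over the measured 33–43% range; an optional correlation matrix exists
because inter-component correlation in real flow data is unreported,
and independence is the default); 15-min sampling over 16 h with
additive ratio noise of SD 0.02 (~1% of the reporter's dynamic range);
a rise-and-decay activity drive peaking at 120 min (drug-induced JNK
peaks at roughly 2 h) scaled to 150 reporter units at normalized peak
1 (below the 200-unit cap, so traces span the reporter's range the way
imaging data do); per-cell reporter expression log-normal around 60 MFI
with log-SD 0.8, putting a few percent of cells outside the 10–200
bounds to exercise the filters; and a logistic commitment layer
(threshold 0.6 normalized units, slope 20, onset in the 8–24 h band)
standing in for the downstream mitochondrial machinery. A
multiplicative threshold modifier emulates anti-apoptotic
over-expression (raising the threshold) or BH3 mimetics (lowering it),
and per-component priming fold-changes emulate HDAC-inhibitor priming.
All generators are pure functions of configuration and seed.

What passing tests show — and what they do not: the generator emulates
the *statistical structure* of the measurements (log-normal abundance
noise, reporter kinetics, delayed stochastic commitment, QC-relevant
expression outliers). It does not emulate segmentation artifacts,
tracking errors, photobleaching, reporter-independent ratio drift, or
any correlation between reporter expression level and measurement
fidelity. Parameter-recovery results on synthetic data therefore
validate the pipeline's internal consistency, not its robustness to
those real-data pathologies.

## Numerical choices

* Integration: `deSolve::lsoda` on a compiled-C right-hand side,
  relative tolerance 1e-8, absolute 1e-10 (configurable). Mass
  conservation per protein holds to better than 1e-6 relative along
  every trajectory (tested on random ensembles).
* Pre-stimulus steady state: long integration at the basal input until
  the maximum derivative falls below 1e-9 of the largest pool per
  minute.
* Oracle: an independent R implementation of the right-hand side under
  classic fixed-step RK4 (step 0.01 min) agrees with the adaptive
  compiled path to better than 1e-3 relative — two implementations,
  two integrators.
* Reporter inversion: bracketed root finding, tolerance 1e-9;
  forward/inverse round trips hold to 1e-6 below the cap.
* Ties and boundaries: a cell exactly at the mean basal peak counts as
  impaired ("unable to activate *above* the mean"); peak and onset ties
  at equal sample times resolve to the earliest time; QC boundary MFIs
  (10, 200) are retained; caspase exactly at 50 never fires.
* Per-cell solver failures are flagged and tolerated up to 1% of an
  ensemble, then the run aborts.
* Problem sizes: module tests run ensembles of 20–400 cells and the
  acceptance-level checks use the full n = 2000 study condition; the
  whole suite completes in about a minute on one core.

## Known limitations

* The rate constants are this package's own calibration; they
  reproduce the study's emergent single-cell statistics but are not
  claimed to match any previously fitted parameter set, and the
  ignition stimulus of the nominal cell (and hence the half-maximum
  Hill estimate discussed above) is a consequence of that calibration.
* Phospho-Akt is held constant over each simulation; whether it should
  deplete after stimulation is unreported.
* The commitment layer is generator-side phenomenology; no mechanistic
  MCL-1/BCL-2/BIM species are modeled.
* The "mean basal activation" threshold uses the whole-population mean
  (the natural reading); a same-cell definition would be a different
  statistic.
* Whether pooled outcome grouping should use raw ratios or converted
  activities is unreported; both are supported (`peakWindowActivities`
  with or without reporter parameters) and the pipeline logs which was
  used.
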