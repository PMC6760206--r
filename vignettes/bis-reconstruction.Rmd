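---
title: "Reconstructing the Bispectral Index from its subparameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the Bispectral Index from its subparameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisre)
```

## The problem

The Bispectral Index (BIS) is the most widely used EEG-derived measure of
anaesthetic depth: a unitless 0–98 scale where values near 40–60 indicate
adequate general anaesthesia. The algorithm that turns raw
electroencephalography into that number is proprietary. What is public is
the set of *subparameters* the monitor computes on the way: the burst
suppression ratio (BSR, % of the trailing minute below 5 µV), the 95%
spectral edge frequency (SEF, Hz), electromyographic power (EMG, dB in
70–110 Hz), the relative beta ratio
(RBR = log10 P[30–47 Hz]/P[11–20 Hz]) and the bispectral SyncFastSlow
(SFS = log10 B[0.5–47 Hz]/B[40–47 Hz]).

`bisre` implements a data-driven reconstruction of the index from these
subparameters:

1. a **range classifier** — a four-node decision tree that assigns one of
   five BIS ranges (0–21 isoelectric, 21–41 profound, 41–61 adequate,
   61–78 sedation, 78–98 awake) from BSR, EMG, SEF and RBR;
2. a **per-range multiple linear regression** that produces the BIS value,
   clipped globally to [0, 98] but *not* forced into the assigned range
   (real predictions stray across range boundaries, and so do ours);
3. the **discovery pipeline** that estimates both from per-second monitor
   tracks: histogram boundary detection, class-balanced sampling, a
   10-tree CART ensemble consolidated by a structure vote, and RANSAC
   robust regressions;
4. the **feature layer** that computes the subparameters from raw EEG; and
5. a **synthetic-data generator** that emulates per-second anaesthesia
   cases and raw EEG, so all of the above is testable without clinical
   recordings.

## The estimator

The classifier evaluates, in order:

| node | condition | outcome |
|------|-----------|---------|
| 1 | BSR > 49.8% | range 0–21 |
| 2 | EMG < 34.2 dB **and** SEF < 20.2 Hz | node 3, else node 4 |
| 3 | BSR > 2.1% **or** SEF < 14.8 Hz | range 21–41, else 41–61 |
| 4 | RBR < −0.7 | range 61–78, else 78–98 |

Comparisons are strict as written; equality falls to the else branch. SFS
is not a classifier. Each range then applies its own regression over all
four subparameters; in the isoelectric range the model is essentially
`BIS = 42.1 − 0.42·BSR`, so a fully suppressed EEG (BSR 100) maps to ≈0.

```{r}
default_bis_model()
```

## Feature extraction

The chain mirrors the monitor's default smoothing: Savitzky–Golay
detrending; 2-s epochs with 75% overlap (57 epochs from the trailing 30 s
for spectral parameters, 27 from the trailing 15 s for the bispectrum);
Blackman window and FFT; epoch-averaged periodogram and bispectrum
`B(f1,f2) = |mean X(f1)X(f2)X*(f1+f2)|` on the principal domain. BSR uses
0.5-s subepochs of the trailing 60 s with the 5 µV amplitude criterion.

Numerical conventions that every ratio depends on:

* **Band edges are inclusive** on the 0.5 Hz grid: 30–47 Hz spans 35 bins,
  11–20 Hz spans 19, so a flat spectrum has RBR = log10(35/19) ≈ 0.265.
* **Bispectral band values** sum |B| over principal-domain pairs with
  `low ≤ f1+f2 ≤ high`.
* The periodogram is normalised by the window power so unit-variance white
  noise has flat expected density.
* Savitzky–Golay parameters are unstated in the source material; we default
  to a 0.5 s window (nearest odd sample count) and order 2, which removes
  drift below the 0.5 Hz analysis floor without touching the delta band.
* The EMG dB reference (0.0001 µV²) is configurable because the monitor's
  reference is undisclosed; the default places intraoperative values in
  the 25–45 dB region where the 34.2 dB threshold lives.
* SFS orientation: the broad-over-fast ratio is the default; `invert =
  TRUE` gives the opposite convention, which also circulates. Our default
  makes SFS *rise* with deepening anaesthesia.
* EMG genuinely requires ≥ 220 Hz sampling (the 70–110 Hz band must lie
  below Nyquist). A 128 Hz export cannot carry it; `extract_subparameters`
  then emits `NA` EMG with one warning, and `compute_emg` raises a
  capability error rather than silently aliasing.

SQI is never computed (its formula is proprietary); it is carried through
from input and used only as the `> 90%` inclusion filter.

## What the generator emulates — and what it does not

`generate_case()` inverts the estimator: a phase plan prescribes
subparameter means over a ~70 min course (awake, sedation with and without
EMG activity, adequate and profound anaesthesia, burst suppression,
emergence), first-order smoothing (time constant 10 s) joins the phases
continuously, Gaussian jitter is added per subparameter, and the observed
BIS is the model prediction plus Gaussian residual noise (sd 1), a 2%
fraction of +10 outliers standing in for smoothing-delay discrepancies,
and clipping to [0, 98].

Defaults were fixed by two principles. First, *model consistency*: each
phase's mean vector was chosen (by evaluating the published regressions)
so that its predicted BIS lies inside the range its subparameters classify
into — a consistency real monitor data has by construction, because the
monitor computed both sides. Second, *identifiability of the thresholds
the pipeline is meant to recover*: several phases straddle a decision
threshold (BSR 49.8 is approached from dense masses at 46 and 54.5, EMG
straddles 34.2 at SEF 19.5, SEF straddles 14.8, RBR straddles −0.7 at high
SEF and low EMG where both regressions keep BIS clear of the 78 label
boundary), while other phases deliberately *overlap* in single features —
profound/adequate cases share the SEF 15–18 band, and some adequate cases
carry RBR above −0.7 — because without that overlap a single ordinal SEF
or RBR cut separates the depth scale too cleanly and the learned root
moves away from BSR. Jitter is sd 1.0 for BSR/SEF/EMG and sd 0.1 for the
log10-scale RBR/SFS.

Known mismatches with real data: no pharmacokinetics (phases are
descriptive), no serial correlation in the jitter beyond the 10 s
smoothing, Gaussian residuals (the true residual law around the monitor's
smoothed output is unknown), no artifact structure other than the
injected EMG phases and BIS outliers, and an SQI that is effectively
always > 90 unless low-quality samples are requested explicitly. Passing
recovery tests on these data therefore demonstrates correctness of the
*pipeline*, not clinical performance.

`synthesize_eeg()` builds band-limited Gaussian noise in the frequency
domain and rescales each band so the realised power equals the request
exactly, then attenuates suppression intervals below the 5 µV criterion;
the default 256 Hz rate exists so the EMG band is representable.

## The discovery pipeline

**Boundaries.** If the index switches regression equations at fixed BIS
values, the pooled histogram shows abrupt frequency changes there.
`detect_boundaries()` flags value *b* when |Δ log count| between *b* and
*b*+1 exceeds `sensitivity` (default 4) times the robust spread of all
the differences — the median absolute deviation scaled by 1.4826 so that
the default sits at roughly four sigmas of within-range count noise.
Counts are offset by 0.5 before logging; adjacent detections merge to the
larger jump so boundary pile-up bins cannot double-fire. The 21 boundary
is barely populated in intraoperative data and is appended as known
(`finalize_boundaries()`). Whether the original identification was visual
or algorithmic is unstated; here it is algorithmic and tunable.

**Balanced sampling.** Intraoperative BIS concentrates at 40–60, so
trees are trained on balanced draws: quota `floor(total/k)` per
represented integer BIS value, remainder to the lowest values (100,000
over 99 values gives counts 1010–1011), without replacement where the
pool allows, with replacement otherwise (recorded). Whether the source
analysis drew with or without replacement is unstated.

**Trees.** Each of 10 fits sees a fresh balanced dataset. CART uses the
entropy ("information") criterion — our reading of "information gain",
with Gini available — a depth cap of 5, and the rule that a node holding
fewer than 10% of samples is not split further. We read the published
stopping rule as a minimum-size-to-*split* rule rather than a minimum
leaf size: with a balanced five-class dataset (largest class ≈22%) a 10%
*leaf* floor makes the five-level univariate expansion of the published
tree infeasible, because the sedation/awake subtree appears under both
the EMG and the SEF guard. A complexity floor (`cp`, default 0.01) keeps
the fit from chasing label noise inside otherwise pure leaves. The fit
itself is delegated to `rpart`; an exhaustive entropy-split search acts
as the independent oracle in the test suite.

**Consolidation.** A majority vote on the threshold-independent structure
signature selects the modal tree shape (ties to first occurrence,
recorded), and each node threshold becomes the median across the modal
trees. `to_treespec()` then reduces the univariate tree to the published
compound-node template: one EMG and one SEF guard in either order merge
into the AND of node 2; the lower BSR/SEF pair merges into the OR of
node 3; when both guard branches carry an RBR split the fourth-node
threshold is their median, and a guard branch that the stopping rules
left as a single sedation/awake leaf is accepted. Anything else raises a
structural-mismatch error carrying the raw tree.

Two recovered quantities deserve honesty notes. The third-node BSR
threshold (2.1%) is only weakly identified under these study conditions:
below ~41 BIS the generator's suppressed cases live either well below or
well above that threshold, so the learned cut floats in the data gap and
is reported as-is. And on the low-SEF/high-EMG guard branch the model's
own geometry places the sedation/awake label flip near RBR ≈ 0 rather
than −0.7 (with SEF < 20.2 the awake regression only exceeds 78 at high
RBR), which is why that branch ends in a leaf under the 10% rule rather
than contributing a second, structurally different RBR threshold.

**Regressions.** Data are partitioned by the *tree's* range (the
estimator applies a regression after the tree has chosen; partitioning by
observed BIS is available as an option), and each range is fitted by
RANSAC: 1000-row random subsets, 100 iterations, inliers within 5 BIS
units of the subset fit over the whole partition, best iteration by
inlier count (ties by median absolute inlier residual), final
least-squares refit on the consensus set — which makes the refit
idempotent. All four subparameters enter every range. The per-iteration
estimator and final refit are unstated in the source; subset least
squares with an inlier refit is the canonical formulation. Its limit is
worth knowing: with ~30% gross contamination every 1000-row subset is
contaminated and the consensus truncation biases the refit (still several
times better than plain least squares, but not immune); at the 10%
contamination of the acceptance experiments recovery is exact to within a
few hundredths.

**Validation.** Node accuracies binarise truth and prediction at each
boundary and are computed on the samples reaching that node along the
predicted path (the conditional population a per-node display implies);
leaf PPVs are per predicted range; regression quality is the per-range
median error and median absolute error; the 99×99 observed-by-predicted
count matrix supports heat-map plots. Overall accuracy and PPV are
reported both sample-weighted and macro-averaged since the aggregation
rule is unstated.

`run_pipeline()` chains the stages with per-stage seeds derived from one
master seed, a case-level 80/20 split (never by sample), the SQI > 90 and
> 30 min filters, and artifact output (model JSON, coefficient CSV,
validation report). Boundary detection always runs and its result is
persisted, but labelling uses the configured boundary set — by default
the known 21/41/61/78 — because on per-second case data the histogram
discontinuities are a weaker signal than on the pooled-count emulator.

## Problem sizes and runtime

The recovery experiments run at deliberately desk-friendly sizes: pools
of 60–80 synthetic cases (≈250,000–330,000 per-second samples), balanced
datasets of 100,000 per tree fit, 10 trees per ensemble, five master
seeds for the reported medians, and 5,000-sample RANSAC experiments.
Under those conditions the consolidated thresholds land within a few
hundredths of 49.8 / 34.2 / 14.8 / −0.7 and the isoelectric regression
recovers 42.1 − 0.42·BSR to the stated tolerances; the whole experiment
takes well under a minute per master seed on one core.

## Limitations

* The generator inherits the published model's blind spots: the QUAZI
  suppression index is undisclosed and absent, which is the likely reason
  the profound-anaesthesia range is the weakest part of the published
  model; nothing here can recover what the data never encode.
* Temporal smoothing of the displayed BIS is not modelled; on real
  monitors it produces transient disagreement during fast state changes.
* The feature layer processes a single channel and performs no artifact
  rejection beyond the SQI filter, mirroring the source analysis.
* Agreement between the estimator and a real monitor is a property of the
  published coefficients, not of this implementation; this package makes
  no clinical claims.
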