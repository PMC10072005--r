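---
title: "Resting-state fNIRS motor-network analysis: models, parameters and design choices"
author: "motornet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state fNIRS motor-network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

After a stroke, the functional organization of the motor cortex
reorganizes, and the degree of that reorganization tracks the severity of
motor impairment. `motornet` implements a complete analysis chain for
quantifying this with resting-state functional near-infrared spectroscopy
(fNIRS): multichannel ΔHbO₂ time series are turned into functional
connectivity networks, the networks are summarized by small-world graph
metrics, and the metrics serve both as the dependent variables of
covariate-adjusted group statistics and as features for classifying the
degree of dyskinesia (Healthy, mild, moderate-to-severe) at the
individual level. A seeded synthetic-cohort generator provides data with
known ground truth so every stage is testable without patient recordings,
which are not publicly deposited for this kind of study.

## Pipeline and models

**Preprocessing** (per recording, channels × samples at 10 Hz):

1. *Motion-artifact detection*: a sample is flagged when the excursion
   (max − min) of a centred 1-s moving window exceeds `k = 5` times the
   channel's robust SD (scaled median absolute deviation); flags are
   dilated by half a window and merged into segments. The parameters are
   exposed (`preprocessParams()`) because instrument-specific values are
   never published; the defaults detect the large transient spikes typical
   of head motion while flagging essentially nothing on clean band-limited
   hemodynamics. On broadband white noise this excursion statistic flags a
   few percent of samples by construction (the range of ten standard
   normals exceeds 5σ about 1.5% of the time), which is why the detector
   is specified and tested on in-band signal.
2. *Spline correction*: inside each flagged segment a cubic smoothing
   spline is fitted and subtracted (removing the artifact's trajectory),
   and the residual is re-anchored to a linear ramp between the clean
   signal levels flanking the segment. `smooth = 0.99` maps to a
   low-smoothness spline that follows the artifact closely; segments
   shorter than four samples fall back to the ramp alone.
3. *Band-pass*: a Butterworth design of order 2 with pass band
   0.01–0.1 Hz, applied forward–backward (zero phase). Zero-phase
   filtering avoids phase distortion that would bias between-channel
   correlations; the effective magnitude response is the squared design
   response, which we treat as the intended reading of a "second-order
   band-pass" since connectivity work standardly uses `filtfilt`.
4. *Common average reference* (CAR): the cross-channel mean is subtracted
   at every sample, suppressing globally shared superficial (scalp)
   signal exactly.
5. *Edge trimming*: the first and last 5 s are dropped, so a 6-min
   recording yields 3500 analyzed samples (350 s). If the residual
   artifact fraction after correction exceeds 5%, the pipeline falls back
   to the cleanest contiguous window that still yields 180 s of analyzed
   signal — a formalization of the common practice of analyzing a shorter
   clean stretch when a recording is badly corrupted; the threshold is a
   package choice, exposed in `preprocessParams()`.

**Connectivity**: Pearson correlations between all channel pairs, Fisher
Z transformed (`atanh`, with |r| clipped at 1−10⁻⁷), diagonal set to 0.
Networks are binarized by *proportional thresholding*: at threshold *t*
the `round((1−t)·n(n−1)/2)` pairs with the largest |z| receive an edge.
This guarantees equal edge counts across subjects at each threshold, so
group differences reflect topology rather than overall correlation
strength. The sweep runs t = 0.30…0.70 in steps of 0.01 (41 networks);
ties at the cut are broken by ascending (row, column) index, making
sweeps deterministic and edge sets nested along the grid. Negative
correlations enter by absolute value.

**Small-world metrics** per binary network with *m* nodes:

- clustering coefficient C = mean over nodes of 2eᵢ/(Kᵢ(Kᵢ−1)), with
  Cᵢ := 0 for degree < 2 (the formula is 0/0 there);
- characteristic path length L = mean shortest-path length over ordered
  *reachable* pairs. On fragmented graphs (possible at sparse thresholds)
  unreachable pairs are excluded and the reachable fraction is reported —
  this keeps L finite across the sweep, matching how threshold-sweep
  curves are conventionally plotted;
- global efficiency GE = mean of 1/d over ordered pairs with 1/∞ := 0,
  so fragmentation lowers GE continuously;
- local efficiency LE = mean over nodes of the global efficiency of the
  subgraph induced by each node's neighbours (0 below two neighbours).
  We use the per-node mean (1/m); a printed 1/(m(m−1)) prefactor
  sometimes seen for this quantity is dimensionally inconsistent with a
  sum of m terms and disagrees with the Brain Connectivity Toolbox
  convention we follow;
- transitivity T = 3·(triangles)/(connected triples), 0 without triples;
- normalized ratios γ = C/C_rand, λ = L/L_rand and small-worldness
  δ = γ/λ, where C_rand and L_rand are means over 100 (configurable)
  degree-preserving Maslov–Sneppen randomizations (double-edge swaps, 10
  attempted swaps per edge, rejection of self-loops and multi-edges).
  A small-world network shows γ > 1, λ ≈ 1, δ > 1.

Each metric's 41-point curve is integrated by the trapezoid rule into a
threshold-independent AUC scalar; the eight AUCs are the subject's
feature vector.

**Group statistics**: each AUC feature is tested by ANCOVA
(`feature ~ group + age + gender`; partial F for the group term), because
age and gender are imbalanced across groups in the study design this
pipeline serves. Pairwise contrasts use covariate-adjusted group means
with the pooled model error and no further adjustment (Fisher's LSD
convention: the omnibus test is the gate). Per-threshold group tests use
the same model with Benjamini–Hochberg FDR across the 41 thresholds of
each metric (the family is per metric; pooling the 8×41 tests into one
family would mix quantities with different meanings). Partial
correlations between patients' FMA scores and each AUC control age and
gender linearly; p-values use a t reference with n − 2 − k degrees of
freedom.

**Classification**: one-versus-rest linear SVMs inside nested
cross-validation. The outer loop is leave-one-out; inside each outer
training fold the features are standardized, optionally re-ranked by
recursive feature elimination (RFE: iteratively dropping the feature with
the smallest aggregate |w| across the three class machines), and the SVM
cost is chosen by stratified 10-fold grid search (10⁻²…10², log-spaced) —
all strictly on the training subjects, so nothing about the held-out
subject leaks into scaling, selection or tuning. The linear kernel is
mandated because per-feature weights are part of the scientific readout,
and only a linear machine provides them. Besides the honest per-fold RFE,
a single full-data RFE ranking (with |w|-based importance normalized to
sum 1) is reported for interpretation, clearly labelled as such; a sweep
over retained-feature counts (`featureCountSweep`) reproduces the common
"best first k features" selection curve. Pooled held-out predictions give
the confusion matrix, accuracy, per-class sensitivity/specificity and
one-versus-rest ROC curves (tie-aware, trapezoidal area).

## The synthetic cohort generator

The generator is a first-class, tested module. Each subject's latent
motor network is a weighted channel-pair matrix built from four
physiological layers (`latentWeightMatrix`):

- **hierarchical modularity** — five modules standing for motor
  subregions; within-module weights are strong, between-module weights
  weak and decaying with module distance. The single group knob *p*
  (`group_rewiring`: Healthy 0.65 > Mild 0.45 > MtS 0.15) interpolates
  the within/between contrast from segregated (low *p*, the
  moderate-to-severe profile: the motor network shifted toward a regular,
  locally clustered topology) to integrated (high *p*), and additionally
  shuffles a fraction *p*/2 of pair weights across the matrix;
- **a spatial gradient** — neighbouring optode channels share cortex and
  scalp, so weight decays with channel distance (0.15·0.7^(d−1));
- **hemispheric structure** — two 11-channel strips; cross-hemisphere
  pairs are attenuated (×(0.15 + 0.55p)), homologous pairs less so
  (×(0.55 + 0.55p)), and same-hemisphere pairs get a baseline boost
  (+0.2). The *group dependence* of the interhemispheric factors mirrors
  the well-documented post-stroke disruption of interhemispheric and
  homotopic resting-state connectivity, and is what carries the global
  efficiency (integration) group effect;
- **pair jitter** (SD 0.03) for subject individuality.

The weight matrix is mapped to a positive-definite covariance by diagonal
loading (`networkToCovariance`; for a binary adjacency the same function
implements the simple contract "connected pairs get covariance
`edge_strength`"). Correlated Gaussian samples are drawn, band-pass
filtered into 0.01–0.1 Hz (one common filter preserves the cross-channel
correlation structure), a shared band-limited superficial component is
added (`global_amplitude`, removable exactly by CAR), the series is
scaled to a realistic fluctuation size (median channel SD 0.02 mM·mm),
and transient motion spikes are injected at 0.5 events/min with 8-SD
peaks. The binary ground-truth network stored per subject is the
strongest-`latent_density` (20%) fraction of the latent weights, so the
latent clustering ordering MtS > Mild > Healthy is directly assertable.

FMA scores are drawn uniformly inside each group's clinical range (Mild
85–99, MtS 15–84, cutoff 85), and the subject's *p* is shifted
within-group by the normalized FMA (`fma_coupling = 0.06`), so that the
negative correlation of clustering-type metrics (and positive correlation
of global efficiency) with FMA is recoverable from patients — not only
the group ordering. Ages and genders follow the per-group distributions
of the study population this pipeline is designed around (Healthy younger
than patients), which deliberately reproduces the age–group confound the
ANCOVA must handle.

Defaults were fixed once, at design time, to reproduce the qualitative
pattern (orderings, correlation signs, significance) at realistic effect
sizes — no subject-level variability figures exist to calibrate effect
sizes against. Design iterations that led here are worth recording
because two "obvious" simpler models fail structurally:

- a *uniform-strength binary* latent network (lattice-style) loses almost
  all contrast: the positive-definiteness loading of a dense binary
  covariance crushes edge correlations, and at 30–70% proportional
  density the clustering difference between a lattice and a random graph
  of equal density is second order;
- a *positive ring/distance kernel* is inverted by the pipeline's own CAR
  step: re-centering makes distant pairs negative, absolute-value
  thresholding then admits them as edges, and the clustering ordering
  flips sign. The modular + hemispheric construction is robust to CAR
  because its structure lives in contrasts that survive re-centering.

What the generator does **not** emulate: hemodynamic response shapes,
cardiac/respiratory harmonics above the analysis band (they would be
filtered out), optode-geometry and head-model physics, Hb/HbO₂ coupling,
baseline drifts and step artifacts (spikes only), dynamic (time-varying)
connectivity, and lesion-site heterogeneity. Passing tests therefore
demonstrate that the pipeline recovers the planted network physiology
under realistic noise — not that it would be robust to every artifact
class of real hardware.

## Numerical choices and degenerate inputs

- Proportional-threshold ties: deterministic (row, column) tie-break;
  edge counts use `round()` of the retained fraction.
- Fisher Z: |r| clipped at 1−10⁻⁷ keeps z finite for duplicated channels.
- Constant channels correlate 0 with everything (warning, not an error).
- Fragmented graphs: L over reachable pairs (fraction reported), 1/∞ = 0
  in GE; a graph with no reachable pair has L = NA with a warning.
- Maslov–Sneppen: R's RNG drives the C++ swap loop, so `set.seed` (or
  the `seed` arguments) makes every ensemble exactly reproducible;
  ensembles use sub-seeds derived by `deriveSeed`, so adding subjects or
  thresholds never shifts other streams.
- PD loading: the covariance diagonal is inflated until the smallest
  eigenvalue is positive; implied correlations shrink accordingly (the
  2-node worked case needs no loading and keeps correlation =
  `edge_strength` exactly).
- The inner-CV cost grid breaks ties toward the smallest cost; inner
  folds are stratified by class and seeded.
- Zero-variance features are centred but not scaled (warning).

## Known limitations

- With 22 nodes and 30–70% retained density, γ at the dense end of the
  sweep is intrinsically pinned near 1 (a degree-preserving ensemble of a
  70%-dense graph has little freedom), so the dense-end group-mean γ
  exceeds 1 only by a small margin; the hemispheric block structure is
  what keeps it positive.
- Global efficiency is the noise-limited feature: proportional
  thresholding fixes the edge count, so GE differences ride only on
  path-length structure and its group effect is the weakest — mirroring
  the fact that integration effects in this design are subtler than
  segregation effects.
- The ANCOVA inherits the age–group confound of the study design;
  adjusted group effects are conservative where age carries part of the
  group signal.
- Whether RFE belongs inside or outside the outer CV is genuinely
  ambiguous when a single global weight list is the published readout;
  both modes are provided (`rfeInFold`) rather than guessing.

## Problem sizes used by the test suite

The packaged tests exercise the full study geometry: 42 subjects
(11/15/16), 22 channels, 350 s analyzed at 10 Hz, the 41-threshold sweep,
and a reduced 20-reference randomization ensemble (the full 100-reference
ensemble is used by `scripts/acceptance.R`); the brute-force oracle suite
covers every connected graph on up to 6 nodes plus 200 random 7-node
graphs; multi-seed recovery checks use 10 cohort seeds, and the
classification check pools held-out predictions over three cohort seeds
(n = 126) because a single 42-subject cohort is underpowered against the
3-class chance level. These sizes keep
the default suite comfortably within a coffee break on one CPU while
preserving the study-scale conditions.
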