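---
title: "Methods: connectivity, graph efficiency and hub disruption in a language-and-memory network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity, graph efficiency and hub disruption in a language-and-memory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lmnet` implements a resting-state functional-connectivity (FC) analysis
over a 72-node language-and-memory network (LMN): 36 homotopic region
pairs spanning frontal, temporal, parietal and limbic cortex, as studied
in mesial temporal lobe epilepsy (mTLE), where seizures arising from one
hippocampal complex reorganize both language and memory circuits. The
pipeline runs from ROI time series to group-level statistics; it never
touches imaging volumes (voxel-level preprocessing, segmentation and
atlas construction are out of scope).

## The model and the pipeline

Each subject contributes a T x N BOLD matrix (default T = 400 volumes at
a 2 s sampling interval, N = 72 regions), six rigid-body motion
parameters and noise-compartment signals (white matter / CSF analogues).
The stages are:

1. **Outlier scans.** Volume *t* is flagged when any interscan
   translation exceeds 2 mm, any rotation exceeds 0.02 rad, or the
   interscan global-signal change exceeds 3 SD of that subject's
   interscan changes. Subjects with strictly more than 12.5% flagged
   volumes are excluded. The global signal here is the mean over ROI
   channels (the image-wide version would require voxel data). Whether
   the 12.5% rule counts per-criterion or composite outliers is an open
   choice; the union mask is used.
2. **Confound regression.** Per ROI channel, OLS residuals on an
   intercept, the six motion parameters, the top 5 principal components
   of the noise-compartment channels (component-based noise correction;
   the component count is not dictated by the analysis it reproduces and
   is exposed as a parameter), and one indicator per flagged volume
   (scrubbing). Collinear columns are dropped with a message. Residuals
   are exactly orthogonal to every retained regressor.
3. **Band-pass 0.008-0.09 Hz.** Discrete-Fourier masking with hard
   cutoffs: zero-phase by construction, bin-aligned passband tones are
   preserved exactly and stopband tones annihilated. The continuous
   confounds (motion, noise components) are band-limited to the same
   band *before* regression; this makes regression and filtering
   commute, so re-running the pipeline on its own output is a numerical
   no-op for subjects with no flagged volumes. The order
   (regress, then filter) is itself a convention; both orders give the
   same result under band-limited confounds.
4. **Connectivity.** Pearson correlation for every region pair, Fisher
   z = arctanh(r) for group statistics. Group tests operate on z rather
   than raw r (the variance-stabilized scale; the source analysis does
   not state which was used).
5. **Edge-wise group statistics.** Welch two-sample t per edge (k =
   2556 edges for N = 72), two-sided, with two correction regimes
   reported side by side: Bonferroni family-wise error (reject when
   p < alpha / k) and Benjamini-Hochberg FDR.
6. **Graph metrics.** Each subject's weighted z-matrix is binarized at
   proportional costs 5-20% (signed ranking, most-positive first; ties
   at the cut broken lexicographically so results are deterministic).
   On the binary graph with hop distances d_ij (infinite when
   disconnected, contributing 0 through 1/d):
   - global efficiency `E_glob = mean over ordered pairs of 1/d_ij`,
   - nodal efficiency `E_nod(i) = mean over j != i of 1/d_ij`,
   - local efficiency `E_loc(i)` = global efficiency of the subgraph
     induced by the neighbours of *i* (nodes with < 2 neighbours
     contribute 0); the network value is the mean over nodes.
   The algebraic identity `mean_i E_nod(i) = E_glob` holds exactly and
   is asserted on every computed graph. A small-world index
   sigma = (C/C_null)/(L/L_null) against degree-preserving rewired
   nulls checks that the cost window sits in the small-world regime.
7. **Nodal z-scores.** Patient values standardized against the control
   mean and SD per node and cost; group differences per node by Welch t
   with BH correction across the 72 nodes (the adjustment method is not
   named in the source; BH is the package default and configurable),
   plus a cross-cost sign-stability flag.
8. **Hub disruption index (HDI, kappa).** Per subject, OLS of
   (subject - reference) against the reference across nodes, where the
   reference is the control-mean nodal-efficiency profile (leave-one-out
   for control subjects, avoiding self-inclusion bias). kappa = 0 means
   the subject tracks the control hub hierarchy; kappa < 0 means
   high-efficiency hubs lost efficiency while peripheral nodes gained
   it. The HDI is computed on nodal efficiency: a regression across
   nodes needs a nodal quantity, so the occasional description of the
   index "based on the network-level metric" is read as its nodal
   decomposition. Group-level tests: one-sample t of patient kappa
   against 0, Welch patients vs controls, and left- vs right-focus
   patients. The headline cost is 5%, with all costs computed, since
   the significance statement and the figure annotation disagree on
   whether 5% or 10% carried the printed result.
9. **Cognition.** Mann-Whitney U (midrank ties; the statistic reported
   is the pair-count for the first sample, with U1 + U2 = n1*n2 as an
   internal check), paired t for within-group volume asymmetry,
   standardized-index conversion z = (index - 100)/15, and Spearman
   correlations between nodal metrics and scores with Bonferroni
   family-wise correction over the pairs tested.

## The synthetic cohort generator

No public data accompany the analysis this package implements, so the
generator is a first-class module: it emulates the statistical structure
the pipeline assumes, and every calibration-style test is run against
its planted truth.

- **Baseline covariance.** Lobe-block structure with strong homotopic
  inflation (base 0.05, within-lobe 0.25, homotopic 0.55), scaled by a
  multiplicative hub-strength gradient (pair-level factors 0.5-1.5) and
  projected to the nearest positive-definite correlation matrix
  (eigenvalue clipping at 1e-4, then unit-diagonal rescaling). The
  gradient matters: without node heterogeneity in expected nodal
  efficiency the network has no hubs, and the HDI regression degenerates
  into pure reference-noise attenuation (everyone's kappa is biased
  negative regardless of disease status). Because no quantitative
  control-group connectivity values are available, the template is a
  design parameter, configurable, not a calibration target.
- **Planted group effects.** Patient groups add `delta_limbic` (default
  0.2 correlation units) to every within-limbic edge and subtract
  `delta_remote` (0.08) from remote-cortical edges, then re-project to a
  correlation matrix. Each patient draws an individual effect multiplier
  from uniform(0.2, 1.8). Both choices are calibrated against printed
  study quantities, not against test thresholds: the wide multiplier
  range reproduces the dysfunctional-hippocampus volume spread of the
  per-patient table (SD 0.74-0.84 cm^3), and delta 0.2 puts the
  simulated volume-to-nodal-efficiency correlation near the reported
  magnitude (around -0.5 to -0.8 at T = 400 and 5% cost).
- **Contaminants.** Slow sinusoidal drifts below 0.008 Hz, leakage of
  the noise-compartment channels into ROI signals, white observation
  noise, and artifact events at `spike_rate`: a transient single-volume
  intensity offset of 5 channel-SD with balanced random signs per
  channel (so the global signal is untouched and the scrubbing regressor
  absorbs it exactly) plus a matched persistent 3 mm / 0.03 rad motion
  step, so the interscan rules flag exactly the event volume. A
  persistent global step was rejected: it survives scrubbing and
  band-pass and inflates between-subject connectivity variance roughly
  threefold.
- **Volumes and scores.** The focus-side hippocampal volume is
  `4.3 + volume_effect * scale * delta_limbic + noise` cm^3 with
  `volume_effect = -6`, so stronger planted limbic connectivity goes
  with a smaller hippocampus (the hyperconnected-yet-atrophied pattern).
  Scores are per-group linear functions of planted strength plus noise,
  standardized across the cohort; signs differ by group (negative
  metric-score coupling in left-focus, positive in right-focus
  patients).

What the generator does **not** emulate: hemodynamic response shapes,
spatial autocorrelation or geometry, non-Gaussian BOLD marginals,
physiological rhythms (cardiac/respiratory aliasing), scanner-specific
noise spectra, and any real anatomical difference between groups beyond
the planted covariance and volume effects. Passing tests therefore
demonstrate that the pipeline recovers the planted statistical structure
under realistic noise — not that it would recover the same structure
from real scanner data.

## Numerical choices and degenerate inputs

- Fisher z clips |r| = 1 to 1 - 1e-7 with a warning; constant channels
  are an error naming the offending node.
- Edges with zero variance in both groups are flagged degenerate and
  excluded from the multiple-testing count.
- Proportional thresholding rounds the edge count to the nearest
  integer and breaks ties lexicographically; signed (not absolute)
  ranking is the default, configurable in spirit by passing transformed
  weights.
- 1/infinity = 0 for disconnected pairs; the characteristic path length
  for the small-world index uses the largest connected component.
- The subject-exclusion rule is strict (a subject at exactly 12.5%
  outliers is retained).
- The 3-SD global-signal rule false-flags about 0.27% of clean volumes
  (the Gaussian tail); this is a property of the rule, not a bug, and
  the tests account for it.
- Welch-Satterthwaite degrees of freedom are computed per edge
  vectorised; equal-n equal-variance inputs reproduce the pooled t
  exactly.

## Problem sizes used by the tests

The packaged checks scale the cohort down so the whole suite runs on a
laptop: oracle comparisons use random graphs up to N = 12 plus an
exhaustive nested threshold sweep at N <= 8; HDI null calibration uses
12 cohorts of 20 controls + 8 null patients at T = 400; HDI recovery
uses 50 cohorts of 16 controls + 16 patients; type-I calibration uses
500 global-null replicates at N = 10 nodes; correlation-sign recovery
uses 50 cohorts with the study's left-focus group size (n = 19). The
per-patient clinical table is packaged in full and its statistics are
recomputed exactly.

## Known limitations

- The binarized-graph metrics inherit the usual proportional-cost
  caveats: at 5% cost graphs can fragment, and nodal efficiencies are
  then dominated by component membership.
- The HDI against a finite control sample carries a small negative bias
  of order var(reference noise)/var(true profile); it shrinks with the
  number of controls and with hub heterogeneity, and the leave-one-out
  reference keeps control and patient kappas comparable.
- Local efficiency at 72 nodes is noisy (neighbour subgraphs are
  small); the same instability is the reason the source analysis found
  few stable local-efficiency effects.
- Spearman p-values use the t approximation (midrank ties), not the
  exact permutation null; at n = 19 the difference is negligible
  relative to the family-wise correction.
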