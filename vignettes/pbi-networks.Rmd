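---
title: "Paired biomarker scoring and ratio networks: model and design notes"
author: "pbinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired biomarker scoring and ratio networks: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbinet)
```

## The problem

Longitudinal (paired) metabolomics studies — the same subjects measured
at a baseline and at one or more follow-up timepoints, for example an
incremental bicycle stress test with capillary blood sampled at rest
(`t0`) and at the individual maximum workload (`tmax`) — call for
feature-ranking statistics that respect the pairing. `pbinet`
implements a two-step discovery strategy for such data:

1. **Prioritization.** Each metabolite is scored with the *paired
   Biomarker Identifier* (pBI), a signed measure of how consistently
   and how strongly the analyte changes within subjects between the two
   timepoints, and binned into weak / moderate / strong predictor
   classes.
2. **Network inference.** Every metabolite *pair* is scored the same
   way through the time course of its concentration ratio, and pairs
   whose score magnitude exceeds a threshold τ become edges of an
   undirected interaction network. Per-timepoint ("kinetic") networks
   trace how the interaction structure develops over the time course,
   and high-degree vertices (hubs) corroborate the step-1 ranking.

## The score

For a metabolite with per-subject concentrations \(x_0\) at baseline
and \(x_t\) at the follow-up, let \(f_i = x_{t,i} / x_{0,i}\) be the
per-subject fold changes and \(\Delta\) their median. Then

\[
  pBI \;=\; \lambda \cdot DA^{*} \cdot
  \left| \frac{\Delta_{change}}{CV} \right| \cdot
  \operatorname{sign}(\Delta_{change}),
  \qquad
  \Delta_{change} =
  \begin{cases}
    \Delta & \Delta \ge 1 \\[2pt]
    -1/\Delta & \text{otherwise,}
  \end{cases}
\]

where

* \(DA^{*} \in [0, 1]\) is the **discriminance**: the fraction of
  subjects whose fold change lies in the dominant direction
  (`max(#f > 1, #f < 1) / n`). Subjects with \(f = 1\) count toward
  neither direction but stay in the denominator — an unchanged subject
  is evidence against either direction.
* \(CV\) is the coefficient of variation (sample sd / mean) of the
  fold-change vector, **capped at 1** so that only low-variance
  responses can boost the score, and floored at `1e-6` so that a
  perfectly uniform response keeps a finite score.
* \(\lambda\) is a scale factor, 100 by default, putting scores on the
  scale on which \(|pBI| > 73\) (strict) defines a strong predictor.

The transform \(\Delta_{change}\) makes halving and doubling symmetric
(magnitudes 2 with opposite signs) and guarantees
\(|\Delta_{change}| \ge 1\); the sign of the score therefore reports the
direction of the concentration change. Because \(DA^{*} = 0\) forces
\(pBI = 0\), a cohort with no change scores exactly zero.

### Reading the score

pBI is a signal-to-noise style quantity: (median effect size ×
directional consistency) / relative dispersion. Two consequences matter
for interpretation:

* It is invariant to rescaling a metabolite's concentrations — only
  fold changes enter — so units cancel per analyte.
* The CV in the denominator means the score grows without bound as the
  cohort's fold changes become more uniform. On data whose relative
  dispersion is tight, even analytes with small median changes can
  reach large scores; the strong-predictor cutoff is meaningful
  relative to the dispersion regime of the data at hand, and the
  threshold-selection step (below) exists precisely to calibrate the
  network cutoff empirically.

## Ratio networks

For metabolites \(i > j\) the per-subject **absolute log2 ratio**
\(r_{ij} = |\log_2(m_i / m_j)|\) is treated as an analyte in its own
right: its paired sample (values at `t0` and at `t_x`) is scored with
the same statistic, giving \(s_{ij}\), and the network contains the
edge \((i,j)\) iff \(|s_{ij}| > \tau\) (strict). The absolute value
makes \(r_{ij} = r_{ji}\), so the score matrix is symmetric by
construction. All metabolites remain vertices; exports can optionally
drop isolated vertices to match the usual figure style.

Numerical details:

* \(r = 0\) (equal concentrations) would make fold changes of the
  ratio undefined; baseline and follow-up ratio values are floored at
  `epsilon` (`1e-6`).
* Zero concentrations follow the configured `zero_policy`: substituted
  by `epsilon`, or the subject is excluded for the affected pairs.
* A **signed variant** (`ratio_type = "signed"`) scores the raw ratio
  \(m_i/m_j\) instead. The two variants differ in an instructive way:
  the absolute form measures movement of the ratio *relative to parity*
  (\(m_i = m_j\)), so it is sensitive to the overall magnitude
  separation of the pair — rescaling a single metabolite changes its
  \(r\) trajectories and hence its scores. The signed form is exactly
  invariant to per-metabolite rescaling (the factor cancels between
  timepoints) but is not symmetric under exchanging numerator and
  denominator. The absolute form is the default because it is the form
  the method defines; a *global* unit change (all concentrations ×k)
  leaves both forms unchanged, which is what unit freedom actually
  requires. When analytes in a panel span orders of magnitude, the
  signed variant is worth comparing.

`kinetic_networks()` applies the construction to every follow-up
timepoint against the baseline; `degree_table()` and `hubs()` summarize
connectivity (ties broken alphabetically; the default of 4 hubs matches
the usual number of named center vertices in this kind of figure).
`correlation_baseline()` provides the customary comparison network
(thresholded Pearson correlation of per-subject log fold changes).

## Threshold selection

`select_tau()` reconstructs the simulation-based calibration of τ: for
each candidate, infer the network, take the metabolites with degree
> 0 as features, and score a k-nearest-neighbor classifier (k = 3,
Euclidean distance on standardized features) that discriminates
baseline from follow-up samples, by 10-fold cross-validation. The
selected τ is the accuracy argmax; ties break toward the smaller
candidate (denser networks keep more interpretable pair reactions at
equal accuracy).

Design choices worth knowing:

* **The classification task** is `t0`-vs-`t_x` sample discrimination —
  the only two-class structure a paired design offers without external
  labels. Every subject contributes one sample per class.
* **Folds are grouped by subject** by default, so a subject's two
  samples never straddle the train/test split; paired samples would
  otherwise leak information across the split and inflate accuracy.
  `grouped_folds = FALSE` switches to naive per-sample folds for
  comparison experiments.
* **Standardization** uses training-fold means and standard deviations
  only; constant features get unit scale.
* An **empty feature set** (τ above the largest |s|) returns the
  chance level 0.5 with a `flagged` attribute instead of failing, so a
  grid evaluation never aborts.
* The default grid runs from 0 to the maximum observed \(|s_{ij}|\) in
  40 even steps, with the configured default threshold (73) injected.
* All randomness (fold assignment, neighbor tie-breaks) derives from
  `config$seed`; identical seeds give identical curves.

## The synthetic cohort generator

`generate_null()` draws every concentration independently from
Normal(10, 1), truncated below at 0 by resampling (truncation rather
than clipping avoids a point mass at zero; at mean 10, sd 1 the effect
is negligible). `plant_effects()` multiplies (or divides) the follow-up
values of a seeded responder subset of subjects by
fold × lognormal jitter, and records the realized truth — which
subjects, which cells — in the dataset's metadata, so recovery
experiments compare against what was actually modified.

`generate_stress_cohort()` is the reference preset used throughout the
tests: 30 subjects, 60 metabolites, `t0`/`tmax`, five planted
up-responders with folds 2, 2.5, 3, 3.5, 4 at responder fraction 0.9
and jitter sd 0.1 (a realistic magnitude for combined biological and
analytical fold variability), at seeded random metabolite positions.
The two planted responders with the widest fold separation are recorded
as expected "interacting pairs": their mutual concentration ratio
shifts by the fold quotient, so they should connect in the inferred
network.

**What the generator does and does not emulate.** It reproduces the
statistical skeleton the method's own calibration uses — an
uncorrelated Normal(10, 1) backbone plus directionally consistent
multiplicative responses. It does **not** emulate several features of
real cohorts: within-subject correlation across timepoints (baseline
and follow-up are independent draws, so even planted fold changes carry
the dispersion of a ratio of two independent draws, about 20% relative
sd, on top of the planted jitter), between-metabolite covariance from
shared pathways, skewed concentration distributions, or
analytical batch effects. Passing recovery tests on these cohorts
therefore demonstrates that the implementation ranks, classifies and
connects planted signals correctly under the stated noise model — not
that the method will attain the same recovery rates on real data.

A related caveat the tests make explicit: on the N(10, 1) null
backbone the relative dispersion of single-analyte fold changes is
small (CV ≈ 0.14), so null single-analyte scores are routinely far
above the strong cutoff — the cutoff separates signal from noise
*within* a dispersion regime, not across regimes. Null *ratio* scores,
by contrast, concentrate just below 73, which is consistent with using
that value as the network threshold on such data. The acceptance suite
measures both behaviors rather than assuming them.

## Degenerate inputs and tie rules

* Minimum paired sample size is 3 everywhere (median and CV of fewer
  pairs are degenerate); analytes and pairs failing it are reported as
  unscored, never silently dropped.
* Missing values: subjects are excluded pairwise per analyte (and per
  ratio pair), with exclusion counts carried in results.
* Median of an even-length vector is the mean of the two central
  values.
* Ranking ties break alphabetically by metabolite name; degree ties
  likewise; threshold ties toward the smaller τ. All orderings are
  deterministic.
* Strict inequalities throughout: predictor classes (`|score| >`
  cutoff) and edges (`|s| > τ`), so boundary values fall in the lower
  class / draw no edge.

## Problem sizes used by the test suite

The recovery and calibration experiments run at the reference
conditions (30 × 60 cohorts) over 100 seeds in the test suite and 25
replicate cohorts in `scripts/acceptance.R`; the oracle-equivalence
check uses 100 random fixtures of 3–50 subjects. These sizes keep the
full suite within a few minutes on one CPU while leaving the binomial
noise of the reported rates at a few percent.

## Known limitations

* The unpaired (independent-samples) variant of the score is out of
  scope; only paired designs are supported.
* The absolute-log-ratio network inflates scores for metabolite pairs
  whose concentrations are widely separated in magnitude and whose
  ratio trajectory is therefore tightly dispersed relative to its
  distance from parity (see the signed variant above for an
  alternative).
* Pathway mapping, reaction directionality and identifier lookups are
  annotation concerns outside the package; exports (GraphML, SIF, edge
  list) are designed to hand networks to Cytoscape or igraph for that
  purpose.
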