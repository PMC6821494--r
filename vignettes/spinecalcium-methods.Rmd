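---
title: "Models and methods behind spinecalcium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spinecalcium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinecalcium)
```

`spinecalcium` analyses calcium fluorescence time series recorded from
dendritic spines, dendritic shaft segments and the soma of a neuron during a
delayed-response decision task, and ships the spike-to-fluorescence forward
simulator used to validate every analysis stage. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
simulation-based tests do and do not establish about real data.

## The measurement problem

Somatic action potentials back-propagate into the dendrite (bAPs) and open
voltage-gated calcium channels everywhere, so most of the calcium signal in
any spine or dendritic segment is a copy of the global somatic signal.
Synapse-specific ("independent" or "local") activity rides on top of this
global component. Every downstream question — how much local activity is
there, which task epochs drive a spine, how similar are two spines, how does
similarity fall off with distance along the dendrite — first requires either
(a) a probabilistic account of activity that does not assume the global
component can be removed (the independence estimator), or (b) removal of the
bAP component (the subtraction methods), whose errors then propagate into
the derived statistics. The simulator exists to measure that propagation.

## Morphology and distances

A `dendrite_tree` is a rooted SWC morphology; arc length is the sum of
straight parent-child steps (node spacing ~2 um in generated trees, so the
polyline error is negligible at the 2.7-um first bin edge). Masks (soma,
spines with zero arc extent, shaft segments) attach to points on edges.
The *traversal distance* between masks is the shortest path through the
tree (computed on the node graph via Dijkstra, with exact handling of
off-node attachment points); the *Euclidean distance* is the 3D chord, and
is never larger. Pairs are classified `within` / `across_one` /
`across_multiple` by the number of bifurcation nodes strictly interior to
the connecting path. `segment_dendrite()` tiles each maximal unbranched
path with `max(1, round(length/target))` equal segments, so a 100-um branch
at a 30-um target yields three 33.3-um segments — lengths are equalized
rather than leaving a remainder stub.

`generate_synthetic_tree()` grows a random morphology: a first branch from
the soma, then branches sprouting from uniformly chosen points of the
existing tree. Defaults — 6 grown branches of 40–70 um (~330 um of dendrite
whose pairwise paths populate the full 0–245 um bin range) at 0.22
spines/um, i.e. ~75 spines per session — define the study conditions used
throughout the tests and the acceptance script. The spine density is at the
lower end of anatomical values, matching what is actually segmentable in
volumetric two-photon data.

## The forward model

Spike trains for all spines *and the soma* (the soma is one row of the same
correlation matrix — an interpretation the model leaves open) are Bernoulli
per imaging sample (`dt = 1/14.5` s; the simulation step equals the sample
period) at `mean_rate = 1.5` Hz. Their pairwise correlations are the target
matrix `l = q (1 - a_pre) + U a_pre`, `U = exp(-x/lambda_pre)`, projected to
the nearest correlation matrix (Higham). The base matrix `q` uses a
one-factor construction with right-skewed loadings (`u = v^2`, `v ~ U(0,1)`)
so that correlations span ~0–0.8 with most pairs weakly correlated, as in
cortical data; only the span is constrained by the model description, the
skew is this package's choice. Sampling is dichotomized-Gaussian: a latent
multivariate normal is thresholded at `qnorm(1 - rate*dt)`, with the latent
correlation for each target obtained by inverting the bivariate-normal
moment relation on a spline grid. Targets infeasible for Bernoulli
marginals raise an error naming the pair; residual indefiniteness of the
latent matrix is repaired by the nearest-correlation projection.

Depolarization at spine *i* is
`p_i = a_s e_i + a_c e_c + a_coop * sum_j exp(-x_ij/lambda_coop) a_s e_j`
(the sum excludes *i* itself — self-cooperativity would double-count
`a_s`). The nonlinear (NMDA-like) component is
`q_i = m_i(t) * sum_{t'=0..tau_nl} exp(-t'/tau_nl) e_i(t - t')` with the
Hill gain `m_i = a_s p^n_nl / (p^n_nl + K_nl^n_nl)`; calcium is
`Ca_i = p_i + r q_i`. Fluorescence convolves calcium with
`exp(-t/tau_i)` — per-spine decay constants are drawn from a multivariate
normal with covariance `tau_s_sd^2 * exp(-x_ij/lambda_decay)`, truncated at
0.05 s — and passes the indicator saturation
`f = g^n_g / (g^n_g + K_g^n_g)`. Defaults are the Full Nonlinear set
(`a_pre = 0.5`, `lambda_pre = 10` um, `a_s = 1`, `a_c = 3`, `a_coop = 0.5`,
`lambda_coop = 10` um, `n_nl = 2`, `K_nl = 5`, `tau_nl = 100` ms, `r = 3`,
`n_g = 2`, `K_g = 12`, `lambda_decay = 32` um, `tau_s = 0.24` s mean,
`tau_c = 0.4` s, `f_max = 16`). "Indicator Nonlinear" is the same model
with `a_coop = 0, r = 0`; "Linear" additionally omits the indicator
saturation. The spread of spine decay constants (`tau_s_sd = 0.08` s) and
the noise SDs (`sigma_s = 0.2`, `sigma_c = 0.05` dF/F, chosen to mimic
high-SNR baseline noise) are not fixed by the model description and are
config-exposed.

Spine traces are scaled by one factor anchoring the 99.5th percentile of
the pooled spine samples at `f_max` exactly; the same factor is applied to
the soma (the description is silent about the soma, and all downstream
statistics are scale-invariant, but simulated somatic dF/F is therefore
larger than real somatic ranges). The soma trace uses the linear chain with
`tau_c`; its nonlinear component is undefined in the model. Gaussian noise
is added last. Given a seed, a session is bit-reproducible.

What the simulator does **not** emulate: axial/lateral motion (hence the
axial baseline/noise corrections of real preprocessing are omitted),
bleaching, neuropil contamination, indicator kinetics beyond one
exponential plus a Hill saturation, incorrect-trial behaviour, and task
tuning of the inputs (spike trains are stationary unless an explicit
epoch-gain matrix is supplied via `tuning`). Passing tests on synthetic
sessions therefore validates the estimators' logic and their behaviour
under the stated noise model — not robustness to motion or tuning
heterogeneity in real recordings.

## Preprocessing

Baseline `f0(t)` is the mode of a Gaussian KDE (Silverman bandwidth) in a
2000-sample sliding window, evaluated every 500 samples and linearly
interpolated (the stride is a cost choice; at 14.5 Hz the window is ~2.3
min). Photon shot noise: with `N = m F` photons, the per-sample SD in dF/F
units is `sqrt(N)/(m f0)`. `m` is estimated as the photons-per-unit factor
from the variance-versus-mean regression across units; note that for
Poisson counts at per-photon amplitude `1/m`, the var-vs-mean slope is
`1/m`, so the package returns the reciprocal of that slope — the printed
rule `N = m f` only counts photons under this reading. Photon counts are
floored at 1 to keep sigma finite.

## Independence estimation

For threshold `u` and per-sample noise `sigma`, the probability that the
signal is above threshold is `P = pnorm((x - u)/sigma)`. The probabilities
`P_independent = P_mask (1 - P_ref)` and `P_coactive = P_mask P_ref`
decompose `P_mask` exactly, and the proportion independent is the ratio of
their time means. The false-positive analogue replaces each probability by
the noise-only tail `pnorm(-u/sigma)`; the literal fixed-at-threshold
reading (`pnorm(u/sigma)`) is exposed as a variant but exceeds 0.5 for any
positive threshold, so it cannot serve as a false-positive rate — the
chosen default vanishes at high thresholds, which is how FPR reference
curves behave. The FPR analogue tracks the measured proportion on
pure-noise traces at practical operating points (thresholds at >= ~2 noise
SDs, e.g. a 0.15 dF/F reference threshold at 0.05 somatic noise); at
thresholds inside the noise the two quantities diverge by construction.
Exclusion windows replace `P_ref` by a directional running maximum so that
mask activity shortly before/after a reference event is not scored
independent. Threshold grids are geometric over 0.05–4 dF/F (mask) and
include the ~0.15 dF/F (1–2 somatic spikes) reference operating point.

## bAP subtraction

The reference (soma or trunk) dF/F is deconvolved by exact non-negative
AR(1) deconvolution (pool-adjacent-violators, i.e. an OASIS-style solver
with no sparsity penalty). The AR coefficient is the autocovariance ratio
at lags 2:1, which is unbiased for an AR(1) signal in white noise; a
multiplicative `fudge` factor is exposed for compatibility with tools whose
spectral estimators over-estimate the coefficient, but the default is 1 —
shrinking the coefficient (e.g. to 0.5x) smears events over transient
tails, pins the per-spine kernel fit at its lower bound and leaves a
soma-correlated residual, which measurably degrades every downstream
statistic on simulated sessions.

Each mask is then fit with `model = a * (events (*) exp(-t/tau))`,
`a in [0, 100]`, `tau in [0.05, 2]` s. The amplitude is linear in the
model, so it is profiled out in closed form and the decay constant found by
a deterministic log-grid plus golden-section search — equivalent to, but
faster and more reproducible than, a stochastic global optimizer. The
residual is the bAP-subtracted trace. Four alternatives are provided:
a non-negative fit whose objective scores the subtracted trace against
empirical CDFs (left tail from the raw trace's negative values, right tail
from the survival function of the regression-subtracted trace's positive
values, Laplace-smoothed with exponential tails beyond the support — the
positive side must use the survival function, otherwise the objective is
minimized by unbounded over-subtraction); robust (bisquare) regression on
the soma; robust regression on the closest 30-um dendrite segment; and the
deconvolution fit with the dendrite segment as reference.

On bAP-only simulations the deconvolution fit removes >99% of the variance
and recovers each spine's decay constant almost exactly; on Full Nonlinear
simulations *every* method leaves inferred spine-soma (input-output)
correlations off by more than 0.1 on average — the benchmark
(`run_subtraction_benchmark()`) reproduces this failure, which is why
quantitative input-output comparisons are avoided while *spatial* statistics
remain trustworthy.

## Task selectivity

Per-trial epoch responses (sample 1.25 s; early/late delay and early/late
response, 1 s each) are means over epoch samples, with counts equalized by
seeded subsampling of the longer sample epoch; only correct, non-early-lick
trials enter. Selectivity is tested with a one-way F statistic over the 10
epoch-by-trial-type groups against 1000 shuffles of the group labels
("nonparametric" refers to the shuffle null, not the statistic); degenerate
zero-variance responses give p = 1 by convention. The epoch angle places
the mean sample/delay/response responses on axes at 90, 210 and 330 degrees
(the 120-degree separation is the model; the absolute rotation is a
documented package constant) and takes the angle of the vector average;
negative post-subtraction means enter as-is and may point opposite an axis.
Its error is the circular SD of 1000 trial-resampling bootstraps; a mask is
epoch-selective when ANOVA p < 0.01 and angle SE < 30 degrees. Differences
between masks use a permutation test that swaps trial identity between the
two masks; trial-type selectivity uses two-sided per-epoch permutation
tests with Bonferroni correction over the five epochs, and categorizes
masks as right / left / both / none.

## Spatial structure of pairwise correlations

Signal correlation is the Pearson correlation between two masks'
10-condition mean-response vectors computed from disjoint random halves of
the trials, averaged over 100 splits — disjoint halves make trial-to-trial
co-fluctuations cancel in expectation, which is the decontamination
property. A single pair's split-averaged estimate retains an irreducible
dataset-level SD of ~0.17 (ten condition means; it does not shrink with
trial count), so decontamination is a statement about the mean over pairs.
Noise correlation is the mean over conditions of the within-condition
across-trial correlation (conditions with < 3 trials are dropped with a
warning). Pairs are binned at the exponential edges 0, 2.7, 4.5, 7.4, 12,
20, 33, 55, 90, 148, 245 um (left-closed, right-open; pairs beyond 245 um
are dropped); bin SEMs are computed on random maximal subsets in which
every mask appears at most once (mean of 100 draws), so shared pair members
do not understate the error. Bin means (centers = mean member distance) are
fit with `y = A exp(-x/lambda) + x L + B` by seeded differential evolution
(bounds `A in [0,1]`, `lambda in [0.5, 200]` um, `L in [-0.02, 0.02]`/um,
`B in [-1, 1]`) with a local polish; a fit with `A` indistinguishable from
zero flags `lambda` unidentifiable. The lambda error is the SD of 300
session-resampling bootstrap refits. The distance effect is tested by
shuffling distances among pairs (statistic: variance of bin means); branch
comparisons permute group labels within random member-disjoint pair
subsets; the motion control compares Euclid-close/traversal-far pairs to
their traversal-matched bins — on simulated geometry (no optical
cross-talk) the two agree.

## The recovery studies and their biases

`run_length_constant_recovery()` simulates sessions under presynaptic
clustering (`a_pre = 0.5, a_coop = 0`), postsynaptic cooperativity
(`a_coop = 0.5, a_pre = 0`), or the null (`a_pre = a_coop = 0`), runs
baseline estimation on raw-wrapped traces, bAP subtraction, pairwise spine
correlations, binning and the exponential-linear fit. Because the simulated
spike trains are stationary, the *split-trial signal correlation is zero by
construction* on these sessions — exactly the contamination it is designed
to remove is the only pairwise signal present — so the recovery study
measures the **noise correlation** by default (`correlation_measure`
config; `signal` and raw `trace` variants are exposed). This is the one
place the pipeline's default statistic differs between real-data use
(signal correlations of task-tuned masks) and the simulation study, and it
is deliberate.

Recovery accuracy differs between the two processes, and the difference is
a property of the biology being simulated, not of the estimator:

* *Presynaptic clustering* writes `exp(-x/lambda_pre)` directly into the
  spike covariance; the fitted length constant is recovered within ~10–25%
  (e.g. 11.1 um for a simulated 10 um at the acceptance scale).
* *Postsynaptic cooperativity* induces, besides the direct coupling
  `a_coop w_ij`, a shared-neighbour term `a_coop^2 sum_k w_ik w_jk` whose
  distance profile on a uniform spine lattice is
  `(x + lambda) exp(-x/lambda)` — fatter than one exponential — so a
  single-exponential fit reads ~1.3–1.8x the simulated `lambda_coop`
  (12–21 um across seeds for a simulated 10 um). The fitted constant should
  be read as the length scale of the *local calcium component*, which for
  cooperative processes exceeds the microscopic interaction constant.

The null configuration (with the heterogeneous decay constants retained at
`lambda_decay = 32` um) shows no significant distance effect in >= 90% of
runs; this holds only because the deconvolution subtraction is nearly
exact — an under-deconvolving reference (e.g. `fudge = 0.5`) leaves
soma-locked leakage whose magnitude co-varies with each spine's decay
constant, and the decay constants' 32-um spatial correlation then becomes a
detectable false distance effect.

## Problem sizes

The acceptance script simulates the stated full conditions: five sessions
of ~75 spines and ~45 min (380 trials) at 14.5 Hz per process (~2 min total
on one CPU). The test suite runs the same pipelines at reduced sizes chosen
as the package's test-scale defaults — 3 sessions of 150 trials for
recovery, 10 single-session null runs of 60 trials for calibration, 300–400
replicate null masks for the permutation type-I checks — keeping the suite
under ~3 minutes.

## Known limitations

Trial tables are assumed regular (no variable delays); incorrect trials are
excluded rather than modelled; the independence estimator assumes Gaussian
shot noise with a known per-sample SD; the exponential-linear fit assumes a
single dominant length scale (mixtures are absorbed into an inflated
lambda, see above); cross-session spine matching and image registration are
out of scope — the package starts from extracted per-mask time series.
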