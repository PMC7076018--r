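---
title: "Task-evoked connectome analysis with gPPI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-evoked connectome analysis with gPPI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gppinet)
```

## The analysis in one paragraph

`gppinet` estimates how a blocked emotional-face task reorganizes
communication in a region-level functional connectome. Resting time series
define intrinsic connectivity networks (ICNs) through shrinkage partial
correlations and consensus community detection. Task time series feed
seed-wise generalized psychophysiological interaction (gPPI) regressions
over every ordered region pair; group tests on the emotion-minus-shape
interaction contrast reduce these to a signed directed *difference matrix*
(+1 task-evoked coupling increase, -1 decrease, 0 no change). Everything
downstream — within/between-ICN densities against a degree-preserving
rewiring null, centrality-based hub classification, and overlap statistics
against reference region sets — characterizes that matrix. A seeded
synthetic-data generator with planted ground truth exercises the full
pipeline end to end.

## Resting branch: from time series to ICNs

Per subject, time series are band-pass filtered (0.01–0.1 Hz, implemented
as projection on the in-band discrete-cosine components so the filter is
exactly linear and testable by projection algebra). The connectome is the
Fisher r-to-z transform of the partial-correlation matrix obtained by
inverting a Ledoit-Wolf shrinkage covariance,

$$\hat\Sigma = (1-\rho)\,S + \rho\,\mu I, \qquad
  \mathrm{pc}_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}},
  \quad \Omega = \hat\Sigma^{-1},$$

with the analytic intensity $\rho$ that minimizes expected Frobenius loss.
Shrinkage guarantees invertibility when nodes approach time points and can
be overridden (`shrinkage = 0` recovers the sample estimator, used by the
oracle tests).

Each subject's matrix is proportionally thresholded — the strongest
`cost` fraction of signed z-values is kept, ties broken by (weight,
node-pair) order so results are platform-independent — and clustered with
a two-level map-equation (Infomap-style) optimizer written in the package:
a codelength function plus greedy node-moving with Louvain-style
aggregation, restarted from independent random node orders. Subject-level
runs are aggregated into a co-assignment matrix; the subject average is
thresholded again and re-clustered; the modal partition over group runs is
returned. A node is *unassigned* when it is isolated after group
thresholding or agrees with the modal partition in fewer than half of the
group runs — the latter rule is this package's choice, since published
pipelines rarely state how unclassified nodes arise.

Default costs are 0.035 (subject) and 0.07 (group), the conventional
values at 278-node scale. The recovery simulations in the test-suite use
0.15/0.15 at 60 nodes: proportional costs do not transfer across graph
sizes, and 0.15 at 60 nodes preserves the edges-per-node regime
(0.035 x 277/2 = 4.8 against 0.15 x 59/2 = 4.4). Similarly the optimizer
run counts (30 subject-level, 60 group-level in the tests; 50/100 in the
pipeline defaults) are stability parameters, not sample sizes; on 60-node
graphs the consensus is already stable at these counts.

## Task branch: GLM and gPPI

First-level designs convolve condition boxcars with a canonical
double-gamma HRF (peak 6 s, undershoot 16 s, peak:undershoot 6:1, 32 s
kernel, discretized at the TR) and append unconvolved motion regressors,
their first differences, and per-session constants. The 3 s cue is
modelled as part of its block by default (`cue_handling` switches to
separate or ignored cues). Temporal preprocessing is a 200 s high-pass
(mean, linear trend and slow discrete-cosine components; the explicit
linear term makes detrending exact) and AR(1) prewhitening in the
Cochrane-Orcutt form: estimate lag-1 residual autocorrelation from an
initial fit, quasi-difference data and design, drop the first row per run.

For every seed region the gPPI design contains, per session: one
interaction column per condition, built as
$\mathrm{HRF} \ast (\hat n_{\text{seed}} \times \text{boxcar}_c)$ where
$\hat n_{\text{seed}}$ is the ridge-deconvolved neural estimate of the
seed time course; the seed BOLD column; the convolved condition
regressors; the nuisance block; and a constant. Deconvolution solves a
ridge problem on an orthonormal discrete-cosine representation with the
penalty scaled relative to the normal-equation diagonal (`lambda = 0.01`
by default; the noiseless round trip reconvolves with R-squared above
0.99, and the penalty can be switched off together with deconvolution
itself via `deconvolve_seed = FALSE`). One decomposition per seed fits all
targets simultaneously.

Within a subject and session the AR(1) coefficient is pooled (median)
across nodes from the residuals of the condition + nuisance GLM and the
same quasi-differencing is applied to every seed design. Pooling is a
deliberate deviation from per-node whitening at this stage: the group
inference runs across subjects, per-target differences in rho are second
order there, and a pooled transform keeps one design decomposition per
seed rather than one per seed-target pair. `prewhiten_ar1()` itself keeps
per-node coefficients with pooling off by default.

Interaction betas are stored per seed, target, condition and session; the
difference matrix applies the emotion-minus-shape contrast averaged over
sessions (weights 1/2, 1/2), a two-sided one-sample t test across
subjects per ordered pair, and a Bonferroni edge threshold
$\alpha/(N(N-1))$ — at 273 nodes, 74,256 ordered pairs and a threshold of
about 6.73e-7. Subjects with incomplete node coverage are excluded with a
message. Estimation and inference are decoupled: the matrix is
reproducible bit-exactly from saved beta stacks.

## Downstream statistics

*Densities.* Within-module density divides sign-matching edge counts by
$n_a(n_a-1)$, between-module by $n_a n_b$; matrices are asymmetric because
edges are directed. The null rewires each sign's edge set by double-edge
swaps that preserve per-node, per-sign in- and out-degrees exactly (ten
attempted swaps per edge by default); empirical p-values use the add-one
rule, two-sidedness is two one-sided tests, and significance is assessed
against $\alpha/(2K^2)$ — 288 tests at twelve networks. Network degree
binarizes significant cells, sums in+out over both signs (a significant
within-module cell contributes one in- and one out-degree to its module),
and a chi-square goodness-of-fit test compares the K-vector to uniformity
(df = K-1).

*Hubs.* On the absolute (unsigned) directed graph, four centrality
measures are computed per direction profile: degree, betweenness
(direction-symmetric, shared by both profiles), participation coefficient
over the ICN partition, and nodal path length (mean shortest-path hops to
or from reachable nodes; ranked ascending since short paths mean central;
nodes reaching under 5% of the graph get the worst rank rather than NaN).
The hub-score rule flags the top `floor(N/3)` ranks and requires at least
three of four qualifying measures in either the in- or out-profile; the
k-means alternative standardizes the four measures (path length negated)
and labels the higher-mean-degree cluster as hubs. Per-ICN hub densities
are tested by shuffling hub labels (add-one p-values, Bonferroni over K).

*Overlap.* Jaccard index with a permutation null that redraws the hub set
uniformly; the odds ratio of a 2x2 overlap table with a Wald CI on the
log scale (Haldane-Anscombe correction on zero cells); and hub-versus-
non-hub comparisons of per-node association scores, globally and within
modules (within-module label shuffles, Bonferroni over K). For inference
the permutation p-values count ties as extreme (add-one rule,
conservative). For *calibration checks* the package exposes
`tie_break = "randomized"`, the standard randomized p-value that is
exactly uniform under the null; the conservative version is discrete and
superuniform by construction, so testing its uniformity directly would
conflate conservativeness with miscalibration.

## The synthetic generator

The generator emulates the study conditions, not arbitrary data: TR
0.72 s, 176 volumes per task session, two sessions, three 21 s
emotion and three shape blocks per session (2 s trials, 1 s intertrial
gaps, 3 s cue merged into its block), and two 1200-volume resting runs.
The printed acquisition numbers are mutually inconsistent about
inter-block fixation — six 21 s blocks plus 8 s gaps do not fit in
126.72 s — so the default layout places blocks back-to-back and exposes
`fix_s` for longer scans, erroring with the exact overrun otherwise.
Block order is counterbalanced across the two sessions: the final block's
HRF response is truncated at scan end, and an uncounterbalanced order
leaves that truncation on one condition, producing a small but systematic
condition-contrast bias that counterbalancing cancels (the reason
experimenters counterbalance in the first place).

Resting signals are latent draws from a block covariance (unit diagonal,
`within_module_corr = 0.5` inside modules, 0 between) convolved with the
HRF — giving them the low-pass spectral character of BOLD, without which a
0.01–0.1 Hz band-pass would discard most of the signal variance — plus
AR(1) noise (coefficient 0.3, sd 0.3), slow drift (sd 0.2) and, for task
runs, six smoothed random-walk motion regressors (bled weakly into the
data so nuisance regression has something to remove). Task activation
adds per-module amplitudes on the convolved emotion boxcar. Planted
connectivity effects are injected at the neural level before convolution:
edge (s, t, condition c, gamma) adds
$\gamma\, n_s(t) \times \text{boxcar}_c$ to the target's neural signal —
exactly the quantity the deconvolution-based gPPI estimator targets.

The planted effect size gamma = 1.2 used in the recovery tests is a
calibration choice (no empirical effect sizes exist for this quantity):
with two 176-volume sessions and the default noise level, per-subject
interaction betas concentrate well below gamma in spread, so a 50-subject
group t comfortably exceeds the Bonferroni threshold while single
subjects do not. What the generator does *not* emulate: voxel-level
structure, cardiac/respiratory physiology, multiband artifacts,
between-subject anatomical variability, and non-Gaussian BOLD amplitude
distributions. Passing recovery tests therefore demonstrates estimator
correctness under the stated generative model, not robustness to every
property of real data.

## Numerical and design choices

- **Problem sizes.** Recovery simulations run at 60 nodes / 6 modules
  (20 subjects for clustering recovery, 50 for edge recovery, 100
  replicates of 24 subjects for null calibration) — the desk-scale regime
  the package targets for routine testing; full-size runs remain a config
  change.
- **Thresholding.** Proportional thresholds keep the largest *signed*
  values, not magnitudes: the map-equation detector needs non-negative
  weights, and cost-based thresholding of z-matrices conventionally
  retains the strongest positive couplings. Surviving negative weights
  (possible in principle) are zeroed with a message.
- **Degenerate inputs.** Constant nodes are an error naming the node
  (partial correlation); zero-variance seeds deconvolve to zero with a
  warning and produce a rank error at the fit, by design; empty graphs
  yield all-unassigned partitions; size-1 modules report NaN
  within-density; all-zero degree vectors make the chi-square NaN.
- **Tie-breaking.** Threshold ties resolve by (weight descending, node
  pair lexicographic); rank ties in hub scoring by node index. Both are
  deterministic across platforms.
- **Seeds.** Every stochastic routine takes an explicit seed and restores
  the caller's RNG state; cohort generation fans a master seed into
  per-subject substreams, so any subject is reproducible in isolation.

## Known limitations

Betweenness has no in/out variant, so it enters both direction profiles —
the centrality table has seven distinct measures, not eight. The map
equation optimizer is greedy; on graphs without modular structure
different restarts return different local optima (the consensus stage is
the remedy, as in standard practice). The rewiring null preserves degree
sequences but not higher-order structure (reciprocity, clustering).
Ridge deconvolution attenuates high-frequency neural fluctuations, so
interaction betas are shrunk toward zero relative to the planted gamma;
group-level sign recovery is unaffected but absolute effect sizes should
not be read off the betas. Finally, gPPI is a moderated regression, not a
causal estimator: when a planted effect changes the coupling of seed s
onto target t, seeds correlated with s carry an attenuated copy of the
same modulation, so strong planted effects can flag a correlated
neighbour's edge as well. This is a property of the estimand, visible in
the synthetic cohorts precisely because their ground truth is known.
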