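---
title: "Static and dynamic functional connectivity states: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic functional connectivity states: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`dynfc` implements a complete resting-state functional-connectivity (FC)
analysis chain for multi-subject BOLD recordings: motion quality control,
group spatial independent component analysis (ICA) with stability analysis
and back-reconstruction, component time-course post-processing, static FC,
tapered sliding-window FC with graphical-lasso covariance estimation, deep
clustering of FC windows into recurring connectivity states, state temporal
metrics, and case-control statistics. A synthetic-cohort generator with
planted covariance states provides ground truth for every stage.

This vignette documents the model assumptions, the tunable parameters, the
numerical choices, and the design decisions that were genuinely open — in
enough detail that a maintainer can see why each piece is the way it is.

# The pipeline

## Quality control

Head motion is summarized per volume by framewise displacement (FD),

$$\mathrm{FD}_t = \sum_{i\in\{x,y,z\}} |\Delta d_{i,t}| \;+\; r \sum_{j\in\{\alpha,\beta,\gamma\}} |\Delta \theta_{j,t}|,$$

the sum of absolute frame-to-frame translation differences (mm) plus the
rotation differences (radians) converted to arc length at an assumed
brain-centre-to-cortex radius $r = 50$ mm. A subject is excluded when mean
FD exceeds 0.5 mm (strict inequality) or when the maximum Euclidean
translation from the reference volume exceeds 4 mm. The reference volume
defaults to the middle volume, matching the usual motion-correction
reference; it is configurable. Motion files are read as 6 whitespace-
delimited columns, rotations first (the common realignment-tool layout);
a switch flips the order. In paediatric cohorts the 50 mm radius slightly
overestimates rotational displacement, which makes the rule conservative.

## Group spatial ICA

Each subject's voxels-by-time matrix is reduced along time by PCA; the
reduced subject matrices are concatenated across the time dimension and
reduced again by a group PCA computed with an expectation-maximization
subspace algorithm (iterated least squares with a final rotation to ordered
principal axes; iteration cap 500, subspace-change tolerance $10^{-6}$
measured as the largest principal angle between successive subspaces). An
exact SVD route is available as a cross-check and is used in the tests as
the oracle for the EM route.

Infomax ICA (natural-gradient maximum likelihood with a logistic source
prior) unmixes the group-reduced data into spatially independent maps. The
logistic prior suits super-Gaussian sources, which is what sparse,
blob-like resting-state networks look like over voxels. Components are
scaled to unit variance and sign-flipped so each map's skewness is
positive — the sign of an ICA component is arbitrary, and a fixed
convention makes runs comparable.

Stability is assessed by repeating ICA from different initializations and
clustering all estimated components by absolute spatial correlation
(average-linkage hierarchical clustering, one cluster per component). A
cluster's stability index $I_q$ is its mean within-cluster similarity minus
its mean similarity to components outside the cluster; aggregate maps are
cluster centrotypes. Components with $I_q \le 0.8$ are flagged for
exclusion. Subject-specific time courses are obtained by projecting the
group mixing matrix back through the group and subject PCA bases (the
projection analogue of dual regression); subject maps are then the
least-squares regression of the subject's data on those time courses.

Intrinsic connectivity networks (ICNs) are selected among stable components
by spectral criteria: the ratio of Welch power below 0.10 Hz to power in
0.15–0.25 Hz, and the spectral dynamic range (maximum minus minimum of the
estimated spectrum). The anatomical criterion used in practice — peak in
grey matter, low overlap with vascular/ventricular/motion artefacts — is
expert visual review and cannot be automated faithfully; the package offers
a mask-overlap proxy (fraction of absolute map mass inside user-supplied
masks) plus manual include/exclude overrides.

*Scale.* The production-scale decomposition (subject PCA 120, group PCA
100, 100 components, 20 ICA repetitions) is available through
configuration. The defaults used for synthetic runs are 30/12/10 dimensions
with 10 repetitions: the algorithms are identical and the synthetic sources
are low-dimensional, so the reduced scale exercises the same code paths at
desk-friendly runtimes.

## Time-course post-processing

Fixed order: polynomial detrending (orthogonal polynomial basis, cubic by
default, removing linear, quadratic and cubic trends), despiking, then
zero-phase low-pass filtering. Despiking flags timepoints whose deviation
from the running median of their six surrounding values (window 7, centre
excluded) exceeds 3 times the MAD of those residuals, and replaces each
flagged point with a cubic spline fitted to the nearest 4 clean points per
side. The centre exclusion matters: a self-inclusive running median equals
the data point itself on locally monotone stretches, which makes residuals
exactly zero and collapses the MAD scale so that no spike is ever flagged.
The low-pass filter is a fifth-order Butterworth with 0.15 Hz cutoff
applied forward and backward (zero phase; DC gain exactly 1; magnitude
response squared), with reflect padding of three filter lengths at each end
to suppress edge transients. Note that a digital Butterworth designed by
the bilinear transform has its cutoff prewarped but frequencies away from
the cutoff warp: at TR = 0.906 s the realized two-pass gain at 0.20 Hz is
0.032, not the 0.053 the continuous-time formula suggests. The tests verify
the implementation against its own transfer function evaluated
independently from the filter coefficients, which also matches scipy's
`butter`/`filtfilt` to eight decimals.

## Static FC

Pairwise Pearson correlation between ICN time courses, Fisher
z-transformed ($z = \operatorname{atanh} r$). Correlations are clipped to
$\pm(1 - 10^{-12})$ before `atanh` so that degenerate inputs produce large
finite values rather than infinities. The diagonal is undefined and stored
as `NA`.

## Sliding-window FC

Windows of 50 TR (45.3 s at TR = 0.906 s) are tapered by convolving the
rectangle with a Gaussian of $\sigma$ = 6 TR (5.436 s) and slid in steps of
1 TR, giving $T - 50 + 1 = 246$ windows for 295 timepoints. The taper is
truncated to the rectangle's support and renormalized to sum to one, so the
weighted covariance keeps a comparable scale across window specifications.

Within each window the taper-weighted covariance is regularized by the
graphical lasso — $L_1$-penalized Gaussian precision estimation by block
coordinate descent, with the diagonal unpenalized — then converted to a
correlation matrix and Fisher z-transformed; each window contributes one
vector of $n(n-1)/2$ edge features. The penalty $\lambda_{L1}$ is selected
per subject by cross-validation: windows are split into 5 contiguous folds;
for each candidate $\lambda$ (10 points log-spaced in $[0.01, 1]$) the
precision fitted to the mean training-window covariance is scored by the
mean held-out Gaussian log-likelihood; ties go to the smaller $\lambda$.
Windows one step apart share 49 of 50 samples, so adjacent folds overlap
slightly; an optional buffer can exclude training windows near the test
block, but it is off by default — experiments showed that the leakage is
second-order while the buffer's cost (fewer, less representative training
windows on state-switching data) inflates the between-subject spread of
selected penalties, occasionally to full shrinkage, which then imprints an
artificial subject-level cluster structure on the standardized features.

## Deep clustering of FC windows

Windows from all subjects are pooled, standardized per edge (z-score across
windows, so the reconstruction loss weights all edges comparably), and
compressed by a fully connected autoencoder: encoding layers of 512, 256
and 32 units mirrored by a symmetric decoder, ReLU activations on hidden
layers, linear activations on the bottleneck and output, trained with Adam
(learning rate $10^{-3}$, the optimizer default) for 200 epochs at batch
size 50 to minimize mean squared reconstruction error. For synthetic
cohorts, whose edge dimension is 45 rather than several hundred, the
default configuration scales the architecture to 128/64/16 units and 60
epochs; development experiments showed state recovery insensitive to this
choice (results match the full architecture), and the smaller network
trains in seconds. All randomness (weight initialization, batch order) is
drawn from R's RNG, so training is bit-reproducible given a seed.

Clustering is two-stage. Per subject, exemplar windows are picked at strict
local maxima of the across-edge variance series (windows with pronounced
connectivity patterns; a constant series falls back to evenly spaced
exemplars). Stage 1 runs 128 repetitions of k-means (Lloyd, at most 1000
iterations), each seeded by k-means++, on the encoded exemplars; the
centroid set with the lowest sum of squared errors then initializes a final
k-means over all encoded windows (at most 10000 iterations).

The number of states $k$ is chosen by the elbow criterion on the ratio of
the mean within-cluster distance (each window to its centroid) to the mean
between-centroid distance, computed for $k = 2,\dots,8$. Formalizing "the
elbow" required a decision. The obvious rule — the maximum positive second
difference of the ratio curve — turns out to be systematically biased
toward $k_{\text{true}} - 1$ whenever the within-cluster drops decay
geometrically, which is exactly what happens when windows are blurred
mixtures of states (see Limitations): the curvature of a geometric decay
peaks one step early. The package instead locates the candidate whose ratio
lies furthest below the straight line joining the curve's endpoints — the
rule used by the reference dynamic-FC toolbox's elbow search. On synthetic
cohorts with four planted states this rule recovers $k = 4$ markedly more
often than the second-difference rule; both are reported in the returned
object (`ratio`, `depth`, `curvature`), along with a low-confidence flag
when the chord depth is shallow relative to the curve's total drop
(threshold 0.3, a heuristic diagnostic, not used for selection).

## State temporal metrics

Dwell time is the mean contiguous run length in a state times the window
step duration, reported in seconds (the unit is recorded in output
headers); fractional occupancy is the fraction of windows assigned to the
state. A state a subject never visits has occupancy 0 and *undefined*
dwell time (`NA`, never imputed 0): "mean time spent in the state" has no
value for a subject who never enters it, and imputing 0 would bias group
comparisons. Subject-level state FC matrices are element-wise medians of
the subject's windows assigned to each state.

## Group statistics

Edge-wise case-control comparison regresses age and sex out of each edge in
a single pooled regression (pooling both groups avoids group-specific
centering artifacts), then applies a two-tailed pooled-variance t-test to
the residuals, with Benjamini–Hochberg FDR across the edge family (level
0.05, applied separately to the static-FC family and to each state's
family). With 21 + 21 subjects the residual t-test has 40 degrees of
freedom, so $|t| > 2.02$ corresponds to uncorrected $P < 0.05$ — a useful
checkpoint that the degrees of freedom are right. Dwell time and fractional
occupancy are compared by ANCOVA (`metric ~ group + age + sex`, ordinary
least squares; no robust variant, as assumption checking was out of scope);
subjects with undefined metrics are dropped and counted, and a state tested
in fewer than 3 subjects per group is reported untested rather than
failing the run.

# The synthetic generator

Each synthetic subject has `n_sources` (default 10) spatial sources —
disjoint blob-like voxel profiles with smooth half-sine cross-sections,
giving the sparse super-Gaussian maps ICA expects — mixed into `n_voxels`
(default 500) channels. Source activity at each timepoint is drawn from the
covariance of the currently active state; the active state follows a
first-order Markov chain over `n_states` (default 4) states with
self-transition probability 0.95, so dwell times are geometric with mean
$1/(1-0.95) = 20$ TR. Default scan length is 295 timepoints at TR 0.906 s,
with 10 subjects per group. State covariances are random rank-2 factor
matrices plus the identity ($\Sigma_s = A_s A_s^\top + I$, factor standard
deviation 1.3), which guarantees positive definiteness and yields strong,
near-orthogonal between-state contrast (per-edge correlation differences
around 0.5 RMS); explicit covariances can be supplied instead. Gaussian
observation noise (default SD 0.5, a moderate signal-to-noise choice for
desk-scale recovery studies) is added per voxel. Motion traces are smooth
random walks in 6 parameters with occasional spikes at a configurable rate,
so QC exclusions are exercisable. Case and control groups share one
generative model unless `group_effect` shifts the case group's off-diagonal
covariances, supporting both null-calibration and effect-recovery studies.

What the generator does *not* emulate: haemodynamic response convolution
(source activity is temporally white within a state), physiological noise,
scanner drift (beyond an optional polynomial trend removed anyway by
detrending), or spatial autocorrelation of noise. Consequently, passing
recovery tests demonstrates that the estimation chain is correct under its
own statistical assumptions — it does not certify performance on real BOLD
data, whose autocorrelation lowers the effective sample size per window.

# Numerical choices

- Graphical lasso: block coordinate descent, convergence when the largest
  change in the working covariance falls below `tol` times the mean
  absolute off-diagonal of the input (default $10^{-5}$, 200 sweeps max);
  verified against an independent reference implementation to $2\times10^{-5}$.
  At $\lambda = 0$ the empirical covariance is returned directly and must
  be non-singular.
- Correlations are clipped to $\pm(1-10^{-12})$ before `atanh`.
- Welch spectra: segment length 64, 50% overlap, Hann taper, one-sided
  normalization; the power-ratio denominator is floored at $10^{-12}$
  times total power so the ratio stays finite.
- EM-PCA: cap 500 iterations, tolerance $10^{-6}$ on the largest principal
  angle between successive subspaces; deterministic sign convention
  (largest-magnitude loading positive).
- k-means uses Lloyd's algorithm with explicit initial centers; k-means++
  seeding is drawn from R's RNG.
- Cluster/ground-truth matching solves the assignment problem exactly by
  permutation enumeration up to 7 items (greedy beyond), on absolute
  centroid correlations.
- Per-stage seeds expand deterministically from the master seed as
  $(97s + 1009i) \bmod (2^{31}-1)$ for stage $i$, isolating the stochastic
  stages from each other.
- Problem sizes for synthetic validation were chosen for desk-scale
  turnaround: 20-subject cohorts, 10-dimensional source spaces, 12
  group-PCA dimensions, 10 ICASSO runs, the 128/64/16 autoencoder. All
  paper-scale values remain reachable through configuration.

# Limitations

The central limitation is structural, not numerical: with mean state dwell
of 20 TR and windows of 50 TR, most windows straddle one or more state
transitions. Windowed FC features are then convex mixtures of state
patterns; roughly half the between-window variance in default synthetic
cohorts is transition blur rather than state contrast. Three consequences,
all reproduced by the package's own validation code:

1. *Occupancy bias.* Even a perfect window classifier cannot reach the
   timepoint-level occupancy: assigning each window to its taper-majority
   state and comparing to true occupancy leaves a mean absolute error of
   about 0.06–0.08 under default conditions, because short visits near
   window edges are systematically absorbed by the locally dominant state.
   The pipeline's occupancy error sits just above this floor.
2. *Dwell-time compression.* Window-level run lengths are smoothed versions
   of timepoint-level run lengths; between-subject dwell variation is
   compressed, and rank correlations with planted dwell times are moderate
   rather than high.
3. *Elbow ambiguity.* The within/between ratio curve loses curvature at
   the true $k$; selection is correct in most but not all cohorts (about
   70% with the chord rule), and the failure mode is selecting $k \pm 1$.
   Cohorts whose long within-state runs happen to be unevenly distributed
   across states are the hard cases: the SSE-optimal clustering then merges
   a thinly represented state.

These effects shrink as dwell times grow relative to the window (e.g.
self-transition 0.99 at the same window length) and are inherent to the
sliding-window estimand itself, not to any particular implementation
choice. They are worth keeping in mind when interpreting window-based dwell
and occupancy estimates on real data with fast state dynamics.

A second limitation: the ICN anatomical criterion is a proxy. Mask-overlap
fractions plus manual overrides approximate, but do not replace, expert
review of spatial maps.
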