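---
title: "Multi-crystal density comparison: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-crystal density comparison: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densdelta)
```

# Overview

`densdelta` detects partial-occupancy changes — typically bound fragments
and the protein rearrangements they induce — by comparing each dataset of
a multi-crystal experiment against a statistical model of the shared
ground-state density. This vignette is the package's own account of the
method: the model and its assumptions, how each parameter is estimated,
what the synthetic-data generator does and does not emulate, and the
numerical choices that were genuinely open.

# The statistical model

After local alignment onto a common isotropic Cartesian grid, the density
of dataset $i$ at voxel $m$ is treated as

$$\rho_{i,m} \sim N\!\left(\mu_m,\; s_m^2 + \sigma_i^2\right),$$

a normal–normal hierarchy: the crystal's "true" density at a voxel is
itself a draw $N(\mu_m, s_m^2)$ — crystals are similar but not identical,
with genuine variation concentrated in flexible regions and lattice
contacts — and measurement contributes independent noise $N(0,
\sigma_i^2)$ per dataset. The assumptions worth stating explicitly:

* **Exchangeability of ground datasets.** Every characterization dataset
  is a draw from the same hierarchy; systematic subgroups (e.g. two
  crystal forms) are not modelled.
* **Voxel independence.** Parameters are estimated per voxel; spatial
  correlation of map noise (which low-pass truncation creates) affects
  the variance of the estimates but not their consistency.
* **Normality.** Both layers are Gaussian. Gross outliers — the very
  events being sought — violate this, which is why the uncertainty
  estimator uses only central quantiles (below).

One unit convention matters: $s_m$ is treated as a *standard deviation*,
entering the Z-score denominator as $\sqrt{\sigma_i^2 + s_m^2}$. Treating
it as a variance would make the denominator dimensionally inconsistent;
the additive-variances convention is the one under which the calibration
tests hold.

## Estimators

**Mean map.** $\hat\mu_m$ is the unweighted voxel mean over the
characterization set. Voxels missing (outside a warped map's support) in
more than half the maps are marked missing. The mean is deliberately not
inverse-variance weighted: with tens of datasets the efficiency gain is
marginal and the unweighted mean is robust to mis-estimated $\sigma_i$.

**Dataset uncertainty $\sigma_i$.** The difference map $\rho_i - \hat\mu$
is sorted and regressed against standard-normal quantiles; the
least-squares slope over theoretical quantiles in $[-1.5, 1.5]$ is
$\hat\sigma_i$. The central-quantile restriction makes the estimate
nearly immune to the heavy tails contributed by real signal: in the test
suite, 1% gross outliers at $\pm 10$ shift the naive standard deviation
by ~40% but the Q–Q slope by under 5%.

**Natural variation $s_m$.** With $\sigma_i$ fixed, $s_m \ge 0$ maximizes
the marginal likelihood. The scalar operation (`estimate_s`) uses bounded
Brent search on $[0, 10\max(\mathrm{sd}, \max\sigma_i)]$ with tolerance
$10^{-6}$, returning 0 when the boundary beats the interior optimum; the
whole-map fit solves the stationarity condition in $u = s^2$,

$$g(u) = \sum_i \frac{(\rho_i-\hat\mu)^2 - (u+\sigma_i^2)}{(u+\sigma_i^2)^2} = 0,$$

by vectorized bisection ($g(0) \le 0$ gives the boundary $u = 0$; the
root is bracketed by the largest squared residual). Both routes agree
with a dense grid scan of the likelihood to $10^{-4}$ in the tests. In a
calibrated ensemble most voxels come out with $s_m = 0$: the observed
spread is fully explained by the measurement uncertainties, and only
genuinely variable regions retain $s_m > 0$.

**Externally studentized Z-maps.** A dataset that belongs to the
characterization ensemble influences the statistics it is standardized
against. For $\hat\mu$ the effect is the benign $\sqrt{1-1/n}$ factor,
but for $\hat s_m$ it is not: the score $g$ weights residuals by
$1/\sigma_i^4$, so the *lowest-noise* dataset dominates the decision
between $s_m = 0$ and $s_m > 0$, and the set $\{\hat s_m = 0\}$ selects
exactly the voxels where that dataset's own residuals happen to be small.
The result is a visibly deflated Z standard deviation for that dataset
(≈0.89 at $n = 40$ in our simulations). `zmap()` therefore standardizes
ensemble members against a leave-one-out estimate $\hat s_{m,-i}$,
obtained from the shared fit by a single Newton step after removing the
dataset's own score term — a one-pass jackknife that reproduces full
refits to well within the calibration bands and restores per-dataset Z
standard deviations to 0.93–0.98. External datasets (not in the
characterization set) use the shared $\hat s_m$ unchanged.

# Resolution management

Crystals diffract to different limits, so maps are compared only at a
common information content. Datasets are binned by resolution ceilings
(user-specified, or 0.1 Å steps spanning the observed range): analysed
once, in the finest admissible bin, and reused for characterization in
all coarser bins. Truncation is emulated in Fourier space: DFT
coefficients with $|k| > 1/d_{\min}$ (a spherical cutoff, the
crystallographic convention) are zeroed and the map back-transformed —
a linear, idempotent projection. Truncation is applied to each complete
map *before* warping, mirroring the fact that truncated structure
factors are Fourier-transformed and then aligned. The grid's Nyquist
period $2 \times$ spacing bounds $d_{\min}$ from below. For real inputs
the package assumes maps were produced with missing-reflection filling
enabled in the upstream refinement program; re-implementing model-phase
filling is out of scope.

# Alignment and warping

The "flexible" alignment is locally rigid: for every residue, a
least-squares (SVD/Kabsch) rigid transform is fitted on the Cα atoms of a
sliding window (default 7 residues, truncated at chain ends). Each output
voxel of the warped map takes its value from the moving map, trilinearly
interpolated at the position given by the transform of the nearest
aligned residue (by Cα distance). Nearest-residue assignment — rather
than blending transforms of several residues — keeps the identity
property exact and testable: warping with the identity alignment is the
identity to interpolation tolerance. Voxels farther than 10 Å from every
residue, or outside the moving map, are marked missing and excluded
pairwise from all downstream statistics (zero-filling would bias the
mean map). Trilinear interpolation smooths white noise at off-lattice
offsets (variance shrink up to 8× at half-voxel shifts); for the
near-isomorphous crystals this tool targets, sampling offsets are small
and the Q–Q estimator measures the post-warp noise actually present, so
the calibration is self-consistent.

# Event detection and background correction

Z-maps are contoured at $Z \ge 2.5$; 26-connected components are kept if
their peak reaches $Z \ge 3$ and their volume is at least 10 Å³ (about a
third of a water molecule), and surviving blobs closer than 5 Å are
merged to a single event. 26-connectivity avoids splitting thin diagonal
features; an optional symmetric pass on $-Z$ detects density loss and is
off by default.

For each event, the fraction $\beta$ of the mean map to subtract is found
by contrast maximization: $\mathrm{corr}(\rho_i - \beta\hat\mu,\,
\hat\mu)$ is computed globally (all non-missing voxels outside the local
region, so the event cannot depress its own baseline) and locally (the
blob expanded by 1 Å, grown in 0.5 Å steps until it holds at least 20
voxels). Locally the dataset is a superposition of ground density and
something unrelated, so the local curve decays faster; BDC is the
$\beta$ maximizing global minus local correlation, ties toward smaller
$\beta$. The correlations are computed from region sufficient statistics,
so the full 0.00–0.99 scan (step 0.01) is effectively free. When the
maximal contrast is below 0.05 the site is flagged low-contrast (locally
indistinguishable from ground). The event map is

$$E = \frac{\rho_i - \mathrm{BDC}\cdot\hat\mu}{1-\mathrm{BDC}},$$

whose endpoints pin the normalization: at BDC = 0 it is the observed map,
and for a noiseless two-state superposition with ground fraction $g$ the
residual to the minor state vanishes exactly and uniquely at
$\beta = g$ — an 80/20 mixture is solved at $\beta = 0.80$. Contrast
maximization tends to overshoot BDC somewhat (event density renders
stronger than unchanged surroundings); correcting this would require
phase-bias modelling, which is out of scope.

# Ensemble models and validation

A modelled changed state is merged with the ground state into one
refinable ensemble: atoms identical in both (same atom key, coordinates
within 0.1 Å — the configurable "moved" tolerance) stay single-conformer;
state-specific or moved atoms get two fresh conformer labels with paired
occupancies $1-q$ and $q = \mathrm{clamp}(2(1-\mathrm{BDC}), 0.05, 1)$,
so each group sums to one. The clamp (not part of the occupancy formula
itself) prevents degenerate refinement groups when BDC ≈ 1. Extraction
inverts the merge: drop the ground-only conformer, rescale the changed
conformer's occupancies back.

Four real-space scores validate a build: RSCC (> 0.7 to pass) between the
observed density and a model density of B-factor- and occupancy-scaled
atom Gaussians (variance $B/8\pi^2$ plus a resolution blur) over a 1.5 Å
atom mask; an RSZD-style score (< 3) — the maximum over atoms of
$|\bar Z|\sqrt{N}$ of the standardized difference density in each atom's
1.5 Å neighbourhood, a documented surrogate calibrated so the null stays
below 3 in ≥ 95% of trials, *not* numerically compatible with the EDSTATS
original; the B-factor ratio of changed atoms to side-chain atoms within
4 Å (warn above 1.5, fail above 3; mean, not median); and coordinate RMSD
between the initial build and the refined positions (< 1 Å, no
re-superposition). Threshold comparisons are strict: RSCC = 0.7 fails.

# The synthetic-data generator

`simulate_screen()` draws datasets from exactly the hierarchy the model
assumes: per voxel, truth $= \mu + s\,\varepsilon$ ($\varepsilon$
standard normal, $s$ nonzero inside designated spherical regions), plus
i.i.d. noise $N(0, \sigma_i^2)$, then low-pass truncation to the
dataset's resolution; event datasets mix $(1-o)\cdot$ground draw $+\,
o\cdot$changed density before noise. The ground-state "protein" is a
self-avoiding Cα walk (3.8 Å steps) scaled to the grid, with designated
side-chain atoms for shift events. Each binding site carries two ordered
waters in the ground state that the changed state displaces — fragments
bind in occupied pockets, and without ground density at the site the
background-correction contrast scan is degenerate (there is locally
nothing to subtract). Optional rigid jitter regenerates model and map
consistently in the jittered frame to emulate small non-isomorphism.

Default conditions, chosen once as representative of a well-behaved
screen: 40 ground datasets, 48³ voxels at 0.6 Å spacing, noise sd drawn
from U(0.03, 0.08) map units (a few percent of a carbon atom's ~1.8 peak
at these settings), resolutions U(1.6, 2.0) Å, one variable region
(s = 0.06, radius 3 Å), no jitter. Two bookkeeping details follow from
the noise-before-truncation order: truncation shrinks the marginal noise
sd by the square root of the kept-coefficient fraction, so the recorded
truth carries both the injected and the effective (post-truncation)
$\sigma_i$ — the latter is what the delivered map actually contains and
what recovery tests compare against; and truncation band-limits the
natural-variation draws the same way. What the generator does *not*
emulate: solvent continuum, spatially correlated natural variation,
anisotropy, radiation damage, and phase-bias coupling between datasets.
Passing tests therefore demonstrate the statistical machinery under the
model's own assumptions — not robustness to everything real maps do.

# Numerical choices and degenerate inputs

* Grid convention: voxel (1,1,1) center at `origin`; position = origin +
  (index−1)·spacing. Index↔position conversion is an exact bijection.
* Map I/O is CCP4/MRC mode 2 (float32, little-endian), axis order 1/2/3
  only; anisotropic voxels are rejected beyond 1e-3 Å since the
  statistics require an isotropic grid. Missing voxels round-trip as NaN.
* Superposition uses SVD with the determinant sign fix; collinear point
  sets (second singular value ≈ 0) are rejected as degenerate rather
  than silently resolved.
* The $s$-bisection runs 50 iterations (relative precision ~$2^{-50}$ of
  the bracket); the Brent search tolerance is $10^{-6}$.
* Zero-variance regions in the BDC scan skip that $\beta$ with a warning;
  if every $\beta$ is degenerate the estimate errors out.
* A dataset failing alignment or uncertainty estimation is quarantined
  with a warning and the run continues; fewer than two usable datasets is
  fatal. Ensembles below 30 characterization datasets trigger a
  convergence note, reflecting the ~30-dataset convergence scale of the
  ensemble model.
* Problem sizes in the test suite were chosen to exercise the study
  conditions (40 datasets, 48³ grids) where calibration claims are made,
  and smaller grids elsewhere; the full suite runs in about a minute.

# Known limitations

Single crystal form only (residue correspondence by numbering; no
cross-form alignment), no reciprocal-space refinement or structure-factor
handling (maps in, maps out), the RSZD surrogate is not EDSTATS, and BDC
contrast maximization retains its documented overshoot at high occupancy.
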