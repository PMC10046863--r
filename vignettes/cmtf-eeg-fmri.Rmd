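---
title: "Coupled matrix-tensor factorization of simultaneous EEG-fMRI: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled matrix-tensor factorization of simultaneous EEG-fMRI: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Simultaneous EEG-fMRI records the same neural events twice: as fast
oscillatory scalp potentials and as slow, spatially precise BOLD
fluctuations. `cmtfusion` treats both recordings as superpositions of a
small number of latent *sources* and estimates them jointly. The EEG is
represented as a third-order spectral-power tensor
$\mathcal{X} \in \mathbb{R}^{I_s \times I_f \times I_c}$
(time segments x frequency bins x channels); the fMRI as a matrix
$\mathbf{Y} \in \mathbb{R}^{I_s \times I_v}$ (time points x ROIs). Both
share the time mode: EEG segments are cut per fMRI volume, so row $t$ of
each describes the same two seconds of brain activity.

The coupled model is

$$
\mathcal{X} \approx \sum_{r=1}^{R} s_r \circ f_r \circ c_r, \qquad
\mathbf{Y} \approx \sum_{r=1}^{R}\sum_{k=1}^{K} (H_k s_r)\,(b_k \odot v_r)^\top
 + \mathbf{N}\mathbf{P}^\top,
$$

where $s_r, f_r, c_r$ are temporal, spectral and channel signatures of
source $r$; $v_r$ its ROI signature; $H_k$ the causal Toeplitz convolution
operator of the $k$-th HRF basis function; $b_k$ the per-ROI basis
coefficients ($\odot$ elementwise over ROIs, giving every ROI its own HRF);
and $\mathbf{N}\mathbf{P}^\top$ a rank-$Q$ term for BOLD structure with no
electrophysiological counterpart. The temporal signatures $s_r$ appear in
both factorizations -- that is the coupling, and the reason sources can be
read out simultaneously in time, frequency, scalp topography and anatomy.

Fitting minimizes

$$
J = \beta_x \lVert \mathcal{X} - \hat{\mathcal{X}} \rVert_F^2
  + \beta_y \lVert \mathbf{Y} - \hat{\mathbf{Y}} \rVert_F^2
  + \gamma_x \lVert \lambda_x \rVert_1
  + \gamma_y \lVert \lambda_y \rVert_1,
$$

with $\lambda_{x,r} = \lVert s_r\rVert\,\lVert f_r\rVert\,\lVert c_r\rVert$
and $\lambda_{y,r} = \sum_k \lVert b_k \odot v_r \rVert$ the per-source
amplitudes in each modality; the L1 terms discourage spuriously large
components.

## Tensorization

`build_eeg_tensor()` composes three steps, each exported on its own:

* **Segmentation** (`segment_eeg()`): strictly contiguous, non-overlapping
  segments of `fs * TR` samples anchored at the first volume marker.
* **Multitaper spectrum** (`multitaper_band_power()`): Thomson's estimator
  with DPSS tapers computed from the symmetric tridiagonal eigenproblem.
  Defaults `NW = 2`, `n_tapers = 3` give a +-1 Hz analysis bandwidth for a
  2 s segment -- a conventional low-variance setting; both are arguments.
  The segment mean is removed first so DC does not leak into the lowest
  bin. No further detrending or windowing: the intended input is already
  band-passed to the 1-30 Hz range during preprocessing, which this
  package deliberately does not reimplement.
* **Binning** (`bin_spectrum()`): squared Fourier amplitudes averaged into
  half-open bins `[left, right)`, by default 58 bins of 0.5 Hz covering
  [1, 30) Hz. Half-open edges make the binning a partition; a grid point at
  exactly 10.0 Hz belongs to [10.0, 10.5). Empty bins are zero with a
  warning rather than an error, since coarse sampling rates make them easy
  to produce accidentally.

## The HRF basis

`build_hrf_basis()` provides the canonical double-gamma response plus its
temporal and dispersion derivatives (K = 1..3, default 3 in the general
API; the analysis drivers use K = 2). The gamma lobes are parametrized so
their *modes* sit exactly at the stated delays (peak 6 s, undershoot 16 s,
ratio 1/6), which makes "shift the peak to 8 s" mean literally that.
Basis functions are causal, sampled at TR, normalized so the canonical
peak is 1, and applied as truncated lower-triangular Toeplitz convolutions
at TR resolution -- the shared signatures live on volume times, and a
finer-grid convolution would require an upsampling model for which there
is no information in the data. ROI-specific HRFs arise as coefficient
combinations `roi_hrf(B, basis, v)`; the coefficients `B` are estimated,
the gamma shape parameters are fixed. Estimating shapes jointly would add
a nonconvex layer the coupled objective does not need at ROI resolution.

## Optimization

Each ensemble run is a two-stage fit, mirroring common practice for
coupled decompositions:

1. **CP initialization** (`cpd_fit()`): alternating least squares on the
   EEG tensor alone from a seeded random start, ridge-stabilised
   (`1e-12`-scaled) normal equations for degenerate modes. The cost trace
   is exposed and is monotone by construction. Iteration stops on a
   relative cost update below `tol` (default `1e-8`), at `max_iter`
   (default 2000), or when the fit reaches machine precision relative to
   the data norm -- ALS converges only linearly, so the relative-update
   rule alone can spin on noiseless problems.
2. **Joint refinement** (`cmtf_fit()`): `V` and `B` are completed
   deterministically (canonical `B` rows `(1, 0, ...)`, then ridge least
   squares for `V`; `N`, `P` from a truncated SVD of the residual), and
   all factors are optimized together by limited-memory quasi-Newton
   (L-BFGS) with analytic gradients. The L1-of-norms penalties are
   smoothed as $\sqrt{x^2 + \varepsilon}$, $\varepsilon = 10^{-9}$, to
   stay compatible with a smooth quasi-Newton solver. Optimization runs in
   segments (default 100 iterations); the cost recorded after each segment
   forms a guaranteed monotone trace, and the relative-update stopping
   rule is applied between segments.

**Weights.** `default_cmtf_weights()` sets
$\beta = 1/\lVert\text{data}\rVert_F^2$ per modality, making each fit term
a squared relative error, and divides the amplitude-penalty weights
(default 0.01) by the corresponding data Frobenius norm. The division is
deliberate: amplitudes $\lambda$ scale with the data while the normalized
fit terms do not, so a fixed raw penalty would dominate or vanish
depending on measurement units. With the normalization, `gamma = 0.01`
means "a penalty of 0.01 per unit of amplitude relative to the data
scale" regardless of units.

**Gauge fixing.** A fitted model is only identified up to per-component
rescalings. `normalize_model()` maps every fit to a canonical form:
$f_r$ and $c_r$ at unit norm with the scale $\alpha_r$ absorbed into
$s_r$, $v_r$ divided by $\alpha_r$ so the fMRI reconstruction is
untouched, and signs flipped so each spectral signature's dominant entry
is positive. $v_r$ itself cannot be forced to unit norm: its scale is
tied to the shared $s_r$, and moving it would change one reconstruction
or the other. Ensemble clustering is unaffected because it compares
signatures by cosine similarity.

## Model selection

For each candidate $R$, `run_ensemble()` repeats the two-stage fit from
independent random starts (the study protocol uses 50; the drivers and
tests scale this down and scale the retention bound with it). Four
indicators then summarize each candidate:

1. **CORCONDIA** (`corcondia()`): the least-squares Tucker core of the
   tensor given the fitted EEG factors, compared to the superdiagonal
   identity; 100% means ideal CP structure, and values collapse (often far
   below zero) when $R$ exceeds the structure in the data. Computed on the
   EEG part only, since that is where the trilinear assumption lives.
2. **Reproducibility** (`graph_cluster()` + `reproducibility_filter()`):
   every component of every run is a node; edges join pairs whose
   four-mode cosine-product similarity reaches the threshold (default
   0.9); clusters are connected components, represented by the member with
   the greatest within-cluster similarity mass. Clusters appearing in more
   than `min_cardinality` distinct runs (default 10, strict) are retained.
   Connected components over a thresholded similarity graph is the
   simplest instantiation of graph-structured clustering; the threshold is
   exposed in the config.
3. **Stimulus similarity** (`stimulus_similarity()`): absolute Pearson
   correlation between a temporal signature and the binary paradigm
   vector. The raw binary vector is the default on purpose -- the shared
   signatures live on the EEG side of the coupling, before the HRF; an
   option convolves the stimulus with the canonical HRF first for
   BOLD-scale signatures.
4. **SnPM significance** (`snpm_significance()`): per ROI, the absolute
   t statistic of regressing that ROI's time series on its model-implied
   coupled regressor $\sum_k B_{vk} H_k s_r$; the null distribution of the
   max statistic over ROIs comes from circular shifts of the regressors,
   which preserve autocorrelation while destroying alignment. The FWE
   threshold is the $(1-\alpha)$ quantile of the max-statistic
   distribution with the observed maximum included, and exceedance is
   strict -- under exchangeability this controls FWE at exactly $\alpha$
   for continuous statistics. Inference is per subject/session; nothing
   is pooled.

`select_best_model()` codifies a deterministic gate-then-maximize rule:
candidates must have CORCONDIA at least 80% and a best-similarity
component that survives the reproducibility filter; among those, the
highest stimulus similarity wins, ties going to the smaller $R$. Manual
selection from the same indicators is inevitably ambiguous; the automatic
rule records its full scoring trace, and the pipeline accepts a
`force_r` override so a human can disagree.

## The synthetic-data generator

Real simultaneous recordings of this kind are not redistributable, so the
package carries a generator that emulates the study conditions: an
80-trial win/lose gambling paradigm in 14 s trials (choice 4 s, gaze 2 s,
feedback arrow 2 s, score 2 s, break 4 s -- the 4 s choice window makes
80 trials fill 18 min 40 s exactly), TR = 2 s giving 560 volumes,
64-channel EEG at 250 Hz, 90 ROIs. A volume is marked as stimulated when
its half-open acquisition window overlaps the feedback phase. The trial
schedule is fixed (no jitter or response-time variability is modeled);
all five phase durations are arguments.

Ground-truth defaults, chosen once as plausible for this kind of data:

* temporal signatures with unit variance -- the stimulus-driven one is the
  binary paradigm smoothed by a short three-point moving average plus 5%
  AR(1) noise, the rest are smooth AR(1) processes; unit variance gives
  sources comparable energy, and correlation with the stimulus is
  scale-invariant;
* unimodal nonnegative spectral bumps at distinct centers within
  [1, 30] Hz;
* spatially smooth channel topographies;
* sparse ROI signatures (15% of ROIs active by default, at most 20%);
* near-canonical HRF coefficients: rows of `B` perturbed around
  `(1, 0, ...)` with sd 0.1, keeping recovered temporal alignment
  identifiable;
* additive white Gaussian noise on both modalities, scaled so
  $10\log_{10}(\lVert\text{signal}\rVert_F^2/\lVert\text{noise}\rVert_F^2)$
  equals the requested SNR exactly (default experiments use 20 dB).

`synthesize_raw_eeg()` additionally renders sample-level EEG whose
per-segment band power follows the temporal signatures, so the
tensorization path can be tested end to end against a known spectrum.

What the generator does *not* emulate: MR gradient/pulse artifacts, line
noise, eye/muscle activity, nonstationary spectra, inter-regional HRF
delays beyond the basis, volumetric fMRI, or trial-by-trial amplitude
variability. Passing tests therefore certify the algebra, optimization,
calibration and selection logic under the model's own assumptions -- they
do not certify robustness to the artifact structure of real concurrent
recordings, which is a preprocessing concern upstream of this package.

## Numerical choices and degenerate inputs

* Pseudo-inverses (CORCONDIA, initialization) are ridge-stabilised SVDs;
  near-rank-deficient factor sets warn and proceed.
* `cpd_fit` / `cmtf_fit` reject non-finite inputs; `cmtf_fit` aborts if
  the cost ever exceeds 10x its initial value (divergence guard).
* Zero columns in `normalize_model()` are left untouched and flagged
  rather than invented.
* Constant temporal signatures make correlation and permutation inference
  undefined and raise errors instead of returning NaN.
* Ensemble runs that fail are skipped and counted, never silently
  imputed.
* All stochastic functions draw from one locally seeded generator and
  restore the caller's RNG state; identical seeds give bit-identical
  output.

## Problem sizes used by the tests

The test-suite experiments run at reduced dimensions chosen to finish in
minutes on one CPU while keeping every qualitative feature of the
full-scale setting: parameter recovery at $200 \times 20 \times 16$ with
30 ROIs and 10 starts; a 50-run ensemble at $98 \times 16 \times 12$ with
20 ROIs; familywise-error calibration over 200 null datasets with 199
permutations each; order selection over $R \in \{1,2,3,4\}$ with 12-run
ensembles and the retention bound scaled accordingly (>3 of 12,
matching the >10-of-50 rate). The analysis drivers under `analysis/` use
a half-size session (280 volumes, 58 bins, 16 channels, 30 ROIs) and
state at each step what they found.

## Known limitations

* The shared-signature assumption is strict equality of $s_r$ across
  modalities; sources whose EEG and BOLD time courses merely co-vary are
  mis-modeled.
* HRF shape parameters are fixed; only basis coefficients adapt per ROI.
* `B` is unconstrained, so an ROI's HRF may be sign-flipped against its
  spatial loading; amplitude interpretation should use
  $\lambda_{y,r}$, not raw `B` entries.
* ALS + L-BFGS reach the stated tolerances on the same objective as
  damped Gauss-Newton / factorization-aware solvers, but need more
  iterations on ill-conditioned problems; the ensemble-and-cluster
  protocol is the defense against individual runs stalling in poor
  optima.
* Model selection compares a finite candidate grid; it cannot flag that
  the true order lies outside the grid beyond low indicator scores.
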