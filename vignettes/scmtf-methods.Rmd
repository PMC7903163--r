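---
title: "Structured coupled matrix-tensor factorization of EEG-fMRI data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured coupled matrix-tensor factorization of EEG-fMRI data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In refractory focal epilepsy, simultaneous EEG-fMRI can localize the brain
regions whose BOLD signal co-fluctuates with interictal epileptic
discharges (IEDs), providing presurgical evidence about the ictal onset
zone. The classical route is mass-univariate regression of every voxel on
an EEG-derived regressor convolved with a fixed canonical hemodynamic
response function (HRF). That approach discards the multiway structure of
the EEG (time x frequency x channel), treats fMRI voxels independently,
and—most importantly—assumes one universal HRF, although neurovascular
coupling demonstrably varies across subjects and brain regions, and is
often distorted near epileptogenic tissue.

This package implements a symmetric, multivariate alternative: a
*structured coupled matrix-tensor factorization* (sCMTF) that jointly
decomposes

* the EEG spectrogram tensor `X` (time points x frequencies x channels),
  and
* the parcellated BOLD matrix `Y` (time points x regions of interest),

into a small number `R` of shared sources, while estimating
region-specific HRFs as part of the same optimization. The estimated HRF
field is then itself mined for localizing information: regions whose HRF
is unusual relative to the rest of the brain (quantified by *extremity*
and *entropy*) are candidate epileptogenic regions, complementary to the
activation maps.

# The generative model

The EEG tensor follows a rank-`R` canonical polyadic (PARAFAC) model

$$X \approx \sum_{r=1}^{R} s_r \circ g_r \circ m_r,$$

with temporal signatures `s_r` (shared with fMRI), spectral signatures
`g_r` and spatial (channel) signatures `m_r`. The fMRI matrix follows

$$Y \approx \sum_{r=1}^{R}\sum_{k=1}^{K} (H_k s_r)\circ(b_k \ast v_r)
 + \sum_{q=1}^{Q} n_q \circ p_q,$$

where `H_k` is the Toeplitz operator performing convolution with the k-th
HRF basis function, `b_k` holds every region's coefficient for that basis
function, `v_r` the region amplitudes of source `r`, and `*` is the
elementwise product. The Khatri-Rao structure `b_k * v_r` encodes the key
constraint that each region has *one* HRF shared by all sources: the
coupled part carries `(R + K) Iv` spatial parameters instead of
`R K Iv`. The uncoupled rank-`Q` term `N P'` absorbs structured fMRI-only
variation (slow drifts, vascular noise) so that it does not bias the
coupled estimates.

Each HRF basis function is a five-parameter double gamma

$$h_k(t) = \frac{\theta_2^{\theta_1}}{\Gamma(\theta_1)}
 t^{\theta_1-1}e^{-\theta_2 t}
 - \theta_5\,\frac{\theta_4^{\theta_3}}{\Gamma(\theta_3)}
 t^{\theta_3-1}e^{-\theta_4 t},$$

sampled at the repetition time on a lag grid spanning `[-t_pre, t_post]`
seconds (defaults 10 and 22 s). Time is measured from the start of the
grid, so a gamma mode smaller than `t_pre` produces a waveform peaking at
a *negative* lag: an acausal HRF, i.e. BOLD changes preceding the EEG
correlate of the discharge. Such responses are repeatedly reported around
epileptogenic tissue, and the Toeplitz operator realizes them through
super-diagonals (`offset = n_pre`); `offset = 0` recovers the ordinary
causal convolution as a special case.

All free variables — `S`, `G`, `M`, `V`, `B`, the HRF parameters
$\theta^{(k)}$, and `N`, `P` — minimize

$$J = \beta_x\lVert X-\hat X\rVert_F^2 + \beta_y\lVert Y-\hat Y\rVert_F^2
 + \gamma_x\lVert\lambda_x\rVert_1 + \gamma_y\lVert\lambda_y\rVert_1,$$

with $\lambda_{x,r} = \lVert s_r\rVert\,\lVert g_r\rVert\,\lVert
m_r\rVert$ and $\lambda_{y,r} = \sum_k \lVert b_k * v_r \rVert$. The
l1 terms penalize excessive source amplitudes, promote parsimony and
discourage degenerate components.

# Pipeline stages and the choices behind them

## EEG enhancement (multi-channel Wiener filter)

Raw interictal EEG has too low an IED signal-to-noise ratio for a blind
decomposition to isolate discharge-related sources. The first stage
therefore trains a spatiotemporal Wiener filter on the annotated IED
segments: the EEG is time-delay embedded with `tau = 4` lags either side
(so 29 channels become `2*29*4 + 29 = 261` rows), covariances `Rxx` (inside
annotations) and `Rnn` (outside) are estimated, and the filter
`W = Rxx^{-1}(Rxx - Rnn)` is formed through the generalized eigenvalue
decomposition of the pencil `(Rxx, Rnn)`, keeping only generalized
eigenvalues above 1. The truncation is the standard rank selection for
this filter: it is exactly the set of directions in which annotated
segments carry more power than background, and it enforces positive
semidefiniteness of `Rxx - Rnn` in the whitened domain. Diagonal
shrinkage (`1e-6 * trace/dim` by default) keeps the background covariance
invertible. The broadband power envelope of the filtered EEG, summed over
all filter outputs in quadrature and integrated per TR window, is the
reference time course `s_ref` used later to identify the IED component.
Which output channels enter the envelope is not uniquely dictated by the
construction; summing all of them is the package's choice and is flagged
here.

## Tensorization

The enhanced channels (the lag-zero rows of the filter output) are
transformed with Thomson's multitaper method on nonoverlapping windows of
one TR (time-bandwidth product 3.5, 6 Slepian tapers by default — a
conventional compromise between variance and leakage; both are
configurable), and squared magnitudes are averaged into 1-Hz bins from 1
to 40 Hz. Each (frequency, channel) fiber is log-transformed and z-scored
along time. The log + z-score convention equalizes the influence of every
channel and frequency and focuses the decomposition on relative power
changes; a plain z-score variant is available (`log = FALSE`). The
log transform is applied only when the fiber is entirely positive (raw
power), which makes the normalization idempotent.

On the fMRI side, confound regression (motion parameters with squares and
derivatives, scrubbing indicators above 1 mm scan-to-scan displacement,
five CSF/WM principal components) precedes a fourth-order zero-phase
Butterworth band-pass of 0.008-0.20 Hz; series are then averaged within
atlas parcels and z-scored per region. Confound regression is applied
before filtering, matching the order in which the steps are usually
listed; empty parcels are dropped but remembered, so maps can be
re-expanded to the full atlas with missing markers.

## Optimization

The joint cost is minimized with L-BFGS over all variables
simultaneously, from a structured initialization: a CPD of the EEG tensor
(alternating least squares, best of three starts) supplies `S`, `G`, `M`;
given `S` and the initial basis, the coupled spatial parameters are
initialized by least squares followed by a rank-1 truncation per region
(imposing the Khatri-Rao structure); `N`, `P` come from a truncated SVD
of the residual. Restarts perturb `V`, `B`, `N`, `P` and the HRF
parameters with 10% relative Gaussian noise; the study-scale default is
50 restarts. Gradients are analytic for all factor matrices; the gradient
with respect to the HRF parameters is chained through a central
finite-difference Jacobian of the waveform (relative step `1e-4`), which
avoids committing to a symbolic derivative of the double gamma while
keeping the matrix gradients exact. Iteration stops at a relative cost
change of `1e-8` or 500 iterations. Restarts with non-finite cost are
discarded; solutions in which some amplitude collapses below `1e-6` of
the largest are flagged as degenerate.

The initial basis spans both causal and acausal peaks (+5 s, -5 s, +7 s
for `K = 3`). This matters: with a purely causal initialization the
optimizer reliably refines causal HRFs but never crosses into the acausal
basin, and planted acausal HRFs in synthetic data go unrecovered.
Spreading the initial peaks over the support fixes this without any loss
on causal ground truth.

## Calibration

A factorization of this kind is identified only up to scales, signs and
permutation. Calibration fixes the convention: columns of `S`, `G`, `M`
are unit norm with amplitudes moved to `lambda_x`; `g_r` and `m_r` have
their largest-magnitude entry positive, with compensating flips pushed
into `s_r` and from there into `v_r` (so reconstructions are bitwise
unchanged — this is asserted in the tests); basis waveforms are unit norm
with scales absorbed into `B`; and each region's HRF has a positive main
lobe, compensated in the region's row of `V`. The HRF polarity choice is
genuinely ambiguous in the model (flipping an HRF and the region's
spatial coefficients together changes nothing); this is why the HRF
deviance metrics below are built to be polarity-immune.

## Model selection

Candidate ranks (default 1-5) are scored on stability (mean pairwise
factor congruence among the five lowest-cost restarts), relevance (the
best restart's maximal correlation between a temporal signature and
`s_ref`) and parsimony (whether the EEG fit curve has plateaued). The
package selects the smallest rank that is stable (>= 0.9), relevant
(>= 0.3) and sits at the start of the fit plateau — operationalized as
"the next-larger rank improves the relative EEG fit by less than 0.03".
The plateau condition is what prevents the degenerate choice of `R = 1`
whenever a single component happens to be stable and IED-correlated: a
rank below the true source count still gains substantially from adding a
component, and is therefore skipped. If no rank qualifies, the most
relevant one is returned, and the full score table accompanies the result
for audit.

## Inference (SnPM)

Significance of the spatial signatures is assessed nonparametrically.
Only the adjusted data `Y - N P'` is resampled: L = 250 surrogates are
built per dataset by a wavelet-based scheme — periodized Daubechies-4
transform after reflection padding to the next power of two, permutation
of coefficients within each scale, inverse transform, truncation, and an
exact restoration of each column's first two moments (the statistic is
location/scale free, so this amplitude adjustment only removes truncation
jitter). One permutation per scale is shared across all regions, which
preserves the instantaneous cross-regional covariance; fully independent
permutations are available as an option. The decomposition depth keeps at
least 8 coefficients in the coarsest scale.

For every region a local design matrix stacks the fitted temporal
signatures convolved with that region's HRF; OLS betas divided by their
standard errors give a pseudo-t per source, and the empirical
distributions of the maximal (minimal) statistic over regions yield
familywise thresholds per source. Two conventions are offered: the
default splits `alpha` across the two tails, so that the event "any
region exceeds either the activation or the deactivation threshold" is
controlled at `alpha` jointly — this is the property the package's null
simulations verify. `tail = "each"` instead thresholds each direction at
the full `alpha` (the 95th percentile of the max and the 5th of the min),
a convention that is common in the literature but whose two-direction
union error approaches `2 alpha`. Observed maps are computed on the
unshuffled data; both the pseudo-t and the raw betas/spatial signatures
are reported, since either can be thresholded. Perfect fits are capped at
`|t| = 1e6` and logged. Thresholds use the m-th largest (smallest) null
value with `m = floor(alpha_tail * L)`, the conservative order-statistic
rule.

## HRF deviance metrics

*Extremity* of a region is one minus the mean absolute correlation
between its HRF and every other region's HRF — 0 when all waveforms
agree, approaching 1 for an outlier. *Entropy* is the negative log of the
region's conditional probability given all other regions: waveforms are
sign-canonicalized (each flipped so its own main lobe is positive — a
per-waveform rule that is exactly invariant to input polarity — then
aligned to the pointwise median of the canonicalized set), unit-normed,
projected onto the top `min(5, Iv - 2)` principal axes, and each
projection is scored under a ridge-regularized Gaussian fitted on the
other `Iv - 1` projections (leave-one-out; ridge `1e-3 * trace/p`). A
leave-one-out kernel density is available behind a flag. The Gaussian
construction is a declared choice: it satisfies the defining properties
(conditional probability given the other HRFs, exact polarity immunity,
scale invariance) without claiming to reproduce any particular density
estimator. The top-20 regions per metric are inspected, and their overlap
with a candidate zone is scored by an exact binomial tail probability at
the zone's region fraction.

# The synthetic data generator

Because the patient data behind this method cannot be shared, every
claim the package makes is validated on synthetic data drawn from the
generative model itself, with known ground truth. The default
configuration emulates a ten-minute EEG-fMRI session at TR 2.2 s
(`Is = 270` volumes), 50 regions, 20 frequency bins and 16 channels, with
`R = 2` sources, `K = 2` HRF basis functions and one nuisance component.
The IED source's temporal signature is a smoothed Poisson spike train at
2 discharges per minute; its spectrum decays with frequency
(low-frequency dominant) and its topography is focal. Ten percent of the
regions form the "zone": they load strongly on the IED source and receive
an acausal HRF peaking near -5 s, while background regions get a causal
canonical HRF. Additive Gaussian noise enters both modalities at 10 dB by
default, and a raw multichannel EEG trace with 0.3-s biphasic template
spikes (amplitude 4 background standard deviations — annotated discharges
are prominent transients) at the spike-train times is emitted for
end-to-end testing of the Wiener filter.

What the generator deliberately does *not* emulate: volume-conducted EEG
from realistic leadfields, nonlinear neurovascular coupling, scanner
artifacts, and physiological noise spectra. Passing tests on these data
therefore demonstrate correctness of the estimation machinery under the
model's own assumptions — parameter recovery, calibration of the error
rates, identifiability — not clinical performance on real recordings.

# Problem sizes used in the checks

The automated checks run at deliberately modest sizes — large enough for
the statistical claims to be meaningful, small enough to rerun casually:
the null-calibration study uses 200 Monte
Carlo datasets with 250 surrogates each; signature/HRF recovery runs 10
seeds at `Is = 300, Iv = 50`; the end-to-end study runs 10 seeds of the
default synthetic session over candidate ranks 1-3 with 3 restarts per
rank. The optimizer's own defaults (50 restarts, ranks 1-5) remain the
recommended settings for real analyses.

# Numerical details and edge cases

* Degenerate inputs: constant spectrogram fibers are zeroed with a
  warning; constant HRF waveforms get extremity 1; `Rnn` singular without
  shrinkage raises an actionable error; rank-deficient local designs fall
  back to the pseudo-inverse with a warning.
* Ties: component selection and top-k ranking break ties by the lowest
  index and say so.
* Multi-run sessions are concatenated in time, as-is; the few samples
  whose HRF convolution spans a run boundary are accepted (an option to
  mask them from the fMRI fit term would be the rigorous alternative and
  is noted as a limitation).
* Reproducibility: every stochastic step takes a seed; the pipeline
  spawns per-stage seeds from one master seed, and the surrogate
  generator is bit-reproducible.

# Known limitations

* The rank-selection heuristic, like any, can be ambiguous when sources
  have similar energy; the score table should be inspected rather than
  trusted blindly.
* HRF polarity in the fMRI factors is intrinsically ambiguous; activation
  and deactivation maps can swap in regions where the calibration picked
  the wrong sign. The deviance metrics are immune by construction and the
  deactivation maps should be read with this caveat.
* The entropy metric's absolute values depend on the declared density
  model; only the induced ranking of regions is meaningful.
* Parcel-level analysis inherits partial-volume effects from the atlas.
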