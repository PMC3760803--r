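---
title: "Noise-aware total-variation regularization of the diffusion tensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-aware total-variation regularization of the diffusion tensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvdti)
```

## The problem

High-resolution diffusion-weighted imaging (DWI) buys its spatial detail
with signal: at 1 x 1 x 2.5 mm voxels the SNR of a single acquisition is
low, and the diffusion tensors fitted from it are noisy enough to break
streamline tractography — fibers terminate early wherever noise tips the
principal eigenvector past the tracker's turning-angle threshold.
Averaging more acquisitions helps but multiplies scan time.

`tvdti` implements an alternative: denoise the *fitted tensor field*
directly with edge-preserving total-variation (TV) regularization, with a
regularization strength that is chosen automatically, per voxel and per
tensor element, from the noise actually present in the data. The noise
estimate comes from the DWI data themselves via independent component
analysis (ICA), so no extra calibration scan is needed.

The processing chain is:

1. **ICA noise split** (`denoise_series`): per axial slice, the N
   direction images are decomposed into N independent spatial components;
   spatially structured components are tissue/diffusion signal, spatially
   white ones are noise. Zeroing one group and inverting the mixing yields
   a denoised series S and a matched noise series e with S + e equal to
   the input exactly.
2. **Tensor fit and noise projection** (`fit_tensor`,
   `fit_noise_tensor`): the standard log-linearized Stejskal–Tanner
   least-squares fit, S_i = S0 exp(-b g_i' D g_i), solved per voxel by the
   cached pseudoinverse of the 6-column design matrix. The noise series is
   pushed through the same linear operator via the first-order
   perturbation of the log, y_i = -e_i/(b S_i), giving a *noise tensor*:
   per-element noise maps in tensor space.
3. **Spatially adaptive TV regularization**
   (`regularize_tensor_field`): a Chambolle-type dual projection solver,
   lifted to the six tensor channels, smooths each slice while the local
   noise variance of each element (5 x 5 moving window over the noise
   tensor) steers how hard each element is smoothed at each voxel.
4. **PSD repair** (`enforce_psd`): negative eigenvalues produced by noise
   or smoothing are clamped to zero, eigenvectors untouched.
5. **Tractography and metrics** (`track_streamlines`,
   `tract_metrics`): a deterministic FACT-style tracker and the four
   summary metrics — mean length (ML), track count (TC), volume (V),
   voxel count (VC) — used as the evaluation surface.

## The TV solver and the automatic regularization tensor

The scalar Rudin–Osher–Fatemi (ROF) problem is solved in its dual form:
for smoothing scale $\lambda$ (units of the data), $u = f - \lambda\,
\mathrm{div}\,p$ where the dual field $p$, $|p|\le 1$, is iterated with
the semi-implicit fixed point

$$p \leftarrow \frac{p + \tau\,\nabla(\mathrm{div}\,p - f/\lambda)}
{1 + \tau\,|\nabla(\mathrm{div}\,p - f/\lambda)|},$$

which is stable for dual step $\tau \le 1/8$ in 2D (forward-difference
gradient, Neumann boundary, negative-adjoint divergence). When the noise
level $\sigma$ is known, $\lambda$ need not be chosen by hand: the
discrepancy principle asks for $\|u - f\|_2 = \sigma\sqrt{N}$, and the
update $\lambda \leftarrow \lambda\,\sigma\sqrt N / \|u-f\|_2$ at each
outer iteration drives the residual to that target. `chambolle_scalar`
implements this loop; `rof_reference`, an independent projected-gradient
solver of the same objective, exists purely to cross-check it.

For tensor fields the data term is weighted per voxel and per element.
The six channels are coupled through a joint Frobenius gradient norm (the
vector-TV generalization), with off-diagonal channels weighted twice
because they appear twice in the symmetric matrix; `coupled = FALSE`
switches to channel-independent TV for ablation. The smoothing scale of
element $c$ at voxel $x$ is factored as
$\lambda_c(x) = \gamma_c\,\sigma_c(x)$: the local noise standard
deviation $\sigma_c(x)$ (square root of the windowed variance tensor)
fixes the spatial profile, and the global per-element factor $\gamma_c$
is updated by the same discrepancy rule at the slice level. Two design
points are worth recording:

* **Why not a fully local update?** Driving the *windowed* residual to
  the windowed noise level independently at every voxel is unstable at
  edges: TV preserves edges, so edge windows under-shoot their residual
  target, the local rule keeps raising the smoothing there, and the edge
  itself eventually erodes — we observed the tensor RMSE getting *worse*
  than the noisy input under that rule. Factoring the spatial profile out
  of the update keeps the per-voxel adaptivity (more smoothing where the
  noise is stronger) while the discrepancy constraint is enforced where
  it is meaningful, per element over the slice. At convergence the local
  residual RMS still matches the local noise std to within a few percent
  in homogeneous regions; the test suite asserts 10%.
* **Orientation of the reported "regularization tensor".** The exported
  `reg_tensor` attribute holds the per-voxel per-element *fidelity
  weights* $1/\lambda_c(x)$: smaller values mean stronger smoothing, so
  the map is low in high-noise (central) regions and high peripherally.

The initialization $\lambda^0_c(x) = \sigma_c(x)$ is not critical: the
converged residual changes by well under 3% when $\lambda^0$ is scaled
across a 10x range (asserted in the tests). Zero-variance voxels/elements
receive infinite fidelity and pass through unchanged. Defaults: $\tau =
1/8$, 25 inner dual steps per outer iteration, at most 50 outer
iterations or relative solution change below $10^{-4}$, window 5.
Regularization is strictly 2D per axial slice — in-plane voxels are
isotropic (1 x 1 mm) so no grid-spacing weighting is needed, and the
coarser through-plane direction never enters.

## The software phantom

No reference data ship with the package; everything is generated in code.
The reference phantom (`reference_phantom()`) is a 60 x 60 x 20 grid of
1 x 1 x 2.5 mm voxels — the acquisition's voxel anisotropy at desk scale —
holding three orthogonal, non-overlapping rectangular fiber bundles
(lengths 50, 50 and 16 voxels) with white-matter-like eigenvalues
(1.7e-3, 3e-4, 3e-4) mm²/s (FA 0.80) in an isotropic background of
0.7e-3 mm²/s. Bundles must not overlap, because a single tensor cannot
represent crossing fibers.

Noise is injected in tensor space (`make_noise_tensor_field` +
`add_tensor_noise`): zero-mean Gaussian per element with standard
deviation `base_sigma` times a radial gain — `center_gain` at the grid
centre decaying linearly in radius to 1 at the corner radius — emulating
the higher noise observed in central brain regions (coil sensitivity,
parallel-imaging g-factor). Any monotone radial profile would satisfy
that qualitative behaviour; linear is the simplest. The defaults
`base_sigma = 1.5e-4` mm²/s and `center_gain = 3` were fixed from two
physical considerations: centrally the per-element noise (4.5e-4) is a
third of the bundle eigenvalue gap $\lambda_1-\lambda_2$ = 1.4e-3, enough
to tip principal eigenvectors by tens of degrees and fragment tracks, while
peripherally (1.5e-4) tracks mostly survive — the regime in which spatially
varying regularization is actually informative.

For exercising the ICA stage, noise is instead added to the DWI signal
(`add_dwi_noise`, optionally with the same radial gain). The companion
generator `make_smooth_tensor_field` produces a PSD tensor field whose
six element maps follow six distinct in-plane spatial frequencies: a
bundle phantom is piecewise constant over four regions and therefore
spans only ~3 independent spatial patterns after centring, far fewer than
tissue does, whereas the smooth field genuinely exhibits the
six-dimensional signal subspace the ICA split is supposed to find. Its
default DWI noise level in the tests (sigma = 10 at S0 = 1000) keeps
each element's signal modulation (~2-5% of the weighted signal) above the
noise floor while the second-order terms of the exponential stay below
it; outside that window the "six signal components" outcome degenerates
for reasons unrelated to the method (sources below the noise floor, or
genuine higher-order smooth components above it).

What the phantom does *not* emulate: Rician magnitude statistics (noise
is Gaussian in both injection paths), crossing fibers, anatomical
geometry, eddy-current or motion artifacts. Passing tests demonstrate
correctness of the algorithms under the stated model, not performance on
scanner data.

## ICA details

The slice-wise decomposition treats the N direction images as mixtures of
N independent spatial sources. Magnitude-domain real-valued ICA is used
(symmetric fixed-point negentropy iteration, tanh contrast, seeded
initialization, eigen-whitening with a floor on near-null covariance
directions so noise-free data remain decomposable). Because the fixed
point can settle in a poor optimum for unlucky initializations, each
slice is decomposed from five deterministically derived starts and the
solution with the largest log-cosh negentropy is kept — the standard
multi-restart practice, made reproducible by deriving the restart seeds
from the slice seed. Components are
variance-normalized with scale carried in the mixing matrix, so
reconstruction is exact by construction.

Classification is content-based: the mean lag-1 spatial autocorrelation
(x and y shifts) of a component map exceeds 0.2 for spatially structured
(signal) components and sits near 0 for spatially white (noise) ones.
This deliberately avoids hard-coding "the first six components are
signal": component order is arbitrary under permutation, and the
six-signal-component outcome on 12-direction data — six because a
symmetric tensor has six independent elements, regardless of N — remains
a testable prediction rather than an assumption.

## Tractography conventions

The tracker is deliberately minimal and deterministic: seeds at every
voxel centre with FA >= 0.15, nearest-neighbour principal-eigenvector
lookup (FACT-style, no interpolation), step of half the smallest voxel
dimension, bidirectional launch with sign alignment to the previous step,
termination on grid exit, FA below threshold, or turning angle above 45
degrees (the one tracking parameter fixed by the evaluation protocol; the
rest follow common tracker defaults). Streamlines shorter than 10 mm are
discarded, the conventional short-track filter of tract viewers; on the
phantom this filter is what keeps spurious two-step seeds in the noisy
isotropic background from inflating TC and VC, reproducing the
characteristic signature that noise *lowers* TC/VC slightly while
collapsing ML. Total length is capped at 10x the grid diagonal to
guarantee termination. V is defined as VC times the voxel volume in ml,
with voxels collected by supersampled polyline traversal.

## Problem sizes and determinism

The validation suite runs entirely on desk-scale objects: 32 x 32 images
for the solver oracles, the 60 x 60 x 20 reference phantom for fit
exactness and the regularization/tractography experiment (10 noise
realizations, matching the protocol of adding noise from ten
measurements), and 60 x 60 slices for the ICA checks. Every stochastic
step is seeded; the pipeline fans a single master seed out to per-stage
seeds by stage-name hashing, so any stage can be rerun in isolation and
full runs are bit-reproducible from their emitted config.

## Known limitations

* 2D regularization only; a 3D extension would have to weigh the
  anisotropic through-plane spacing and is out of scope.
* The ICA is real-valued on magnitudes; complex-valued raw scanner data
  are not handled.
* The log-linearized LLS fit is unweighted — no RESTORE-style outlier
  handling, no Cholesky-constrained fitting; PSD is restored by
  eigenvalue clamping instead.
* Tract metrics depend on tracker conventions (step, interpolation,
  length filter); comparisons are therefore made *within* the package's
  tracker, never against absolute external values.
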