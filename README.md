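# tvdti

Noise-aware, spatially adaptive total-variation regularization of the
diffusion tensor, for diffusion tensor MRI (DTI) at high spatial
resolution and low SNR.

High-resolution DWI (e.g. 1 × 1 × 2.5 mm voxels) trades signal for
detail: tensors fitted from a single acquisition are noisy enough that
streamline tractography breaks down — fibers terminate wherever noise
tips the principal eigenvector past the tracker's turning-angle
threshold. `tvdti` addresses this by denoising the fitted tensor field
itself with edge-preserving total variation, using a regularization
strength chosen *automatically, per voxel and per tensor element*, from
the noise present in the data:

1. **ICA noise split** — the N direction images of each slice are
   decomposed into independent spatial components; spatially structured
   components are tissue signal, spatially white ones are noise. This
   yields a denoised series Ŝ and a matched noise series ε with
   Ŝ + ε equal to the input exactly.
2. **Tensor fit + noise projection** — the log-linearized
   Stejskal–Tanner least-squares fit `S_i = S0·exp(−b·gᵢᵀDgᵢ)` maps Ŝ to
   the diffusion tensor **D**; pushing ε through the same pseudoinverse
   (first-order perturbation `yε_i = −ε_i/(b·Ŝ_i)`) gives a *noise
   tensor* — per-element noise maps in tensor space.
3. **Adaptive TV regularization** — a Chambolle-type dual projection
   solver (`p ← (p + τ∇(div p − f/λ))/(1 + τ|∇(div p − f/λ)|)`, τ ≤ 1/8),
   lifted to the six tensor channels with a joint Frobenius gradient
   norm. The smoothing scale per element and voxel is
   `λ_c(x) = γ_c·σ_c(x)`: the local noise std σ_c(x) (5×5 moving window
   over the noise tensor) sets the spatial profile, and γ_c is updated
   each iteration by the discrepancy principle
   `γ ← γ·‖σ_c‖/‖u_c − f_c‖` — no hand-tuned regularization parameter
   anywhere.
4. **PSD repair** — negative eigenvalues clamped to zero.
5. **Tractography metrics** — a deterministic FACT-style tracker (45°
   angle threshold) and the four tract metrics ML / TC / V / VC.

A software fiber phantom (tensor-space bundles plus radially modulated
tensor-space noise) makes the whole chain testable end to end without
any external data.

## Worked example

```r
library(tvdti)

# reference phantom: 60 x 60 x 20 voxels of 1 x 1 x 2.5 mm,
# three orthogonal WM-like bundles (FA 0.80) in an isotropic background
ph <- reference_phantom()

# add spatially varying tensor-space noise (3x stronger centrally)
nf    <- make_noise_tensor_field(ph$grid, noise_model(seed = 1))
noisy <- add_tensor_noise(ph$tensors, nf)

# regularize, repair PSD, track, summarize
reg <- regularize_tensor_field(noisy, nf, psd_after = TRUE)
tract_metrics(track_streamlines(ph$tensors))          # noise-free
tract_metrics(track_streamlines(enforce_psd(noisy)))  # noisy
tract_metrics(track_streamlines(reg))                 # regularized
```

which prints

```
ML = 47.6 mm, TC = 2976, V = 7.440 ml, VC = 2976
ML = 21.7 mm, TC = 2149, V = 8.540 ml, VC = 3416
ML = 44.9 mm, TC = 3381, V = 9.543 ml, VC = 3817
```

Noise collapses the mean tract length from 47.6 mm to 21.7 mm — tracks
fragment where the noisy eigenvector field exceeds the 45° threshold —
and drops the track count. After regularization the mean length recovers
to within ~6% of the noise-free value and every metric exceeds its noisy
counterpart, with the noise level never supplied by hand: it was
estimated from the noise field's local variance. The full protocol
(mean ± sd over ten noise draws) is available as
`run_phantom_experiment(n_realizations = 10)`.

For DWI-space data the whole chain is one call:

```r
cfg <- pipeline_config(dwi = "dwi.nii.gz", bval = "dwi.bval",
                       bvec = "dwi.bvec", out_dir = "out", seed = 1)
res <- run_pipeline(cfg)   # denoise -> fit -> project -> regularize -> track
```

A thin command-line wrapper with `phantom`, `denoise`, `fit`,
`regularize`, `track`, `pipeline` and `phantom-experiment` subcommands is
installed at `inst/cli/tvdti`.

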