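---
title: "Denoising fast myocardial perfusion SPECT with an attention-gated GAN: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising fast myocardial perfusion SPECT with an attention-gated GAN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Myocardial perfusion SPECT (MP-SPECT) images blood flow to the heart muscle
from gamma-camera projections acquired over a 180-degree arc. Reducing the
acquisition time per view from the standard 10 s to 1-7 s makes the exam
faster and more comfortable, but the projections become photon-starved and
the reconstructed images noisy. `attspect` implements a
projection-domain deep-learning denoiser for this setting: a conditional
generative adversarial network whose U-Net generator carries
attention-gated skip connections (AttGAN), trained to map fast projection
stacks to their full-time (FT) counterparts, together with everything
needed to exercise it end to end on a desk machine — a synthetic cardiac
phantom cohort, an attenuated parallel-beam projector with its exact
adjoint, Poisson counting noise, binomial count thinning, OS-EM
reconstruction, and the quantitative evaluation protocol (NMSE/SSIM/PSNR
over a cardiac VOI, polar-map intensity ratios, a defect-extent surrogate,
Bland-Altman agreement, joint-histogram regression, paired testing).

Because no clinical cohort ships with the package, every empirical result
it produces refers to the synthetic cohort described below.

## Simulation chain

### Phantom

`make_phantom()` builds each subject as a truncated ellipsoidal shell
(the LV myocardium, uniform uptake 1) inside a soft-tissue body ellipse
(uptake 0.1 of the wall) with two low-attenuation lung regions
(0.04 cm^-1 versus 0.15 cm^-1 soft tissue at 140 keV). Geometry — outer
radius, long-axis ratio, wall thickness, axis tilt — is drawn per subject
from configurable intervals; generation is a pure function of
`(rng_seed, subject_index)`, which the tests verify bitwise. A subject
carries a perfusion defect with probability `defect_fraction`
(default 0.36, matching a typical stress-cohort prevalence); the defect is
a transmural, full-length angular wedge with fractional uptake reduction
("severity") drawn from its own interval. The wedge shape makes the
ground-truth extent — the defect's share of wall voxels, in percent —
essentially equal to its angular share, which keeps the polar-map
surrogate interpretable.

The clinical-scale default grid is 64 x 64 x 24 at 0.6096 cm voxels with
anatomical radii (2.6-3.4 cm). The desk-scale cohort used by the packaged
experiments (`build_cohort()`) is 32^3 at 1.2 cm voxels; at that
resolution an anatomical heart would be about one voxel thick, so the
desk cohort enlarges the myocardium proportionally (outer radius 4-5 cm,
wall 1.7-2.2 cm, i.e. a ~2-voxel wall). This is a deliberate
resolvability choice, not an anatomical claim.

### Projector and noise

`project_op()` is an ideal parallel-beam projector: the volume is rotated
in-plane per view (bilinear interpolation) and summed along one axis, with
optional attenuation weighting `exp(-integral mu dl)` accumulated along
each ray. `backproject_op()` applies the transposed interpolation weights,
so the pair is an exact adjoint (`<Ax, y> = <x, A'y>` to machine
precision) — the property OS-EM needs. The scanner's true CZT geometry,
collimator response and scatter are deliberately out of scope; the
simulation is scatter-free, so the clinical dual-energy-window scatter
correction becomes the identity.

`forward_project()` scales the line integrals so the FT stack's mean
counts per view hits the acquisition spec (default 20,000); the
calibration is optional so that the operator itself stays linear.
`add_poisson()` draws independent Poisson counts per bin. `thin_to_time()`
replaces each bin count n by a Binomial(n, p) draw with
p = target/full time — statistically exactly the sub-acquisition that
truncating list-mode data at a fraction p of the events would give, which
is how the fast scans this package emulates are derived clinically. The
tests verify the thinned stacks' Poisson marginals (variance/mean ratio)
and the two-stage-equals-one-stage composition property.

### Reconstruction

`osem_reconstruct()` is standard ordered-subset EM: 5 iterations, 4
subsets by default, view i in subset i mod 4, subsets processed in order,
uniform positive start, multiplicative updates (non-negativity preserved
by construction), epsilon 1e-12 guarding empty bins — relevant at
1 s/view, where zero-count bins are common. Full-time reference volumes
are post-filtered with an isotropic Gaussian of 0.6 voxel (reflecting
boundaries, so counts are preserved near edges); fast and denoised
reconstructions are evaluated unfiltered, mirroring the clinical protocol
the package follows.

## The network

### Generator

The generator is a 3D U-Net. Each encoding level is one block of
convolution (3x3x3) - batch normalization - ReLU - dropout, with 2x2x2
max-pooling between levels; the deepest block is the bottleneck; the
decoder mirrors the encoder with nearest-neighbour up-sampling, one skip
connection per level, channel concatenation, and the same blocks. A final
3x3x3 convolution with ReLU yields the non-negative output. The level and
filter counts are restricted to the hyper-parameter grid the underlying
study searched (2-5 levels; 8, 16, 24, 32 or 40 base filters).

Two numerical choices deserve notice:

* **Output activation.** ReLU enforces count non-negativity, but a ReLU
  output layer can die: if the pre-activation goes non-positive
  everywhere, the gradient vanishes and L1 training can never revive it.
  We observed exactly this collapse with a zero-initialized output bias;
  the bias therefore starts at 0.1, inside the active region.
* **Internal layout.** Stacks enter the network with the view axis last,
  `(nx, nz, V)`, so the innermost kernel loops run along detector bins.

### Attention gate

For encoder features `x` and up-sampled decoder features `d` at the same
spatial size, the gate computes 1x1x1 projections `g_i = Wg' x_i`,
`f_i = Wf' d_i`, the per-voxel inner product `alpha_i = <f_i, g_i>`, then
ReLU, a 1x1x1 convolution (scalar weight `w`, bias `b`) and a softmax over
the spatial axis, giving an attention map `r` that sums to one; the gated
skip is `Att_i = N r_i x_i`. This is the memory-linear convention used in
training: it costs O(N) rather than the O(N^2) of a dense voxel-pair
inner product, and with `Wf = 0` it degenerates to `r = 1/N`, i.e. exactly
the plain skip — so the attention-disabled network nests the cGAN/U-Net
baseline. The dense voxel-pair formulation
(`alpha_ij = f(d_i)' g(x_j)`, softmax over contributing voxels, output
`sum_i x_i r_ij`) is kept as `attention_gate_dense()`, a brute-force
oracle for small feature maps; its `Wf = 0` closed form is the spatial
mean of `x` broadcast everywhere. The unit tests pin both degenerate
forms and the shared uniform attention map. The gate's `w`, `b` start at
zero, so every gate opens as an identity skip and learns to deviate.

### Discriminator and objective

The discriminator is a PatchGAN-style CNN on the channel-concatenated
(fast, candidate) pair: four strided 3x3x3 convolutions with filters
32 to 256, LeakyReLU(0.2), batch normalization from the second level, and
a 1x1x1 convolution whose spatial mean is the real/fake logit. The
published source of the architecture this emulates did not specify its
discriminator, so this is the standard pix2pix-family choice.

Training minimizes `L_ADV + lambda * L1` over the generator (lambda = 100)
and the non-saturating cross-entropy over the discriminator, with Adam at
an initial learning rate of 1e-4, alternating updates, and the
(fake, real) pairs of a minibatch stacked into one discriminator batch
(batch-norm statistics shared across both halves). With
`adversarial_weight = 0` the discriminator is never built and training is
pure L1 — the U-Net baseline; with `attention_enabled = FALSE` the
generator is the plain cGAN generator. Dose-specific training (one model
per acquisition-time level) is the intended use; `denoise()` warns when a
model meets a stack from a different level.

All of this — convolutions, batch-norm, pooling, gates, backpropagation,
Adam — is implemented in this package (single-precision im2col/offset-gemm
kernels in C++ behind R orchestration). Every layer's analytic gradient is
verified against central finite differences in a double-precision kernel
mode by the test suite.

### Defect conditioning

`AttGAN-def` embeds the subject's binary defect label (0/1) as four
constant slices appended at the tail of the view axis before the
generator; the four label slices are stripped from the generator output
before any loss is computed, and the discriminator sees the stripped
stacks. Where the label block sits, and whether it participates in the
loss, were open choices; both are fixed here (tail; stripped) and recorded
as the package convention.

### Normalization

Projection stacks are normalized to 0-1 before training. Within a
subject, the fast stack is divided by the *full-time* maximum (so a stack
thinned at p = 0.1 peaks near 0.1, preserving the count-level contrast
between input and target); per-stack self-normalization is available
behind a switch. At inference the FT maximum is estimated as
`max(fast counts) / p` unless the true scale is supplied.

## Desk-scale study conditions

The packaged experiments run at a deliberately small problem size chosen
once, as the package's own desk configuration:

* cohort: 50 subjects, seed 7, 32^3 grid, 1.2 cm voxels, defect
  prevalence 0.36, enlarged myocardium as above;
* acquisition: 8 views over 180 degrees, 10 s/view full time, 20,000 mean
  counts per view at FT; fast level 1 s/view (thinning p = 0.1);
* reconstruction: OS-EM 5 iterations / 4 subsets with attenuation, 0.6
  voxel Gaussian post-filter on the FT references only;
* network: 3 levels, 16 base filters, lambda = 100, Adam 1e-4, 50 epochs,
  35/5/10 train/validation/test split per training seed, best-validation
  checkpointing.

Two training-protocol parameters differ from the full-scale architecture
defaults, selected by validation L1 on a held-out split (the same
training-validation procedure the underlying study used for its
hyper-parameters): dropout 0.1 (instead of 0.5) and minibatch size 3.
At 16 filters and 50 epochs, 0.5 dropout injects more noise than the
small network can average out — validation loss never leaves the
predict-zero level — and batches of 5 leave too few optimizer updates
(350) for reliable convergence, while batch 3 (~580 updates) converges
across seeds. The full-scale `generator_spec()` default keeps dropout 0.5.

What passing the packaged experiments shows — and what it does not: the
synthetic cohort has uniform-uptake wedge defects, no respiratory or
cardiac motion, no scatter, no collimator blur, and ideal parallel-beam
geometry. Success here demonstrates that the implementation learns to
restore count statistics and defect contrast under controlled conditions;
it is not evidence about clinical performance.

## Evaluation protocol

All voxel metrics are computed over an 18^3 VOI (5832 voxels) anchored on
the phantom's known LV centroid:

* `NMSE = sum((I_D - I_FT)^2) / sum(I_FT^2)`;
* SSIM as a single global value over the VOI with the constants
  C1 = 0.01, C2 = 0.02 taken exactly as the protocol prints them (the
  conventional `(K L)^2` derivation is *not* applied);
* `PSNR = 10 log10(MAX_FT / MSE)` — the printed formula, whose numerator
  is the reference maximum rather than its square; the standard squared
  convention is available via `convention = "standard"`.

The polar (bull's-eye) map samples, for each axial ring of the LV and
each angular sector, the maximum count along the ray from the LV long
axis — nearest-voxel sampling, because interpolation systematically
under-reads a wall one or two voxels thick. Rings are restricted to
slices where wall and cavity coexist; the solid apex cap has no
meaningful angular structure. The intensity ratio divides the defect-ROI
mean by a normal-ROI mean, with ROIs fixed per subject (from the
ground-truth defect sector) and shared across methods. The defect-extent
surrogate is the percentage of map pixels below 0.6 of the normal-region
mean; it stands in for proprietary clinical defect-size software and is
*not* that algorithm. On noiseless, well-resolved phantoms it tracks the
true extent to about 2.5 percentage points; the residual bias is the
max-profile's edge behaviour (a sector reads normal if any sampled voxel
is normal), which cancels in method-versus-method comparisons made with
the same convention. Bland-Altman limits are mean difference ±1.96 SD;
joint regression is ordinary least squares of test on reference voxels
with R^2 the squared Pearson correlation; the paired test is the
two-tailed paired t with Bonferroni multiplication (degenerate
zero-variance differences yield p = 1 for identical samples, p = 0
otherwise, with a warning).

Every metric is cross-checked in the tests against an independently coded
brute-force implementation on random inputs at 1e-10 relative tolerance.

## Cross-validation harness

`make_folds()` shuffles the cohort once (seeded) and cuts five contiguous
test blocks, so the five test sets partition the subjects exactly; within
each fold the remainder splits 35/5 into training and validation. The
assignment mechanism of the original protocol is unspecified; the seeded
shuffle is this package's choice. `run_experiment()` trains per fold,
time level and method, refuses test subjects that appear in a model's
recorded training ids, reconstructs denoised stacks without post-filter,
and emits one tidy row per subject, method, time level and metric. The
`identity` method passes the fast stack through untouched and reproduces
the raw fast-SPECT metrics bit-identically — the pipeline-wiring check.
Hyper-parameter searches over the grid are done once on the first fold's
validation split, not nested per fold.

## Known limitations

* The simulation omits scatter, collimator-detector response, motion and
  the real fan-beam CZT geometry; absolute metric values are not
  comparable to clinical numbers.
* The desk cohort's enlarged heart and 8-view arc trade realism for
  runtime; the full-scale configuration (64-grid, 60 views, 400 epochs)
  is expressed by the same code but is not exercised by the tests.
* The defect-extent surrogate and the simplified polar map are documented
  stand-ins for clinical quantification software and 17-segment
  rendering.
* Adversarial training at this scale is stochastic across seeds; the
  packaged experiment quantifies that spread rather than hiding it (the
  headline property is asserted over 10 training seeds).
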