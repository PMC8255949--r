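---
title: "Tomographic reconstruction as modular convex optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tomographic reconstruction as modular convex optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomopt)
```

## The problem

Computed tomography measures line integrals of an unknown attenuation image
$u$: a parallel beam scans the object at a set of rotation angles, and each
detector element records (after flat-field normalisation and the
Lambert-Beer negative logarithm) one sample of the Radon transform.
Discretized, acquisition is the generic linear inverse problem

$$ A u = b, $$

with $A$ the discretized Radon transform (forward projection), $b$ the
measured sinogram and $u$ the voxelized image.  Filtered back-projection
(FBP) inverts this analytically and is exact for dense, low-noise,
uniformly sampled data — but degrades badly on few-view, noisy or
non-standard acquisitions.  The alternative pursued here is to state the
reconstruction as a convex optimization problem that combines a data
fidelity with prior knowledge (smoothness, sparsity, bounds) and to solve
it with first-order methods.  `tomopt` provides the building blocks —
geometry-aware data containers, linear operators with adjoints, convex
functions with gradients and proximal mappings, and iterative solvers —
so that a problem such as total-variation-regularized least squares

$$ u^\star = \arg\min_u \; \|A u - b\|_2^2 + \alpha \|D u\|_{2,1} $$

is assembled from parts rather than implemented as a monolith.  Everything
is exercised on synthetic phantoms generated by the package itself.

## Data model

`acquisition_geometry()` records beam type, angles (degrees by default,
counterclockwise; the convention is ours to fix since either is
workable), detector pixel counts and pitches, and the rotation-axis
offset.  `image_geometry()` records the voxel grid.  Data containers
(`allocate()`, `as_tomo_data()`) attach a dense array to a geometry with
named axes — canonical order `(angle, vertical, horizontal)` for
acquisitions and `(vertical, horizontal_y, horizontal_x)` for images, 2D
dropping `vertical` — so that subsetting (`get_slice`,
`slice_axes`) and permutation (`reorder_dims`) are label-driven rather
than positional.  Algebra (`+`, `-`, `*`, `/`, `exp`, `log`, `abs`,
`mean`, `dot`, `l2norm`) never touches geometry metadata.
`block_data()` groups containers so that stacked objects like the
Tikhonov right-hand side $(b; 0)$ and gradient images inherit the same
algebra; inner products sum over blocks.

ROI arguments use 1-based inclusive `(start, stop, step)` ranges, the
natural R convention (a language-agnostic statement of the same pipeline
in 0-based half-open form keeps identical element counts).

## Operators and the adjoint contract

Every `linear_operator` supplies `op_direct()` and `op_adjoint()`, and the
package's load-bearing invariant is the adjoint identity
$\langle A v, z\rangle = \langle v, A^* z\rangle$, tested at $10^{-6}$
relative tolerance for every operator kind on random pairs.  The native
parallel-beam projector is ray-driven with Joseph-style bilinear
interpolation (sampling step = smallest in-plane voxel pitch,
length-weighted), and the back-projector is the *exact transpose* of that
discretization rather than an independently discretized operator.  A
matched pair costs some smoothing relative to unmatched pairs but makes
the convergence theory of CGLS, FISTA and PDHG actually apply to the
discrete problem — the standard trade, and the one we take.  3D
parallel-beam data is projected slice by slice; cone-beam geometries are
representable (for metadata round trips) but deliberately not projected.

Coordinates: voxel centres, origin on the rotation axis plus `center_*`
offsets; detector coordinate $s$ increases with $+x$ at $\theta = 0$ and
the ray through $s$ is $\{x\cos\theta + y\sin\theta = s - \delta\}$ with
$\delta$ the rotation-axis offset.  The sign and orientation conventions
are a gauge; what matters (and is tested) is that the projector, the
centre-of-rotation estimator and FBP agree on them.

`block_operator()` arranges operators in a grid (rows share ranges,
columns share domains), giving the Tikhonov stack $(A; \alpha D)$ and the
PDHG operator $K = (A; D)$; nesting is allowed, and `gradient_operator()`
is itself a stack of per-axis finite differences (forward differences,
Neumann boundary: last entry of each axis is zero).
`operator_norm()` estimates $\|A\|_2$ by power iteration on $A^*A$ with a
seeded start, used for default step sizes.

## Functions, proximal mappings, total variation

A `tomo_function` carries whatever calculus exists: `value`, `gradient`
with Lipschitz constant $L$, the proximal mapping
$\mathrm{prox}_{\tau g}(u)$, the conjugate value and the conjugate prox.
Closed forms are used where they exist (soft-thresholding for $\ell_1$,
linear shrink for squared $\ell_2$, per-voxel vector shrinkage for the
mixed $\ell_{2,1}$ norm, clipping for box indicators, a quadratic root
for Kullback-Leibler); the conjugate prox falls back on the Moreau
identity otherwise.  Choices worth recording:

* **Kullback-Leibler.** The count-data divergence
  $\sum_i (v_i + \eta_i) - b_i + b_i \log(b_i/(v_i+\eta_i))$ with
  background $\eta$ (default 0) and the convention $0\log 0 = 0$.  The
  field's PET-style definition; only the name is fixed by convention
  elsewhere, so the formula is stated here and tested via the Gibbs
  inequality, a finite-difference gradient check, and the prox
  characterization inequality.
* **Total variation.** Isotropic coupling
  $\|Du\|_{2,1} = \sum_v \sqrt{\sum_k (D_k u)_v^2}$ with Neumann
  differences.  `tv_proximal()` solves the denoising subproblem by fast
  gradient projection (FGP) on the dual: dual step $1/(4d\lambda)$ for
  $d$ differenced axes ($\|D\|^2 \le 4d$) and $\lambda = \alpha\tau$,
  FISTA momentum on the dual variables, optional nonnegativity projection
  of the primal, stopping on `inner_iters` (default 100) or relative dual
  change below `tol` (default 1e-5).  Dual variables are warm-started
  across outer FISTA iterations (stored inside the `total_variation()`
  closure), which is what makes FISTA-TV affordable.  The default inner
  budget is our own; no parity with any particular implementation is
  claimed, and the mapping is verified against a long-run (1e5
  iterations) *non-accelerated* dual solver on small images.
* **Smoothed TV.** `smooth_l21_norm(beta)` replaces the voxel norm by
  $\sqrt{\cdot + \beta^2}$, making the objective $L$-smooth with
  $L = \alpha/\beta$, so plain gradient descent applies.

## Solvers

All solvers return a resumable state: `run_more(state, m)` after
`run_*(..., max_iters = n)` is bit-identical to `n + m` iterations in one
call, which the suite asserts for CGLS, SIRT, GD, FISTA and (fixed-step)
PDHG.  Objective histories (plus dual and gap for PDHG) are recorded and
exportable as CSV.

* **CGLS** minimizes $\|Au-b\|_2^2$ on the normal equations without
  forming $A^*A$; on noisy data it semi-converges, so the iteration count
  is the regularization parameter (the suite verifies an interior error
  minimum over 100 iterations at 5% noise).
* **SIRT** iterates $x \leftarrow P_{[l,u]}(x + D A^*(M(b - Ax)))$ with
  row/column-sum weights obtained by applying $A$, $A^*$ to ones; zero
  sums get zero weight with a warning.  Box bounds hold at every iterate.
* **GD** supports a constant step (default $1/L$) or Armijo backtracking
  (shrink 0.5, slope $10^{-4}$, trial step 1 each iteration).
* **FISTA** uses $t_{k+1} = (1+\sqrt{1+4t_k^2})/2$ momentum and step
  $1/L$.
* **PDHG** uses $\theta = 1$ and defaults
  $\sigma = \tau = 1/\|K\|$ — the conservative standard choice given that
  only the bound $\sigma\tau\|K\|^2 \le 1$ is dictated by theory; the
  bound is checked and violation is an error.  When $g = 0$ the reported
  dual objective is the unconstrained surrogate $-\sum_i f_i^*(y_i)$
  (the feasibility term $K^*y = 0$ is relaxed), so the reported gap can
  be negative early; it is the trend to zero that certifies convergence.

## FBP baseline

`filter_sinogram()` applies the $|\nu|$ ramp (optionally Shepp-Logan
apodized) in the frequency domain with zero-padding to the next power of
two at least twice the detector width.  `fbp_reconstruct()` weights each
projection by its angular gap in radians — the half-gap rule reduces to
$\pi/n$ for equispaced views over 180° and handles golden-angle sets
without special casing — back-projects with the matched adjoint and
divides by the voxel pitch, which converts the discretized adjoint into
true backprojection (the adjoint of the sampled ray integral carries an
extra factor of the voxel area over the detector pitch).  The constant is
not free: FBP of an analytic disc sinogram must recover amplitude ≈ 1,
and the suite asserts ≥ 25 dB self-consistency at 128², 180 views.  Ramp
filtering of a constant projection leaves $O(1/\text{width})$ box-edge
leakage inside the window; the DC-removal test therefore examines the
interior of a realistic 512-wide detector.

## The synthetic world

The generator states a world and stays there:

* **Geometries.** The running 3D example is 91 projections over 180° on a
  160×135 panel (so the last projection mirrors the first, which the
  slicing chain drops: 91 → 90 → every 6th → 15).  The golden-angle
  example uses 186 views at steps of $(\sqrt 5 - 1)/2 \cdot 180° =
  111.246°$.
* **Phantoms.** `disc` (analytic chord length $2\sqrt{r^2 - s^2}$ for
  calibration), `steel_wire_like` (low-value host cylinder, eccentric
  high-value wire, three zero-value bubbles), and `rods` (host cylinder
  with 10 circular inserts of distinct values in two rings, emulating a
  metal-rod resolution sample).  Objects are rendered with 4×4
  partial-volume supersampling so a discretized disc projects
  rotationally faithfully — a hard indicator on a 64² grid would show
  ~1.5% angular anisotropy that says nothing about the projector.
* **Noise.** Gaussian with stated $\sigma$, or Poisson counting noise:
  counts $\sim \mathrm{Pois}(I_0 e^{-y})$ mapped back through
  $-\log(\mathrm{counts}/I_0)$ with zero counts floored at 0.5 counts
  (the floor is a stated, configurable convention; the source experiment
  never meets zero counts at the chosen $I_0$).  For the rods experiment
  the attenuation scale is `v_max = 0.05` per unit pitch on a 48² grid,
  putting peak optical depths near 1.5 — the regime of the neutron data
  it emulates — and $I_0 = 10^4$ counts.  Seeds are mandatory and all
  randomness is reproducible from them.
* **What a green test does not establish.** The phantoms are 2D/stacked
  2D, noise is pixelwise independent, and there are no rings, beam
  hardening, scatter or detector crosstalk; agreement at desk scale does
  not certify numeric parity with any external dataset or any particular
  plugin projector discretization.

## Scaled-down validation experiments

The published-scale experiments are reproduced as desk-scale analogues in
`tests/testthat/test-acceptance.R`:

* FISTA(LS + $\alpha$TV) vs PDHG on a 32² phantom with 15 views: final
  objectives within 0.5%, solutions within 1% RMS, PDHG gap below $10^{-3}$
  of its first-iteration value.
* The rods/golden-angle/Poisson pipeline on a 48² grid: PDHG-TV (weight
  chosen on a short-run log grid) improves PSNR over FBP by ≥ 2 dB, and
  gradient descent on smoothed TV ($\beta = 10^{-3}$) matches PDHG-TV
  within 2% RMS.  Both solvers are warm-started from the FBP
  reconstruction — initialisation does not change the minimizers being
  compared and keeps the iteration budgets honest on one CPU.

## Numerical choices and degenerate inputs

* Containers store doubles in memory; TIFF output is 32-bit float (the
  format's scientific default), and round trips are bit-exact at that
  precision.  Inner products accumulate in double.
* Geometry equality uses $10^{-9}$ absolute tolerance per numeric field.
* `normalise()` guards $|flat - dark| < 10^{-8}$ pixels (set to 1,
  counted in a warning); `negative_log()` floors at `clip_floor`
  ($10^{-6}$ default) and counts floored entries.
* The centre-of-rotation estimator needs an opposing pair within 0.1°; it
  uses *normalized* cross-correlation (plain correlation is
  brightness-biased) of the central row against the flipped opposing row,
  with 3-point parabolic sub-pixel refinement, and half the argmax lag is
  the offset.  Flat profiles and missing pairs are errors, not guesses.
  The estimate is written into the geometry (consumed by the projector
  and FBP) instead of resampling the data, avoiding interpolation loss.
* Binning uses the mean, not the sum, so transmission data stays in
  $[0, 1]$; remainders are dropped.
* `operator_norm` of the zero operator is 0 by convention; PDHG refuses
  step sizes violating its bound instead of silently diverging.

## Known limitations

Cone-beam projection (and hence FDK/laminography reconstruction),
ring-artefact removal, multi-channel data, TGV/symmetrised gradients and
stochastic or ADMM-type splitting solvers are out of scope.  The CLI
reads only the package's own TIFF/HDF5 dialects; vendor formats are not
parsed.  The projector is single-threaded C++; it is sized for desk-scale
experiments, not beamline volumes.

## File formats and CLI

TIFF stacks (one 32-bit float file per projection/slice, 5-digit
suffixes, YAML geometry sidecar) and a minimal fixed-tree HDF5 container
(`/entry1/tomo_entry/data/data` plus `/entry1/tomo_entry/config/*`)
round-trip data and geometry; the HDF5 dialect aims at self-consistency,
not full NXtomo compliance.  The `tomo-opt` executable
(`exec/tomo-opt`) drives `simulate`, `preprocess`, `recon`
(`fbp`, `cgls`, `sirt`, `fista-tv`, `pdhg-tv`, `gd-stv`) and `metrics`
from a YAML configuration and can log objective histories to CSV.

```{r example, eval = FALSE}
ag <- acquisition_geometry("parallel2D", angles = seq(0, 178, by = 2),
                           pixel_num_h = 64)
ig <- default_image_geometry(ag)
phantom <- make_phantom(phantom_spec("steel_wire_like", 64, seed = 1))
sino <- simulate_acquisition(phantom, ag,
                             noise = list(type = "gaussian", sigma = 0.75,
                                          seed = 7))
rec_fbp <- fbp_reconstruct(sino, ig)

A <- projection_operator(ig, ag)
D <- gradient_operator(ig)
K <- block_operator(list(A, D), nrow = 2)
f <- block_function(l2sq_norm(b = sino), mixed_l21_norm(1))
fit <- run_pdhg(f, K, x0 = rec_fbp, max_iters = 1500)
psnr(fit$x, phantom)
```
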