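---
title: "Streaming tomographic reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming tomographic reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomostream)
```

## The problem

Single-axis electron tomography reconstructs a 3D density volume $x$ from a
tilt series $b$: projection images acquired while the specimen rotates about
a fixed axis over a restricted angular range (typically within $\pm 75°$).
Because alignment and iterative reconstruction are traditionally run offline
after acquisition, structural feedback arrives hours late. This package
implements the headless core of a *live* pipeline: projections are ingested
as files appear in an acquisition directory, appended to a running solver
without restarting it, and consistent intermediate volumes are published for
a consumer while the solver keeps iterating.

## Geometry and the operator pair

Conventions, fixed package-wide: the volume is indexed $(y, x, z)$ with the
tilt (rotation) axis along $y$ and the beam along $+z$ at $0°$; angles are
degrees, counter-clockwise about $+y$, accepted on the closed interval
$[-90°, 90°]$; pixels are 0-based with centers on integer coordinates and
rotation about the slice center $((n_x-1)/2,\,(n_z-1)/2)$; detector bin
count equals $n_x$ at magnification 1.

The measurement operator $A$ acts independently on each $y$-slice: one
parallel ray per detector bin, sampled at unit-voxel steps with bilinear
interpolation in the $(x,z)$ plane (a nearest-neighbour kernel is available;
it is useful for analytic checks because column sums become exact ray
lengths). The adjoint scatters the *same* interpolation weights, so the pair
is matched: $\langle Au, v\rangle = \langle u, A^{T}v\rangle$ holds to
rounding ($\sim 10^{-17}$ relative in the test suite). A matched pair is a
deliberate choice — unmatched forward/backprojector pairs break the descent
guarantees that the solvers below rely on. Out-of-support samples contribute
zero. Because unit-spaced sampling of the linear B-spline kernel forms a
partition of unity, straight rays through a unit cube reproduce exact chord
lengths, and projection mass is conserved to better than 0.5 % for phantoms
supported away from the boundary.

## Reconstruction engines

**WBP.** Per $y$-slice the sinogram is filtered along the detector axis by a
frequency-domain ramp $|f|$ (normalized to 1 at Nyquist; optional Hamming
apodization), backprojected with $A^T$ and scaled by $\pi/(2\,n_{\rm
angles})$. Rows are padded to the next power of two $\ge 2 n_x$ with *edge
replication* rather than zeros: a constant row then stays constant on the
whole circle and the nulled DC bin removes it exactly, while compactly
supported projections behave exactly as zero-padded. This keeps the filter
linear, exactly DC-free, and leaves a fully sampled disc phantom at NRMSE
$\approx 0.077$ inside its support. Slices are emitted in increasing $y$, so
a live consumer watches the volume grow along the tilt axis.

**SIRT.** Implemented as plain gradient descent on $\|Ax-b\|_2^2$,
$$x_{k+1} = x_k - \frac{s}{L}\,A^T(Ax_k - b),$$
with $L = \|A^TA\|_2$ estimated by the power method and a safety factor $s$
(`stepSafety`, default 0.95) so the step always sits inside the stable
region. We chose the Lipschitz-stepped form over the classical
row/column-sum-preconditioned SIRT because the step-size machinery for
dynamic extension (below) is naturally expressed in terms of $L$; on our
geometries the preconditioned variant converges no faster. Fresh runs start
from $x_0 = 0$ — reproducible, and it makes the iterate converge to the
*minimum-norm* least-squares solution on consistent data. The normalized
residual $\|Ax_k-b\|_2/\|b\|_2$ is recorded once per iteration (it is
guaranteed non-increasing for a convex quadratic at this step size) and is
the quantity a user should watch for convergence.

A caveat the tests make explicit: convergence *toward* the minimum-norm
solution is geometric per singular mode with rate $(1 - s\,\sigma_i^2 /
\sigma_{\max}^2)$. For an 8-angle $\pm70°$ geometry the spectrum of $A$
reaches $\sigma_{\min}/\sigma_{\max} \sim 4\times10^{-3}$, so the slowest
identifiable modes need thousands of iterations; after 500 iterations the
iterate still differs from the pseudoinverse solution by several percent
even though the data residual is $\sim 10^{-3}$. This is intrinsic to
limited-angle sampling, not to the implementation.

**TVmin.** Volumes of physical specimens are approximately piecewise
constant, so we regularize with the isotropic total variation
$\|x\|_{TV} = \sum_v \sqrt{\Delta_x^2+\Delta_y^2+\Delta_z^2+\epsilon^2} -
\epsilon$ (forward differences, one-sided at boundaries; `tvEpsilon`
default $10^{-8}$ smooths the norm at zero gradient). Each outer iteration
alternates (i) one SIRT data step followed by a nonnegativity clip
(densities are physical) and (ii) `tvDescentSteps` (default 10) steps of
normalized TV-gradient descent whose length is the data-step magnitude
multiplied by a **dampening envelope** that decays *linearly* from
`tvStepAlpha0` (default 0.2) to `tvStepAlphaMin` (default 0) over
`maxIters` iterations:
$$\alpha(k) = \alpha_0\,(1 - w_k) + \alpha_{\min} w_k,\qquad
w_k = \min(k, k_{\max})/k_{\max}.$$
Early iterations therefore smooth aggressively while late iterations let
the data term dominate. With $\alpha_0 = 0$ the trajectory is bitwise
identical to SIRT under the same configuration — a structural identity the
suite asserts. The residual is recorded after the data step (before the TV
steps), and the TV value after the TV steps.

Because the plain least-squares solver must converge to the (generally
signed) minimum-norm solution while the TV solver clips at zero, the
nonnegativity clip is a configuration flag: `nonneg` defaults to `TRUE` for
`tvmin` and `FALSE` for `sirt`, and either solver honors whatever the
shared config says — that is what makes the bitwise-equivalence comparison
well defined.

## Dynamic extension

When a projection arrives mid-run the operator gains rows, so the safe step
shrinks. `extendState()` keeps the current iterate as a warm start,
re-estimates $L$ with the power method warm-started from the stored
eigenvector, and resets the step to `stepSafety / L`. Warm-starting gives a
useful monotonicity guarantee: the Rayleigh quotient of the enlarged
$A^TA$ at the old eigenvector is at least the old estimate, and power
iterations only increase it, so the reported $L$ never decreases when rows
are appended. WBP needs no descent parameters; its extension contract is
full recomputation, bitwise identical to a batch run on the full series.

## Alignment

Projections must share a consistent origin before reconstruction. For an
isolated object whose projected mass is fixed across tilts, the projected
center of mass $x_{CM} = \sum_i x_i\rho(x_i)/\sum_i \rho(x_i)$ traces a
circle centered on the rotation axis, so the per-projection $x$-CoM belongs
at the detector center and the $y$-CoM (along the tilt axis) is
angle-invariant. `comAlign()` therefore corrects $x$ toward the detector
center and $y$ toward the across-angle mean $y$-CoM. One consequence worth
stating: a rigid global $y$-offset of the whole series is unobservable from
projections, so only the mean-free part of injected $y$-jitter is
recoverable — the recovery tests compare against exactly that identifiable
component, and recover it to machine precision on noiseless phantoms.
Because the CoM is sensitive to background, a constant background estimated
as the mean of the outermost border frame (`borderFrac`, default 0.05 of
each dimension) is subtracted first and negatives are clipped; the border
frame was chosen over histogram- or corner-based estimators for
determinism. The rotation-axis offset is the across-angle mean of
$(x_{CM} - \text{detector center})$, recovered to well under half a pixel
across offsets in $[-8, 8]$ px.

For non-isolated fields of view `xcorrAlign()` registers consecutive
projections by the frequency-domain correlation peak (integer precision —
subpixel upsampling is deliberately out of scope) and accumulates shifts
relative to the lowest-|angle| projection, the frame closest to untilted
and hence the least foreshortened reference.

## Streaming and the snapshot contract

The watcher polls the acquisition directory (default 1 s; polling was chosen
over OS notification hooks for determinism and portability) and emits one
event per file whose size is unchanged across two consecutive polls — a
write-completion guard against ingesting half-written images. Angles come
from a sidecar angle list indexed by the filename's sequence prefix when one
is present, else from the last signed decimal token in the filename; a file
whose angle cannot be parsed is skipped with a warning, never a crash. A
re-acquired angle replaces the stored projection (latest wins).

Publishing an intermediate volume uses a triple-buffer contract: the solver
owns the working copy; consumers read the published copy; a transient
staging copy is made only at an iteration boundary and then swapped in. The
peak number of live full-volume copies is therefore exactly three, and every
snapshot corresponds to a completed iteration whose recorded residual can be
reproduced from the snapshot volume and the projections present at that
time (the suite checks agreement to $10^{-6}$). Snapshot cadence is
`updateEvery` (default 1) iterations for iterative solvers and one slice
for WBP.

## The synthetic module

The generator exists so that every stage is testable with known ground
truth. Defaults emulate the acquisition conditions the pipeline targets: a
$-64°..+71°$ grid at $1°$ (136 projections — an asymmetric missing wedge),
$64^3$ phantoms, and a scaled-Poisson dose model (counts
$\sim\mathrm{Pois}(d\cdot I/\max I)$ rescaled to the original intensity
scale) with a realistic peak dose of order $10^3$ counts/px when noise is
requested. Phantoms: random non-overlapping **spheres** (piecewise-constant
density, the TV-friendly case), a chiral **helix** (a tube of spheres whose
handedness flips bitwise under an $x$ mirror — handedness is exactly the
property that needs 3D data to determine), a periodic Gaussian-blob
**lattice** (its $1/\text{period}$ spectral peak mirrors FFT-based checks of
atomic-resolution data), plus an **impulse** and a **disc** for point-spread
and filter fidelity. Corruptions (shift jitter, axis offset, Poisson dose)
are fully seeded, and the generator returns the injected truth so alignment
is validated by parameter recovery, not by eyeballing.

What the generator does *not* emulate: physics-based STEM contrast (probe
convergence, detector geometry), alignment-breaking mass loss or beam
damage, in-plane rotations, and non-rigid drift. Passing tests therefore
demonstrate correctness of the numerics and the streaming contracts, not
robustness to every experimental pathology.

## Problem sizes and numerical choices

The suite and the acceptance script run phantoms of $16^3$–$32^3$ with
10–46 angles (plus a $128^2$ single-slice disc with 360 views and one
136-projection watcher stress case), sizes at which dense oracles
(pseudoinverse, full eigendecomposition) are computable for cross-checks.
Tolerances: adjoint consistency $10^{-6}$ relative (measured $10^{-17}$);
power-method Lipschitz within 1 % of the dense eigenvalue (measured
$10^{-10}$) with 50 iterations / $10^{-6}$ Rayleigh tolerance as the
runtime default; TIFF storage is min–max scaled 32-bit samples with the
affine scale in a JSON sidecar (round trips exact to $\sim2^{-32}$ of the
range), while the raw-binary container is bit-exact at its stored (default
float32) precision. Degenerate inputs have defined behavior: all-zero
profiles raise a degenerate-profile error naming the projection; $b = 0$
is a fixed point of SIRT with an all-zero residual history; a constant
volume exports mid-gray orthoslices with a warning; an empty directory run
returns an iteration-0 state.
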