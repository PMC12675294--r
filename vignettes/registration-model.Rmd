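---
title: "Auto-decoded stationary-velocity-field registration of vascular surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auto-decoded stationary-velocity-field registration of vascular surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vascuflow)
```

## The model

`vascuflow` registers a cohort of closed vascular surfaces
$\{\mathcal S_i\}_{i=1}^{N_s}$ to a fixed template $\mathcal T$. Every
surface is reduced to a weighted point cloud: cell centroids with
normalized cell areas as weights. Isolated points thus carry large weight,
densely triangulated regions small weight, which keeps area-weighted
measures meaningful on unevenly refined meshes.

The per-shape deformation is the time-1 flow of a stationary velocity
field,
$$\partial_t \varphi_i(x;t) = v\!\left(\varphi_i(x;t);\Theta, z_i\right),
  \qquad \varphi_i(x;0)=x,$$
with a single network $v$ shared across the cohort and a per-shape latent
code $z_i \in \mathbb R^{N_z}$. Because $v$ is fully connected with
Leaky-ReLU activations it is globally Lipschitz, the ODE has a unique
solution, and the resulting map is a diffeomorphism with the backward-time
flow as its inverse. This is the *auto-decoder* arrangement: the codes are
trainable inputs, not encoder outputs, so the model has roughly half the
parameters of an encoder–decoder and unseen shapes are handled by a small
test-time optimization over $z$ alone.

### Conditioning

Codes enter position-awarely: $z_i$ is reshaped (row-major, documented in
`reshapeCode`) onto a $g_z\times g_z\times g_z$ grid of channel vectors
whose nodes sit at the corners of the unit cube (for the default
$g_z = 2$), and the network is fed the trilinear interpolation
$\bar z_i(x)$ of that grid at the query point. Conditioning therefore
varies smoothly in space while the input dimension drops from $N_z$ to
$N_z/g_z^3$.

### Network

$v = F_{DF}\big(F_{FPE}(F_{FA}(x,\bar z)),\ \bar z\big)$:

* **FA-NN** — a shallow feature-augmentation net (default 3 layers of
  width 64). Its published description composes the three blocks in the
  reverse of the data-flow order; we implement the data-flow order
  (FA first) and note the published form as a notation slip.
* **FPE** — deterministic Fourier features per channel:
  $[u, \sin 2^e\pi u, \cos 2^e\pi u]_{e=0..N_e-1}$, width
  $(2N_e{+}1)N_{FA}$ (448 at the defaults), countering the spectral bias
  of coordinate MLPs. The octave exponents and the $\pi u$ base are the
  most common convention consistent with that width; whether the FA output
  passes through an activation first is unspecified, and we use a linear
  FA output.
* **DF-NN** — the flow net proper (default 5 layers of width 256) taking
  the encoded features concatenated with $\bar z$, with a linear 3-output
  head. The head is **zero-initialized** so training starts exactly from
  the identity map — a stabilizing choice beyond the published
  Kaiming-normal initialization of the hidden layers. The published
  parameter count (~278k) cannot be reconciled exactly under any layer
  reading we tried; `countParameters()` logs ours instead of asserting it.

### Integration

Forward maps use $K{=}10$ explicit Euler steps
$x^{(k+1)} = x^{(k)} + v(x^{(k)})/K$. The backward-time map has two
implementations:

* the **modified Euler** scheme
  $x^{(k-1)} = x^{(k)} - v\!\big(x^{(k)} - v(x^{(k)})/K\big)/K$, cheap and
  differentiable, used inside training;
* the **implicit backward Euler** step
  $x^{(k-1)} = x^{(k)} - v(x^{(k-1)})/K$, solved by fixed-point iteration
  warm-started at the modified-Euler estimate. When the per-step
  contraction $\mathrm{Lip}(v)/K < 1$ holds this is the *exact* inverse of
  the forward scheme, which the suite uses as the integrator's oracle. We
  chose fixed-point over Newton because it needs only velocity
  evaluations; the iteration cap is generous (500) since the contraction
  rate can approach 1 for strongly trained fields.

Points are deliberately **not** clamped to the unit cube during
integration — clamping would destroy invertibility; only the code lookup
clamps internally. The unit-cube margin default of 0.05 keeps trajectories
inside the conditioning grid's span in practice.

### Loss and training loop

Per batch, the loss is the mean bidirectional error
$D(\varphi_i(S_i^b), T^b) + D(\varphi_i^{-1}(T^b), S_i^b)$ over the batch,
plus $w_z\lVert Z\rVert^2 + w_\Theta\lVert\Theta\rVert^2 + w_v L_{reg}$
with the kinetic energy $L_{reg}$ summed from the logged per-step
velocities of both passes. Defaults $w_z = 10^{-3}$, $w_v = 10^{-4}$;
$w_\Theta$ was never given a value in the source material, so it defaults
to 0 with the term available. Both directions are weighted equally. The
same measure serves both directions; a train-NCD/test-CD fallback is a
config switch, not automatic.

Shapes are partitioned into seed-shuffled batches; the published batch
count bound (ceil($N_s/B$) with $B{+}1$-sized leading batches) over-counts
(780, 8 → 788), so we instead require the sizes to partition $N_s$
exactly: the first $N_s \bmod B$ batches take the extra element. Sub-clouds
of $M$ points are drawn by two-stage sampling: $\lfloor aM\rfloor$
top-loss points retained (default $a = 0.15$), the rest uniform without
replacement; measures without a pointwise decomposition (Sinkhorn) fall
back to uniform sampling. The template's pointwise loss is recomputed each
epoch as the average of that epoch's per-shape inverse losses. Updates are
Adam at a shared learning rate $\lambda = 10^{-3}$; a batch update touches
$\Theta$ and only the batch's codes. Training backpropagates through the
modified-Euler inverse pass as well (the loss contains the inverse term;
the source is silent on this, and including it is the only reading that
makes the inverse loss trainable).

At test time only the $N_z$ code entries are optimized: 100 Adam epochs at
$50\lambda$ (the published 50x speed-up factor is attached to the Adam
phase; L-BFGS has its own strong-Wolfe line search), then 10 L-BFGS
iterations on a fixed sub-sample so the quasi-Newton objective is
deterministic. A line-search failure falls back to the Adam iterate.

### Attachment measures

All Chamfer-family measures follow the printed formulas with squared
Euclidean distances and mean prefactors; the weighted variants' printed
prefactor symbols ($N, N'$) are read as the cloud cardinalities ($M, M'$)
— the notation switches letters mid-equation. Nearest-neighbour ties break
toward the lowest index for cross-platform determinism. Normals of a
deformed cloud are carried over unchanged from the source mesh (the
alternative, recomputing or transporting them through $\varphi$, is not
attempted); a consequence is that the NCD normals penalty is locally
constant in the positions and contributes no positional gradient. The
normals appearing in the published NCD formula are described as belonging
to the target surface for all four symbols; we read them as each cloud's
own normals. The point-to-plane Chamfer minimizes the *projected* squared
distance jointly, exactly as printed.

The Sinkhorn divergence is the debiased entropic OT value
$S_\varepsilon = OT_\varepsilon(\alpha,\beta) - \tfrac12
OT_\varepsilon(\alpha,\alpha) - \tfrac12 OT_\varepsilon(\beta,\beta)$ with
quadratic cost $\lVert x-y\rVert^2$ (whether a $\tfrac12$ belongs in the
cost is unstated; we use the unhalved form), $\varepsilon$-scaling from
the squared diameter down to $\varepsilon = 10^{-4}$ by factor 0.9, and
log-domain iterations. Convergence is judged on the *column* marginal —
the final potential update enforces the row marginal identically, so
checking it would be vacuous. Gradients use the envelope theorem at the
converged potentials. FLD/BLD error metrics are unsquared nearest-neighbour
distances, reported in cm through the stored inverse unit-cube transform.

### Generative layer

Codes are sampled from $\mathcal N(0, \Sigma_z)$ with $\Sigma_z$ the
unbiased covariance of the trained codes — zero-centered rather than
mean-centered, matching the $w_z$ shrinkage toward the origin — via the
eigendecomposition square root with negative eigenvalues clipped at 0.
SLERP follows the great-arc formula with a linear fallback (and warning)
for degenerate pairs. The signal-to-noise perturbation is defined as a
Euclidean-norm ratio, $\lVert e\rVert = \mathrm{snr}\cdot\lVert z\rVert$
(the source never defines its SNR; this interpretation is recorded in the
output metadata and not asserted against published numbers). Decoding
applies the modified-Euler backward flow to the template, matching
training; the synthetic cloud always carries the template's weights and
point count.

## The synthetic world

No patient data ship with the package. `aortaSpec()`/`makeCohort()` build
closed, consistently oriented tube meshes around spline centerlines — a
curved, tapering trunk with up to three branch stubs — with exact
cross-product areas and outward normals, so every precondition of the
cloud constructor holds by construction. Branch stubs are separate closed
components rather than merged junctions: cohort members share topology and
the branch membership of every point is known, which is what the
topology-preservation checks need. Cohort variation multiplies radius,
extent and curvature by $1 + \mathcal N(0, s^2)$ factors and adds a
low-frequency centerline wiggle at relative scale $s$ (default
$s = 0.1$; the registration experiments use $s = 0.08$, chosen once as a
realistic inter-patient variability for healthy aortas at fixture scale).
Analytic sinusoidal warps with displacement-gradient norm below 1 provide
invertible ground-truth deformations. What the fixtures do **not**
emulate: patient statistics, open inlets/outlets by default (a `caps`
flag restores them), segmentation noise, or merged branch junctions — so a
green recovery test establishes correctness of the optimization machinery,
not clinical-grade accuracy.

The desk-scale experiments in the test suite shrink the published setup
(hundreds of shapes, $N_z = 256$, 500 epochs, hours of GPU time) to a
4-shape cohort of ~480-point clouds, $N_z = 32$, a 2x32 / 3x64 network and
150 epochs at batch size 1 on one CPU — batch 1 because with 4 shapes a
batch of 8 would collapse each epoch into a single optimizer step, whereas
the full-size setup takes ~97 steps per epoch. These reproduce the
*properties* of the method (error reduction, inverse consistency,
latent-inference generalization, generative monotonicity), not the
published error tables, which require the original data and augmentation
pipeline.

## Numerical choices

* Gradients are hand-written reverse mode end to end (the dense-layer
  stack lives in `src/mlp.cpp`); every piece is tested against central
  differences. Chamfer gradients freeze the nearest-neighbour assignment
  (exact almost everywhere; a subgradient at ties).
* The implicit inverse tolerance is an infinity norm (default $10^{-10}$);
  the composition test allows $10\times$ that.
* CPD: rigid EM with isotropic scale and uniform outlier weight 0.1 (the
  cited algorithm without settings); convergence on the relative change of
  the EM objective.
* TPS: 3-D kernel $U(r) = r$ (the biharmonic choice; the original
  supplement with the exact recipe is unavailable, so the augmentation
  helper here is a generic stand-in, not a reproduction).
* The unit-cube transform is fitted once per cohort (template + sources)
  so all shapes share a frame; fitting per shape would destroy
  cross-shape comparability of coordinates. Degenerate (zero-extent) axes
  are centred with unit scale and a warning.
* Configs are JSON (`jsonlite`), not YAML: no YAML parser is available in
  the target environment, and JSON round-trips the nested structure
  losslessly.

## Known limitations

* Held-out latent inference at desk scale does not reach the quality of
  training-shape registration: with at most eight training shapes the
  learned codes are mutually near-orthogonal, so the conditioned field
  acts as a lookup over the training codes rather than a smooth latent
  manifold, and the inferred code for an unseen shape plateaus well above
  the training error (random restarts and longer optimization reach the
  same floor). This is a data-scarcity property of the auto-decoder, not
  an optimizer defect; the full-scale setting relies on hundreds of
  cohort shapes.
* Sinkhorn training is supported but slow at small $\varepsilon$, exactly
  as reported for the original method; adaptive sampling is unavailable
  there.
* The implicit inverse can converge to a wrong branch if
  $\mathrm{Lip}(v) \ge K$ (the fixed-point precondition); the trainer's
  kinetic-energy penalty discourages this regime but does not enforce it.
* Normals are never transported through the deformation, so normal-based
  measures evaluated on strongly rotated regions are approximate.
* `estimateNormals`' outward orientation uses a centroid viewpoint
  heuristic, which can fail on strongly concave geometries; meshes should
  be preferred as the normal source whenever available.
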