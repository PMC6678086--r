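---
title: "Quantifying inter-domain motion in biomolecular trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-domain motion in biomolecular trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainmotion)
```

## The problem

Multi-domain proteins — a T-cell receptor's variable domains, the two
helices framing an MHC peptide-binding groove, and countless other
examples — move as ensembles of quasi-rigid bodies connected by soft
linkers. Molecular dynamics (MD) trajectories resolve this motion at
atomic detail, but the raw coordinates conflate three very different
things: whole-molecule translation and tumbling, rigid-body motion of
domains relative to each other, and deformation *within* each domain.
`domainmotion` separates these signals and reduces a trajectory to a
small set of interpretable time series:

* **inter-domain distance** `d(t)` between domain geometric centers;
* **orientation angles** `alpha(t), beta(t), gamma(t)` between
  corresponding principal axes of two domains;
* **RMSD(t)** of each domain after superposition on itself
  (intra-domain deformation);
* **per-residue RMSF** about the time-averaged position (local
  flexibility).

A typical scientific question is comparative: does complex formation
(a *bound* state) rigidify the relative motion of two domains compared
with simulations of the isolated molecules (*free* states)? The package
answers this descriptively, with per-state means, standard deviations
and the two-sample Kolmogorov–Smirnov statistic `D` on pooled
per-frame samples.

## The model and its assumptions

### Domains as point clouds

A domain is a named selection of C-alpha atoms (chain + inclusive
residue intervals). Everything downstream — centers, fits, principal
axes — operates on this C-alpha cloud, unweighted. This is deliberate:
the statistic of interest is geometric (shape and placement of the
backbone), not inertial, so geometric centers are used rather than
centers of mass and no mass weighting appears anywhere.

### Local frames from per-frame PCA

For one domain in one frame, the 3×3 covariance of the centered
C-alpha coordinates (population form, `1/N`; only the eigenvector
directions matter downstream) is eigen-decomposed. The orthonormal
eigenvectors `v1, v2, v3`, ordered by decreasing eigenvalue, form a
local coordinate system that travels with the domain; `v1` points
along the domain's main extension. Two conventions remove the inherent
sign ambiguity of eigenvectors:

1. **Raw sign rule** (reference structures): each eigenvector is
   flipped so its largest-magnitude component is positive (ties: the
   first such component). Deterministic, and independent of any other
   structure.
2. **Reference standardization** (trajectory frames): `v1` and `v2`
   are flipped independently so their dot product with the
   corresponding axis of the *crystal-reference* triad is
   non-negative; `v3` is then recomputed as `v1 × v2`. This guarantees
   a proper right-handed triad in every frame. The reference triad
   comes from the untransformed crystal structure, not from frame 1 of
   any particular run, so triads are comparable across independent
   runs and across bound/free ensembles.

The cross-product rule for `v3` is a design choice: standardizing all
three axes independently by dot product could produce a left-handed
triad; rebuilding `v3` cannot. Standardization is exact (idempotent,
never flips when the frame is within 90° of the reference per axis)
and breaks exact-orthogonality ties by keeping the raw sign, with a
note attached to the frame.

The decomposition degenerates when eigenvalues coincide. A collinear
cloud (`lambda2 ≈ 0`) is an error; a near-degenerate pair
(`lambda_i − lambda_{i+1} < 1e-3 · lambda1`, a conservative threshold —
real immunoglobulin-fold domains are strongly anisotropic) attaches a
warning to the frame, and `frame_series()` reports how many frames
carried warnings while still completing.

### Orientation angles

For two domains with standardized triads `(v1,v2,v3)` and
`(w1,w2,w3)`, the package reports
`angle_i = acos(clamp(v_i · w_i, −1, 1))` in degrees, for the three
corresponding pairs. The *signed* cosine is used — standardization is
what makes the sign meaningful — so angles span the full `[0°, 180°]`
range. Angles, not raw cosines, are exported, matching how such
results are read in practice.

### Superposition and deformation

Global motion removal superposes every frame onto a reference by the
SVD-based least-squares rigid fit (Kabsch algorithm, determinant
correction to exclude reflections) of a fit selection — by default all
protein C-alpha atoms — and applies that one transform to all atoms of
the frame. Inter-domain distances are invariant under this (they are
invariant under any common rigid transform); RMSF is not, which is why
`rmsf_profile()` documents alignment as a precondition.

`rmsd_series()` fits *on the domain's own atoms* before summing
deviations, reading domain RMSD as intra-domain deformation; the first
analyzed frame is the default reference and yields exactly 0. The
alternative reading (deviation within a molecule-level alignment) is
available by aligning first and passing `fit = "none"`.
`rmsf_profile()` uses the time-averaged position of each atom as its
reference — the choice that minimizes RMSF, a property asserted in the
test suite.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `atom_filter` | `"CA"` | – | all selections are C-alpha clouds |
| analysis stride | 0.2 | ns | distance/RMSD/angle sampling interval |
| input frame spacing `dt_ns` | 0.04 | ns | one frame per 40 ps |
| near-degeneracy threshold | `1e-3·lambda1` | nm² | conservative warning level |
| SD convention | `n−1` | – | sample SD; fixed for reproducibility |
| quartiles | type 7 | – | linear interpolation |
| KS statistic | exact | – | integer-ratio `D`, no asymptotics |

A 40 ns run written every 40 ps has exactly 1000 frames (frames at
`k·Δt`, k = 1…1000); thinned to the 0.2 ns analysis stride it
contributes 200 samples, and ten pooled runs per state give 2000.

## What the synthetic generator emulates — and what it does not

The MD data behind studies of this kind are rarely deposited, so the
package ships a generator whose runs have *known ground truth*. Each
run contains two anisotropic Gaussian C-alpha clouds, canonicalized
onto their own sample principal axes (which is what makes noise-free
closed-loop recovery exact to machine precision):

* domain sizes default to 104 and 117 atoms — the sizes of the TCR
  variable domains in the system that motivated the design;
* principal SDs (0.90, 0.60, 0.30) and (1.05, 0.70, 0.35) nm, i.e.
  elongated domains with successive-axis anisotropy ≥ 1.5 (isotropic
  specs are rejected: eigenvectors would be unidentifiable);
* the inter-center distance follows a constant, sinusoidal, or
  Ornstein–Uhlenbeck (OU) law (default: constant 2.5 nm, the scale of
  a V-domain pair separation);
* the relative rotation of domain B follows per-component angle laws
  about specified axes; OU processes are sampled with the exact
  discrete-time transition (so any output interval is statistically
  faithful), relaxation time 2 ns by default — slow enough to be
  visibly autocorrelated at the 0.2 ns stride, fast enough to
  decorrelate many times within 40 ns;
* i.i.d. Gaussian jitter, SD 0.02 nm per coordinate, stands in for
  fast thermal fluctuation;
* an optional "breathing" mode scales one principal axis sinusoidally
  to exercise RMSD sensitivity.

The bound/free ensemble constructor contrasts a *bound-like* state (OU
angle about the first principal axis: mean 63°, stationary SD 2°) with
a *free-like* state (mean 57°, SD 6°) — the qualitative signature of
binding-induced rigidification. All runs of both states share one pair
of base clouds — they model repeated simulations of the *same*
molecule, so every run is comparable against the one crystal-like
reference, exactly as pooled MD runs are — while motion seeds derive
deterministically from one master seed.

What the generator does **not** emulate: force fields, solvent,
thermodynamic consistency, anharmonic conformational transitions,
correlated internal modes, or secondary-structure changes. A green
closed-loop test therefore establishes that the *analysis chain* is
correct (selection → alignment → PCA → standardization → statistics),
not that any biological conclusion is reproduced; conversely it cannot
be fooled by the analysis compensating for generator quirks, because
ground truth is recorded independently of both.

## Numerical choices

* Unit conventions: nm internally everywhere; PDB I/O converts by the
  exact factor 10 at the boundary. PDB's 3-decimal Ångström fields
  bound round-trip error by 5×10⁻⁵ nm.
* `acos` arguments are clamped to `[−1, 1]`; near 0° the angle error
  grows like the square root of the dot-product error, which is why
  closed-loop recovery is asserted at 10⁻⁶ degrees rather than machine
  epsilon.
* The Kabsch fit refuses < 3 points and collinear clouds (rotation
  about the line undetermined) with errors naming the degeneracy.
* KS `D` is computed as `max |n2·C_x − n1·C_y| / (n1·n2)` over pooled
  points with integer counts, so it is exact — a ratio of integers —
  and comparable bit-for-bit against brute-force enumeration.
* altLoc records resolve to the highest occupancy (ties: first
  encountered); missing residues inside a selection interval warn and
  are skipped (crystal gaps), but a fully empty selection is an error.

## Known limitations

* PDB is the only trajectory format; compressed MD formats (XTC/DCD)
  would require an external reader not available in this environment.
* Per-frame PCA frames assume quasi-rigid, clearly anisotropic
  domains; for nearly axially symmetric domains the second and third
  axes are unstable (the warnings exist precisely for this).
* Residue ranges defining domains must be supplied by the user;
  nothing is hard-coded, because published domain sizes alone do not
  determine the boundaries.
* The bound/free comparison is descriptive (`D`, means, SDs); no
  p-values or multiple-testing control are provided or intended.
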