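---
title: "Models and methods behind ftszdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ftszdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ftszdyn characterises the assembly dynamics of FtsZ-like protofilaments
from coordinate trajectories. FtsZ, the bacterial tubulin homolog, forms
single-stranded head-to-tail filaments whose subunits switch between a
tense, open-cleft T conformation (polymer-like, high affinity) and a
relaxed, closed-cleft R conformation (monomer-like, low affinity). The
package quantifies that switch and the accompanying interface changes
with five coupled analyses: inter-subunit rotation decomposition, buried
interface area, conformational-state classification with a
nucleation-species census, free-energy landscapes over an SVD projection,
and anisotropic network model (ANM) correlation maps. A synthetic
trajectory generator with exact ground truth closes the loop: every
analysis stage is validated by recovering what the generator imposed.

## Inter-subunit rotations

A filament-anchored frame is built from the middle subunit: the z axis
runs along the filament (centroid of the subunit below to the one above),
the x axis is the projection of the middle subunit's C-domain offset onto
the plane normal to z (the preferred bending direction), and y completes
a right-handed triad. Per frame, the middle subunit is superposed onto
the straight reference, the moving (top or bottom) subunit is Kabsch
fitted onto its reference pose, and the resulting proper rotation --
expressed in the frame basis -- is decomposed as intrinsic rotations in
the order z (`theta1`, twist), then x (`theta2`), then y (`theta3`):

```{r}
R <- compose_zxy(theta1, theta2, theta3)  # = Rz %*% Rx %*% Ry
```

The z-first order was chosen because twist is named first in the field's
convention and dominates the reported flexibility; the order is recorded
in every output (`attr(x, "order")`) so results are unambiguous, and the
decomposition round-trips its composition to 1e-8 over the full angle
space away from gimbal lock (`theta2` within 0.1 degrees of +/-90 is
flagged). Angles for the bottom subunit use the same middle-subunit
alignment. Kabsch superposition excludes reflections by construction
(determinant +1).

## Buried interface area

Interface tightness is half the solvent-accessible surface area (SASA)
lost on complexation,

buried = (M1 + M2 - M12) / 2,

with M1, M2 the SASA of each subunit alone and M12 that of the pair.
SASA uses Shrake-Rupley quadrature on a deterministic Fibonacci sphere
lattice (960 points per atom by default; doubling the count changes
totals by under 1 percent), probe radius 1.4 Angstrom, and a uniform
1.9 Angstrom pseudo-atom radius for synthetic structures (real input
resolves radii per element from a built-in table). All three knobs are
exposed because absolute buried-area values depend on them. The fixed
lattice makes areas bit-reproducible across runs and platforms; the
price is a sub-percent orientation dependence, which bounds how exactly
rigid-motion invariance can hold. All supplied atoms enter the
calculation (the heavy-atom-only alternative is the caller's selection).

## State classification and the species census

The classifiers implement the reported operational definitions directly:
a subunit is R when its inter-domain distance (between N- and C-domain
CA centroids) has dropped strictly more than 2.5 Angstrom below the
T-state reference, and an interface is closed above 1100 Angstrom^2 of
buried area, open below 1000. Because only the R side of the gap is
defined by that rule, a T band (reduction at most 1.0 Angstrom) and an
indeterminate band in between were added so mid-gap frames are not
force-labelled; indeterminate members render as `?` in trimer strings
and are excluded from the census of that dimer position. The T reference
defaults to the mean inter-domain distance over the first 5 percent of
frames -- appropriate for runs that start from the T state -- and should
be supplied explicitly otherwise (the synthetic workflow passes the
template's known separation).

Dimer species letters are ordered upper-then-lower ("T-R" at the bottom
dimer means middle T over bottom R, i.e. the middle-bottom convention);
this is stated in the outputs because published species lists mix
top-bottom and middle-bottom orderings.

Per-category twist peaks (IF1 = closed, IF2 = open, within each
nucleotide tag) pool theta1 samples from both interfaces over all frames
of the category, then take the mode of a 1-degree histogram with
three-point parabolic refinement. Pooling per frame (rather than
averaging per interface first) was chosen as the default; categories
with fewer than 10 samples are reported as undersampled rather than
given a meaningless mode.

## Free-energy landscapes

Frames are featurised as the flattened upper triangle of the CA pairwise
distance matrix (rigid-motion invariant by construction), columns are
mean-centred, and a thin SVD projects frames onto the top two singular
vectors with scores scaled by the singular values. Component signs are
fixed so each component's largest-magnitude loading is positive.
Occupancy over a 40 x 40 grid on that plane, smoothed with a 1-bin
Gaussian kernel, gives F = -ln(P / Pmax) in kBT, so the occupied minimum
is exactly 0; unoccupied bins carry a sentinel above every occupied
value. The raw (pre-smoothing) histogram defines occupancy; the smoothed
density defines the energies.

Funnels are detected by watershed flooding with persistence merging:
bins are flooded in order of increasing F, and when a basin first meets
a deeper one it survives as a separate funnel only if its watershed
saddle lies at least 1 kBT above its own minimum. Two numerical guards
matter in sparse landscapes. First, flooding runs over the support of
the smoothed density rather than only the occupied bins, so sampling
gaps inside one basin do not fragment it. Second, a basin must hold at
least 1 percent of all frames: an isolated outlier frame is disconnected
from every saddle and would otherwise always count as a funnel. Bin
count, smoothing width, barrier and occupancy threshold are all exposed.
The defaults are stable for ensembles of roughly 500 to 10,000 frames;
the bundled analyses use 600-frame ensembles, for which the GTP- and
GDP-condition defaults yield two and three funnels reproducibly across
seeds.

## Adjusted regression

Consecutive trajectory frames are far from independent. Ordinary least
squares is fitted on all points, but the F-statistic p-value uses an
effective sample size `n_eff = floor(total_time / decorrelation)` with
degrees of freedom (1, n_eff - 2), defaulting to a 1 ns decorrelation
interval. With `decorrelation = frame_dt` the classical F-test is
recovered exactly, and under the null the test holds its nominal 5
percent rejection rate (verified over 2000 replicates). Below n_eff = 4
the p-value is reported as undefined rather than extrapolated.

## Anisotropic network model

Nodes (all pseudo-residues of synthetic structures; CA atoms of real
ones) within a 15 Angstrom cutoff are coupled by the standard ANM
super-element Hessian, off-diagonal block `-gamma / d^2 (r %o% r)`.
Cross-correlations use the lowest 45 non-zero modes (the published mode
count is taken to exclude the six rigid-body modes):
`cov_ij = sum_k lambda_k^-1 (v_k,i . v_k,j)`, normalised to unit
diagonal. Zero modes are identified by the relative threshold
`|lambda| < 1e-8 lambda_max` rather than "first six", so disconnected
contact graphs are flagged instead of silently mis-analysed. The spring
constant cancels in the normalised map (checked over two orders of
magnitude). The coupling profile summarises, per oligomer size, the mean
|C| between the N- and C-domain node sets of the end subunits and
between the two end subunits -- the quantitative handle on
polymerisation-enhanced cooperativity.

## The synthetic generator

The generator emulates the study conditions with known ground truth.
Each pseudo-subunit is two rigid point clouds of 30 (N-domain) and 24
(C-domain) pseudo-residues on jittered prolate ellipsoidal shells
(semi-axes 7.5 Angstrom transverse, 14 axial), domain centroids 38
Angstrom apart along a nearly axial direction, stacked at a 40 Angstrom
rise. These constants were fixed together, once, to satisfy three
simultaneous constraints: the straight (closed) interface buries about
1190 Angstrom^2 -- the same order as real subunit interfaces and above
the 1100 closed threshold; a 5 Angstrom axial opening drops it to about
930, below the 1000 open threshold; and the N- and C-domain tips of one
subunit stay within the 15 Angstrom ANM cutoff, so the contact graph of
any oligomer is connected with exactly six zero modes. Spherical shells
cannot meet all three at once at this bead count and radius -- deep
interface interdigitation forces a domain separation near the rise,
which leaves a 20 Angstrom intra-subunit void -- which is why the shells
are prolate.

Each frame samples a conformer cluster, rotates the end subunits about
the middle-subunit frame by the cluster's per-interface angle triples
plus Gaussian angle noise (2 degrees by default), translates the
C-domain of the cluster's R subunits 3 Angstrom toward the N-domain
(safely beyond the 2.5 Angstrom classifier threshold; a rotation-based
closure is available through the domain-rotation operation), opens
designated interfaces by the 5 Angstrom axial shift, and adds 0.3
Angstrom per-atom jitter. Cluster twist means are the published
per-interface peaks (-6.1 and -35.7 degrees for the GTP closed/open
interfaces; -9.4 and -33.1 for GDP) and the bending means are the
per-state averages; the GTP condition populates two clusters (T-T-T and
T-T-R, top interface open) and the GDP condition three (R-R-R, R-R-T,
R-T-R), matching the reported two and three energy funnels. Randomness
comes from reseeding R's generator per frame with a deterministic hash
of (seed, frame) -- a stand-in for a counter-based generator, which base
R lacks -- so outputs are a pure function of the specification.

What the generator does not emulate: no force field or Brownian
dynamics, no sequence or side-chain realism, no gradual transitions
(states switch cluster-wise), and interface opening is a rigid
translation rather than a diffusive unbinding. Passing tests therefore
demonstrate that the analysis stack recovers imposed geometry and
composition under realistic noise -- not that it would resolve subtler
signals in experimental-quality trajectories. One consequence of the
pure-translation closure is visible in the GDP defaults: R-state
closures perturb their subunit's upper interface by roughly 100-200
Angstrom^2, so the all-R "closed-ish" cluster sits mostly in the
intermediate interface band rather than above 1100 -- consistent with
reported late-stage GDP interfaces (about 930-980 Angstrom^2) but worth
knowing when interpreting census and peak tables.

## Degenerate inputs and numerical choices

Kabsch requires at least three non-collinear points and rejects count
mismatches; RMSF requires at least two frames and iterates mean-structure
superposition to 1e-6 Angstrom (at most 20 passes). PDB round trips are
exact to the format's 0.001 Angstrom; models with inconsistent atom
counts fail naming the offending model. Alternate locations keep the
highest-occupancy conformer, first on ties. The pitch/twist conversion
exposes both a full-turn (360 degrees) and a half-turn (180 degrees)
convention because published pitch/twist pairs for FtsZ helices are
internally consistent only under the half-turn reading (six subunits per
turn at a 4 nm rise giving about 30 degrees per subunit); neither is
asserted correct. The domain split between N- and C-terminal halves is
always user-supplied configuration, never inferred from coordinates.

## Problem sizes

The bundled analyses and validation suite use 600-frame ensembles for
landscapes and state censuses, 2000 frames for the twist-peak recovery,
and oligomers of one to five subunits (54 to 270 nodes) for the ANM;
these sizes give seed-stable funnel counts and sub-half-degree peak
recovery while keeping a full run in minutes on one core.
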