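---
title: "Separating and coupling tertiary and quaternary motions with qtcouple"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating and coupling tertiary and quaternary motions with qtcouple}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtcouple)
```

## The problem

Allosteric multi-chain proteins — hemoglobin is the prototype — change both
their *tertiary* structure (conformation within each chain) and their
*quaternary* structure (the rigid-body arrangement of the chains) during a
functional transition such as T to R. The mechanistic question is how the
two are coupled: which internal motions drive, or respond to, the global
rearrangement. qtcouple implements an analysis that answers this in three
steps: a strict orthogonal separation of the two kinds of motion, a
regression-based search for the internal collective coordinate most
correlated with the dominant global motion, and a structural dissection of
that coupling at the chain interfaces.

## The decomposition

Given a reference structure (for hemoglobin, the T state) and a partition
of the atoms into chains (any domain definition works; chains are the
default), every trajectory frame is decomposed by per-chain least-squares
superposition (Kabsch, proper rotations only):

* **tertiary-only (T) trajectory** — each chain of the frame is superposed
  onto its reference chain. All chains then share the reference centre of
  mass and orientation; only subunit-internal fluctuations remain. For C
  chains this removes 6C degrees of freedom, leaving 3N − 6C.
* **quaternary-only (Q) trajectory** — conversely, each rigid *reference*
  chain is posed onto the corresponding chain of the frame. Internal
  coordinates are frozen at the reference; only the 6 rigid-body degrees
  of freedom per chain remain, i.e. 6C − 6 = 18 for a tetramer once the
  global fit is removed.

The per-frame, per-chain poses are stored at decomposition time, so
applying them to the tertiary-only coordinates reproduces the raw frame to
machine precision — `recombine()` is exact by construction, which the test
suite asserts at 1e-9 nm on every frame it generates. Both parts are kept
in the full 3N Cartesian space, so tertiary and quaternary collective
modes live in one vector space and scalar products between them are well
defined.

At linear order around the reference the two subspaces are exactly
orthogonal. Finite rotations curve the manifold of rigid poses: the
covariance of a quaternary-only trajectory acquires spurious eigenvalues
of relative magnitude roughly (amplitude / chain size)^2 beyond the 18
tangent directions. Dimensionality statements are therefore tangent-space
statements, and the package's rank checks drive the generator in the
small-displacement regime (rigid jitter of 1e-7 nm/rad), where the 19th
relative eigenvalue sits around 1e-14 and the count above the 1e-12
threshold is exactly 18. At physically realistic amplitudes the spectrum
still shows the same steep drop after 18 modes, but the curvature tail is
far above machine precision; `covariance_spectrum()` exposes the threshold
so users can judge this on their own data.

## From motions to collective coordinates

**cQ.** The Q trajectory is summarised by PCA (`traj_pca()`); the first
eigenvector, cQ, is the dominant inter-chain motion. Eigenvector signs
follow a fixed convention (largest-magnitude component positive) so
results do not flip between runs.

**cT by PLS-FMA.** Functional mode analysis finds the collective
coordinate in a configuration space maximally correlated with a scalar
functional property — here, the projection of the Q trajectory onto cQ.
Because the tertiary space is vastly higher-dimensional than the number of
frames, an unconstrained regression would overfit; the package uses
partial least squares (PLS1 with standard NIPALS deflation, implemented in
`pls_fma()`), which builds a small number of latent vectors maximising
covariance with the target and regresses the target on them. The
coordinate-space gradient of the fitted linear model is composed
explicitly and exposed as the unit 3N-vector cT.

The model is constructed on the first half of the (possibly concatenated)
frames and validated on the second half; `select_components()` scans the
component count, picks the cross-validation maximiser, and refits the
final model with that count on all frames. The split is a deliberate
first-half/second-half split in trajectory order, not a random one:
adjacent MD frames are strongly autocorrelated, and a random split would
leak the training data into validation.

**cTew.** cT is the *maximally correlated* motion, which may be a rare
one. For structural interpretation the package follows the
ensemble-weighting idea: `ensemble_weight()` reweights the latent vectors
underlying cT by their contribution to the overall coordinate variance,
cTew ∝ Σ_k c_k σ²_k v_k, where v_k are the unit latent directions in
coordinate space, c_k their regression coefficients and σ²_k the data
variance along v_k. This specific formula is a design choice of this
package; it reduces to cT for a single latent vector and for exactly
isotropic data (both asserted in the tests), which are the properties the
reweighting is meant to have.

## The coupling plane and its structural dissection

Frames are projected onto the plane spanned by cQ and cTew
(`project_plane()`; the construction guarantees near-orthogonality, and a
scalar product above 0.5 is rejected as an ill-defined plane). The span of
the projections, extended to include the T/R anchor structures when given,
is divided equidistantly into 20 parts per axis (`build_grid()`, the
centres of the parts being the cell coordinates), and every cell is mapped
back to a full structure, coords = origin + a·cQ + b·cTew
(`backproject()`). Backprojection is linear, so it ignores the curvature
of finite rigid rotations; backprojected structures are two-dimensional
representatives of the coupling process, not physical conformations —
which is precisely why steric scores on them are informative.

Along the L-shaped path from the T-state cell — first parallel to cQ, then
parallel to cTew, to the R-state cell (`make_path()`; both legs share the
corner cell exactly once) — the package computes:

* **inter-chain van der Waals overlap** (`vdw_overlap()`): for every atom
  pair on *different* chains, the penetration max(0, r_i + r_j − d_ij),
  summed once per pair; a length in nm scoring how sterically strained the
  interface is. A full-dimensional, clash-free structure scores exactly
  zero; only the dimensionally reduced backprojected structures score
  positive values, and the landscape over the grid (`overlap_surface()`)
  shows where. A per-atom accounting (each pair attributed to both atoms,
  hence summed twice) is available via `double_count = TRUE`, since either
  bookkeeping is defensible. Radii come from a bundled Bondi-style
  element table (`default_radii()`), user-replaceable via
  `read_radius_table()`; absolute overlap values therefore depend on the
  chosen radii and should be compared within one table only.
* **residue contacts** (`find_contacts()`): a residue pair on different
  chains is in contact when any heavy-atom pair is closer than 0.3 nm.
  The package treats 0.3 nm as the physically sensible default for an
  atomic contact criterion. Contact search uses a cell-list accelerated
  neighbour search; a brute-force all-pairs search is kept as an exactly
  equivalent alternative (`method = "brute"`) and doubles as the test
  oracle.

Contacts observed along the path are classified (`classify_contacts()`)
by *where* they are present, using three disjoint segments — T end, elbow
(around the path corner), R end: **pulling** contacts hold at both ends
and break in the off-diagonal elbow; **pushing** contacts form only in
the elbow; **switching** residues change contact partner between the two
ends; contacts present everywhere are **static**, anything else
**other**. The segment widths default to 3 end cells and a corner ±2
elbow on typical (~17-cell) paths and shrink proportionally on
shorter paths so the segments stay disjoint; both widths are arguments.

## Transition detection and the T–R difference

`tr_difference()` builds the normalised difference vector between two end
states (the second globally fitted onto the first) and decomposes it with
the same machinery into tertiary and quaternary components, enabling
scalar-product tables between cQ, cT, cTew and the crystallographic
difference modes. `detect_transition()` projects a trajectory onto the
full difference mode and calls a transition when the covered fraction of
the T-to-R distance reaches 80% (configurable). Screening of outlier
runs — transitions that overshoot the common range so strongly that they
would dominate the covariance — uses an explicit, configurable rule:
exclude transition trajectories whose peak fraction exceeds the median by
more than 5 MADs. The rule is a quantitative stand-in for a qualitative
judgement; with a zero MAD a small floor proportional to the median keeps
equal-valued sets intact.

## The synthetic study system

Real transition trajectories require microseconds of MD; the package
instead validates every stage on a generator (`synthetic_spec()`,
`generate_trajectory()`) that emulates the *statistical structure* the
analysis assumes:

* four helical bead chains (50 beads each by default) arranged around a
  common centre with facing interfaces;
* a scalar progress variable q(t): a logistic ramp from 0 to 1 (one
  spontaneous T→R crossing per run, midpoint at half the trajectory,
  width 5%) plus a small AR(1) fluctuation (sd 0.05) representing thermal
  motion along the transition coordinate;
* a coherent quaternary path driven by q: each chain rotates about its
  axis (0.15 rad at q = 1) and translates towards the centre (0.25 nm at
  q = 1), closing the interfaces;
* a planted internal mode, amplitude α·q(t) with α = 0.5 nm: the
  rigid-free projection of the reversed interface approach, so the
  coupled motion retracts the interface beads exactly where the
  quaternary motion would otherwise clash — this is what makes the
  overlap landscape minimal along the plane diagonal and larger
  orthogonally, the qualitative signature the analysis is designed to
  expose;
* five independent internal noise modes (per-frame amplitudes, sd
  0.05 nm), per-chain rigid-body jitter (0.02 rad / 0.02 nm) exciting all
  quaternary degrees of freedom, and isotropic positional noise
  (sd 0.02 nm).

With these defaults the nominal signal-to-noise ratio of the planted
coupling, α·sd(q)/σ, is about 10. All draws flow from one seed;
regeneration is bit-identical and the global RNG state is restored.

What the generator does **not** emulate: chemical detail (no force field,
no energetics, no hydrogen bonds), realistic contact networks (bead
chains touch at a handful of residue pairs, not the dense interfaces of a
real tetramer), anisotropic or state-dependent noise, and any lag between
tertiary and quaternary motion. Passing tests therefore demonstrate that
the machinery recovers planted linear, instantaneous coupling from data
with the assumed structure — not that any particular protein behaves this
way.

## Validation protocol and problem sizes

The packaged checks mirror how the method would be used: two
independently seeded 1000-frame transition runs are concatenated (so both
the model and the validation half contain a transition, as in a multi-run
analysis), decomposed, cQ extracted, and PLS-FMA run with the component
count chosen by cross-validation. Under the default study conditions this
yields cross-validation correlations above 0.9 and recovers the planted
tertiary mode with cosine above 0.95; with the coupling removed (α = 0)
the median |cv correlation| over 20 seeds stays below 0.1 (these runs use
1000 frames and 30-bead chains, sizes chosen to keep the whole validation
suite fast while leaving the conclusions unchanged). Dimensionality
checks use 2000 frames in the linear regime as described above;
neighbour-search equivalence is asserted exactly on 500-atom frames.

## Numerical choices

* Superposition is unweighted over all heavy atoms by default; per-atom
  weights (e.g. masses) are accepted everywhere a fit happens. Unweighted
  fitting is the simplest reproducible choice and the switch allows
  sensitivity checks.
* Units are nm throughout; PDB Å are converted on read/write. Hydrogens
  are dropped at load time by default.
* The heavy-atom selection policy `"protein_prosthetic"` counts protein
  *and* prosthetic-group (e.g. heme) heavy atoms and excludes solvent and
  monoatomic ions by residue name; the policy is an argument of
  `count_heavy_atoms()`.
* Rank counting uses eigenvalue > 1e-12 × the largest; the threshold is
  an argument of `covariance_spectrum()`.
* Coordinates and target are centred on training-half means inside
  `pls_fma()`; coordinates are never variance-scaled (they share units).
* Degenerate inputs fail loudly: collinear/coincident point sets in the
  fit, zero-variance targets, zero projection ranges in the grid,
  identical end states in the difference mode, paths too short for the
  classification segments.
* The plane origin is the T-state reference; grid bounds include the
  anchors when provided, and anchors are not forced onto exact grid
  points.

## Limitations

The coupling model is linear and instantaneous; nonlinear or time-lagged
coupling is out of scope. Backprojected structures inherit the
linearisation of rigid-body motion and are not physical conformations.
Absolute overlap values depend on the radius table. The outlier rule and
the classification segment widths are explicit stand-ins for qualitative
judgements and should be reported alongside results.
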