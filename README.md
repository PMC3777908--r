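# qtcouple

Quantifying the coupling between **tertiary** (within-chain) and
**quaternary** (rigid-body, between-chain) motions in trajectories of
multi-chain proteins — the analysis behind questions like *"which internal
motions of hemoglobin's subunits drive its T→R quaternary transition?"*
It is written for structural biophysicists analysing MD (or other
conformational-ensemble) trajectories of oligomeric proteins.

## What it computes

Given a trajectory, a reference structure and a chain partition:

1. **Orthogonal decomposition.** Each frame is split by per-chain Kabsch
   superposition into a *tertiary-only* part `T` (every chain superposed
   onto its reference chain; only internal fluctuations, 3N − 6C degrees
   of freedom) and a *quaternary-only* part `Q` (rigid reference chains
   posed onto the frame; 6C − 6 degrees of freedom after the global fit,
   i.e. 18 for a tetramer). The stored poses recombine both parts into the
   original frames exactly.
2. **cQ.** PCA of `Q`; the leading eigenvector cQ is the dominant
   inter-chain motion.
3. **cT / cTew by PLS-FMA.** Partial-least-squares functional mode
   analysis finds the unit 3N-vector cT in the tertiary subspace whose
   projection best predicts the cQ projection,

   &nbsp;&nbsp;&nbsp;&nbsp;cT ∝ ∇<sub>x</sub> ŷ,&nbsp;&nbsp;
   ŷ = ȳ + Σ<sub>k</sub> c<sub>k</sub> t<sub>k</sub>(x),

   with latent vectors t_k chosen to maximise covariance with the target,
   the component count chosen by split-half cross-validation (model on the
   first half of the frames, validation on the second), and an
   ensemble-weighted variant cTew ∝ Σ_k c_k σ²_k v_k for structural
   interpretation.
4. **Coupling plane.** Frames are projected onto the (cQ, cTew) plane; a
   20 × 20 equidistant grid over the projections is backprojected to full
   structures, scored by inter-chain van der Waals overlap
   Σ max(0, r_i + r_j − d_ij), and an L-shaped path (along cQ, then along
   cTew) from the T cell to the R cell carries a residue-contact analysis
   (0.3 nm heavy-atom cutoff) that classifies interface contacts as
   **pulling**, **pushing**, **switching** or **static**.
5. **Transition detection.** Projection onto the (decomposed) T–R
   difference vector, an 80%-coverage transition criterion and median/MAD
   outlier screening.

A seeded synthetic generator (4 helical bead chains, a sigmoidal
transition coordinate driving a rigid quaternary path plus a linearly
coupled planted internal mode, independent noise modes, rigid jitter and
isotropic noise) provides ground truth for every stage.

## Worked example

Two concatenated synthetic transition runs (2000 frames, 200 atoms, the
variant whose interfaces come into contact), analysed end to end:

```r
library(qtcouple)
spec <- synthetic_spec(n_frames = 1000, d_max = 0.35, seed = 1)
runs <- lapply(c(1001, 1002), function(s)
  generate_trajectory(synthetic_spec(n_frames = 1000, d_max = 0.35,
                                     seed = s)))
traj <- concat_trajectories(lapply(runs, `[[`, "trajectory"))
ref  <- runs[[1]]$reference
ends <- synthetic_endpoints(spec)

res <- run_pipeline(traj, ref,
                    t_state = ends$t_state, r_state = ends$r_state,
                    k_max = 10)
res
#> qt_pipeline result
#>   frames: 2000, chains: 4
#>   cQ explained fraction: 0.963
#>   PLS components: 1, fit_r = 0.994, cv_r = 0.994
#>   contacts: 67 pair(s): other 51, pushing 16
round(res$scalar_products, 2)
#>               cQ  cT cTew TR_full TR_tertiary TR_quaternary
#> cQ             1 0.0  0.0     1.0         0.0             1
#> cT             0 1.0  1.0     0.1         1.0             0
#> cTew           0 1.0  1.0     0.1         1.0             0
#> TR_full        1 0.1  0.1     1.0         0.1             1
#> TR_tertiary    0 1.0  1.0     0.1         1.0             0
#> TR_quaternary  1 0.0  0.0     1.0         0.0             1
res$transition
#> qt_verdict: transition (max fraction 1.198 at frame 1996)
```

Reading the numbers: the first quaternary mode carries 96% of the
inter-chain variance; a one-component PLS model predicts it from the
internal coordinates alone with correlation 0.99 both in fit and
cross-validation — the planted tertiary–quaternary coupling is fully
recovered. cQ and cTew are orthogonal (scalar product 0.00) even though
their *projections* are almost perfectly correlated: the coupling is a
property of the dynamics, not of the basis. The T–R difference decomposes
into a quaternary part parallel to cQ and a tertiary part parallel to
cTew, and 16 interface contacts form only in the off-diagonal
intermediate states (class "pushing"). The trajectory covers 120% of the
T-to-R distance, so it counts as a transition run.

`run_pipeline(..., out_dir = "...")` writes per-frame projections with
the split-half correlations, plane coordinates, the overlap grid, the
classified contact table, the scalar-product matrix, per-frame chain
poses and the modes as CSV/JSON. A thin command-line front-end over the
same functions ships in `inst/cli/qtcouple.R`
(`simulate | decompose | detect | run`).

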