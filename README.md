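# mlfit — maximum-likelihood density-guided model refinement

`mlfit` is an R toolkit for refining particle models into cryo-EM style
density maps by biased stochastic dynamics.  It is aimed at people who
want to study *how* density-guided refinement behaves — the shape of the
fitting potential, the balance between data and structural prior, the
work a biasing protocol exerts — on fully controlled, self-generated
systems, rather than at production all-atom refinement.

## The method

Refinement is framed as maximum likelihood: find the coordinates
**x** most likely to have produced the observed map ρ.  The total
energy is

    U_tot(x) = U_ff(x) + U_fit(x, ρ),      U_fit = −k · S(ρ, ρˢ(x))

with `U_ff` a structural prior (harmonic bonds/angles), `ρˢ(x)` the
model density obtained by spreading a truncated Gaussian of width σ on
each atom (σ chosen so the Gaussian FWHM equals the target resolution;
truncation at 4σ keeps > 99.8 % of the mass), and `S` one of four
similarity scores:

| kind | score | character |
|---|---|---|
| `ip`  | Σ ρ ρˢ | inner product, short-ranged |
| `cc`  | Σ ρ ρˢ / (‖ρ‖‖ρˢ‖) | cosine cross-correlation |
| `re`  | Σ ρ log(ρˢ/ρ) = −KL(ρ‖ρˢ) | Poisson noise model; long-ranged, ≤ 0, 0 at perfect agreement |
| `res` | Σ ρˢ log ρ | Dirichlet noise model (inner product against the log map) |

Forces are assembled analytically as
`F_i = k Σ_v (∂S/∂ρˢ_v) ∇_i ρˢ_v` — the exact negative gradient of
`U_fit`, including the Jacobian of the model-density normalization.
The force constant `k` is managed by an adaptive protocol: an
exponential moving average of S is monitored, and `k` is divided by
(1 + α) when similarity improves and multiplied by (1 + 2α) when it
degrades, with α = N_fit·Δt/τ.  The exerted work `W = Σ k ΔS` is
tracked per frame, and refinement ends when forces exceed an
integrator-compatibility threshold.

The package also ships a toy Brownian-dynamics engine and the model
studies built on it (1D/2D effective-landscape scans, a
fixed-vs-adaptive work benchmark at matched mean first-passage time, a
bead-helix-into-kinked-density refinement), plus scoring tools:
Fourier shell correlation with unweighted averaging and threshold
resolution, and superposition-free RMSD.  MRC/CCP4 maps and PDB
structures are read and written natively.

## Worked example: refine a straight helix into a kinked density

```r
library(mlfit)

helix <- make_bead_helix()                      # 20 beads, bonds + angles
kt    <- make_kinked_target(helix, kink_angle = 30)
kt$target
#> density_grid: 25 x 30 x 48 voxels
#>   origin  (A): -12 -17 -9
#>   spacing (A): 1 1 1
#>   value range: [0, 0.01676], sum 19.98

rmsd_no_superposition(helix$atoms, kt$reference)
#> [1] 3.463122

scaling <- scaling_config(alpha = alpha_from_timescale(10, helix$dt, 0.8),
                          ema_weight = 0.1, k_init = 1e-3, f_max = 80)
traj <- run_refinement(helix, kt$target, "relative-entropy", scaling,
                       n_steps = 60000, seed = 1, params = kt$params)
traj
#> refinement_trajectory (relative-entropy): 5032 frames, force_limit
#>   S: -1.4615 -> -0.00046595   k: 0.001 -> 6.01e+03   W = 19.01

final <- helix$atoms
final$positions <- traj$final_positions
rmsd_no_superposition(final, kt$reference)
#> [1] 0.07432929
```

The similarity climbs from −1.46 to −0.0005 (0 is perfect agreement)
while the adaptive force constant ratchets from 10⁻³ up to ~6000 before
the run hits its force limit — the protocol's normal endpoint — and the
bead RMSD to the kinked ground truth drops from 3.46 Å to 0.07 Å, with
19 units of exerted work accounted along the way.  The per-frame log
(`traj$log`: S, EMA, k, work, max force) is the same monitoring table
the CLI writes as CSV.

## Command line

A thin wrapper over the same functions lives in `exec/mlfit`:

```sh
mlfit make-fixture helix --beads 20 --kink 30 --out-prefix helix
mlfit spread helix_straight.pdb --resolution 4 --out model.mrc
mlfit score --kind re helix_target.mrc helix_target.mrc   # S = 0
mlfit fsc model.mrc helix_target.mrc --threshold 0.143
mlfit refine --pdb helix_straight.pdb --map helix_target.mrc --kind re
mlfit benchmark --replicas 100 --seed 1
```

Every artifact-producing command writes a JSON manifest (config + seed +
version) next to its outputs.

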