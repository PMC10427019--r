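---
title: "Density-guided refinement with maximum-likelihood potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-guided refinement with maximum-likelihood potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlfit)
```

## The model

`mlfit` refines particle models into density maps by treating refinement
as a maximum-likelihood problem: find the coordinates most likely to have
produced the observed map.  The total energy is

$$U_\mathrm{tot}(x) = U_\mathrm{ff}(x) + U_\mathrm{fit}(x, \rho),
\qquad U_\mathrm{fit} = -k\,S(\rho, \rho^s(x)),$$

where $U_\mathrm{ff}$ is a structural prior (here: harmonic bonds and
angles of a bead model), $\rho$ the target map, $\rho^s(x)$ the model
density generated from the coordinates, $S$ a similarity score, and $k$
a force constant balancing data against prior.  All scores are
larger-is-better, so fitting forces follow $+k\,\nabla S$.

Two voxel-noise models give the distinctive scores:

* a **Dirichlet** model (each detected electron scatters at exactly one
  voxel, with probability proportional to the density) leads to the
  *swapped relative entropy* $S_\mathrm{I} = \sum_v \rho^s_v \log
  \rho_v$ — an inner product against the log target;
* a **Poisson** model (independent per-voxel interaction counts) leads
  to the *relative entropy* $S_\mathrm{II} = \sum_v \rho_v \log
  (\rho^s_v / \rho_v) = -\mathrm{KL}(\rho \,\|\, \rho^s) \le 0$, which is
  zero exactly at perfect agreement.

Both treat densities as probability distributions, so the target is
prepared by clipping negative voxels and normalizing to unit sum
(`prepare_target()`), and the model density is normalized the same way.
The classical inner-product and cross-correlation scores are provided
for comparison; cross-correlation is implemented as cosine similarity
without mean subtraction (self-score exactly 1, the common
flexible-fitting convention; nothing here depends on that choice and the
mean-subtracted variant would only shift each shell by a constant).

The noise-model scale parameters (the expected interaction counts) are
*not* estimated; they multiply the score and are absorbed into $k$,
which the adaptive protocol below manages.  A full Bayesian treatment of
those scales is out of scope.

### Forward model

`spread_density()` places a Gaussian of width $\sigma$ and amplitude
$A_i$ on each atom and evaluates it at voxel centers (point evaluation,
no per-voxel integral).  Amplitudes are 1 for heavy atoms and 0 for
hydrogens; per-atom Gaussians are normalized to unit integral before
amplitude scaling, so $A_i$ is the atom's total mass contribution and
the dimensionality exponent follows the number of non-degenerate grid
axes (1D/2D model systems reuse the same code with size-1 dimensions).

The width comes from the rule that the Gaussian's full width at half
maximum equals the target resolution,
$\sigma = \mathrm{res} / (2\sqrt{2\ln 2})$
(`sigma_from_resolution()`), with the maximum representable resolution
on a grid being twice the voxel size (`sigma_from_voxel()`); for a
1.23 Å voxel map this gives $\sigma \approx 1.045$ Å.  Spreading is
hard-truncated at $4\sigma$ (a real-space sphere tested against voxel
centers), which keeps more than 99.8 % of a 3D Gaussian's mass
(`truncation_mass_fraction(4)` $= 0.9989$, the $\chi^2_3$ CDF at 16).

### Forces

Forces decompose into a per-voxel score derivative contracted with the
analytic spreading gradient:

$$F_i = k \sum_v \frac{\partial S}{\partial \rho^s_v}\,
\nabla_{r_i}\rho^s_v, \qquad
\nabla_{r_i}\rho^s_v = \rho^s_{v,i}\,\frac{c_v - r_i}{\sigma^2}.$$

For the relative-entropy kinds the unit-sum normalization of the model
is part of the forward model, and its Jacobian is propagated through
`score_derivative()` (the uniform mode is projected out); without it the
forces would carry a spurious uniform component and would not be the
exact gradient of $U_\mathrm{fit}$.  Energy–force consistency is the
suite's central property test: for all four kinds, forces match central
finite differences of $U_\mathrm{fit}$ to better than $10^{-5}$ relative
error.

Density forces may be applied every $N_\mathrm{fit}$ integration steps,
scaled by $N_\mathrm{fit}$ (`apply_multiple_timestep()`), preserving the
delivered impulse.

### Adaptive force scaling and work

`scaling_update()` maintains an exponential moving average of $S$ and,
at each fitting application, divides $k$ by $1 + \alpha$ if the average
rose and multiplies it by $1 + 2\alpha$ if it fell.  The asymmetry
forces net progress; $\alpha = N_\mathrm{fit}\,\Delta t / \tau$ couples
the increment to a time scale $\tau$.  Refinement terminates when the
maximum per-atom force exceeds `f_max` — the normal endpoint, since $k$
keeps ratcheting upward once the fit has converged.

The exerted work along the similarity coordinate is
$W = \sum_f k_f \, \Delta S_f$ (`accumulate_work()`).  Because the
protocol buys its early similarity gains at small $k$ and only then
ramps $k$ by orders of magnitude, the work on a net-improving refinement
trace stays far below $k_\mathrm{final}(S_\mathrm{end} -
S_\mathrm{start})$, the price of a constant force at the final constant.
This is a statement about the protocol's operating regime, not a
theorem: on a trace whose $S$ increases strictly monotonically the
protocol only ever *lowers* $k$, making $k_\mathrm{final}$ the smallest
value on the trace and the same inequality impossible.  The test suite
therefore asserts the inequality on actual refinement traces (which is
also how the claim is meaningful in practice), not on arbitrary monotone
sequences.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `sigma` | from resolution/voxel rule | Å | spreading width |
| `cutoff_multiple` | 4 | σ | truncation radius |
| `alpha` | $N_\mathrm{fit}\Delta t/\tau$ | — | scaling increment |
| `ema_weight` | 0.1 | — | EMA weight per fitting step |
| `k_init` | small (e.g. $10^{-3}$) | energy/score | initial force constant |
| `f_max` | study-dependent | energy/Å | termination threshold |
| `n_fit` | 10 | steps | force application period |

The EMA constant and `k_init` have no canonical values; the defaults
smooth score noise over roughly ten applications and start the bias
gently (the protocol is insensitive to `k_init` because the ratchet
finds the working scale exponentially fast).  `f_max` is tied to
integrator stability and is therefore system-dependent; for the bead
helix it is set to 80 (energy/Å), roughly ten times the largest bonded
force seen in a short unbiased equilibration.

## Numerical choices

* **Positivity floor.**  Truncated spreading yields exact zeros, which
  would send the relative-entropy scores to $-\infty$.  Log arguments
  are floored at $\varepsilon = 10^{-12}$ (relative to unit-sum
  densities) and the derivative is set to zero where the floor binds.
  The floor leaves a $\sim 10^{-5}$-relative imprint on the otherwise
  exactly quadratic 1D single-particle landscape (far target tails see
  floored model voxels).
* **Truncation and differentiability.**  The hard $4\sigma$ cutoff
  makes $U_\mathrm{fit}$ piecewise smooth: crossing the cutoff sphere
  steps the density by $e^{-8}$ relative to the peak.  Finite-difference
  oracle tests therefore use a truncation radius covering the whole test
  grid, so they probe the gradient algebra on the smooth part;
  truncation behavior (captured mass, zero contribution beyond the
  sphere) is tested separately.
* **Landscape scans.**  The 1D/2D effective-landscape studies
  (`landscape_study()`) likewise use a truncation covering the scan
  domain: the claims under test (harmonic shape of the relative-entropy
  potential, minima structure) are continuum statements that the
  truncation sphere would otherwise imprint on by construction.
* **Ties.**  A tied EMA comparison decreases $k$, biasing toward
  gentleness.  `should_terminate()` uses a strict inequality.
* **Degenerate inputs.**  Zero-amplitude systems spread to all-zero
  grids (and stay all-zero under normalization); all-nonpositive targets
  are rejected for probability kinds; empty atom sets cannot be
  centered.
* **FSC shells** are one reciprocal voxel wide up to Nyquist; the DC
  term is excluded (it would trivially contribute 1 and dominate the
  unweighted average).  Degenerate grid dimensions contribute zero
  frequency, so the same code serves 1D/2D grids.

## The synthetic studies: what they emulate, and what they do not

The package generates all of its study inputs itself.

**Bead-helix refinement** (`make_bead_helix()`,
`make_kinked_target()`, `helix_refinement_study()`): a straight 20-bead
helix (rise 1.5 Å, radius 2.3 Å, twist 100° per bead; bonds
$k_b = 200$, angles $k_a = 50$, in units of $k_BT_\mathrm{ref}$ per Å²
and rad², with $k_BT = 0.05$ — a stiff, low-noise chain) refined into
the synthetic map of its 30°-kinked copy.  No dihedral terms: torsions
stay free, so the kink is reachable while connectivity and local
stiffness persist — the prior supplies stereochemistry, the density the
conformation.  The target map is generated at 4 Å nominal resolution
($\sigma \approx 1.70$ Å, voxel 1 Å): for a featureless bead chain a
bead-resolving map would carry registry-shift local minima that an
all-atom model, whose side chains break the sliding symmetry, does not
have, so the bead-merged tube is the faithful analog.  Study size:
5 replicates × 60 000 Brownian steps ($\Delta t = 2\times10^{-3}$,
$N_\mathrm{fit} = 10$, $\tau = 0.8$, so $\alpha = 0.025$).  All five
replicates end below 3 % of the initial superposition-free RMSD, most
of them terminated by the force limit.

**Brownian work benchmark** (`brownian_benchmark()`): a 1D particle
whose similarity is its coordinate, with a Gaussian barrier (height 8,
width 0.5) at $x = 1.5$ on a $0 \to 10$ coordinate at $k_BT = 0.25$ —
a localized, thermally uncrossable barrier early on a long path.  This
is the regime in which adaptation pays: a constant force strong enough
to cross the barrier must be paid along the entire coordinate, while
the adaptive protocol raises the force only at the barrier.  The fixed
arm is calibrated by bisection (common random numbers) to the adaptive
arm's mean first-passage time within 5 %; with 100 replicas the
adaptive arm exerts significantly less work (one-sided Welch test).
With a weak barrier, or one crossable by the noise-floor force the
ratchet maintains anyway, the ordering reverses — the benchmark
potential is part of the study design, not a free knob.

**What passing these studies does and does not show.**  The studies are
noise-free: the target maps are exact forward-model outputs, so they
probe the potentials' geometry (long-rangedness, minima structure,
smoothness) and the scaling protocol's work behavior, not robustness to
experimental noise, solvent density, map sharpening artifacts, or
model/map mass mismatches.  The relative-entropy score in particular is
known to be sensitive to unmodeled density; nothing here tests that
regime.  The Brownian propagator probes no inertial or thermostat
effects.

## Limitations

* Real-space spreading only; no Fourier-space evaluation, no
  element-specific amplitudes, no B-factors, no local-resolution-varying
  width.
* The toy engine is overdamped Brownian dynamics with bonds and angles;
  it is not an MD engine and makes no claim about all-atom kinetics.
* No mmCIF, map symmetry, or half-map handling; no masked or
  phase-randomized FSC.
* The noise-model scale parameters are heuristically absorbed into the
  adaptive force constant; the trajectory is a non-equilibrium path, not
  a posterior sample.

## Problem sizes

The shipped tests run the studies at: 1000-pair Gibbs suite on grids up
to $5^3$; 20 random force instances per similarity kind on $8^3$ grids;
landscape scans at 61–121 grid points per axis; 100 + 100 benchmark
replicas; 5 helix replicates of 60 000 steps; FSC suites on $48^3$
grids.  These sizes were chosen so the full suite completes in minutes
on a single core while every statistical assertion retains a comfortable
margin (seeded, hence deterministic).
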