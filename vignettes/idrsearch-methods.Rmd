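---
title: "Models and methods behind idrsearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind idrsearch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrsearch)
```

## The physical picture

Most eukaryotic transcription factors (TFs) carry, besides a structured
DNA-binding domain (DBD), a long intrinsically disordered region (IDR) that
behaves like a flexible polymer and contains several short linear motifs able
to bind DNA weakly.  `idrsearch` implements a coarse-grained model of how
such a disordered tail changes (i) the equilibrium probability that the DBD
occupies its specific target, and (ii) the time the TF needs to find that
target inside the nucleus.

The TF is an ideal bead–spring chain of `n_tilde = n_b + 1` sites: a
terminal DBD site plus `n_b` IDR binding sites joined by Gaussian segments
of statistical length `l0`.  The DNA near the specific site is a straight
"antenna": the DBD target sits at the origin and `n_t` IDR targets sit at
spacing `d` along a line.  Lengths are in base pairs (1 bp = 0.34 nm),
energies in kT, times in `t0 = bp^2 / D` with `D` the diffusion coefficient
of one coarse-grained site.  The site-to-amino-acid mapping is left
symbolic throughout: all reproduced quantities are ratios of times or
probabilities, so only `t0` carries the absolute scale, and the
`aa_per_segment` constant (default 20) is used solely to label truncation
axes in amino acids.

## Equilibrium binding

For two chain sites `n_seg` segments apart the separation density is the
ideal-chain propagator

    f(r, l) = (3 / (2 pi l^2))^{3/2} exp(-3 r^2 / (2 l^2)),  l = sqrt(n_seg) l0,

(`gaussian_propagator()`).  A binding configuration is an injective partial
matching of IDR sites onto IDR targets (crossing orientations included),
together with the DBD bound/unbound state — `2 sum_n C(n_b, n) C(n_t, n) n!`
configurations in all.  Integrating out the unbound degrees of freedom gives
each configuration the weight

* free chain: the translational volume `V`;
* first bound contact (lowest chain index): `exp(E) V1`;
* each further contact: `exp(E) V1 f(target separation, contour distance)`,

with `E = E_DBD` for the DBD contact and `E_B` per IDR contact and `V1` the
target volume.  This convention is fixed by two requirements: it must reduce
to the single-contact affinity ratio `Q = 1 + P` with enhancement factor
`P = exp(E_B) V1 f(d, l0)` for `n_b = n_t = 1`, and the weak-binding sum
must telescope into products of `P` over consecutive contacts.  It is also
verified against a continuous-space Metropolis sampler (below).
`binding_probability()` performs the sum exactly in log space; branches
whose Gaussian product falls below `1e-300` are pruned, which bounds the
cost of the largest scans without touching any reported digit.

Two derived quantities organise the design principles: the affinity ratio
`Q = P_TF / P_simple` against a TF without an IDR, and the threshold energy
`E_th(phi) = (3/2)(log(2 pi / (3 phi^2)) + 1)` at which one contact breaks
even (`P = 1`) when `l0 = d`, with `phi = V1^{1/3} / d` the linear target
fraction.  `scan_design_principles()` reproduces the standard scans: the
optimum at `l0 = d`, the heatmap governed by `min(n_b, n_t)`, the minimal
diagonal counts reaching `P_TF >= 0.9`, the switch-like rise of `Q` around
`E_th` towards the saturation `1 / P_simple`, and the truncation curve.

A property of the exact sum worth knowing: sites and targets are *not*
interchangeable away from the diagonal.  Extra targets beyond the site
count add almost nothing (`Q(n_b, n_t > n_b)` sits within a couple of
percent of `Q(n_b, n_b)`), because placements far from the anchored DBD
contact are cut off by the first-contact propagator.  Extra *sites* beyond
the target count keep helping, by a factor of a few, because a site `k`
segments from the last contact still reaches a target at distance `d` with
weight `~ k^{-3/2} exp(-3 d^2 / (2 k l0^2))` — the orientation sum over
sites decays slowly.  Affinity is still governed by `min(n_b, n_t)` to
leading order, but the heatmap is quantitatively asymmetric in the
unsaturated regime; the Monte Carlo sampler confirms this is a property of
the model, not of the enumeration.

Two modelling choices deserve a note.  The DBD site binds only the DBD
target and IDR sites bind only IDR targets; allowing IDR sites to park on
an unbound DBD target would perturb `P_IDR_only` slightly but not the
DBD-occupancy results, and the restriction matches the four-state
single-site model.  Configurations are injective (one site per target):
that is the configuration count used by the combinatorics, and in the
dynamical model the excluded-volume interaction enforces the same rule.

### The Monte Carlo cross-check

`metropolis_binding()` is an independent estimate of `P_TF`: the chain with
harmonic bonds is sampled in a periodic cell of volume `V`, targets are
square wells of volume `V1` (depth `E_B` or `E_DBD`), and a hard
single-occupancy constraint mirrors the injective matching.  Mixing uses
three move types — local site displacements, symmetric rigid translations,
and an independence proposal that redraws the whole internal conformation
from its exact bond Gaussians (the bond energy cancels against the proposal
density, so only well energies enter the acceptance).  Errors come from
batch means.  The comparison runs use wells of radius 2 bp in a 50 bp cell
so that occupancies are of order 0.1–0.4 and mixing is fast; finite-well
and periodic-image corrections are then below the Monte Carlo error.

## Search dynamics

`run_search()` integrates overdamped Langevin dynamics (Euler–Maruyama) of
the chain inside a reflecting sphere of radius `R`.  The antenna lies along
a diameter; the absorbing DBD target (radius `a`) sits at the centre and
IDR targets are Gaussian wells of depth `E_B` and width `w_d = 1` bp placed
symmetrically at spacing `d` up to the span `L`.  Forces are harmonic
springs (`k = 3 kT / l0^2`), the attractive wells, and a WCA repulsion of
diameter 1 bp between all site pairs that keeps two sites out of one well.
Near the antenna the time step adapts as
`dt = 0.01 min(1, kT / (max_i |f_i| bp))`, keeping the drift per step well
below the well width; far from the antenna (beyond 10 bp) the chain is
translated rigidly with diffusion coefficient `D / n_tilde` and a step
whose RMS displacement is one fifth of that threshold, and the WCA and well
forces are frozen — search times are insensitive to the exact threshold.
Reflection is a mirror correction about the sphere's tangent plane, which
preserves the uniform equilibrium measure for pure diffusion at small
steps.  Runs start from an equilibrated chain placed uniformly in the
sphere and end when the DBD site enters the capture radius, or at a
censoring horizon (50x the two-term prediction) after which the run is
flagged rather than dropped.

Attachment and detachment are trajectory *diagnostics*, not forces: the
chain counts as attached when any site is within `2 w_d` of a target, and
as detached when every site has stayed beyond the far-field threshold for
longer than one chain relaxation time `n_tilde^2 l0^2 / D`.  The 3D/1D
split (`t_3d`, `n_rounds`) therefore depends mildly on these two constants;
they are exposed in `search_config()` so the sensitivity can be audited.

`point_searcher_reference()` validates the integrator against closed forms:
a single particle absorbed by a central sphere reproduces
`t_simple = R^3 / (3 D a)`, and absorption on a thin central cylinder
reproduces the slender-antenna capture time
`alpha (R^3 / D L) log(L / r_p)`.  Its distance-adaptive step (RMS step =
0.1x the distance to the absorber, floored at 0.2 capture radii) was chosen
by convergence checks against the spherical closed form; the residual
integrator bias is a few percent, well below the Monte Carlo error of the
reference runs.  The fitted cylinder prefactor comes out 10–20% below the
slender-ellipsoid value 2/3 at moderate `log(L / r_p)`, the expected
finite-thickness correction for a cylindrical absorber.

## Search-time theory

`t_total_theory()` evaluates the two-term search time

    t_total = alpha n_tilde R^3 log(L / r_p) / (D L) + beta L^2 / D,

with `r_p = sqrt(n_tilde / 6) l0` the gyration radius: a 3D capture term
for a searcher of diffusivity `D / n_tilde` finding a thin antenna, plus a
1D walk over the antenna.  `fit_alpha_beta()` fits the two prefactors by
weighted least squares on simulated `t_3d` and `t_1d` tables (reference
values `alpha = 0.5`, `beta = 14.5` at the published optimum
`E_B = 11`, `n_tilde = 4`); `optimal_antenna()` minimises the expression
over `L` (bracketed scalar minimisation, relative tolerance `1e-6`, ties
toward smaller `L`), giving `L* ~ R` and `t_min ~ R^2`, an order of
magnitude below `t_simple` at nuclear scales.  The simple-TF baseline uses
the single-site `D`, not `D / n_tilde`: the simple TF is a single bead.

`binding_rates()` converts a search time into biochemical rates.  With
`copy_number` independent searchers the per-cell association time is
`t_eff = t_total / copy_number`; for one target in the nuclear volume
`V_n`, the target concentration is `c = 1 / (V_n N_A)` and

    k_on = 1 / (t_eff c),   k_off = (1 - P_TF) / (P_TF t_eff),
    k_D = k_off / k_on.

A literal reading "k_on = t_total / V_c" that circulates for this
conversion is dimensionally inconsistent (a time divided by a volume is not
a second-order rate); the package implements the consistent form above and
records the formula in its outputs.  With yeast-scale parameters
(`R = 1 um`, `D = 1e-13 m^2/s`, 100 copies) the optimal antenna gives
`k_on` of order `1e8 M^-1 s^-1`, and across an IDR-length sweep the
variation of `k_D` is carried almost entirely by `k_off`.

## The octopusing walk

While attached, the chain slides along the antenna by asynchronously
binding and unbinding its sites — an effective 1D walk.  `octopus_summary()`
quantifies it from subsampled trajectories: the bound-count histogram, the
effective `D1` (MSD of the antenna-axis centre of mass within attached
episodes, fitted over lags of 10–100 strides — the window is reported so
its influence is auditable), the full-detachment rate, and the
compensatory feedback: the rate of gaining a contact falls, and of losing
one rises, with the number already bound.  This feedback is how the walk
bypasses the speed–stability trade-off: binding stays strong on average
while individual contacts turn over quickly.

## Problem sizes, seeds and reproducibility

All stochastic entry points take explicit integer seeds; replicate `i` of a
sweep derives its stream as `seed + i` (or `seed + 1000 g + k` for nested
grids), so any run can be reproduced bit for bit from its manifest.  The
package's own test suite and drivers run the dynamics at reduced scale,
chosen so that every documented phenomenon is resolved at 2–3 standard
errors within minutes of CPU time.  The reference reduced conditions for
the antenna-length study are a sphere of `R = 100` bp, a four-site chain
(`l0 = 5` bp, `E_B = 8` kT), targets every `d = 5` bp, an absorber of
`a = 0.5` bp and 50 runs per antenna length on the grid
`L ∈ {8, 100, 150}` bp; the 8 bp point is shorter than twice the spacing,
so it realises the bare-search limit of an antenna too short to host IDR
targets.  At these conditions the interior minimum of `t_total(L)`, the
exponential first-passage tail and single-round dominance near the optimum
are all resolved.  Octopusing statistics use smaller, stickier systems
(`R = 25` bp, `E_B = 8–9` kT) where attached episodes are long.  The published-scale optimum
(`R = 500 bp`, `L* = 300 bp`, `E_B* = 11`, `n_tilde* = 4`) sits behind
orders of magnitude more simulation effort; the package reproduces it
through the fitted two-term theory rather than by brute force, and the
figure drivers record grid and run counts in their manifests.

What the reduced-scale simulations do *not* probe: chromatin structure and
coiled or curved antenna geometries, hydrodynamic or electrostatic
interactions, rotational rigid-body diffusion, sequence-level motif
recognition, and nonspecific binding to the rest of the genome.  Equally,
the synthetic layouts (equal-spaced or Poisson-spaced targets on a straight
line) emulate the *assumed* geometry of a target-rich flanking region, not
measured genomic target positions, so passing tests demonstrate internal
consistency of the model, not agreement with any particular locus.

## Numerical choices

* Configuration sums accumulate in log space (log-sum-exp); argmax ties in
  scans break toward the smaller parameter.
* Enumeration refuses grids beyond `1e7` configurations unless the pruning
  path is used; pruning drops branches whose Gaussian product is below
  `1e-300`.
* The Euler–Maruyama step keeps `max |f| dt <= 0.01 bp`; the WCA core
  force is capped at 100 kT/bp (the cap only engages deep inside the core,
  where the drift limit would otherwise freeze the adaptive step).
* Well interactions are cut off where the Gaussian factor falls below
  `exp(-60)`; besides being negligible, this keeps subnormal floating-point
  values out of the force loop.
* The Brownian kernels draw their normals from a Marsaglia–Tsang ziggurat
  seeded per run; its moments and distribution are audited in the test
  suite alongside the integrator checks.
* Degenerate inputs fail loudly: `L <= r_p` in the theory, `phi <= 0`,
  non-positive volumes, `P_TF` on the boundary of (0, 1).
* Censored searches are excluded from means and reported; more than 10%
  censoring raises a warning.
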