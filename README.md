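# idrsearch

Most eukaryotic transcription factors (TFs) pair a structured DNA-binding
domain (DBD) with a long intrinsically disordered region (IDR) carrying
several weak DNA-binding motifs.  `idrsearch` is an R package for studying,
with a coarse-grained polymer model, how such a disordered tail changes

* the **equilibrium probability** that the DBD occupies its specific target
  site, and
* the **search time** the TF needs to find that site inside the nucleus.

It is aimed at biophysicists and quantitative biologists who want a small,
fully scriptable laboratory for multivalent TF–DNA binding and
facilitated-search kinetics.

## The model in brief

The TF is an ideal bead–spring chain of `ñ = n_b + 1` sites (one terminal
DBD site, `n_b` IDR sites, segment length `l0`).  Its targets sit on a
straight DNA "antenna": the DBD target plus `n_t` IDR targets at spacing
`d`.  Lengths are in base pairs (1 bp = 0.34 nm), energies in kT, times in
`t0 = bp² / D`.

**Equilibrium.**  Every injective matching of IDR sites onto IDR targets
(`2 Σ C(n_b,n) C(n_t,n) n!` configurations) gets the weight implied by the
Gaussian chain propagator `f(r,l) = (3/2πl²)^{3/2} exp(−3r²/2l²)`; the
exact configuration sum yields `P_TF` and the affinity ratio
`Q = P_TF / P_simple` against a TF without an IDR.  A single extra contact
multiplies the binding weight by the enhancement factor
`𝓟 = e^{E_B} V₁ f(d, l0)`, and one contact breaks even (`𝓟 = 1`) at the
threshold energy `E_th = (3/2)[ln(2π/3φ²) + 1]`, `φ = V₁^{1/3}/d`.
A continuous-space Metropolis sampler provides an independent check.

**Dynamics.**  Overdamped Langevin simulation of the chain in a reflecting
sphere of radius `R`, with Gaussian-well targets (depth `E_B`, width 1 bp)
on a central antenna of length `L` and an absorbing DBD target (radius `a`)
at the centre.  The mean first-passage time decomposes into a 3D capture
term and a 1D sliding ("octopusing") term,

    t_total ≈ α (ñR³/DL) ln(L/r_p) + β L²/D,     r_p = √(ñ/6) l0,

which the package fits (`α`, `β`), minimises over `L`, and converts into
`k_on`, `k_off` and `k_D`.

## Worked example

```r
library(idrsearch)

arch <- tf_architecture(n_b = 1, l0 = sqrt(50))   # one IDR site
lay  <- target_layout(n_t = 1, d = sqrt(50))      # one IDR target
en   <- energy_model(E_B = 10, E_DBD = 15, V1 = 1, V = nm3_to_bp3(1e9))

binding_probability(arch, lay, en)
#> Equilibrium binding (1 IDR sites, 1 IDR targets):
#>   P_TF = 0.0007172   P_IDR_only = 8.651e-07   P_free = 0.9993
#>   P_simple = 0.0001285   Q = P_TF / P_simple = 5.583

enhancement_factor(10, sqrt(50), sqrt(50), 1)
#> [1] 4.586276
threshold_energy(sqrt(0.02))
#> [1] 8.476932
```

One weak contact (`E_B = 10 kT`, one segment) multiplies the DBD occupancy
nearly six-fold (`Q ≈ 1 + 𝓟`); contacts start paying off above
`E_th ≈ 8.5 kT` at a 2% target area fraction.  On the kinetic side:

```r
opt <- optimal_antenna(n_tilde = 4, R = 500, D = 1, l0 = 5)
opt$L_star; opt$t_min / simple_tf_time(500, 1, 0.5)
#> [1] 305.767
#> [1] 0.05861499
```

With the reference prefactors (`α = 0.5`, `β = 14.5`) a 500 bp nucleus has
its optimal antenna near 300 bp, and the optimised search is ~17× faster
than the bare-DBD baseline `R³/(3Da)`.  `run_search()` /
`estimate_mfpt()` generate the corresponding first-passage statistics by
simulation, and `octopus_summary()` quantifies the 1D walk (bound-site
histogram, effective `D1`, on/off feedback).

A thin CLI wraps the same functions, e.g.

```sh
Rscript inst/scripts/idrsearch simulate-search --R 60 --L 40 --e-b 7 --n-runs 50 --seed 1 --out search/
Rscript inst/scripts/idrsearch figure --id fig2d --seed 1 --out figures/
```

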