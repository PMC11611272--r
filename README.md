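# mitofission

Dynamics and sensitivity analysis of Drp1/Mff-dependent mitochondrial
fission.

Mitochondria fragment when the cytosolic GTPase **Drp1** is recruited to
the outer mitochondrial membrane by the receptor **Mff**, and the
resulting Drp1–Mff complexes polymerize into helical oligomers long
enough to constrict and sever the organelle. Hyperfission accompanies
ischemic injury and neurodegeneration, so the question of *which kinetic
steps actually control the fission rate* matters for target selection.
This package implements a deterministic mass-action model of that
mechanism and the analysis suite built around it, for modelers who want
to simulate it, locate its bifurcations, or rank its parameters.

## The model

State `(T, M, C1..CN)`: cytosolic Drp1 tetramers, unbound membrane Mff,
and oligomers of size `i` (all nM), with reactions

```
T + M  <->  C1            (k1, k_m1)
Ci + C1 <-> C(i+1)        (k_plus, k_minus, size-independent)
Ci  -> i T + i M          at rate a for i > ell   (fission)
```

Fission is size-thresholded (`ell = 25`, `N = 30`): only oligomers large
enough to encircle a mitochondrion fire, and the event returns their
material to the free pools. The Drp1 balance carries the
membrane-to-cytosol space ratio `gamma`. Total Drp1 and total Mff are
conserved. The observable is the **total fission rate**
`TFR(t) = a * sum_{i>ell} Ci(t)` (events nM/s) and its time integral, the
**cumulative total fission**.

Rescaling by total Mff and `1/k_minus` leaves four dimensionless groups —
`mu = k_plus*M_total/k_minus` (build-to-disassembly ratio), `alpha =
a/k_minus`, `beta = k1*M_total/k_minus`, `zeta = k_m1/k_minus` — and the
analyses show the TFR undergoes a **Hopf bifurcation in `mu`** (damped to
sustained oscillations) while the cumulative TF depends on `mu`
non-monotonically, rising to an interior optimum and falling again.

## Worked example

```r
library(mitofission)

p <- fission_params()          # canonical rate table
traj <- simulate_fission(p)    # stiff solver, 5000 s
traj
#> <fission_trajectory> dimensional system, 32 states, 2001 time points
#>   window [0, 5000], final TFR 0.006903, cumulative TF 30.558
#>   conservation drift 1.47e-14
classify_oscillation(traj)
#> [1] "damped"
```

The TFR oscillates in sync with free Mff and damps toward a steady state;
over 5000 s about 30.6 nM of mitochondria-severing events accumulate, and
both conserved totals drift only at roundoff level.

```r
nd <- nondimensionalize(p)
nd
#> Dimensionless fission-model parameters
#>   mu = 750  alpha = 50  beta = 150  zeta = 0.2
#>   gamma = 0.1  theta = 1.33333
#>   threshold ell = 25, max size N = 30

find_steady_state(nd)
#> <steady_state> dimensionless fission model
#>   residual sup-norm 3.483e-15 after 2 Newton iteration(s)
#>   2 zero eigenvalue(s) (|lambda| < 1e-08), 30 nonzero
#>   max Re(nonzero) = -0.01333  ->  stable
```

The Newton solver (on the conservation-reduced system) converges to a
fixed point whose spectrum has exactly two zero eigenvalues — one per
conserved quantity — and 30 stable ones: at `mu = 750` the damped
oscillations die out. Raising `mu` by 25% pushes a conjugate eigenvalue
pair across the imaginary axis (`find_hopf_mu()` brackets the crossing
near `mu ≈ 827`) and the oscillations become self-sustaining, while the
cumulative TF peaks between the baseline and +25%:

```r
oat_scan(nd, "mu")
#> <oat_result> dimensionless 'mu' (baseline 750), window [0, 500]
#>  multiplier  value cumulative_tf oscillation error
#>        0.25  187.5     0.2528974      damped  <NA>
#>        0.75  562.5     1.3159677      damped  <NA>
#>        1.00  750.0     2.0371727      damped  <NA>
#>        1.25  937.5     2.2704489   sustained  <NA>
#>        1.75 1312.5     2.1475107   sustained  <NA>
```

Variance-based sensitivity analysis (native Saltelli/Sobol engine with
bootstrap CIs) ranks the rate constants by their share of the cumulative
TF's variance, e.g. `run_gsa_case("case1", base_N = 2048, seed = 1)` for
the four dimensional rates, `"case2"` to add total Mff, or
`"dimensionless"` for the four groups — where `mu` alone carries
essentially all of the variance (first-order index ≈ 0.98).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/fission nondim
Rscript inst/cli/fission sobol --case 1 --base-n 2048 --seed 1 --outdir out/
```

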