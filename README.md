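# lvcomm

Stability and resilience of random Lotka–Volterra communities, as a
function of how mutualistic they are.

A long-standing view in theoretical ecology holds that mutualism
(+/+ interactions) destabilizes communities, a conclusion usually
reached by analysing the eigenvalues of a random interaction matrix
**A** alone. `lvcomm` implements the density-weighted analysis: for a
community of *n* species with dynamics

    dN_i/dt = N_i ( r_i + Σ_j a_ij N_j ),   a_ii = −1,  r_i = +1,

local stability at the feasible interior equilibrium
**N\*** (solving **A N\* = −r**, all densities positive) is governed by
the community matrix (Jacobian)

    S = D A,   D = diag(N*_1, …, N*_n),

whose leading eigenvalue Λ = max Re(λ_i) sets the asymptotic return
rate |Λ| after a disturbance. Because **S N\* = −N\***, every feasible
community carries a −1 outlier eigenvalue, and for purely mutualistic
communities Perron–Frobenius pins Λ = −1 exactly. Mutualism raises
equilibrium densities — the uniform-model mean field is
N\* = 1/[1 − (n−1) m C P] — which shifts the random-matrix bulk of
eigenvalues left (its centre tracks −⟨N\*⟩) and drives
Λ ≃ max{−N\*_min, −1} downward until it saturates at −1. Higher
densities mean stronger pullback: mutualists recover from pulse
perturbations much faster, not slower.

The package is for ecological theorists and systems biologists who want
these ensembles, spectra and perturbation experiments as reproducible,
seeded, tidy pipelines.

## What's inside

- `generate_chen_cohen()`, `generate_uniform()`, `generate_gaussian()` —
  random interaction matrices with a prescribed proportion *P* of
  mutualistic pairs, connectance *C*, half-normal magnitude scale σ,
  and exploitative / competitive / random backgrounds.
- `solve_equilibrium()`, `mean_field_Nstar()`, `blowup_bound()`,
  `may_condition()`, `feasibility_probability()` — equilibria,
  feasibility, and the closed-form bounds that constrain mutualism.
- `community_matrix()`, `community_spectrum()`, `lambda_approx()`,
  `eigen_density_relation()`, `trace_identity_check()` — the S = DA
  spectrum with bulk/outlier decomposition.
- `integrate_lv()`, `pulse_perturb()`, `return_time()`,
  `recovery_phases()` — nonlinear dynamics, pulse disturbances, and
  two-phase recovery-rate estimation.
- `sweep_P()` / `crossing_P()`, `eigen_cloud()`,
  `pulse_recovery_experiment()` — the full seeded experiments, as
  tibbles with `tidy()` / `glance()` / `autoplot()` support.
- A thin command-line front end at `inst/cli/lvcomm.R`
  (`generate`, `equilibrium`, `spectrum`, `perturb`, `sweep`, `cloud`,
  `pulse-compare`).

## Worked example

```r
library(lvcomm)

# one random community at the study scale
x  <- generate_chen_cohen(gen_params(n = 100, P = 0.5, C = 0.7,
                                     sigma = 0.02, seed = 1))
eq <- solve_equilibrium(x)
eq
#> <lv_equilibrium> n = 100, feasible
#>   min N* = 1.269, mean N* = 2.21, residual = 2.3e-15
sp <- community_spectrum(community_matrix(eq), eq$Nstar)
sp
#> <spectral_summary> n = 100, Lambda = -1 (locally stable)
#>   outlier = -1+0i, bulk centre = -2.2221+0i
lambda_approx(eq$Nstar)
#> [1] -1
```

At *P* = 0.5 the minimum density already exceeds 1, so the leading
eigenvalue sits on the −1 outlier (the community is as resilient, in the
asymptotic sense, as it can get) while the bulk centre −2.22 matches the
negated mean density −⟨N\*⟩ = −2.21.

```r
sw <- sweep_P(gen_params(n = 30, C = 0.7, sigma = 0.02),
              P_grid = seq(0, 0.8, by = 0.2), reps = 20, seed = 1)
dplyr::select(tibble::as_tibble(sw), P, Lambda_mean, Nmin_mean,
              Nmean_mean, mean_field)
#>       P Lambda_mean Nmin_mean Nmean_mean mean_field
#> 1   0        -0.849     0.823      0.995       1
#> 2   0.2      -0.905     0.883      1.07        1.07
#> 3   0.4      -0.946     0.936      1.15        1.15
#> 4   0.6      -0.995     1.04       1.25        1.24
#> 5   0.8      -1         1.15       1.35        1.35
```

Λ falls with *P* while it tracks −N\*_min, then saturates at −1 once the
minimum density crosses 1; the mean density follows the mean-field
formula closely. `autoplot(sw)` draws the curves.

```r
pe <- pulse_recovery_experiment(n = 10, depth = 0.4, n_seeds = 5, seed = 1)
glance(pe)
#>   ensemble    mean_return_time mean_Nmean mean_Lambda  runs
#> 1 mean-zero               4.1       0.973      -0.728     5
#> 2 mutualistic             1.66     11.4        -1         5
```

Depressing one species by 0.4 density units, the purely mutualistic
ensemble (mean interaction 0.1, all positive) returns to its
equilibrium band about 2.5× faster than the mean-zero ensemble — its
equilibrium densities, near the mean-field value 1/(1 − 9·0.1) = 10,
give the community matrix much stronger restoring rates.

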