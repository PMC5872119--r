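# phagegrid

Bacteria growing in biofilms and other structured habitats persist at far
higher densities under lytic phage attack than the same cells do in liquid
culture. `phagegrid` is a simulation toolkit for asking how much of that
elevation spatial structure *alone* can produce when the only thing keeping
the phage in check is death at spatially fixed sinks — exopolysaccharide
(EPS) laid down at fixed patches, and short-lived debris from lysed cells.
It is aimed at microbial ecologists and phage-therapy modelers who want to
regenerate, probe, or extend this class of lattice predator–prey models.

The package contains three models that share one parameterization:

* **Spatial grid model** — a stochastic torus lattice. Each patch holds at
  most one cell (uninfected, or infected with an age); EPS flags and debris
  counters are per patch; free phage are integer counts. Each time step runs
  four global phases: *lysis* (infected cells of age `infected_lifespan`
  release `b` phage and may leave debris), *reproduction* (daughters into
  empty neighboring patches, orthogonal preferred), *infection* (each phage
  runs one Bernoulli trial per entity present — `k_C`, `k_I`, `k_D`, `k_E` —
  in random order, first success wins; only the cell hit is productive), and
  *diffusion* (a truncated bivariate-normal 3×3 kernel applied
  deterministically, with unbiased stochastic rounding to integer counts).
* **Mass-action grid model** — identical mechanics and finite population,
  but every step all phage are multinomially reassigned to patches and all
  cells reassigned to distinct patches, which abolishes spatial structure.
* **Delay-ODE mass-action model** — the classic well-mixed counterpart,

  dC/dt = r C (1 − C/K) − κ C P
  dP/dt = b κ C_L P_L − κ C P − δ P,

  where the subscript L marks values a lysis delay L minutes in the past.

## The amplification statistics

At any mass-action equilibrium each burst replaces itself, so with

α = k_C C / (k_C C + k_I I + k_D D + k_E E)

(the productive fraction of all free-phage loss routes) the product α·b
equals 1. Computed from the global densities of a *spatial* run, α·b
measures how far the system sits above what mass action would sustain.
Without superinfection or debris (k_I = k_D = 0) the equilibrium cell
density is the constant Ĉ = k_E E / (k_C (b − 1)), and

A_g = C_obs / Ĉ,  with upper bound A_ub,g = 1/Ĉ = k_C (b − 1) / (k_E E),

is the fold elevation of cell density attributable to spatial structure.
The ODE analogue references C̄ = δ / (κ (b − 1)): A_ode = mean(C)/C̄ with
A_ub,ode = K/C̄. The per-minute correspondences δ = −ln(1 − k_E E) and
κ = −ln(1 − k_C)/K connect the grid's per-step probabilities to the ODE's
rates.

## Worked example

A clustered-EPS run on a 20×20 torus (burst 10, EPS on 30% of patches,
k_C = 0.25, k_E = 0.35, 3000 steps averaged over the last 1500):

```r
library(phagegrid)
p <- sim_params(width = 20, height = 20, burst_b = 10, eps_fraction_E = 0.3,
                eps_layout = "clustered_rows", n_steps = 3000,
                avg_window = 1500, seed = 11)
r <- run_spatial(p)
r
#> phage_sim: spatial run, 20 x 20 grid, b = 10, E = 0.3 (clustered_rows)
#>   3000 steps; window means over last 1500 steps:
#>     C = 0.1249  I = 0.1416  D = 0  P = 899.8
#>     alpha*b = 2.27  A_g = 2.68 (upper bound 21.4)
```

α·b ≈ 2.3 and A_g ≈ 2.7: the spatial system holds cells at about 2.7 times
the density mass action could sustain with these parameters. The
self-organization diagnostics show why — cells pile into the EPS band while
free phage avoid it, and per-burst losses balance the burst size:

```r
s <- r$summary
#> C:E = 0.99  P:E = 0.057  I:E = 0.81
#> per-burst losses: P->C 1.00, P->E 9.02 (sum 10.02 vs b = 10)
```

Of every burst of 10, on average one phage goes on to a productive
infection and nine die on EPS. The same seed reproduces these numbers
bit-identically; `run_mass_action(p)` with random EPS layout typically ends
in extinction at these parameters. The well-mixed counterpart by ODE:

```r
fit <- run_dde(ode_params(kappa = 5e-11, delta = 0.1, b = 10))
fit
#> phage_dde: b = 10, delta = 0.1, kappa = 5e-11, L = 20 (completed)
#>   A_ode = 1.72 (windows 1.73, 1.72, 1.72, 1.72); upper bound 4.5
```

Here the elevation above C̄ comes entirely from sustained oscillations, not
self-organization. A thin command-line wrapper over these functions is in
`inst/cli/phagegrid.R` (subcommands `simulate`, `massaction`, `ode`,
`sweep`, `snapshot`).

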