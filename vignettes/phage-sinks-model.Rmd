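---
title: "Spatial self-organization of phage and bacteria around fixed phage sinks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial self-organization of phage and bacteria around fixed phage sinks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagegrid)
```

## The question and the models

Sensitive bacteria in biofilms persist under lytic phage attack at densities
far above what well-mixed (mass-action) theory predicts. This package
implements a minimal mechanistic setting for that phenomenon: cells are
intrinsically susceptible, and their only protection is that phage die at
*spatially fixed sinks* — permanent exopolysaccharide (EPS) patches and,
optionally, short-lived debris left by lysed cells. Because phage death is
anchored in space while phage killing of cells is wherever the phage are,
cells and phage can sort themselves into complementary refuges: cells
accumulate where phage die, phage accumulate where nothing kills them. The
quantitative question is how much this self-organization elevates the
sustained cell density above the mass-action equilibrium.

Three models share one parameterization:

1. the stochastic spatial lattice (`run_spatial()`),
2. its shuffled mass-action twin (`run_mass_action()`): same finite
   population, same rules, but global random relocation of phage and cells
   each step, and
3. a delay differential equation model (`run_dde()`), the classic
   continuous-density limit of mass action.

## The measuring stick: alpha, C-hat and the A statistics

Cell density alone cannot reveal an effect of spatial structure, because the
mass-action equilibrium density itself moves with every parameter. The
package's metrics are all referenced to the reproductive-equilibrium
identity: at a mass-action equilibrium each infection replaces itself, so
the productive fraction of free-phage losses,

$$\alpha = \frac{k_C C}{k_C C + k_I I + k_D D + k_E E},$$

satisfies $\alpha b = 1$. Computed from the *global* densities of a spatial
run (deliberately ignoring the spatial arrangement that produced them),
$\alpha b > 1$ means that a sudden switch to mass action would let each
burst launch $\alpha b$ new infections — the degree of protection the
spatial arrangement is giving the cells. With $k_I = k_D = 0$ the identity
inverts to an equilibrium density $\hat C = k_E E / (k_C (b-1))$, giving
$A_g = C_{obs}/\hat C$ with upper bound $A_{ub,g} = 1/\hat C$ (a grid
completely full of cells). When superinfection or debris is active,
$\hat C$ would depend on dynamic variables, so summaries switch to
$\alpha b$ (`summarize_window()` does this automatically; the generalized
$\hat C$ form is available from `c_hat()` but only with caller-supplied
`I`, `D`, and it is flagged approximate). The per-step $\alpha b$ values
are averaged over the trailing window; the alternative — $\alpha$ of the
window-mean densities — is reported alongside as `alpha_b_of_means`, and
the 10th–90th percentile span of the per-step values serves as the
oscillation diagnostic.

## The spatial model, phase by phase

A step applies four phases globally (every patch finishes one phase before
the next begins), in the order lysis, reproduction, infection, diffusion.
The alternative per-patch asynchronous order is known from prototype work
to give comparable results; the global order is the one implemented.

**Lysis.** Infected ages increment, then cells at `infected_lifespan`
(default 20 steps) burst: `burst_b` phage appear in the patch, and with
debris enabled the patch gains a debris marker lasting `debris_lifespan`
steps (default 2). A cell infected at step $t$ therefore lyses exactly
`infected_lifespan` steps later. Debris does not stack: a new burst on a
debris patch refreshes the countdown, mirroring the way a patch holds at
most one infected cell as a sink.

**Reproduction.** Each uninfected cell reproduces with probability
`cell_repro_prob`, independently. Eligibility and target choice use the
pre-phase occupancy snapshot: a uniformly chosen empty orthogonal neighbor,
else a uniformly chosen empty diagonal neighbor, else nothing. Placements
are committed sequentially in random cell order so two daughters can never
share a patch. Cells never move once placed.

**Infection.** Within a patch, phage are processed one at a time; each runs
one Bernoulli trial per entity type present, in a uniformly random order of
the present types, stopping at the first success. The random order removes
allocation bias among sinks, and the escape probability is
$\prod_x (1-k_x)$ over present sinks regardless of order. A success against
the uninfected cell converts it immediately, so later phage in the same
patch and step face an infected cell ($k_I$) instead. A phage that fails
all its trials waits for the next step — per-step probabilities are
single-trial. As an implementation shortcut, a patch whose only
positive-probability sink is a single killing sink is resolved by one
binomial draw, which is distributionally identical to the sequential rule;
the sequential path is exercised whenever an uninfected cell or several
sink types are present.

**Diffusion.** Movement weights come from a symmetric bivariate normal of
scale $\sigma$ integrated over the nine unit squares of the 3×3
neighborhood and renormalized: with $A = 2F(0.5/\sigma) - 1$ and
$B = F(1.5/\sigma) - F(0.5/\sigma)$, the stay/orthogonal/diagonal masses
are $A^2$, $AB$, $B^2$, normalized by $A^2 + 4AB + 4B^2$. Each patch's new
real-valued load is computed synchronously from the pre-phase counts and
converted to an integer by stochastic rounding (floor plus a Bernoulli on
the fractional part), which is unbiased, so phage number is a martingale
under pure diffusion. Runs are usually parameterized by the *leave
fraction* $d = 1 - w_{center}$ rather than $\sigma$;
`sigma_from_leave_fraction()` inverts the monotone relation by
root-finding to $10^{-10}$. One consequence worth knowing: a 3×3 kernel
cannot scatter more than $8/9$ of a patch's phage in one step (the
$\sigma \to \infty$ limit is the uniform kernel), so $d$ must lie in
$(0, 8/9)$.

## Parameters, defaults, and what they emulate

| parameter | default | meaning |
|---|---|---|
| `width`, `height` | 100 × 100 | torus size in patches |
| `burst_b` | 10 | phage per lysis; 2D analogue of a much larger 3D burst |
| `eps_fraction_E` | 0.3 | fraction of patches with EPS (exact count) |
| `eps_layout` | random | `random` or `clustered_rows` (one contiguous band) |
| `k_C`, `k_E` | 0.25, 0.35 | per-step adsorption to cells / EPS |
| `k_I`, `k_D` | 0, 0 | superinfection / debris adsorption (off by default) |
| `cell_repro_prob` | 0.1 | per-step reproduction probability |
| `diffuse_fraction` | 0.2 | per-step phage leave fraction |
| `infected_lifespan` | 20 steps | infection-to-lysis latency |
| `debris_lifespan` | 2 steps | debris persistence when enabled |
| `n_steps`, `avg_window` | 10000, 3000 | run length and trailing window |
| `init_cell_frac`, `init_phage_frac` | 0.3, 0.3 | independent seeding fractions |

The attachment probabilities, lifespans, run length, window, and seeding
fractions are the standard study conditions for this model family. The
per-panel reproduction and diffusion rates are not part of the published
text, so the package fixes `cell_repro_prob = 0.1` and
`diffuse_fraction = 0.2` as its own defaults — a slowly reproducing cell
(one division per ten steps) and predominantly local phage movement, the
regime in which refuge formation is expected — and treats both as ordinary
user-settable parameters. EPS counts are exact
(`round(E * N)` patches sampled without replacement, or filled row by row),
not Bernoulli per patch, so the $E$ entering $\alpha$ and $\hat C$ is exact
and identical across seeds. Initial cell and phage placements are
independent samples, so a patch may start with both.

## The mass-action twin and the delay-ODE model

The shuffled variant keeps every rule and parameter but relocates all free
phage (independent-uniform, i.e. multinomially) right after lysis — so
freshly burst phage are dispersed before they can infect — and all live
cells (to distinct patches, ages preserved) right after reproduction.
Localized diffusion is off. Clustered EPS is rejected for this mode, since
under global shuffling only the amount of EPS can matter. These runs are
the like-for-like mass-action baseline: finite population, same
stochasticity, no spatial structure.

The delay-ODE model
$\dot C = rC(1-C/K) - \kappa C P$,
$\dot P = b \kappa C_L P_L - \kappa C P - \delta P$
is integrated with `deSolve::dede()` under a constant history
$(C_0, P_0)$ on $[-L, 0]$. Its equilibrium $\bar C = \delta/(\kappa(b-1))$
anchors $A_{ode} = \langle C \rangle / \bar C$, averaged in four
consecutive 10000-minute windows after a 10000-minute burn-in, with bound
$A_{ub,ode} = K/\bar C$. The correspondences
$\delta = -\ln(1-k_E E)$ and $\kappa = -\ln(1-k_C)/K$ translate the grid's
per-step escape probabilities into per-minute rates at matched maximum
density (a full grid vs $K$); they are approximate equivalences, meant to
show the ODE parameters sit in a realistic range rather than to force an
exact match.

## Numerical choices

* **DDE tolerances.** `run_dde()` defaults to `rtol = 1e-8` and
  `atol = 1e-30`. The absolute tolerance is deliberately at the underflow
  floor: in the oscillatory coexistence regimes the phage density dips to
  ~1e-22 per mL and recovers, and any looser `atol` silently flattens the
  dip to zero, converting a stable limit cycle into spurious extinction
  (and $A_{ode}$ to its upper bound). States are clipped at zero inside
  the right-hand side (with a warning if the output needed clipping);
  a state below 1e-30 marks effective extinction (`"underflow"`), above
  1e30 `"blowup"` — the operational meaning of "premature termination" for
  expanding oscillations.
* **Initial conditions.** The history defaults are $C_0 = 10^6$,
  $P_0 = 10^4$ per mL; for limit cycles and fixed points the window means
  from $t \ge 10000$ are insensitive to this choice, which the test suite
  confirms against a second set ($10^7$, $10^5$).
* **Stochastic rounding vs multinomial noise.** Deterministic kernel
  splitting plus unbiased rounding has much lower per-patch variance than
  multinomial relocation. Because of this (and the $8/9$ kernel bound),
  cranking the leave fraction toward its maximum makes spatial runs
  *converge toward* but not exactly match the shuffled model, even on a
  3×3 world where the kernel neighborhood is the entire torus; the test
  suite checks monotone convergence of the extinction-time distributions
  rather than exact distributional equality.
* **Extinction bookkeeping.** Cells are extinct when no live cell remains;
  phage are extinct when free phage are zero *and* no infected cell is
  latent (a pending burst counts as phage alive). Extinct trials are
  excluded from ensemble means and counted separately, with an all-extinct
  ensemble rendered as a missing-value row.
* **Ensemble seeding.** `run_ensemble()` derives child seeds from the
  master seed with a single `sample.int()` draw, splitting the seed budget
  across the initial-condition set (15 seeds over three initial conditions
  means five trials each, the replication design of the summary tables).
  The default initial-condition set {(0.3, 0.3), (0.1, 0.1), (0.5, 0.5)}
  spans sparser and denser starts around the 30%/30% baseline, which is
  the one fixed by the model description; the other two are package
  choices and configurable.

## What the simulations show — and scale

On grids from 20×20 up, clustered-EPS runs at moderate bursts reproduce the
characteristic self-organization: nearly all uninfected cells sit inside
the EPS band (C:E near 1), free phage concentrate outside it (P:E near 0),
and the fraction of infections occurring inside the EPS zone rises with
burst size as phage push deeper into the refuge at higher fecundity. Over a
stationary window the per-burst losses balance the burst size,
$P{\to}C + P{\to}I + P{\to}E + P{\to}D \approx b$. The shuffled twin at the
same parameters typically spirals into extinction wherever the spatial
$A_g$ is appreciably above 1.

The test suite and acceptance checks run these demonstrations at reduced
scale — 20×20 grids, 2000–3000 steps, five seeds — which this package
treats as its standard small-world configuration; full-scale 100×100,
10000-step runs are reached with the same functions and finish in minutes.
At the reduced scale, large bursts (40+) overwhelm a 20×20 world and drive
frequent extinction; this is a genuine property of small worlds (refuge
zones too shallow for the phage incursion depth), which is why the
trend-with-burst checks use bursts 2–10.

## Known limitations

* The model is two-dimensional with at most one cell per patch, so the
  dynamic range of $A_g$ is bounded by $A_{ub,g}$; empirical biofilm
  elevations of several orders of magnitude are outside what this
  mechanism alone can produce.
* The simulated worlds here are small relative to the published 100×100
  standard; quantitative table values also depend on reproduction and
  diffusion settings that are user-set, so tests assert trends, identities
  and sampling distributions rather than specific table entries.
* Nutrient-dependent growth, cell motility, continuous-space phage walks,
  multiple cells per patch, and temperate (lysogenic) phages are out of
  scope.
* The mean-field correspondence between the shuffled grid and the
  delay-ODE model is approximate (discrete time, per-step probabilities,
  integer populations); the package's mass-action baseline for grid runs
  is the shuffled twin, not the ODE.
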