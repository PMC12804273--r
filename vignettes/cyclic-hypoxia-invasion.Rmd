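---
title: "Cyclic hypoxia, hypoxic memory and tumor invasion: model and methods"
author: "hypoxmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyclic hypoxia, hypoxic memory and tumor invasion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxmem)
```

## The biological setting and the model

Avascular tumors experience oxygen levels that fluctuate in time ("cyclic
hypoxia") as perfusion in nearby vessels switches on and off. Cells adapt:
under hypoxia they stop proliferating and become migratory, degrade the
surrounding extracellular matrix (ECM) and invade; on reoxygenation they can
revert — but often only slowly, a persistence called *hypoxic memory*. The
package implements a go-or-grow model of this process in one spatial
dimension with a continuous internal trait.

The state consists of a normoxic density $n(x,t)$ (proliferative, immobile),
a phenotype-structured hypoxic density $h(x,t,\mu)$, and the ECM $e(x,t)$,
with $H = \int_0^1 h\,d\mu$. The trait $\mu \in [0,1]$ *is* a rate: the
cell's hypoxic-to-normoxic transition propensity once oxygen returns. The
dimensionless system is

$$\partial_t n = \lambda_n n (1-n-H-e)\,\mathcal H(c-c_H)
  + \textstyle\int \mu h\,d\mu\,\mathcal H(c-c_H)
  - \mu_{nh} n\,\mathcal H(c_H-c) - \gamma_n n\,\mathcal H(c_N-c),$$

$$\partial_t h = \partial_x\!\big(D_h(1-n-H-e)\partial_x h - \xi_h h \partial_x e\big)
  - \partial_\mu\big(v(\mu,c)\,h\big)
  + \mu_{nh} n\,\mathcal H(c_H-c)\,I(\mu-\mu_{hn0})
  - \mu h\,\mathcal H(c-c_H) - \gamma_h h\,\mathcal H(c_N-c),$$

$$\partial_t e = -\delta H e,$$

where $\mathcal H$ is the Heaviside step with $\mathcal H(0)=0$ (so at
$c = c_H$ exactly *no* gated branch is active, on either side) and $I$ is
the point indicator that injects all newly converted hypoxic cells at the
basal trait $\mu_{hn0}$. Oxygen is spatially homogeneous and piecewise
constant in time: each cycle of length $P$ starts with a normoxic phase at
$c_1$ and ends with a hypoxic phase at $c_2$ occupying the final
`bias` fraction of the cycle; switch instants belong to the phase they
close (left-open/right-closed intervals), and $t=0$ is normoxic.

Memory is the trait drift
$v(\mu, c) = -\big(\alpha(1-c) + \mu - \mu_{hn0}\big)/\beta$: under
sustained hypoxia at level $c_2$ all hypoxic mass converges to the stable
equilibrium $\mu^* = \mu_{hn0} - \alpha(1-c_2)$ (`hypoxic_equilibrium_phenotype()`),
and under normoxia it relaxes back toward $\mu_{hn0}$. With $\alpha = 0$
the velocity vanishes at $\mu_{hn0}$ for every oxygen level, so the model
collapses exactly to a memoryless two-compartment system — the baseline arm
of every experiment.

### Parameters

Defaults of `model_params()`, all dimensionless (time is scaled by the
reference diffusion time, oxygen by the normoxic level, densities by the
carrying capacity):

| parameter | default | meaning |
|---|---|---|
| `D_h` | 0.01 | hypoxic-cell diffusivity, damped by the free volume $1-n-H-e$ |
| `xi_h` | 0.001 | haptotaxis coefficient (drift up ECM gradients) |
| `lambda_n` | 0.1 | normoxic proliferation rate (sets the division timescale $1/\lambda_n = 10$) |
| `mu_nh` | 0.5 | normoxic→hypoxic conversion rate under hypoxia |
| `mu_hn0` | 0.5 | basal hypoxic→normoxic rate; trait injection coordinate |
| `gamma_n`, `gamma_h` | 0.001 | necrosis rates below `c_N` |
| `delta` | 15 | ECM degradation rate by hypoxic cells |
| `c_H`, `c_N` | 0.5, 0.1 | hypoxic and necrotic oxygen thresholds |
| `alpha` | 0.8 | memory-induction strength (0 = no memory) |
| `beta_l` | 2 | memory-induction timescale, active while $c < c_H$ |
| `beta_h` | 20 | memory-erasure timescale, active while $c \ge c_H$ |

The two $\beta$ values encode the experimental asymmetry of phenotypic
memory: induction within one half to two cell divisions
($\beta_l \in [2, 10]$ in units where a division takes $1/\lambda_n = 10$)
and erasure over four to ten divisions ($\beta_h \in [20, 50]$). The drift
law uses a single symbol $\beta$; this package switches it with the oxygen
regime (`select_beta()`), at $c_H$ and with the same $\mathcal H(0)=0$
tie-break as the reaction gating, because induction is by definition the
hypoxic-side process and erasure the normoxic-side one. A continuous
interpolation of $\beta$ near $c_H$ would be equally defensible; with the
two-level protocols used here the oxygen level never dwells near $c_H$, so
the choice is inconsequential.

The cyclic protocol's hypoxic level defaults to $c_2 = 0.4$. Any value
below $c_H$ is admissible; $0.4$ is the level used by the constant-hypoxia
verification case, and with $\alpha = 0.8$ it puts the memory equilibrium
at the minimal positive trait $\mu^* = 0.02$ — the constructor rejects
combinations with $\mu^* \le 0$, which would drive transition rates
negative. Protocols must straddle the threshold ($c_2 < c_H < c_1$).

## Scenario geometry and initial condition

The tumor starts as a pure-normoxic slab, $n = n_0$ on $[a,b]$ with ECM
$e = e_0$ outside it and no hypoxic cells; defaults $n_0 = e_0 = 0.5$,
$[a,b] = [4,6]$, $X = 10$. On the mesh the two interface nodes at $x=a$ and
$x=b$ take the mean of the one-sided limits ($n_0/2$, $e_0/2$). This is the
Riemann-consistent sampling of a discontinuous profile, and it is what
makes the discrete initial mass equal the continuum value
$N_0 = n_0 (b-a) = 1$ *exactly*, so conservation statements can be tested
against the closed forms at machine precision rather than to $O(\Delta x)$.

## Numerical scheme

Uniform meshes: $N$ spatial nodes ($\Delta x = X/(N-1)$) and $M$ trait
nodes ($\Delta\mu = 1/(M-1)$); the trait mesh must contain $\mu_{hn0}$ as
an exact node (validated at construction), since all hypoxic mass enters
there. Defaults $N = 201$, $M = 101$, which also place the memory
equilibrium $\mu^* = 0.02$ on a node.

- **Spatial transport** (`spatial_flux_update()`): conservative flux form
  with arithmetic face averages of the free-volume factor and of $h$; the
  *total* (diffusive + haptotactic) flux is zeroed at $x \in \{0, X\}$.
  The rectangle-rule spatial integral is then conserved exactly by
  transport — the reason all spatial integrals in the package use the
  rectangle rule rather than trapezoid weights.
- **Trait advection** (`phenotype_advection_update()`): conservative
  donor-cell (first-order upwind) differencing of
  $\partial_\mu (v h)$ with velocities evaluated exactly at cell faces
  (the law is linear in $\mu$) and zero boundary fluxes at
  $\mu \in \{0,1\}$. Phenotype mass per spatial node is preserved to
  rounding. Donor-cell upwinding adds numerical diffusion along the trait;
  because the flow is everywhere compressive
  ($\partial v/\partial\mu = -1/\beta < 0$), mass still parks exactly on
  the equilibrium node under sustained hypoxia — the discrete steady state
  is a point mass at $\mu^*$.
- **Reactions**: pointwise with Heaviside gating. The injection is a
  trait-space point source carried by the single node at $\mu_{hn0}$ with
  weight $1/\Delta\mu$, so its rectangle-rule trait integral equals the
  normoxic loss $\mu_{nh} n$ exactly — the discrete transition pair
  conserves $n + H$ to machine precision, which the test suite asserts at
  $10^{-10}$ over full runs.
- **Trait quadrature**: rectangle rule over all $M$ nodes
  ($\sum_j h_j \Delta\mu$), matching the discrete sums above; its
  normalization error on smooth profiles is $O(\Delta\mu)$ and irrelevant
  to the conserved pairing.
- **Time stepping**: forward Euler with
  $\Delta t = s \cdot \min\!\big(\Delta x^2/(2 D_h),\; \Delta\mu/f_{\max},\;
  1/\max(\delta, \mu_{nh}+\gamma_n, 1+\gamma_h)\big)$, safety $s = 0.9$.
  $f_{\max}$ is the worst-case trait speed over $\mu \in [0,1]$ and every
  oxygen level the protocol visits (the maximum sits at a trait endpoint),
  computed once before the run, so the advection bound holds for every
  step. The third, reaction-positivity bound is not part of the classical
  CFL pair; it keeps the explicit pure-decay updates (ECM degradation at
  rate $\delta H$ with $\delta = 15$, trait-dependent escape at rate up to
  1) from overshooting zero — without it, memoryless runs (whose advection
  bound is dropped: with $\alpha = 0$ the velocity vanishes where all the
  mass sits) would take diffusion-limited steps large enough to drive the
  ECM negative. With $\alpha = 0.8$ the advection bound is the binding one
  ($\Delta t \approx 0.018$ at defaults). The step count is rounded so the
  run lands exactly on `t_final`.
- **Degenerate values**: entries in $[-10^{-12}, 0)$ — roundoff from the
  centrally differenced haptotaxis term — are clipped to zero and counted
  (`$clip_count`); anything more negative, or any non-finite entry, aborts
  the run, because it signals a genuine stability violation rather than
  noise. Runs at the defaults clip nothing.
- **Determinism**: there is no randomness anywhere; identical
  configurations give bit-for-bit identical trajectories.

`simulate()` integrates with an optimized vectorized loop that also skips
trait columns above the highest coordinate mass can ever reach (injection
at $\mu_{hn0}$, drift above it always downward for $c \le 1$); the exported
`step_state()` is the reference implementation, and the test suite pins the
two together to $10^{-13}$ and verifies `step_state()` itself against the
composition of the individual exported operators.

## Closed-form verification

Two constant-oxygen regimes admit closed forms used as oracles
(`run_case_studies()`):

- **Sustained hypoxia** ($c = 0.4$, between the thresholds): only the
  normoxic→hypoxic conversion acts on the totals, so
  $n_{tot} = N_0 e^{-\mu_{nh} t}$ and $h_{tot} = N_0(1 - e^{-\mu_{nh}t})$,
  summing to $N_0$ for all $t$. At the default mesh the numerical sup
  error is $1.7\times10^{-3}$, halving under one mesh refinement (the
  error is pure forward-Euler $O(\Delta t)$, and the refined step is
  exactly half), and the sum is conserved to $10^{-15}$.
- **Sustained normoxia** ($c = 1$): hypoxic cells never form
  ($h \equiv 0$ identically, not just small) and the ECM is frozen.
  Because normoxic cells are immobile, every spatial node is an
  *independent* logistic with capacity $1 - e(x,0)$; the classical lumped
  logistic formula therefore holds nodewise, and the package verifies the
  numerical total against the nodewise closed form integrated over the
  mesh. A naive lumped reading with the domain-integrated ECM is not
  meaningful for this slab geometry (it would put the integrated ECM, 4,
  above the unit carrying capacity); the nodewise reading is the
  mathematically consistent one and measures pure time-integration error,
  $5\times10^{-4}$ at defaults.

Both closed forms are themselves cross-checked against high-accuracy
`deSolve` integrations of the lumped kinetics to $10^{-8}$ in the test
suite, keeping the oracle independent of the code path it verifies.

## Observables

- **Tumor right boundary**: largest $x$ where $n + H$ crosses
  $10^{-6}$, placed by linear interpolation between the bracketing nodes
  (the raw-node variant is available via `interpolate = FALSE`).
  Interpolation makes hitting times mesh-insensitive; on the initial sharp
  step the interpolated crossing sits one cell beyond the support edge,
  which is the honest reading of a sub-threshold crossing on a
  discontinuity. "Tumor volume" in 1D is $\int (n+H)\,dx$ over the domain.
- **Front region**: the strip within 0.5 units of the right boundary; the
  front hypoxic fraction is $\int_{front} H / \int_{front}(n+H)$, with an
  explicit `NA` marker (never a silent 0) when the strip holds no cells.
  Time averages are taken over all recorded outputs (stride 0.1 by
  default).
- **Hitting times**: first recorded time the boundary reaches a target,
  linearly interpolated between records; `NA` marks "never reached", and
  `NA` propagates through `percent_change()`. At the default mesh and
  $t = 60$ some arms' fronts stop just short of the literature hitting
  targets ($x = 9.62$ for period sweeps, $x = 9.1$ for bias sweeps); the
  sweep tables therefore also carry the percent change in final boundary
  position, which is defined for every run, and the peak-memory-effect
  period is identified from the volume percent change (the two criteria
  peak at the same period).
- **Memory structure**: `phenotype_distribution()` integrates $h$ over a
  region (bulk = whole domain, or front strip), normalizes to sum 1, and
  feeds `strong_memory_fraction()` (mass with $\mu < 0.25$),
  front-to-bulk ratios, and `jensen_shannon_divergence()` (natural log,
  bounded by $\log 2$, $0\log 0 = 0$).

## Experiment families and the conditions they emulate

All runners share the slab initial condition and $t_{final} = 60$ (six
division times), recording observables every 0.1:

- `run_period_sweep()`: full-cycle periods $\{5, 10, 15, 20\}$ at
  symmetric bias, i.e. half to two division times per cycle — the
  experimentally motivated cyclic-hypoxia range — with memory
  ($\alpha=0.8$, $\beta_l=2$, $\beta_h=20$) and memoryless arms.
- `run_bias_sweep()`: hypoxic bias $\{0.25, 0.4, 0.5, 0.6, 0.75\}$ at
  period 5.
- `run_beta_grid()`: $\beta_l \in \{2, 10\} \times \beta_h \in \{20, 50\}$
  at period 5, with per-axis sensitivity ranges reported rather than a
  hard-coded verdict on which axis dominates.
- `run_memory_structure()`: field snapshots at the end of the last
  normoxic and last hypoxic phases, bulk/front distributions, strong-memory
  fractions and front-bulk divergences.

The acceptance tests assert the reproduced findings — memory trades volume
for invasion at every period, with the largest volume effect at period 10;
shorter cycles keep the front more hypoxic; increasing bias shrinks volume
and extends invasion in both arms; fast induction with slow erasure is the
most invasive corner, with induction the dominant axis; the front is
enriched in strong-memory cells, less so for longer cycles — and re-check
every ordering under one halving of $\Delta x$ and $\Delta\mu$
(on representative sweep subsets, to keep the suite fast) so that no
conclusion hinges on the default mesh.

## What the simulations do and do not show

The scenario generator reproduces an idealized *in vitro* protocol:
spatially uniform, exactly two-level oxygen switching; a 1D slab geometry;
strictly exclusive go-or-grow phenotypes; phenomenological memory with a
single linear drift law; ECM as a passive, degradable volume fraction.
Passing tests show the solver integrates *this* system faithfully and that
its qualitative conclusions are mesh-robust. They do not show anything
about spatially heterogeneous oxygen fields (gradients inside spheroids),
oxygen consumption feedback, mechanistic memory circuits, hybrid
phenotypes, or 2D/3D geometry — all outside this package's scope. Absolute
front positions are logarithmically sensitive to the $10^{-6}$ boundary
threshold riding the diffusive tail of $h$; orderings and percent changes
are the robust outputs, and hitting times against fixed literature targets
should be read with that caveat (hence the `NA` policy above).
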