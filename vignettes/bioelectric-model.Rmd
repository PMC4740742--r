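---
title: "A bistable membrane model for multicellular bioelectric patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable membrane model for multicellular bioelectric patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioelec)
```

## The single-cell model

A non-excitable model cell carries two phenomenological voltage-gated
channels. Each contributes a current

$$I(V) = G\, p(V)\,(V - E), \qquad
  p(V) = \frac{1}{1 + e^{\pm z (V - V_{th})/V_T}},$$

with conductance $G$, reversal potential $E$, threshold $V_{th}$ (where
$p = 1/2$), gating charge $z$, and thermal potential $V_T = RT/F$. The
inward rectifier takes the $+z$ sign — it is open at hyperpolarized
potentials and pins the cell near $E_{in}$ — and the outward rectifier is
its mirror image, favoring $E_{out}$. Currents are positive outward and the
isolated cell relaxes as $C\,dV/dt = -I_{tot}(V)$, so zero-current roots
with $dI/dV > 0$ are stable.

The defaults of `membrane_model()` are the canonical bistable set:
$G_{in} = G_{out} = 1$ nS, $V_{th} = -25$ mV, $z = 3$, $E_{in} = -60$ mV,
$E_{out} = 0$ mV, $V_T = 27$ mV ($T = 310$ K), $C_0 = 100$ pF. $V_T$ is
stored as the literal 27 mV constant rather than recomputed from $R$, $T$,
$F$, so worked numbers reproduce exactly; `thermal_potential()` computes
$RT/F$ for any temperature (26.71 mV at 310 K, i.e. 27 to the displayed
precision).

```{r fixed-points}
model <- membrane_model()
find_fixed_points(model)
```

Three roots: hyperpolarized stable (near $E_{in}$), unstable threshold,
depolarized stable (near $E_{out}$). The cell is a two-state memory.
`bifurcation_diagram()` sweeps $E_{in}$ parametrically in the conductance
ratio $G_{out}/G_{in}$ and reports branches and saddle-node (fold)
boundaries, located where the root count changes on the $E_{in}$ grid: at
ratio 0 the diagram collapses onto $V_m = E_{in}$, at ratio 1 a bistable
window with hysteresis opens, and large ratios pull the cell into the
depolarized regime.

**Root finding.** Roots are bracketed by sign changes on a 0.1 mV scan of
$[-100, 40]$ mV and refined by `uniroot()` to $10^{-6}$ mV; stability uses
the analytic slope. A grid point where the current vanishes without a sign
change (a tangential root, possible exactly at a fold) is reported once
with a warning. The scan step bounds the resolvable root separation;
0.1 mV is two orders below the ~8 mV separation at the default parameters,
and the suite cross-checks every root against an independent 0.01 mV
bisection oracle.

## The coupled ensemble

$N$ identical cells sit on a rows × cols square lattice with the 4-neighbor
(von Neumann) neighborhood; edge cells simply have fewer neighbors, the
no-flux analogue for a finite tissue patch. Gap junctions are ohmic with
dimensionless conductance $g = G/G_{in}$ per edge (uniform by default, a
per-edge field if supplied). Junction capacitance is accepted in the
configuration but constrained to zero: at physiological junction values the
conductive term dominates, and dropping the capacitive one keeps the
coupling matrix constant. In dimensionless variables ($v = V/V_T$,
$\hat t = t/\tau$, $\tau = C_0/G_{in} = 100$ ms),

$$\dot v_i = -\hat\imath_{tot}(v_i; r_i) + \sum_{j \in nn(i)} g\,(v_j - v_i),$$

where $r_i = (G_{out}/G_{in})_i$ is the only spatially varying cell
parameter ($E$, $V_{th}$, $z$ stay global: ionic concentrations are assumed
buffered over the fast electrical timescale).

**Integration.** The coupling term is a graph Laplacian $L$, so the system
is stiff in the coupling but linear there. The stepper assembles
$A = I + \hat{dt}\,L$ once per run (symmetric positive definite, smallest
eigenvalue 1), factorizes it by sparse Cholesky, and advances

$$A\,\Delta v = \hat{dt}\,\big[-\hat\imath_{tot}(v^n) - L v^n\big], \qquad
  v^{n+1} = v^n + \Delta v,$$

i.e. implicit coupling, explicit channel current. A uniform state at a
single-cell fixed point is exactly stationary (the coupling residual
cancels identically), pure coupling conserves $\sum_i v_i$ to solver
tolerance (zero row sums), and the scheme converges to the explicit-Euler
limit at first order, all verified in the suite. Defaults
$\hat{dt} = 0.01$, $\hat t_{final} = 10$ (1 s): halving or quintupling
$\hat{dt}$ leaves the reported depolarized fractions unchanged to the cell,
so the defaults are comfortably converged for the 50 × 50 runs used
throughout; those runs take on the order of a second each.

**Classification.** `summarize_state()` counts a cell as depolarized when
its potential exceeds the unstable root of its *local* single-cell model —
the basin boundary of the isolated-cell dynamics, the least arbitrary
threshold available. Where the local model is monostable there is no basin
boundary; such cells are classed by the side of the midpoint of
$(E_{in}, E_{out})$ their single root falls on (fraction 0 or 1), which
handles fully blocked ($r \to 0$) and fully upregulated columns.

**Study conditions.** The preset normalization experiment uses a 50 × 50
lattice with a centered 10 × 10 depolarized patch (both configurable; the
patch size is a reading of the published maps, not a printed number), cells
initialized exactly at the two stable roots. Strong coupling ($g = 0.25$)
normalizes the patch — 99.8% of cells are hyperpolarized at $\hat t = 10$
and the last four central cells cross the basin threshold at
$\hat t \approx 10.5$ — while weak coupling ($g = 0.05$) leaves a 60-cell
depolarized core at the same horizon (it too eventually normalizes, near
$\hat t \approx 40$: at these parameters weak coupling delays rather than
permanently protects the abnormal island). Upregulating the outward channel
(uniform $r = 2.5$, $g = 0.25$) reverses the flow: the depolarized fraction
grows monotonically from 0.04 — invasion of the abnormal state.

## Blocker microenvironment

Blocking of the outward rectifier is modeled as local equilibrium binding:

$$G_{out}(c) = \frac{G_{out}^0}{1 + K c},$$

with blocking constant $K$ and an *unblocked* conductance $G_{out}^0$ that
may exceed $G_{in}$ under upregulation. The ratio spans $(0, r_0]$: full
blocking at $c \to \infty$, $r_0$ at $c = 0$. Because only the product
$K c$ is identifiable, steady profiles are specified directly in ratio
space; the canonical endpoints 0.05 (maximum blocking) and 2.50
(unblocked, upregulated) are pinned exactly at the domain boundaries by all
profile families.

Axial families: `linear`, `exponential` (geometric — the shape a steady
exponential concentration gradient induces through the hyperbolic law) and
`logistic` (a sigmoidal front; steepness 8 on the unit coordinate by
default, a mid-grid front width of a few cells). The 2-D "cross" profile
emulates a blocker released along the two central axes: concentration
decays exponentially with normalized distance to the *nearer* axis (the
pointwise maximum of the two separable axis decays — an additive form
cannot hold the printed ratio on the whole cross), then maps through the
blocking law with $K$ and $r_0$ solved from the endpoint pinning. The decay
rate (default 6 per half-grid) must satisfy $e^{-a} < r_{min}/r_{max}$ for
the pinning to be solvable; it sets how sharply the pattern transitions and
is exposed in the configuration.

The blocking reaction is taken as fast: the ratio field maps pointwise onto
the cells with no lag state. Blocker transport, when wanted, is explicit
forward-time centered-space diffusion with mirrored ghost cells (no-flux),
a hard stability guard ($D\,dt/dx^2 \le 1/2$ in 1-D, $\le 1/4$ in 2-D —
violating configurations are rejected, naming the bound), exact mass
conservation and a discrete maximum principle; the suite verifies it
against the cosine-series closed form for a step initial condition with
second-order spatial accuracy. The separation of scales is the point:
$\tau_d = L^2/D \approx 10^4$ s for $L = 1$ mm, $D = 10^{-10}$ m²/s —
hours, versus the ~100 ms electrical relaxation — so the patterning runs
assume a fully developed steady profile.

Starting from uniformly *depolarized* tissue (the post-upregulation
abnormal state that blocking is meant to rescue; the published experiments
do not print their initial map, and this choice makes the rescue
explicit), the axial profile yields a hyperpolarized region advancing from
the blocked side and stalling where the local ratio restores bistability,
and the cross profile yields a hyperpolarized cross with depolarized
corners — patterning without any anisotropic coupling.

## Nanoparticles

A fixed budget $N_p$ of particles with valence $z_{np}$ (default +1,
cationic) equilibrates over the potential map with weights
$w_i \propto e^{-z_{np} v_i}$ (energy $z_{np} e V_i$ against $kT$;
max-shifted before exponentiation, hence exactly gauge invariant).
$N_p$ and $z_{np}$ are not constrained by any printed value — only ratios
and orderings are meaningful — so the defaults ($N_p = 10^4$, about 4 per
cell on the 50 × 50 map, $z_{np} = 1$) are display choices. The potential a
particle "sees" is the cell's membrane potential, not a spatially resolved
extracellular field. Integerization is largest-remainder rounding with
index-order tie-breaking: deterministic, conserves $N_p$ exactly, and
keeps every count within one particle of its real-valued quota, so the
two-cell Boltzmann ratio $e^{\Delta V/V_T}$ is reproduced to rounding.

## Scenarios, I/O, reproducibility

`run_scenario()` composes these pieces into the preset experiments listed
by `list_scenarios()`, writing potential maps as delimited-text matrices
with commented metadata headers (time, grid, coupling, ratio range,
parameter hash, tool version) and a YAML run record sufficient to
reproduce the run; re-running a configuration reproduces the text outputs
byte for byte. Runs are deterministic; the only randomness in the package
is optional initial-condition jitter, which refuses to run without an
explicit seed and records it. The command-line wrapper
(`inst/cli/bioelec`) is a thin shell over `cli_main()`; YAML configuration
files merge under explicit flags.

## What the synthetic experiments do and do not show

Everything here is synthetic: initial conditions are built from the
model's own fixed points and blocker fields are prescribed, which is what
makes exact invariants (stationarity, conservation, pinning) testable.
Passing tests show the dynamical mechanisms — bistability, coupling-driven
normalization or invasion, blocker-directed patterning, potential-directed
particle placement — are implemented as specified. They do not show that
real tissue behaves this way: the model has two generic channels with
frozen reversal potentials (no pumps, no Nernst feedback, no ionic
dynamics), identical cells on a static lattice (no growth, no division, no
heterogeneity beyond the ratio field), ohmic junctions, and no biochemical
signaling downstream of $V_m$. Quantitative figures — reversion times,
invasion speeds, pattern sharpness — depend on the figure-read patch
geometry and profile shapes and should be read as qualitative.

## Numerical summary

| Quantity | Default | Notes |
|---|---|---|
| scan step (roots) | 0.1 mV | refinement to 1e-6 mV |
| $\hat{dt}$ | 0.01 | IMEX, constant $A$ |
| $\hat t_{final}$ | 10 | = 1 s at default $\tau$ |
| lattice | 50 × 50 | patch 10 × 10 |
| $g$ | 0.05–0.25 | per-edge field allowed |
| ratio endpoints | 0.05 / 2.50 | pinned exactly |
| FTCS stability | $r \le 1/2$ (1-D), $1/4$ (2-D) | enforced |
| $N_p$, $z_{np}$ | $10^4$, +1 | display defaults |
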