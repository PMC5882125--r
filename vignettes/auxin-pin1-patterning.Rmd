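---
title: "Models of auxin-PIN1 patterning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of auxin-PIN1 patterning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxinpin)
```

## The scientific problem

Leaf primordia arise at the shoot apical meristem at regularly spaced
auxin maxima. The textbook explanation is an *up-the-gradient* feedback:
the efflux carrier PIN1 accumulates on the cell membrane facing
neighbors with more auxin, pumping auxin against its own gradient so
that small auxin excesses amplify into isolated maxima with a preferred
spacing. `auxinpin` implements a family of cell-lattice ordinary
differential equation models of this feedback and asks a sharper
question: what happens to the *spacing regularity* when the cell wall
space (apoplast) between cells — through which all real PIN1-mediated
transport passes — is made explicit, and what kind of molecular
mechanism restores it?

Three model families are provided.

**Model O** (no extracellular space). Per-cell auxin $a_i$ and directed
PIN1 densities $p_{i,j}$ on a periodic lattice with $K$ neighbors per
cell:

$$\frac{da_i}{dt} = G_a (A - a_i) - \sum_j E_p (p_{i,j} a_i -
p_{j,i} a_j) + \sum_j D_a (a_j - a_i),$$

$$\frac{dp_{i,j}}{dt} = G_p\left(\frac{K p\,\varphi_0(a_j)}
{\sum_j \varphi_0(a_j)} - p_{i,j}\right),$$

with $\varphi_0(a) = a^n$ by default. The per-cell PIN1 total relaxes to
$Kp$; the uniform equilibrium is $a_i = A$, $p_{i,j} = p$. When PIN1
turnover is fast, the allocation can be substituted algebraically
(variant `"O_qss"`).

**Model A** (explicit apoplast). One well-mixed compartment per
interface, with auxin $a'_{ij}$, PIN1 efflux into it, influx carriers
(efficiency $E_q$, density $q$) pumping back into cells, and
cytoplasm–apoplast diffusion; the apoplast-to-cytoplasm volume ratio $V$
scales all apoplast fluxes by $1/V$. PIN1 now polarizes toward apoplast
auxin, $\varphi_a(a'_{ij}) = (a')^n$. Variants add direct cell–cell
("symplast", `A_symplast`) or apoplast–apoplast (`A_apoplast`, 1D only)
auxin diffusion.

**Model B** (a diffusible mediator X). Model A plus a molecule $X$
synthesized under auxin control, $G_x(\theta(a_i) - x_i)$ with
$\theta(a) = 2a^r/(a_{eq}^r + a^r)$, moving between cytoplasm and
apoplast (`"simple"`), directly between cells (`"symplast"`), or between
apoplast spaces (`"apoplast"`, 1D only). Six feedbacks of X on the
auxin-PIN1 system define variants B1–B6; the biologically decisive one
is **B6**, in which apoplast X multiplies the PIN1 polarization weight,
$\varphi_a \cdot \varphi_x(x'_{ij})$ with $\varphi_x(x') = (x')^m$ — X
transmits the auxin signal to the PIN1 machinery of the neighboring
cell.

## Linear stability and wavelength selection

On a 1D ring the linearization about the uniform equilibrium is
block-circulant, so growth rates are functions of
$\nu = \cos(2\pi k/N)$:

* Model O (QSS PIN1): $\lambda(\nu) = 4c_2\nu^2 + 2c_1\nu + c_0 - 2c_2$
  with $c_1 = E_p p + D_a$,
  $c_2 = -E_p p\, a_{eq} \varphi_0'(a_{eq})/2\varphi_0(a_{eq})$ and
  $c_0 = -(G_a + 2c_1 + 2c_2)$, so $\lambda(1) = -G_a$ identically. A
  pattern forms iff $\nu_* = -c_1/4c_2$ satisfies $|\nu_*| < 1$ and
  $\lambda(\nu_*) > 0$, with preferred wavelength
  $L_* = 2\pi/\arccos\nu_*$ cells; for powers,
  $\nu_* = (1 + R_a)/2n$ with $R_a = D_a/E_p p$.
* Model A: $\lambda(\nu) = 2c_1\nu + c_0$ is *affine*, so the maximum
  over the band is at an endpoint; whenever the equilibrium is unstable
  the winner is $\nu = -1$, i.e. **2 apoplast spaces**, independent of
  parameters (for powers the instability condition is
  $D_a < (n-1)E_p p$). The explicit apoplast destroys macroscopic
  wavelength selection.
* Model B6 (reduced, $\varphi_a = 1$): the same quadratic form with
  coefficients damped by $\gamma$ (fast-auxin factor) and $\kappa$
  (fast-X factor); $\nu_*$ again moves with the rates, so a diffusible
  mediator acting on PIN1 polarization restores parameter-dependent
  spacing.

`dispersion()` evaluates these relations; `jacobian_spectrum()` is the
independent check: it differentiates the actual right-hand side
numerically at the equilibrium, verifies shift-invariance, and
block-diagonalizes by a discrete Fourier transform. For Model O the two
agree to $10^{-6}$ relative; for Model A the affine relation is exact
for the doubly reduced system (quasi-steady PIN1 plus adiabatic
elimination of cytosolic auxin — a Schur complement at $\lambda = 0$,
available via `eliminate = "a"`).

Two derivation subtleties are worth recording:

* **The Model O boundary.** The instability region in the $p$–$D_a$
  plane is computed from $|\nu_*| < 1 \wedge \lambda(\nu_*) > 0$
  directly, not from a factored closed form, and is cross-checked
  against the oracle along transects. The closed form
  $\nu_* = (1+R_a)/2n$ is reproduced exactly.
* **The B6 relation is a fast-mediator approximation.** The $\kappa$
  factor amounts to adiabatic elimination of the X fields. When X
  kinetics are fast relative to the auxin-PIN1 rates
  ($G_x \gtrsim 10\times$), the relation matches the exact spectrum in
  sign and maximizing wavenumber ($\pm 1$); at slow X kinetics (e.g.
  $G_x = 0.5$ with transport rates of order 10) it can predict
  stability where the exact linearization — and the simulations — show
  patterns. Tests of the approximate relation therefore sample the
  fast-mediator regime; everything outside it rests on
  `jacobian_spectrum()` and simulation.

### PIN1 inertia

The quadratic Model O relation assumes quasi-steady PIN1. With the
turnover rate $G_p = 1$ and strong transport ($E_p p = 40$), PIN1 is
the *slowest* field and the exact full-model spectrum peaks at about
half the QSS wavenumber; simulations of the full model track the exact
spectrum, as they must. Wavelength-selection checks against the printed
$L_*$ are therefore run on the QSS variant, where that prediction is
the exact linear theory; the shift itself is asserted in the stability
tests, and `mode_growth_rate()` lets you measure any single mode's
growth directly in simulation.

## Nonlinear selection: what steady states actually show

Linear analysis predicts the *fastest-growing* mode; the saturated
steady state need not inherit it exactly:

* Model O (QSS) steady states land close to $L_*$ (within roughly
  $\pm 40\%$ at $N = 40$: the discrete modes nearest $\nu_*$).
* Model A saturates extremely fast ($\lambda_{max} \approx 65$ at the
  reference parameters, i.e. within $t \approx 0.1$) — many modes near
  the band edge grow almost equally before nonlinearity freezes the
  field. The result is isolated single-interface auxin spots spaced 2–3
  apoplast spaces: the cluster index is exactly $L_2 = 1$, while the
  spectral index lands in $L_1 \in (2, 3)$ rather than exactly 2. The
  exact "2" is a statement about the linear spectrum (where it holds to
  machine precision); the frozen nonlinear state keeps the interface
  scale but with defects. Both facts are asserted in the tests.
* Model B6 coarsens slowly at large $D_x$; transect runs use a horizon
  of 500 time units, by which the ordering of $L_1$ across $D_x$ is
  stable.

## The synthetic study conditions

There is no external data; all runs start from the analytic equilibrium
with independent multiplicative noise, $v \mapsto v(1 + u)$,
$u \sim U(-0.01, 0.01)$ ("1% fluctuation"), integrated by explicit
Euler with $\Delta t = 0.001$ under periodic boundaries. These are the
published protocol values and are the package defaults
(`sim_control()`, `perturb_state()`). Choices the protocol leaves open,
fixed here once:

* *Noise law*: uniform multiplicative (a Gaussian option exists in the
  perturbation amplitude sense via a user-supplied state); the
  published wording fixes only the 1% amplitude.
* *Horizon and stopping*: `max_time = 1000` with early stop when every
  derivative falls below `steady_tol = 1e-8`. All 1D rate constants are
  of order 0.1–10, so relaxation completes well inside this horizon;
  every result records its stop reason. Scaled-down runs in the test
  suite use horizons of 40–500 time units and rings of 16–40 cells
  (200 for analytic dispersion grids), and the 2D checks use a 14×14
  torus — the sizes at which the qualitative claims are already stable.
* *Integrator*: fixed-step explicit Euler is retained as the study's
  method; it preserves the linear mass invariants to rounding error
  (asserted over $10^5$ steps). Negative or non-finite excursions abort
  the run rather than being clamped, because clamping would silently
  change the dynamics. A blown-up sweep cell is recorded as failed and
  the sweep continues.
* *Per-cell seeds*: sweep grid points derive their seeds from a master
  seed by a counter scheme, so any single cell is reproducible in
  isolation.

What the generator deliberately does **not** emulate: growing or
deforming tissue, cell division, irregular meshes, stochastic reaction
noise during the run, and saturation of carrier activity. Passing tests
therefore demonstrate the self-organization properties of the stated
reaction-transport dynamics, not agreement with live-imaging data.

## Regulatory-function conventions

The polarization and synthesis functions printed with the models are
powers and a normalized Hill ($\theta(a_{eq}) = 1$). The forms of the
B1–B5 feedback functions $\psi_1, \psi_2$ are not printed; the package
default makes them normalized Hill functions referenced at the
corresponding equilibrium concentration, so that every feedback equals
1 at the uniform equilibrium and the closed-form equilibria of Models
A/B remain exact fixed points of B1–B5 (asserted to $10^{-12}$). A
normalized power form `(c/ref)^m` is selectable
(`psi_form = "power_ref"`), and the B1–B5 conclusions are checked under
both. Two degenerate combinations require a documented stance:

* **B4/B5 with symplast X diffusion**: apoplast X is identically zero
  at equilibrium, so no normalized $\psi_2$ exists; the combination is
  rejected at construction rather than silently shifting the
  equilibrium.
* **B6 with symplast X diffusion**: likewise $x'_{ij} \equiv 0$ would
  zero every polarization weight; in this mode the polarization signal
  is taken from the neighboring cell's cytosolic X, $\varphi_x(x_j)$ —
  the direct symplast analogue of Model O's $\varphi_0(a_j)$, and the
  reading under which this mode restores patterns as reported.
* The saturating form $f(c) = c^e/(1 + (c/R)^e)$ used in some 2D runs
  is available behind an explicit flag (`reg_fun("hill_ceiling")`) and
  is **off** by default; the packaged 2D experiments run without it.
  In the 2D mediator run the $\theta$ exponent is $r = 2$, the value
  used in all dedicated B6 analyses (with $r = 1$ and no saturation the
  14×14 sheet relaxes to uniformity).

## Pattern metrics

For a periodic 1D series, `wavelength_L1()` returns $L_1 = N/k_1$ with
$k_1 \in [1, N/2]$ the strongest DFT mode (ties broken toward the
longest wavelength and flagged; a constant series is flagged
undefined), and `cluster_size_L2()` returns spots (strictly above the
mean) per cluster (maximal runs with wrap-around). Both are invariant
under rotation and increasing affine rescaling. Metrics are always
recorded for both the cell and the apoplast series; the interface-scale
collapse of Model A lives on the apoplast series, the Models O/B
results on the cell series. In 2D, an above-mean mask percolates at
about 50% occupancy regardless of structure, so cluster statistics
(`cluster_stats_2d()`) are complemented by the adjacent-cell Pearson
correlation (`neighbor_correlation()`): near zero for interface-scale
speckle (Model A), 0.5–0.7 for genuine multi-cell maxima (Models O,
B6).

## Numerical choices and degenerate inputs

* Dispersion coefficients are evaluated from the analytic equilibrium
  and the regulatory derivatives (`reg_deriv()`, closed forms, checked
  against central differences at $10^{-5}$ relative).
* $c_2 = 0$ (no feedback curvature) reports "stable, $\nu_*$
  undefined" rather than dividing by zero.
* A PIN1 allocation denominator of zero (all-zero weights, possible
  when a positive exponent meets an all-zero field) is an error, not a
  0/0 patch.
* The oracle uses central differences with per-variable steps scaled to
  the equilibrium, verifies circulant structure to $10^{-6}$ relative
  before diagonalizing, and reports the leading eigenvalue per
  wavenumber.
* Ring lattices require $N \ge 3$ and hex tori $n_x, n_y \ge 3$;
  smaller sizes would create duplicate interfaces between the same cell
  pair.

## Known limitations

* The dispersion toolkit is 1D; 2D claims are supported by simulation
  and the 2D metrics only.
* The apoplast-diffusion variants (auxin and X) are defined on rings
  only, matching where they are deployed.
* Explicit Euler is first-order; `integrate_model()` exposes `dt`, and
  the convergence tests demonstrate the expected first-order behavior,
  but no adaptive error control is attempted on the primary path.
* Steady-state detection by derivative norm can declare glassy,
  defect-pinned configurations "steady"; that is the phenomenon itself
  (see the Model A discussion), not an artifact, but interpretations of
  $L_1$ at strongly degenerate parameters should consult the recorded
  trajectory.
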