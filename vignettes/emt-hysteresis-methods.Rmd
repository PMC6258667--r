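---
title: "Modelling hysteresis in TGF-beta-induced EMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hysteresis in TGF-beta-induced EMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtswitch)
```

## The circuit and its equations

The epithelial-mesenchymal transition (EMT) of mammary epithelial cells under
TGF-beta is modelled as a four-species circuit per cell: TGF-beta `T`
(exogenous dose plus autocrine production), the miR-200 family `M`, the ZEB
transcription factors `Z` (ZEB1/2 lumped into one species, the miR-200
clusters likewise), and E-cadherin `E` as the epithelial readout. All
quantities are in arbitrary concentration units; time is in arbitrary units
with decay rates near 1, so one time unit is one relaxation time of a free
species.

$$\begin{aligned}
\dot T &= \mathrm{dose} + \frac{k_T}{1+(M/K_{MT})^{h_T}} - d_T T \\
\dot M &= b_M + \frac{k_M}{1+(Z/K_Z')^{h_M}} - d_M M \\
\dot Z &= b_Z + \frac{k_Z T}{K_T+T} - k_{MZ} M Z - d_Z Z \\
\dot E &= b_E + \frac{k_E}{1+(Z/K_Z'')^{h_E}} - d_E E
\end{aligned}$$

Induction of ZEB by TGF-beta is Michaelis-Menten, promoter repression terms
are Hill functions, and the post-transcriptional removal of ZEB by miR-200 is
mass action ($k_{MZ} M Z$) — the standard kinetic forms for this motif. Two
nested feedback loops matter:

* the **double-negative miR-200/ZEB loop** (ZEB represses the miR-200
  promoter with constant $K_Z'$; miR-200 removes ZEB with coefficient
  $k_{MZ}$), and
* the **autocrine loop** (miR-200 represses TGF-beta production with
  constant $K_{MT}$; TGF-beta induces ZEB, which represses miR-200).

E-cadherin is slaved to ZEB through $K_Z''$ and does not feed back. This has
a useful exact consequence: at steady state $M$ is an explicit function of
$Z$, $T$ is an explicit function of $M$, and the ZEB balance closes the loop,
so **every steady state of the 4-D system is a root of one scalar residual in
$Z$**. The package exploits this for fast, exact steady-state counting (the
`method = "reduced"` route of `bistable_window()`).

## Calibration of the wildtype preset

The calibrated preset (frozen in `default_parameters("wildtype")`, produced
by `tools/calibrate_preset.R`) satisfies three structural constraints at
once:

1. the quasi-static dose response is bistable over a window of roughly
   2.5-12 a.u. of exogenous dose;
2. increasing $K_Z'$ alone shrinks the hysteresis extent monotonically and
   abolishes bistability at about $2.2\times$ the wildtype value — the
   model's rendering of deleting a ZEB binding site on the miR-200 promoter;
3. all constants not named below stay at unity-order values (basal rates
   0.01, decay rates 1, maximal transcription rates 1, Hill coefficients 2).

```{r preset}
default_parameters("wildtype")
```

Two findings from the calibration shaped the preset and are worth recording.

First, the double-negative loop alone cannot carry a window this wide: with
the T-arm fixed, its bistable range in the induction input has a
high-to-low-bound ratio of at most about 1.8 (measured by root counting over
a broad grid of $K_Z'$, $k_{MZ}$ and Hill coefficients at cooperativity 2-4),
while 12/2.5 needs ~4.8 after accounting for the autocrine shift between
branches. The preset therefore keeps the double-negative loop *subcritical*
— no bistability of its own, but a sharp ultrasensitive $M(T)$ relay — and
lets the autocrine loop supply the hysteresis width: the backward
(mesenchymal-history) branch enjoys nearly the full autocrine production
$k_T$, the forward (epithelial-history) branch almost none, which is why
$k_T \approx 18$ is comparable to the window width. This is also why the
calibration had to tune $K_T$, $k_T$ and $K_{MT}$ in addition to the four
loop constants: the window spans $T$ values of order 2-40, which pins the
induction half-saturation and the autocrine scale far from 1.

Second, the monotone disappearance of hysteresis under a $K_Z'$ ramp is a
genuine constraint, not a free consequence of the equations. In large parts
of parameter space the window first *migrates to higher doses and widens*
before collapsing at a cusp (the saturating induction term stretches dose
intervals as the required ZEB level approaches its ceiling $k_Z$). The
calibration penalises that behaviour explicitly, using the exact root-count
extent, and the shipped preset decreases from 9.5 to 0 along the ramp.

The mutant preset multiplies $K_Z'$ by 2.5 (just past the cusp at ~2.2): it
is monostable at every dose, still responds to TGF-beta — ZEB rises with
dose and E-cadherin falls gradually to about 0.6 rather than 0.03 — but has
no memory. `"non_hysteretic_alt"` (multiplier 4) is a more conservative
monostable comparator.

Dose units are arbitrary throughout; no mapping to experimental pM
concentrations is attempted, and none of the laboratory time constants
(hours, days) are claims of this model — only orderings and ratios of model
times are.

## Bifurcation analysis

`sweep_branch()` performs quasi-static continuation: the steady state at one
dose seeds the next, upward from the dose-0 epithelial attractor or downward
from the top-dose mesenchymal attractor. Branch disagreement (more than 5%
of the epithelial E-cadherin level) defines the bistable window;
`bistable_window()` refines the saddle-node bounds by bisection to 0.02 dose
units. The reduced root-counting route computes the same bounds from the
scalar steady-state residual; the two agree to the bisection resolution and
are cross-checked in the tests. Monostable systems report extent exactly 0.
A window that reaches the top of `dose_range` raises an error rather than
returning a clipped number.

```{r window}
bistable_window(default_parameters("wildtype"), method = "reduced")
hysteresis_extent(default_parameters("mutant"), method = "reduced")
```

## Stochastic populations

`simulate_population()` integrates independent cells with the
Euler-Maruyama scheme (step 0.01), multiplicative noise
$\sigma X\,\mathrm{d}W$ per species ($\sigma = 0.05$) and lognormal
initial-condition jitter (CV 0.1). Multiplicative noise keeps states
non-negative and produces the log-scale spread characteristic of single-cell
protein measurements; the amplitudes are conventional choices of this
package, selected once as a realistic cell-to-cell variability scale, not
fitted to data. Cells are classified E-low/E-high against the geometric
midpoint of the epithelial and mesenchymal attractor E levels, recomputed
per parameter set so the threshold tracks recalibration.

Population modality is decided by 1- versus 2-component Gaussian mixtures on
log E (unequal variances), accepting two modes only when the 2-component BIC
wins by more than 10 — a deliberately conservative evidence margin — plus
the skewness/kurtosis bimodality coefficient as a descriptive statistic.

With these noise levels, noise-driven commitment from the epithelial branch
is appreciable only in the upper part of the bistable window, where the
escape barrier is small: a wildtype population held at dose 11.5 splits into
two modes, while at deep-window doses (say 7) it remains unimodally
epithelial over the simulated horizon. That is how the bimodal-transition
claim is exercised here; it does not mean every dose inside the window
yields a 50:50 split.

Pulse memory and MET reversion use the same machinery. At dose 20 the
wildtype circuit commits within ~9 time units, so a 12-unit pulse followed
by 12 units of washout leaves the pulsed fraction within a few percent of
the continuously treated one, while the mutant relaxes back in ~2 units and
retains nothing. After withdrawal, wildtype reversion dwells ~17 units in a
mesenchymal ghost state (the autocrine loop decays only as miR-200 creeps
back up) and passes through a clearly bimodal intermediate; the mutant
reverts gradually and unimodally about 8 times faster. The orderings and
ratios, not the absolute times, are the reproduction surface.

## Global sensitivity analysis (RS-HDMR)

`sample_hypercube()` draws i.i.d. uniform samples (maximum entropy on a box)
of the four loop constants $k_Z, K_Z', k_{MZ}, K_Z''$. The default box is a
factor-of-10 box around the wildtype values, $[v/10,\,10v]$; log-uniform
sampling is available as a flag. `evaluate_extent_map()` computes the
hysteresis extent per sample via the reduced route, scanning doses 0-60
(about five times the wildtype window top): windows that migrate beyond that
regime are recorded as missing and excluded pairwise, with the count
reported — about 10% of the default box. Imputing zero instead would pull
the indices toward the migration direction, which is why exclusion-plus-count
was chosen.

`fit_hdmr()` implements random-sampling HDMR: inputs rescaled to the unit
cube, first-order components expanded in orthonormal shifted-Legendre
polynomials (degree 5), second-order components in 3x3 tensor products, all
coefficients estimated jointly by least squares. Because the basis is
orthonormal under the sampling measure, each component's variance is its sum
of squared coefficients; indices are normalised by the model-consistent
total (component variances plus residual mean square), so they are
non-negative and sum to one with the residual fraction exactly.

On the extent map this identifies $K_Z'$ as the dominant first-order input
(index ~0.15, versus ~0.08 for $k_Z$, ~0.03 for $k_{MZ}$ and ~0.001 for
$K_Z''$ — the last is structurally zero since E does not feed back), with
$k_Z\!:\!K_Z'$ and $K_Z'\!:\!k_{MZ}$ the leading interactions, and a
strongly non-linear $K_Z'$ component that contributes to hysteresis only at
small $K_Z'$. The extent distribution over the box is bimodal: a ~2/3 mass
at zero and a positive mode near the wildtype extent, the footprint of the
bifurcation itself. The residual variance fraction (~0.55) is reported, not
hidden: the extent map has a cliff (the cusp), which a degree-5/3x3
expansion cannot capture; the ranking is insensitive to this.

The narrower reading of the box, $[v/\sqrt{10}, v\sqrt{10}]$, was examined
and rejected: it confines sampling to the pre-cusp regime where the window
mostly migrates rather than disappears, which hands the top first-order
index to $k_Z$. The factor-of-10 box spans both regimes and is the default.

## The paracrine lattice

`init_field()`/`run_field()` place one cell per site of a periodic 64x64
lattice. Operator splitting advances each step: local reaction (forward
Euler, dt = 0.02) then explicit diffusion of the TGF-beta field with the
standard 5-point Laplacian; miR-200, ZEB and E-cadherin stay
cell-intrinsic. The time step must satisfy the diffusion stability bound
$dt \le dx^2/4D$, enforced at construction. A random 2% of sites act as
treated point sources (injection rate 600 a.u./time while the source phase
lasts, default 40 time units; with $D = 3$ this makes the lattice-wide mean
field sit below the upper saddle-node while source neighbourhoods exceed
it). EMT then spreads outward from the sources in contiguous patches with
irregular diffusion-shaped edges, and after the sources shut off the
hysteretic tissue retains the patches for many relaxation times while the
mutant tissue collapses back almost immediately. `mesenchymal_fraction()`
and `largest_patch()` (connected components under 4-adjacency with periodic
wrap) summarise the fields.

`reversion_field_experiment()` runs the spatially resolved withdrawal
protocol: a uniform conditioning dose, then autocrine production and
diffusion alone. On a uniform lattice the Laplacian vanishes and every site
follows the single-cell trajectory exactly — one of the cross-checks in the
test suite, together with discrete mass conservation of the diffusion
operator and cyclic translation equivariance of the whole simulation.

## Synthetic cytometry

`facs_spec()`/`generate_facs()` provide a ground-truth generator emulating
single-cell E-cadherin fluorescence histograms: 1- or 2-component lognormal
mixtures (log10-scale means and SDs), multiplicative lognormal instrument
noise, and a detector floor with the clipped fraction reported.
`facs_from_model()` pushes simulated population snapshots through the same
measurement model, so the modality analysis can be validated against known
mixtures and then applied unchanged to model output. The generator encodes
no experimental histogram; it is synthetic by design.

## Numerical choices and problem sizes

* Stiff single-cell integration: `deSolve::lsoda`, rel_tol 1e-8, abs_tol
  1e-10, restarts at protocol segment boundaries; negative excursions beyond
  abs_tol are integrator errors, smaller ones are clamped to zero.
* Steady-state detection: relative rate max |f_i|/(|x_i| + abs_tol) < 1e-7,
  t_max 1e4.
* Window bisection resolution 0.02 dose units; hysteretic/non-hysteretic
  classification threshold is twice that, with a strict inequality so an
  extent exactly at threshold classifies as non-hysteretic.
* Default study sizes: ensembles of 400-1000 cells over 40-150 time units;
  HDMR with 5000 samples; 64x64 lattice over 45 time units. These run in
  roughly a minute and a half altogether in `scripts/acceptance.R`; the
  qualitative results are stable under halving any of them (the test suite
  includes dt-halving and tolerance-halving consistency checks).

## Limitations

The model distinguishes only epithelial versus EMT-like attractors; partial
EMT ladders, SNAI1/miR-34 circuitry, cell division, motility and discrete
molecular noise are out of scope. The synthetic-data layers emulate the
phenomenology of single-cell readouts (log-scale mixtures, multiplicative
noise), not any instrument's calibration, so passing tests demonstrate
internal consistency and qualitative agreement with the modelled circuit,
not quantitative agreement with laboratory measurements. Dose and time units
are arbitrary; experimental concentrations and durations cannot be read off
the model.
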