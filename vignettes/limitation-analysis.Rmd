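---
title: "Partitioning photosynthetic limitation across VPD gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning photosynthetic limitation across VPD gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpdlim)
```

## The problem

High atmospheric vapour pressure deficit (VPD) is a water stress in its
own right: even in well-watered soil, the evaporative demand at the
leaf-air boundary can outrun root supply, leaf water potential falls, and
the plant throttles both stomatal and mesophyll CO2 transport. Net
photosynthesis then declines — but the *reason* it declines shifts along
the gradient. At low VPD the diffusion pathway is wide open and the
biochemistry (Rubisco carboxylation capacity) is the bottleneck; at high
VPD the stomata and mesophyll close down and CO2 starvation at the
chloroplast takes over. `vpdlim` quantifies that shift.

## The model

### Steady-state leaf

Net assimilation follows the Farquhar–von Caemmerer–Berry (FvCB) model for
C3 leaves, evaluated at the chloroplastic CO2 mole fraction $C_c$:

$$A = \min(A_c, A_j) - R_d, \qquad
  A_c = \frac{V_{cmax}(C_c - \Gamma^*)}{C_c + K_c(1 + O/K_o)}, \qquad
  A_j = \frac{J(C_c - \Gamma^*)}{4 C_c + 8\Gamma^*},$$

with $J$ the electron transport rate from a non-rectangular hyperbola in
PPFD ($\theta = 0.9$, $\alpha = 0.3$). Diffusion supplies CO2 through the
stomatal and mesophyll conductances in series,
$g_{tot} = (1/g_{sc} + 1/g_m)^{-1}$, and the steady state is the unique
$C_c$ where supply equals demand:

$$g_{tot}(C_a - C_c) = \min(A_c, A_j) - R_d.$$

`solve_steady_state()` brackets this root on $(0, C_a + R_d/g_{tot}]$ and
solves it with `uniroot` to a tolerance of $10^{-12}$; the emitted records
keep the supply–demand residual below $10^{-6}$ µmol m⁻² s⁻¹. The
transition between limitation states is a hard minimum, not a hyperbolic
blend: the partition analysis differentiates $A(C_c)$, and a smoothed
minimum would contaminate the window used for that slope.

The simulated PSII operating efficiency is back-computed from the *actual*
electron flux consistent with the achieved carboxylation,
$J = (A + R_d)(4C_c + 8\Gamma^*)/(C_c - \Gamma^*)$. On
RuBP-regeneration-limited points this equals the light-response $J$;
under Rubisco limitation it is lower, exactly as fluorescence — which
tracks realised photochemistry, not potential — would report. This is
what makes the variable-J estimator exact on noiseless synthetic records
in either state (the generator routes no electrons to alternative sinks;
real leaves may, which is why a Rubisco-screening flag is still offered).

### Conductance estimation

The variable-J estimator inverts $A_j$ at the measured $J$ to get the
implied $C_c$, and divides the assimilation flux by the mesophyll
draw-down:

$$g_m = \frac{P_n}{C_i - \Gamma^*\dfrac{J + 8(P_n + R_d)}{J - 4(P_n + R_d)}}.$$

Estimates with $J \le 4(P_n + R_d)$ are errors (electron transport cannot
support the measured assimilation); a non-positive denominator yields a
flagged `NA`, never a silent drop, and downstream summaries skip flags and
report counts.

$R_d$ and $\Gamma^*$ come from the Laisk two-light procedure: straight
lines are fitted to low-CO2 (Ca 30–120 µmol mol⁻¹) $P_n$–$C_i$ responses
at 75 and 500 µmol m⁻² s⁻¹ PPFD, and their intersection is read as
$(\Gamma^*, -R_d)$. Both curves truly pass through
$(\Gamma^* - R_d/g_m, -R_d)$, so the estimate carries a bias of order
$R_d/g_m$ plus a line-approximation error from the curvature of the
responses; the bias is documented in the fit diagnostics rather than
corrected, because the field convention reports the x-intersection as
$\Gamma^*$. With $g_m = 10$ mol m⁻² s⁻¹ the round trip recovers
$\Gamma^* = 40$ within 0.4 and $R_d = 1$ within 0.18; with the generator's
realistic $g_m \approx 0.6$ the recovered $\Gamma^*$ is ≈ 2.4 µmol mol⁻¹
low, which propagates a proportional (few-percent) bias into downstream
$g_m$ estimates — visible in the pipeline's regression table and accepted
as part of the method.

### Capacity fitting

`fit_fvcb()` fits $V_{cmax}$ and $J_{max}$ by nonlinear least squares of
$P_n$ against $\min(A_c, A_j) - R_d$. The axis is $C_c$ when a mesophyll
conductance is available and $C_i$ (infinite $g_m$) otherwise, and the
choice is recorded — instrument campaigns report both conventions, so the
output must say which was used. Determinism matters for reproducibility:
the optimiser is grid-seeded ($V_{cmax} \in \{25, 50, 100, 200\}$,
$J_{max} = 2V_{cmax}$) and the best converged start wins. A curve whose
points all sit on one limitation branch makes the other capacity's
gradient vanish (a singular model); the fit then falls back to the
single-branch model and flags the unidentifiable parameter instead of
failing.

### The partition

With $k = \partial A/\partial C_c$, total differentiation of the
supply–demand balance splits the relative limitation into

$$L_s = \frac{g_{tot}/g_{sc}\, k}{g_{tot} + k},\qquad
  L_m = \frac{g_{tot}/g_m\, k}{g_{tot} + k},\qquad
  L_b = \frac{g_{tot}}{g_{tot} + k},$$

which sum to one identically (the tests verify closure to $10^{-9}$ on
random inputs). $k$ is measured as the OLS slope of $P_n$ on $C_c$ over
$C_c \in [40, 110]$ µmol mol⁻¹. That window is interpreted on the $C_c$
axis — it is the variable being differentiated — and the standard A-Ci
protocol leaves only two points there, so the pipeline measures a
dedicated low-CO2 ramp (Ca 50, 75, 100, 125, 150 µmol mol⁻¹) at each VPD
level to populate the window. The partition is computed per VPD level from
that level's own conductances and slope; no cross-level reference state is
involved.

### Water relations

Air water potential uses the Kelvin relation
$\Psi_{air} = (RT/\bar V_w)\ln(\mathrm{RH})$ with Tetens saturation vapour
pressure, giving −42.6 MPa at 1 kPa VPD and 28 °C — three orders beyond
typical leaf potentials, which is the entire story of the leaf-air
driving force. A linearised mode ($-\,(RT/\bar V_w)\,\mathrm{VPD}/e_s$) is
provided because empirical driving-force regressions are linear in VPD;
its error is $(\mathrm{VPD}/e_s)/2$ to first order. A third,
regression-passthrough mode (`driving_force_ratio_from_trends()`)
evaluates published component regressions directly, so worked-example
reproduction does not depend on any particular thermodynamic conversion.

One physical subtlety: a leaf at 28 °C cannot face a 4.5 kPa VPD in
28 °C air ($e_s(28) = 3.78$ kPa). The pipeline therefore carries a
separate air temperature (default 32 °C, $e_s = 4.76$ kPa) for the
$\Psi_{air}$ calculation, configurable in `pipeline_config()`.

## The synthetic study

The generator's defaults *are* the study conditions of the motivating
tomato experiment, not free dials:

* VPD grid 0.5, 1.5, 2.5, 3.5, 4.5 kPa; leaf 28 °C, PPFD 1100
  µmol m⁻² s⁻¹, Ca 400 µmol mol⁻¹; n = 4 replicates.
* Conductance declines, ABA rise and leaf-water-potential decline use the
  published caption coefficients per acclimation regime (HVPD/LVPD), e.g.
  LVPD $g_{sw} = -0.200\,\mathrm{VPD} + 0.928$,
  $\mathrm{ABA} = 301.3e^{0.15\,\mathrm{VPD}}$,
  $\Psi_{leaf} = -0.258\,\mathrm{VPD} - 0.347$ (`ref_vpd_trends()`).
  The caption conductances are treated as water-vapour-basis $g_{sw}$ and
  divided by 1.6.
* Soil water potential follows from caption algebra
  ($\Psi_{leaf}$-intercept + $\Delta\Psi_{soil-leaf}$-intercept):
  −0.24 MPa (HVPD), −0.217 MPa (LVPD).
* FvCB kinetics use widely published tobacco-derived constants
  ($K_c = 404$ µmol mol⁻¹, $K_o = 278$ mmol mol⁻¹, $\Gamma^* = 40$
  µmol mol⁻¹) with no temperature response — the protocol holds a single
  temperature, so they are at-measurement-temperature inputs.
* $V_{cmax} = 110$, $J_{max} = 140$ µmol m⁻² s⁻¹. The ratio (1.27) is at
  the low end of the C3 range, deliberately: the variable-J method
  presumes the measurement point is RuBP-regeneration-limited, and this
  pair keeps the leaf in that state at the standard environment for
  VPD ≤ 3.5 kPa under the caption conductances. A "textbook" ratio near
  1.8 would put the operating point on the Rubisco branch and contradict
  the method being exercised.
* Measurement noise is multiplicative Gaussian on the observables
  ($P_n$ CV 2%, $g_{sw}$ CV 5% — instrument-realistic repeatability;
  these are configuration, not published values), with $C_i$ recomputed
  from the noisy observables so each record stays internally consistent.
  Replicates differ only through noise.

What the generator does *not* emulate: alternative electron sinks and
patchy stomatal closure (both bias real variable-J estimates), dynamic
stomatal kinetics, leaf energy balance, mechanistic ABA signalling, and
cultivar-level biological variance. Passing recovery tests therefore
demonstrates the *estimators* are correct and the pipeline is internally
consistent — not that field data will be as kind.

## Noise sensitivity and the replicate-mean convention

The variable-J estimator is intrinsically noise-hungry at ambient CO2:
the implied $C_c$ responds to $P_n$ with gain
$dC_c/dP_n = (4C_c + 8\Gamma^*)^2 / (12 J \Gamma^*) \approx 36$ at the
reference state, so a 2% error in $P_n$ moves the estimate by tens of
percent. Two standard practices keep the analysis honest:
`gm_from_replicates()` averages the replicate observables *first* and
inverts once (derived quantities from treatment means), which removes
most of the nonlinear skew; and estimates remain point-flagged so invalid
inversions are visible. Under 2% noise with n = 4 replicates the
median bias across 20 simulation seeds is under 5% for $g_m$, $V_{cmax}$
and $J_{max}$; the per-seed spread of $g_m$ remains large (tens of
percent), which is a property of the method, not of the implementation.

## Numerical choices

* Root bracketing $(10^{-9}, C_a + R_d/g_{tot} + 50]$ covers the dark
  case $C_c > C_a$; no sign change is reported as a non-physical
  parameter combination.
* Exponential regressions are fitted by log-linear OLS, not nonlinear
  least squares; published caption R² values are consistent with
  transformed-scale fits, and both R² scales are reported.
* A constant response is given slope 0 and R² 0 by convention.
* Laisk lines are declared parallel below a slope difference of
  $10^{-8}$.
* Ties in the FvCB multi-start are broken toward the first (smallest)
  start; convergence tolerances are fixed (`ftol = ptol = 1e-12`) for
  bit-reproducibility.
* Written tables round to 6 significant digits so reruns are
  byte-identical.

## Problem sizes

The bundled configurations are sized for interactive use: two regimes ×
five VPD levels × four replicates of steady states, an 11-point A-Ci
curve and a 5-point low-CO2 ramp per level, and an 8-point two-light
Laisk set per regime — a full pipeline run takes about a second, and the
complete test suite (including 20-seed noise studies) well under a
minute. Larger campaigns only change the configuration.

## Known limitations

* The partition is the conductance-weighted local decomposition above;
  Grassi–Magnani-style relative-change decompositions against a reference
  state are out of scope.
* No temperature normalisation of capacities, no TPU limitation, no
  pressure–volume analysis, no hydraulic conductance estimation.
* The Laisk $\Gamma^*$ inherits the $C_i$-axis bias discussed above;
  at realistic $g_m$ this propagates a few percent into $g_m$ and the
  mesophyll share of the partition.
* ABA is an empirical exponential response used for correlation analyses,
  not a mechanistic signalling model.
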