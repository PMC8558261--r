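---
title: "Passive cable models of dendritic signalling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive cable models of dendritic signalling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrisig)
```

# The scientific problem

Tauopathies such as the frontotemporal-dementia-linked P301L mutation alter
the morphology of neocortical pyramidal neurons — spine loss, apical tuft
regression, diameter changes — while leaving somatically measured input
resistance and membrane time constant within normal ranges.  Whether such
morphological regression degrades *subthreshold dendritic signalling* (how
well, and how fast, a synaptic potential generated somewhere on the dendrite
reaches the soma) cannot be measured directly at hundreds of dendritic
sites; it can, however, be computed in anatomically faithful passive cable
models.  `dendrisig` implements that workflow end to end: morphology in,
fitted passive cable model, per-site signalling descriptors, and two-group
statistics out, together with a seeded generator of pyramidal-like test
morphologies so the full pipeline runs and is testable without any external
reconstruction files.

# Model

## Passive cable and compartments

The membrane potential obeys the linear cable equation
\[
C_m \frac{\partial V}{\partial t} + \frac{V}{R_m}
  = \frac{r}{2 R_a} \frac{\partial^2 V}{\partial x^2},
\]
with specific capacitance $C_m$ (µF/cm²), specific resistance $R_m$
(Ω·cm²), axial resistivity $R_a$ (Ω·cm) and radius $r$.  Dendrites are
discretized into cylindrical compartments; the soma is one isopotential
sphere whose surface area is either taken from the reconstruction (an
override attached to the morphology) or computed as $4\pi r^2$ from the mean
soma sample radius.  Compartment length never exceeds
$\min(37\ \mu m,\ 0.2\lambda)$, where
$\lambda = \sqrt{d\,R_m^{*}/(4 R_a)}$ is the space constant computed with the
spine-corrected membrane resistance (below); this reproduces the synaptic
injection-site spacing rule of the experimental modelling literature this
package follows.

Numerically, each compartment lumps the membrane of its cable interval at
its midpoint.  Three choices keep the scheme second-order accurate, which we
verify by the refinement invariant (halving the spacing changes somatic
input resistance by well under 0.2%):

* membrane area is integrated exactly over the underlying sample cylinders
  (so total membrane capacitance is independent of the discretization);
* axial half-resistances integrate $4R_a/(\pi d^2)$ piecewise over the
  samples of each half-compartment rather than using a single mean diameter;
* at branch points, the massless junction node is eliminated exactly by a
  star–mesh transform (sibling branches acquire the small direct coupling
  the exact Schur complement prescribes).  Unbranched runs are additionally
  split wherever the sample diameter steps by more than ~18%, so no
  compartment lumps membrane asymmetrically across a step.

Internally the package works in µm/ms/mV/nA, giving MΩ, µS and nF as the
derived electrical units (τ = nF/µS = ms with no conversion factors); the
specific constants keep their conventional units and every conversion lives
in one file.

## Spine folding

Spines are not modelled as geometry.  Each dendritic compartment's specific
capacitance and leak conductance are scaled by
$q = (A_s + A_d)/A_d$, with $A_s = \rho\, l\, a_s$ the total spine membrane
received by the compartment ($\rho$ spines/µm, $a_s = 1.5$ µm² per spine)
and $A_d = \pi d l$ the smooth cylinder area, so
$q = 1 + \rho a_s/(\pi d)$.  The soma has $q = 1$.  The space constant in
the spacing rule and in electrotonic distances uses the corrected
$R_m/q$.  A folded model is exactly equivalent to one whose lateral areas
are inflated by the spine area, which is asserted as a matrix-identity test.

## Membrane fitting

Experiments constrain two somatic quantities per group: input resistance
$R_{in} = \Delta V / I$ under constant somatic current, and the membrane
time constant measured as the time for the soma to reach 63% ($1 - e^{-1}$)
of peak depolarization under a 200-ms current step.  The fit is the
two-step procedure of the source experiments:

1. **fit_Rm**: Brent root-finding on $\log_{10} R_m$ against the target
   $R_{in}$ (the map is strictly increasing), re-compartmentalizing at every
   candidate because λ depends on $R_m$; bracket $[10^3, 10^6]$ Ω·cm²,
   widened once if needed.
2. **fit_Cm**: with $R_m$ fixed, the passive system scales time exactly
   linearly in $C_m$, so one simulation gives
   $C_m^{*} = C_m^{(0)}\,\tau_{target}/\tau^{(0)}$; a secant polish absorbs
   the (tiny) grid-interpolation ripple.  Relative tolerance $10^{-3}$ for
   both steps.

Each neuron is fitted to its *group's* mean targets (197 MΩ / 32.5 ms and
228 MΩ / 35.2 ms for the wild-type-like and mutant-like presets), mirroring
the original procedure of matching electrophysiologically determined group
means; per-neuron targets are accepted through the same interface.  Because
the spine density is folded in before fitting, the fit absorbs spine load
into $R_m$ and $C_m$, again as in the source procedure.  The measured
$\tau_{63}$ is an operational quantity: with a 200-ms window the peak is
taken at the step end, which for τ ≈ 33 ms sits ~0.2% below the asymptote;
fit and measurement use the same definition, so targets are matched exactly
as defined.

## Solvers

* **Steady state**: direct solve of $(G_{leak} + G_{axial})V = I e_{site}$.
* **Phasor**: $(G + i\,2\pi f C)\tilde V = I e_{site}$; $|\tilde V|$ is the
  sinusoidal steady-state amplitude (checked against the time domain to
  0.5%).
* **Time domain**: Crank–Nicolson at $dt = 0.025$ ms, unconditionally
  stable and second order.  Currents and synaptic conductances are evaluated
  at half steps; the time-varying synaptic conductance enters the implicit
  matrix and is applied through a rank-$k$ Woodbury update of the
  pre-factorized system, preserving second-order accuracy.  Voltages are
  deviations from rest; the resting potential enters only through the
  synaptic driving force $V - (E_{syn} - E_{rest})$, exploiting the
  affine structure of the passive system.

# Signalling descriptors

For every dendritic compartment midpoint (the modelled synaptic site):

* **Steady and 50-Hz voltage transfer** — ratio of somatic to local
  amplitude under current injection at the site.
* **Current transfer** — fraction of injected current delivered to the
  voltage-clamped soma, computed from the Schur complement of the
  conductance matrix.  By reciprocity this equals the somatofugal voltage
  transfer from soma to site; the equality is held as a dual-route test at
  $10^{-8}$, never assumed by the implementation.
* **Centroid delays** — local (current → local voltage), propagation
  (local → somatic voltage) and total.  The definitional route integrates
  the model and takes centroid differences of the traces; because the system
  is linear these are input-shape independent (tested: alpha current vs a
  1-ms pulse).  The batch route evaluates the identical quantities exactly
  from the first moment of the transfer function,
  $\text{delay}_{j \leftarrow i} = (G^{-1} C\, G^{-1})_{ji} / (G^{-1})_{ji}$,
  for all sites in one factorization; both routes are cross-checked to
  0.01 ms.  For the injected-current centroid the half-step samples the
  integrator consumes are used — for that sequence the discrete centroid
  identity is exact, whereas full-step trapezoids misplace step
  discontinuities by $O(dt)$.
* **Somatic EPSP shape** — 10–90% rise time and half-width of the somatic
  EPSP evoked by an AMPAR-like alpha conductance at the site
  ($g_{max} = 0.25$ nS, $t_{peak} = 0.5$ ms, $E_{syn} = 0$ mV), crossings
  located by linear interpolation.
* **Electrotonic distance** — $L_i = \sum_k l_k/\lambda_k$ along the soma
  path with spine-corrected $\lambda_k$; the within-cell mean and variance
  of $L_i$ over sites are the two synaptic input pattern-recognition
  predictors.
* **Area-weighted means** — $\sum A_i D_i / \sum A_i$, with $A_i$ the
  spine-corrected receptive area $q_i A_{d,i}$ by default (a proxy for
  synapse counts); a switch provides smooth areas, since the source
  procedure does not state which was used.

# Group comparison statistics

Two families of comparison graphs are built per descriptor, arbor
(apical/basal) and scale (absolute or percent-of-neuron-maximum,
10% bins): the distance dependence of the descriptor (per-neuron bin means;
50-µm default bins) and the distribution of dendritic surface area over
descriptor values (per-neuron area fractions; default widths 0.05 for
transfers, 2 ms for delays and half-widths, 1 ms for rise times — chosen to
mirror the granularity of the source figures; all configurable).

Each graph is tested by a fixed-effects two-way ANOVA (group × bin) on the
per-neuron bin values with Type-II sums of squares for the unbalanced
design; neurons, not sites, are the replicates (each neuron contributes at
most one value per bin).  Bonferroni-corrected two-sample t tests per bin
(Mann–Whitney by option) are run only in bins with at least three values in
both groups; the percentage of eligible intervals flagged summarizes the
degree of alteration per descriptor.  The calibration test draws per-neuron
bin values iid from one distribution and confirms the group-effect size at
0.05 ± 0.02 over 400 replicates.  A caveat stated deliberately: if real
data carried strong neuron-level random intercepts, the fixed-effects ANOVA
would be anticonservative; a mixed model is out of scope here because the
source analysis is a fixed-effects ANOVA.

Identity of binned length and surface-area distributions is tested with a
Kolmogorov–Smirnov statistic on the cumulative binned curves.  Because the
binned fractions are weighted quantities rather than iid samples, the
p-value uses the classical asymptotic formula with the number of bins as
effective sample size and is flagged approximate in the output.  Scalar
group contrasts (fitted $R_m$, $C_m$, electrotonic predictors, area-weighted
means) use two-sided Mann–Whitney tests.

# The synthetic morphology generator

The generator emulates two populations of layer-III-pyramidal-like neurons:
a soma sphere, 4 basal stems grown as a depth-limited Galton–Watson process
(bifurcation guaranteed at the first two branch orders, probability decaying
with depth, lognormal segment lengths, diameter taper 0.82 per order,
extent capped at half the total), and an apical trunk with oblique side
branches and a terminal tuft whose extent scales with `tuft_size_factor`.
All randomness flows through R's seeded Mersenne-Twister, so populations are
bit-reproducible.

The two presets encode the study contrasts: spine density 1.25 vs 1.00 /µm,
apical tuft extent ×0.8 in the mutant-like group, resting potential −75 vs
−65 mV, fit targets 197 MΩ/32.5 ms vs 228 MΩ/35.2 ms, and soma radii
matching the reported mean soma areas (146.2 vs 205.2 µm²).  The mutant-like
preset also thins dendrites mildly (basal stems 0.93 vs 1.0 µm, apical trunk
1.45 vs 1.7 µm).  The thinning magnitude was chosen once so that the two
presets share the same electrotonic architecture (the observed condition in
the modelled populations, whose pattern-recognition predictors were
indistinguishable); with architecture matched, the group difference in
delays follows from the time-constant targets alone.  Fitted constants then
land in physiological ranges ($R_m \sim$ 19–32 kΩ·cm², $C_m \sim$ 1.3–2.3
µF/cm²) and per-arbor compartment counts fall near the reported ranges.

What the generator does *not* claim: statistical fidelity to any real
morphometric dataset (branch-angle statistics, 3D space filling, diameter
correlations are stylized).  Consequently the within-group variability of
the apical arbor is larger than in the reconstructions the study used: at
n = 10 per group the apical-arbor delay increase is directionally present
but not reliably significant on its own, while the basal-arbor and
whole-dendrite contrasts are robust.  The seeded end-to-end test asserts
exactly that pattern, and passing it demonstrates the pipeline's behaviour
under these synthetic conditions — not a reproduction of effect sizes in
real reconstructions.

# Numerical choices and degenerate inputs

* $dt = 0.025$ ms everywhere; time-constant steps 200 ms; delay windows
  400 ms (> 10τ, centroid truncation < $10^{-3}$ ms); EPSP windows 250 ms
  with an explicit error if the EPSP has not decayed to half amplitude.
* Rin/τ step amplitude +10 pA (depolarizing); results are
  amplitude-independent in a passive model and tested as such.
* Soma-only morphologies compartmentalize to a single compartment;
  soma-less cables are supported for analytic fixtures (input resistance is
  then measured at the root compartment).  Morphologies with structure
  codes other than soma/basal/apical are accepted, labelled `other`, and
  excluded from arbor-specific analyses with a warning.
* Zero-length SWC segments are dropped with a warning; orphan points,
  cycles, multiple roots and non-positive radii are hard errors with typed
  conditions.
* Degenerate comparison data (zero variance) raise a typed error rather
  than returning p = NaN; empty arbors skip a neuron with a warning at the
  graph-building stage.

The test suite runs the solvers at small problem sizes (trees of ~40–160
compartments, 10–20 neurons per population, 400 statistical replicates),
chosen so the full suite completes in a few minutes while every oracle
comparison stays well inside its stated tolerance.

# Known limitations

* Membrane is strictly passive: no voltage-gated channels, no $I_h$ sag, no
  NMDA voltage dependence.  Back-propagation efficacy is represented only
  through the passive current-transfer identity.
* Spines enter only as folded membrane; intra-spine signalling and
  anomalous diffusion effects are out of scope.
* The KS test on weighted binned distributions is approximate by
  construction and flagged as such.
* The fixed-effects ANOVA treats per-neuron bin values as independent
  across bins; see the statistics section for the calibration this does and
  does not cover.
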