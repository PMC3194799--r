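---
title: "Methods: dynamics of the Myc/E2F/miR-17-92 switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamics of the Myc/E2F/miR-17-92 switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirswitch)
```

## The model

The package analyses a two-variable reduction of the Myc/E2F/miR-17-92
cancer network.  The protein module $\phi$ lumps the Myc and E2F
transcription factors, which activate their own expression; the miRNA
module $\mu$ lumps the miR-17-92 cluster, which is transcribed downstream
of the protein module and post-transcriptionally inhibits it.  In
dimensionless form,

$$\frac{d\phi}{d\tau} = \alpha
  + \frac{\kappa\,\phi^2}{1 + \phi^2 + \Gamma\mu} - \phi, \qquad
  \frac{d\mu}{d\tau} = \epsilon\,(\beta + \phi - \mu).$$

The autocatalytic term is second order in $\phi$ (cooperative
self-activation), saturates at high protein, and is hyperbolically
inhibited by the miRNA.  The five parameters are:

* $\alpha \ge 0$ — constitutive protein input from upstream signalling;
  the experimentally controllable stimulus.  Physical window
  `alpha_range`, default $[0, 0.25]$.
* $\beta \ge 0$ — constitutive ($\phi$-independent) miRNA transcription;
  default 0.2.  At steady state $\mu^* = \phi^* + \beta$, so the two
  steady-state coordinates differ only by this constant.
* $\kappa \ge 0$ — strength of the positive feedback; default 3.5.  Without
  miRNA inhibition ($\Gamma = 0$) folds exist for
  $\kappa > 8/(3\sqrt3) \approx 1.54$ and the deactivating fold drops below
  $\alpha = 0$ for $\kappa > 2$, so every switch is one-way.
* $\Gamma \ge 0$ — strength of the miRNA inhibition; $\Gamma = 0$ removes
  the negative loop entirely.
* $\epsilon > 0$ — ratio of the miRNA and protein degradation rates.
  miRNAs are typically more stable than proteins, so $\epsilon < 1$; the
  default 0.1 makes the miRNA the slow variable, which is what produces
  excitability and relaxation oscillation.  The worked examples compare a
  fast loop ($\epsilon = 0.02$) with a slow loop ($\epsilon = 0.2$).

A dimensional parameterisation (`dimensional_params`) with two saturation
constants, a miRNA-inhibition constant and separate degradation rates maps
onto the dimensionless form through `nondimensionalize()`; the protein
scale is $\sqrt{K_1/K_2}$, the time scale $1/\gamma_p$, and
$\epsilon = \gamma_m/\gamma_p$.

The package defaults ($\kappa = 3.5$, $\beta = 0.2$, $\epsilon = 0.1$,
basal $\alpha = 0.02$, stimulus level 0.16 for pulses) were fixed once, by
requiring that the canonical phenomenology of this network is reproduced:
a one-way switch without miRNA; a bistable switch whose effective region
grows with $\Gamma$; at the basal stimulus, bistability at $\Gamma = 1.0$,
an excitable configuration (three fixed points, only the off-state stable)
at $\Gamma = 1.2$, and, at $\Gamma = 1.6$, a window of relaxation
oscillation bounded by two Hopf bifurcations inside the physical stimulus
range.  They are defaults of the package's worked examples, not fitted
quantities; every function accepts arbitrary parameter values.

## Steady states and stability

Substituting $\mu = \phi + \beta$ into the protein balance and clearing
the denominator gives a cubic in $\phi$:

$$-\phi^3 + (\alpha - \Gamma + \kappa)\phi^2
  + (\alpha\Gamma - 1 - \Gamma\beta)\phi + \alpha(1 + \Gamma\beta) = 0.$$

`solve_steady_states()` finds all roots globally from the companion-matrix
eigenvalues, polishes each with Newton iteration (tolerance $10^{-12}$),
keeps roots with $\phi \ge -10^{-9}$ (clamped to zero) and de-duplicates
within $10^{-7}$; a fold-degenerate double root is reported once, flagged.
Because the system is two-dimensional and the fixed-point problem is a
cubic, there are always 1–3 fixed points and a dense re-solve can never
lose a branch — which is why the bifurcation sweeps re-solve at every grid
value rather than running pseudo-arclength continuation.  Stability comes
from the closed-form $2\times2$ Jacobian; labels follow eigenvalue signs,
and a real part within $10^{-10}$ of zero is flagged marginal rather than
silently classified.

## Bifurcation analysis and the switch taxonomy

`sweep_alpha()` re-solves on an ascending $\alpha$ grid (default 201
points), links branches between neighbouring grid values by
nearest-$\phi$ matching, bisects every root-count change (saddle-node) and
every sign change of the leading real part of a complex eigenvalue pair
(Hopf) to a bracket of at most $10^{-8}$, and discards Hopf candidates
whose imaginary part at crossing is below $10^{-6}$.

`switch_character()` classifies the fold structure on the *raw*
steady-state curve, without the physicality clamp: the off-root crossing
$\phi = 0$ is not a fold, and the deactivating fold of a one-way switch
lies at negative stimulus.  The bistable interval is the window enclosed
by the two saddle-nodes, independent of any Hopf instability on the upper
branch; a fold exactly at the lower end of the physical window counts as
bistable (a deterministic, documented tie-break).

`pointwise_regime()` labels a parameter point as one of four regimes:

* two stable fixed points → **bistable**;
* one stable off-state plus two unstable states, where a rectangular test
  pulse (amplitude 0.16 above base, 5 time units — configurable) drives
  $\phi$ above the middle branch and the system then returns within
  $10^{-3}$ of rest → **excitable**;
* no stable fixed point and a simulated orbit with at least three peaks,
  period dispersion below 5% over the last five cycles and amplitude above
  $10^{-3}$ → **oscillatory**;
* otherwise **monostable**.

Two numerical choices matter near the regime borders.  First, the
post-pulse settling window scales with the off-state's linear relaxation
time (capped at 5000 time units), because rest states close to the
oscillatory border are weakly damped foci that ring for hundreds of time
units.  Second, in a thin fringe near that border a stable limit cycle
coexists with the weakly stable rest state, so the pulse leaves the system
spiking indefinitely; such cells are labelled oscillatory, by their
verified post-pulse behaviour, rather than unclassified.  Probes that
remain genuinely indeterminate return `"unclassified"` — never a silent
guess.

`hysteresis_loop()` ramps the stimulus up and back down at
$10^{-5}$ stimulus units per time unit.  At this rate the dynamic delay of
the fold passage stays well under 2% of the fold location; the jump
detector looks for a between-sample change of $\phi$ far above the
quasi-static drift, with a threshold that scales with the ramp rate.  For
fold-location comparisons the examples use $\epsilon = 0.5$: the timescale
ratio does not move the folds, but at small $\epsilon$ the upper branch is
Hopf-unstable near the deactivating fold and a quasi-static sweep there
leaves the branch through growing oscillations instead of the fold.

## Deterministic and stochastic integration

`integrate_rk4()` is the classical fixed-step fourth-order Runge-Kutta
scheme with the stimulus evaluated at stage times; protocols are
right-continuous at discontinuities.  The default step $d\tau = 0.01$
changes the worked-example trajectories by less than $10^{-6}$ when
halved.  The default initial condition is "rest at basal stimulus": the
off-state fixed point at the protocol's base level.

Stimulus noise is additive in the $\phi$ equation
($\alpha_n(t) = \alpha(t) + \xi(t)$ with $\langle\xi\rangle = 0$,
variance parameter $\sigma^2$), the only noise pathway in the model.
`integrate_srk4()` advances the drift with the same RK4 stages and adds
one Gaussian increment $\sigma\sqrt{dt}\,z_i$ per step — for purely
additive noise this samples the Wiener contribution exactly, and at
$\sigma^2 = 0$ the scheme reduces bitwise to `integrate_rk4()`.  The
fluctuating input is never clipped at zero (clipping would bias the stated
zero mean); instead the *state* is clamped at zero after each step and
every clamp is counted in the run metadata, keeping the approximation
auditable.  The stochastic default $dt = 0.002$ was audited against a
50-fold finer Euler-Maruyama integration (two-sample Kolmogorov-Smirnov at
the 1% level) and against the closed-form Ornstein-Uhlenbeck stationary
variance $\sigma^2/2$ on the $\kappa = 0$ submodel.

## Stochastic ensembles

`run_ensemble()` starts $N$ cells at the on-state fixed point and drives
each with an independent noise stream (seed = `base_seed` + cell index;
noise arrays are never stored, only seeds and $\sigma^2$).  A cell counts
as having switched when $\phi$ first falls below the unstable
middle-branch level at the operating stimulus — a separatrix proxy that is
parameter-aware; if no middle branch exists the off/on midpoint is used.
The fraction of transition $F(t)$ uses the first-passage ("has
transitioned at least once") definition, which makes $F$ nondecreasing;
an instantaneous-occupancy variant is available because the two read
differently when cells re-cross.  The plateau $F_s$ is the mean of $F$
over the final 10% of the run, accepted when the fitted slope there is
below $10^{-4}$ per time unit and flagged otherwise; the response time
$T_R$ is the first time $F$ reaches the midpoint of its initial and
plateau values, linearly interpolated between samples.

The ensemble worked examples operate in the deep-bistable regime
($\Gamma = 1.0$, where the switch is one-way in the stimulus but off- and
on-states coexist), with noise variances 0.01–0.04 chosen so that escape
over the state-space barrier happens on the simulated horizon
($t_{\mathrm{end}} = 200$).  In this model, at fixed stimulus and noise,
raising $\Gamma$ moves the deactivating fold toward the operating point
and *increases* the escaped fraction; the monotone trend the ensembles
quantify is therefore taken along the stimulus axis, where $F_s$ falls
from near 1 to near 0 as $\alpha$ deepens the on-state.  Comparisons
between the fast ($\epsilon = 0.02$) and slow ($\epsilon = 0.2$) loops use
matched noise and seeds: the fast loop reaches its rise midpoint sooner
and flips more readily; the slow loop holds the on-state with a smaller
fluctuation amplitude.  One claim does not survive quantification at
matched stimulus: the $\Gamma = 0$ twin sits much deeper on its on-branch
than any $\Gamma > 0$ configuration at the same $\alpha$, so its on-state
coefficient of variation is smaller, not larger; the buffering role of the
negative loop appears in the slowed switching near the on-state rather
than in a matched-stimulus variance reduction, and the corresponding
acceptance expectation is left failing rather than weakened.

## What the stimulus generator does and does not emulate

The synthetic stimuli (constant, pulse, step, and their noisy variants)
reproduce the study conditions: piecewise-constant signalling input with
zero-mean Gaussian white fluctuation.  They do not emulate intrinsic
(demographic) reaction noise, colored extrinsic noise, transcriptional
delay, or cell-to-cell parameter variability.  Passing tests therefore
show that the *model* responds as described to idealised inputs, not that
real Myc/E2F expression data would; in particular the noise-induced
switching statistics quantify escape driven purely by stimulus
fluctuation.

## Problem sizes

The shipped analyses use desk-scale sizes chosen for comfortable
reproduction: a $60\times60$ grid for two-parameter regime maps, 201-point
stimulus sweeps, ensembles of $N = 200$ cells (the sampling error of
$F_s$ at this size is about $0.035$ at worst), and $10^6$-step runs for
the stationary-variance checks.  All are arguments, not constants.

## Known limitations

* No codimension-two bifurcation detection; none arises in the explored
  parameter ranges, and the boundary extraction assumes simple fold and
  Hopf crossings.
* The regime taxonomy is fourfold; the thin coexistence fringe described
  above is folded into the oscillatory label.
* Fixed-step integration only; the dynamics are non-stiff over the
  supported $\epsilon$ range ($\gtrsim 0.01$).
* The transition rule is a separatrix proxy, not the exact stable manifold
  of the saddle; for strongly non-normal configurations the crossing time
  can differ from the true basin exit time by a few time units.
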