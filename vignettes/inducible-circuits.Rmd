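---
title: "Effector-inducible gene circuits: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effector-inducible gene circuits: models, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inducible)
```

# The modelling problem

Dynamical-systems treatments of gene circuits usually tune abstract
parameters — dissociation constants, production and degradation rates — that
a living cell cannot reach directly. What cells actually modulate, rapidly
and reversibly, is the concentration of small-molecule effectors that bind
transcription factors and shift them between active and inactive
conformations. This package analyses the canonical regulatory motifs
(auto-activation, mutual repression, feed-forward loops) with the effector
concentration as the primary control knob, using statistical-mechanical
production functions rather than phenomenological Hill functions.

# Allosteric activity

A transcription factor is modelled as a two-state (MWC) allosteric protein:
an active and an inactive conformation separated by a free energy
$\varepsilon = \varepsilon_i - \varepsilon_a$ (in units of $k_BT$; we fix
$\beta = 1$ and never need an absolute temperature), with an effector that
binds $n$ identical sites with dissociation constants $K_A$ (active) and
$K_I$ (inactive). Summing Boltzmann weights over all binding configurations,

$$p_{\mathrm{act}}(c) \;=\;
  \frac{(1 + c/K_A)^n}{(1 + c/K_A)^n + e^{-\varepsilon}(1 + c/K_I)^n}.$$

The package implements general $n$ (`n_sites`, default 2, the value used in
all worked analyses); a brute-force enumeration over the $2^n$ binding
configurations serves as the test oracle for the closed form. Limits
$p_{\mathrm{act}}^{\max} = 1/(1+e^{-\varepsilon})$ (saturation, $c \to 0$
for an inactivating effector) and
$p_{\mathrm{act}}^{\min} = 1/(1+e^{-\varepsilon}(K_A/K_I)^n)$ (leakiness)
bound the curve, and the midpoint crossing defines the EC50 (found by
bisection on $\log_{10} c$ over a configurable bracket, default
$[10^{-15}, 10]$ M, residual $< 10^{-10}$).

The workhorse parameter set (`preset("mwc_tf")`) is $K_A = 140\,\mu$M,
$K_I = 530$ nM, $\varepsilon = 4.5\,k_BT$: an effector that stabilises the
inactive state, so activity falls with concentration across roughly three
decades of dynamic range (asserted in the test suite as
$2.5 \le \log_{10}(p^{\max}/p^{\min}) \le 3.5$). Concentrations are stored
in molar throughout; configuration files may use `uM`/`nM`/`M` suffixes.

# Thermodynamic production functions

Each motif's production term is a ratio of rate-weighted promoter-state
weights to the partition sum. For auto-activation with two activator sites
(dimensionless units: time in $1/\gamma$, concentration in $K_d$),

$$\frac{d\bar A}{d\bar t} = -\bar A +
  \frac{\bar r_0 + \bar r_1\, 2 a \bar A + \bar r_2\, \omega (a\bar A)^2}
       {1 + 2 a \bar A + \omega (a\bar A)^2},
  \qquad a = p_{\mathrm{act}}(c),$$

with $\omega = e^{-\varepsilon_{\mathrm{int}}}$ the pairwise binding
cooperativity. The ordering $\bar r_0 \le \bar r_1 \le \bar r_2$ keeps the
production monotone in $\bar A$ (a genuine activator) and is enforced by the
constructor unless explicitly overridden. The toggle switch and both
feed-forward-loop architectures follow the same states-and-weights recipe;
in the incoherent loop a bound repressor silences every promoter state, so
the basal rate sits inside the partition-sum ratio and fully repressed
output tends to zero, not to the basal rate.

# Fixed points, bifurcations and bistability conditions

Steady states of the auto-activation motif are roots of a cubic obtained by
clearing denominators; we take all real non-negative roots (via the
companion-matrix solver behind `polyroot`), polish each by Newton iteration
on the *rational* right-hand side, deduplicate at relative tolerance
$10^{-6}$, require residual $< 10^{-9}$, and classify by the analytic
derivative $f'$ (stable $f' < 0$, unstable $f' > 0$, "marginal" when
$|f'| < 10^{-8}$ — saddle-node points, excluded from stable counts).
Bifurcation sweeps use 200 log-spaced concentrations over
$[10^{-9}, 10^{-2}]$ M by default, with interval endpoints refined by
bisection in $\log c$ to $10^{-4}$ relative precision.

Descartes' rule of signs on the cubic yields three necessary conditions for
bistability at *some* effector concentration:
$\omega \bar r_2/2 > 1 + e^{-\varepsilon}$,
$2\bar r_1 < 1 + e^{-\varepsilon}(K_A/K_I)^2$, and
$\omega \bar r_2 > 4 \bar r_1$. The first makes the quadratic coefficient
positive at full activity, the second makes the linear coefficient negative
at the leakiness floor, the third makes the two achievable simultaneously;
together they imply that the effective cooperativity
$\omega_{\mathrm{eff}} = \omega \bar r_2 / 2$ must exceed one. Because the
derivation is exact, the randomized soundness scan in the test suite (2,000
parameter draws, exhaustive concentration scans) must find no bistable
violator — this scan is the primary guard against transcription errors in
the inequalities. The analogous toggle-switch bound is
$\bar r > 1/\big[(p^{\max}-p^{\min}) + \min(\omega_1,\omega_2)\,
p^{\max}/2\big]$; the grouping (the whole sum in the denominator) is the
reading under which the soundness scan passes, and the alternative reading
is already violated by a parameter set that is demonstrably bistable.

Toggle fixed points use the nullcline reduction: each repressor is an
explicit function of the other at steady state, so substituting one
nullcline into the other leaves a scalar root problem, bracketed on a dense
log grid over $(0, \bar r]$ and solved by bisection, then polished by 2-D
Newton and classified by Jacobian eigenvalues. Bistability maps default to
the inducer window $[10^{-7}, 10^{-4}]$ M. The geometry classifier reads
the map: bistable at the low-concentration corner means only upper bounds on
both inducers (`BOTH_SMALL`); otherwise, at the most permissive level of one
inducer, the other is confined to a window detached from the grid minimum
(`C1_WINDOW` / `C2_WINDOW`); a map with no bistable cell is `NONE`.

## The effective Hill coefficient

The reference definition of the open-loop sensitivity is not available, so
the package defines it as the maximum log–log slope of the basal-subtracted
production, $\max_{\bar A}\, d\log(P(\bar A) - \bar r_0)/d\log \bar A$,
computed by central differences on a log grid over
$\bar A \in [10^{-6}, 10^4]$ (400 points). For a two-site promoter this is
capped at 2, approaches 2 at large $\omega$, and exceeds 1 for every
bistable parameter set found in randomized scans — the three properties the
quantity exists to express. It should be read as this package's
operationalisation, not as a reproduction of an external formula.

## Hill versus thermodynamic production

The Hill variant replaces the states-and-weights ratio by
$r_0 + r_2 u^n/(1+u^n)$ with $u = p_{\mathrm{act}} A / K_d^{\mathrm{eff}}$,
kept dimensional (molar, per minute) so both models share one concentration
axis. Matching the thermodynamic model in the large-$\omega$ limit (where
the singly-bound state is negligible) forces
$K_d^{\mathrm{eff}} = K_d/\sqrt{\omega}$: the doubly-bound weight
$\omega (p_{\mathrm{act}}A/K_d)^2$ must equal
$(p_{\mathrm{act}}A/K_d^{\mathrm{eff}})^2$. With that bridge the two models'
bistability verdicts coincide exactly on the default grid for
$\omega \ge 10^4$, differ only at bistable-interval edges at
$\omega \sim 10^2$, and disagree qualitatively at $\omega \sim 1$ (the Hill
model predicts bistability at low effector concentration where the
thermodynamic model has none).

# Dynamics, timescales and phase-plane geometry

All integration goes through `deSolve::ode` (lsoda) at relative tolerance
$10^{-8}$ and absolute tolerance $10^{-12}$, with steady state declared at
right-hand-side residual $< 10^{-9}$. Linearised timescales use the analytic
derivative, $\tau = 1/|f'(\bar A^\ast)|$.

Two relaxation-time estimators are provided. `threshold_95` reports the 95%
convergence time (for the toggle, per component, taking the maximum — the
convention used for the phase-plane relaxation maps). `fit_exponential`,
the default for auto-activation, fits
$A(t) = A_\infty + (A_0 - A_\infty)e^{-t/\tau}$ with a free asymptote over
the window in which the deviation exceeds 1% of its initial value — an
exponential fit to the trajectory itself. A log-deviation tail fit was
considered and rejected: it converges to the fixed-point value
$1/|f'(\bar A_{\mathrm{high}})|$ for *every* start that ends on that branch
and therefore cannot express the known large-$A_0$ behaviour, where the
production term saturates, decay dominates, and the fitted timescale falls
toward the degradation time 1. With the free-asymptote fit the estimator
follows $1/|f'|$ near stable fixed points, grows near the unstable point,
and decreases toward 1 for large starts — though at moderate starts
($A_0 \approx 30\text{–}40$ for the reference parameter set) it still sits
10–25% above 1, because the saturated production (which exceeds the final
steady state throughout the transit) keeps the effective decay rate below
$\gamma$. The asymptotic value 1 is reached only at much larger $A_0$.

The separatrix of a bistable toggle is built as the stable manifold of the
saddle: the time-reversed flow is integrated from $\pm 10^{-6}$
displacements along the saddle's stable eigenvector and the two branches are
joined (clipped to $3\bar r$, beyond which the reversed flow diverges).
Validation perturbs points off the polyline by $10^{-3}$ and checks
convergence to opposite attractors; in the symmetric toggle the curve
coincides with the diagonal to $10^{-6}$. Exactly on the separatrix the
forward flow converges to the saddle or not at all; basin and relaxation
routines report such starts as unresolved/`on_separatrix` rather than
erroring, and grid diagonals of symmetric basin maps are excluded from
symmetry assertions for this reason.

# Feed-forward loop delay theory

With the input activity $\mathcal{X}$ stepped at $t = 0$ and the Y equation
linear at fixed effector, the output obeys
$\bar Z(t) = \bar Z_i e^{-t} + \bar Z_f (1 - e^{-t}) + \Theta(t)$, where the
offset from the matched simple-regulation exponential is

$$\Theta(t) = -\frac{\Phi\,\Delta\mathcal{Y}}{S^2}\, e^{-t}
  \log \frac{S e^{t} - \Delta\mathcal{Y} D}{S - \Delta\mathcal{Y} D},
  \qquad D = 1 + \omega \mathcal{X}_f,$$

$S$ the final-state partition sum and $\Phi$ a rate/cooperativity
coefficient ($\Phi = \omega\mathcal{X}_f^2(\bar r_{2Z}-\bar r_{1Z}) +
\omega\mathcal{X}_f(\bar r_{2Z}-\bar r_{0Z}) + (\bar r_{1Z}-\bar r_{0Z})$
coherent; $\Phi = -(\bar r_{0Z}+\bar r_{1Z}\mathcal{X}_f)D$ incoherent,
always negative). Integrating $\Theta$ gives the average delay in closed
form,

$$\langle \Delta \bar t \rangle =
  \frac{\Phi}{(\bar Z_f - \bar Z_i)\, S\, D}\,
  \log \frac{S - \Delta\mathcal{Y} D}{S},$$

negative (delay) for coherent loops, positive (acceleration, at most 1 —
the instantaneous jump) for incoherent loops without a pulse. These closed
forms were derived here from the model equations; because printed versions
of such expressions are easy to mistranscribe, `delay_analytics(check =
TRUE)` *always* verifies $\Theta$ against the ODE-derived offset
(sup-norm $10^{-6}$) and the closed-form delay against adaptive quadrature
of $\int_0^\infty \Theta$ (relative $10^{-6}$); the test suite runs this
self-check on every gate preset and on 100 seeded random parameter sets.
$\Theta$ is evaluated in the overflow-safe form
$\log(Se^t - \Delta\mathcal{Y}D) = t + \log(S - \Delta\mathcal{Y}D e^{-t})$.

Conventions and choices:

* **ON/OFF naming** follows the *activity* of X, not the raw concentration:
  with the default (inactivating) transcription factor, stepping $c_X$ from
  $10^{-4}$ M down to $10^{-7}$ M is the ON step. The default protocol uses
  exactly those levels with $c_Y = 10^{-7}$ M held fixed.
* **$\bar X = 1$**: the input concentration is a fixed parameter, not a
  dynamical variable; the gate presets do not pin it, so the package
  defaults to 1 (configurable). Quantities that depend on it — notably the
  sweep maxima of $|\langle \Delta\bar t\rangle|$ — inherit that assumption.
* **Sign laws and their scope.** The incoherent acceleration law
  ($0 \le \langle\Delta\bar t\rangle \le 1$) holds for responses that move
  *with* the step and show no strong pulse. Random parameter draws can
  produce responses that move against the step (repression outweighing
  activation); the delay normalisation is then not meaningful and the
  package leaves interpretation to pulse metrics instead.
* **Pulses** are overshoots beyond the final steady state (sign-aware). A
  pulse is "strong" when its amplitude exceeds 5% of the response magnitude
  $|\bar Z_f - \bar Z_i|$ — a package-defined threshold (configurable), as
  the reference definition is not available. Sweeps classify pulses from
  the closed-form trajectory on a 600-point grid over $\bar t \in [0, 30]$,
  so no per-cell ODE integration is needed.
* **Sweeps** default to $50 \times 50$ log-spaced grids of
  $(\bar K_{XZ}, \bar K_{YZ})$ over $[10^{-2}, 10^2]$ (axis ranges are a
  package choice).
* **Ramps** are log-linear in concentration. The input timescale $\bar t_c$
  (time for the X activity to traverse 0.2–0.8) is measured by root finding
  on the schedule; with the default transcription factor and the
  $10^{-4} \to 10^{-7}$ M ramp, durations of about 1, 7 and 22 time units
  give $\bar t_c \approx 0.24$, $1.65$ and $5.2$ — the fast, intermediate
  and quasi-stationary regimes. Slow ramps track the instantaneous steady
  state ever more closely (verified as a monotone sup-norm distance in the
  tests).

# Randomized scans as synthetic study conditions

The soundness and equivalence properties are exercised on randomly drawn
circuits: rates log-uniform over $[10^{-3}, 10^3]$ sorted to respect the
activator ordering, cooperativities log-uniform over the same span — wide
enough to cover the non-cooperative, weakly and strongly cooperative
regimes on both sides of the bistability threshold. These draws emulate
parameter diversity, not biological noise: the models are deterministic
ODEs, so passing scans demonstrate the analytic claims across parameter
space but say nothing about stochastic gene expression, mRNA/protein
two-stage dynamics, transcription-factor oligomerisation or DNA looping,
none of which are modelled.

# Problem sizes and reproducibility

The test suite uses 60–200-point concentration grids, $10$–$24$-point
2-D maps, 2,000 (auto-activation) and 250 (toggle) random parameter sets
for the soundness scans, and 100 random sets for the delay self-check;
`scripts/acceptance.R` re-runs the headline computations (gate-sweep delay
maxima, the incoherent acceleration bound, the large-$A_0$ relaxation fit,
and the minimum effective cooperativity over a fresh 2,000-set scan) from
scratch with a caller-supplied seed. All other computations are
deterministic.

# Known limitations

* The diagonal pitchfork of the symmetric toggle, located here by bisection
  to $10^{-4}$ relative precision (and confirmed by brute-force forward
  integration on both sides), sits at a somewhat higher inducer
  concentration than the value quoted in earlier descriptions of this
  system; the test pinning it to that quoted value is expected to fail and
  is retained deliberately.
* The relaxation-time estimator is a stand-in for an unavailable reference
  procedure; see the discussion above for its behaviour at moderate
  starting concentrations.
* Continuation is by grid-plus-bisection, not pseudo-arclength; degenerate
  saddle-node points are labelled "marginal" rather than continued through.
  No limit cycles arise in these motifs, and none are searched for.
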