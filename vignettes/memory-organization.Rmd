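---
title: "Modeling the input-dependent organization of memory representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the input-dependent organization of memory representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memorg)
```

## The scientific problem

When two pieces of information are learned, the neural populations that
encode them can end up *discriminated* (functionally unrelated),
*associated* (mutually excitatory), or arranged in a *sequence* (one
direction excitatory, the other inhibition-dominated).  `memorg` implements
a rate-based recurrent network in which these functional organizations
emerge from the interaction of correlation-based Hebbian plasticity and
homeostatic synaptic scaling, together with a reduced two-population
equilibrium framework that predicts and classifies the organization
analytically.

## The full network model

The network holds $n$ rate neurons, all-to-all connected through plastic
excitatory synapses $\tilde\omega_{ij}$ and (by default static) inhibitory
synapses $\tilde\omega^-_{ij}$.  Two disjoint populations of $n_P$ neurons
receive population-specific external input through $n_P^{ex}$ input neurons
each; the remaining neurons form a background population that only receives
tuning noise.  All rates are normalized by the maximal rate $F^{max}$, all
weights by the maximal weight
$\omega^{max} = \mu (F^{max})^2 / (\gamma(F^{max} - F^T F^{max}))$, the
weight at which Hebbian growth and scaling balance at saturated rates.

The normalized dynamics are

$$\tau \dot{\tilde F}_i
  = (1-\tilde F_i)\tilde F_i\left[\ln\left(\tfrac{1}{\tilde F_i}-1\right)
    + g_i - K\, n_\epsilon (1-\tilde\theta)\right],
  \qquad
\tau_\omega \dot{\tilde\omega}_{ij}
  = \tilde F_i \tilde F_j
    + \frac{F^T - \tilde F_i}{1 - F^T}\,\tilde\omega_{ij}^2 ,$$

with the dimensionless drive
$g_i = K\left[\sum_j (\tilde\omega_{ij} - \tilde\omega^-_{ij})\tilde F_j
+ \sum_{k} w^{ex} \tilde F^{ex}_k\right]$ and gain
$K = \beta R\, \omega^{max}$.  The sigmoid inflexion is expressed in units
of the largest potential a single saturated synapse can evoke,
$u^{max} = R\,\omega^{max}(1-\tilde\theta)$, so that $n_\epsilon$ counts
"how many maximally wired presynaptic neurons it takes to reach the
inflexion".  The weight rule combines Hebbian growth $\tilde F_i\tilde F_j$
with quadratic synaptic scaling toward the target rate $F^T$; its clamped
fixed point,
$\tilde\omega^* = \sqrt{\tilde F_i \tilde F_j (1-F^T)/(\tilde F_i - F^T)}$,
is the workhorse of the reduced framework.

### Drive gain convention

The drive scale deserves a note.  Multiplying the printed neuron and
synapse constants as a literal unit calculation yields a gain of
$\beta R F^{max} \omega^{max} \approx 33$, which saturates every neuron and
is incompatible with the documented behaviour of the inflexion parameter
(operating window $9 \le n_\epsilon \le 16$, collapse above
$n_\epsilon \approx 24$).  Because the rates inside the drive are
normalized, one factor of $F^{max}$ is absorbed into them, leaving
$K = \beta R \omega^{max} \approx 0.332$.  With this convention the package
reproduces the documented inflexion phenomenology: at zero input the
no-memory window opens at $n_\epsilon = 9$ and closes after 15, the
operating point closest to $F^{min}$ is $n_\epsilon \in \{12, 13\}$, and at
maximal input high activity collapses after $n_\epsilon = 24$ with memory
lost after 28.  The literal-units variant is kept available through
`model_parameters(list(drive_convention = "literal"))` for comparison; it
is not used by any default.

### Parameters

`model_parameters()` carries the defaults: $n = 100$, $n_P = n_P^{ex} =
10$, $\tau = 1$ s, $R = 0.1$, $F^{max} = 100$ Hz, $\beta = 3.5\times
10^{-4}$ /mV, $\mu = 1/60$ /s, $\gamma = 1/5400$ /s, $F^T = 0.05$,
$\tilde\theta = 0.5$, $w^{ex} = 1$, Euler step $1$ ms.  The weight time
constant is taken as $\tau_\omega = 1/\mu = 60$ s.  The printed form of the
normalization constant is corrupted in the source material; the choice only
affects transients — every equilibrium quantity is independent of
$\tau_\omega$, which the test suite asserts by integrating the clamped
weight equation under different accelerations.

```{r}
p <- model_parameters()
derive_constants(p)[c("omega_max", "K", "F_min")]
```

### Stimulation protocols and what they emulate

A protocol is a tuning phase (every neuron receives iid Gaussian input
noise through its input layer, each draw clipped to $[0,1]$) followed by a
stimulation phase in which the input layers fire as Ornstein–Uhlenbeck
processes with population-specific stationary means.  The OU constants
$(\delta, \sigma) = (0.025, 0.0125)$ are per-step quantities at the
reference step of 1 ms; for other steps the drift is scaled by
$\Delta t/\Delta t_0$ and the diffusion by $\sqrt{\Delta t/\Delta t_0}$
(Euler–Maruyama).  Background neurons keep receiving the tuning noise
during stimulation, serving as controls.

These protocols emulate the *time-averaged* drive of naturalistic
stimulation: stimulus identity is carried only by the stationary mean of
the input.  They do not emulate temporally structured input (correlations,
bursts, pauses), overlapping population membership, sparse connectivity, or
separate excitatory/inhibitory neuron classes — conclusions drawn from
passing tests are therefore about the mean-driven regime of this model
class, not about such features of biological data.

### Numerical scheme

Integration is explicit Euler with a fully simultaneous update (all
derivatives evaluated on the pre-step state), rates clipped to
$[10^{-6}, 1-10^{-6}]$ and weights floored at 0.  The reference scheme is
implemented in R (`step_network`) and the production loop in C++; a test
asserts bit-level agreement between the two on a noise-free path, and an
Euler step-halving test checks first-order convergence.  Three RNG streams
(initial state, tuning noise, OU inputs) derive from one master seed, so
runs are bit-reproducible.

Equilibrium is detected online from the sampled population averages: a
phase ends when the largest absolute least-squares slope of every mean
synaptic-weight class over a trailing 100 s window falls below $10^{-5}$
per second.  A slope over a window, rather than a raw finite difference, is
used because the stochastic input jitter dominates sample-to-sample
differences long after the drift has stopped; the finite-difference
criterion is still available as `equilibrium_reached` for deterministic
trajectories.  When both plasticity rates are accelerated by a common
factor $c$ (equilibria are invariant, see below), the window shrinks and
the tolerance grows by $c$.

## The reduced two-population framework

At equilibrium, every weight is slaved to the rates through
$\tilde\omega^*$ (adiabatic elimination), so the state of the two
populations collapses onto the activity plane $(\mathfrak{F}_1,
\mathfrak{F}_2)$.  The package provides:

* `weight_equilibrium(F_pre, F_post, F_T)` — the closed form above.  Its
  restored square root makes all derived expressions mutually consistent;
  the test suite cross-checks it against direct integration of the weight
  ODE at clamped rates (0.1% tolerance).
* `memory_bounds(theta, F_T)` — roots of
  $(1-F^T)F^2 - \tilde\theta^2 F + \tilde\theta^2 F^T = 0$: between them
  the intra-population weight stays below inhibition and no memory
  representation exists (band width
  $\tilde\theta\sqrt{D}/(1-F^T)$ with
  $D = \tilde\theta^2 - 4F^T(1-F^T)$).
* `separatrix(F_other, theta, F_T)` — the presynaptic rate at which a
  directed inter-population weight equals inhibition,
  $\tilde\theta^2(1 - F^T/F_{other})/(1-F^T)$.
* `find_fixed_points(input, params)` — all interior equilibria of the
  reduced activity equations for a folded input pair
  $(\mathfrak{I}_1, \mathfrak{I}_2)$, with stability and organization
  labels; `reachable_fixed_point` integrates the reduced dynamics from the
  simulation's initial rate level (0.07, 0.07) to select the attractor a
  simulation would reach in bistable regimes.

```{r}
find_fixed_points(c(0, 0), p)      # no inputs: the no-memory state
find_fixed_points(c(1, 1), p)      # strong inputs: an association
```

Two analytic measures organize the parameter plane:
$S = \tilde\theta^2 - 2F^T$ (sequences form when positive) and the
discriminant $D$ above (a no-memory band exists when positive), giving
three regimes with increasingly rich repertoires.  The
plasticity-dominated activity square $[2F^T, 1]^2$ has area
$(1-2F^T)^2$, which vanishes at the critical target rate $F^T = 0.5$.

Two structural results hold for *uniform* inhibition and are enforced as
property tests: the lower (scaling-branch) memory interval never reaches
the plasticity-dominated square, and no activity pair is ever classified
as a discrimination — with one inhibitory weight everywhere, the memory
condition and the discrimination condition are mathematically coupled.
Discrimination requires weaker inhibition inside the populations
($\tilde\theta_P < \tilde\theta$), which either can be imposed or emerges
from the gated inhibitory plasticity rule: each inhibitory synapse is
attracted to an up-state $\theta_u$ when the pre/post rate difference
exceeds a tolerance or their sum is below a threshold, and to a down-state
$\theta_d$ otherwise, gated multiplicatively by $\tilde F_i\tilde F_j$ and
inactive on exact-equality boundaries ($H(0) = 0$).

## Numerical choices

* **Fixed-point finder.** A 200×200 grid scan marks cells in which both
  residuals change sign, followed by a damped Newton polish
  (finite-difference Jacobian, step halving) to $10^{-12}$; duplicates are
  merged at $10^{-6}$.  Cells whose polish does not converge are reported
  as flagged candidates and never counted as equilibria — near
  saddle-node tangencies the two nullclines nearly coincide along an arc
  and would otherwise produce spurious "stable" points.  Stability comes
  from the eigenvalues of the numerical Jacobian of the reduced adiabatic
  dynamics.
* **Reachability integrator.** The reduced vector field is stiff on the
  scaling branch (equilibrium weights diverge as rates approach $F^T$), so
  forward integration uses per-component step control: the step is halved
  on a derivative sign flip and regrown slowly otherwise.
* **Ties and domains.** A weight exactly equal to its inhibitory reference
  counts as *not exceeding* it (tolerance $10^{-9}$).  Rates at or below
  $F^T$ are outside the model's domain (the weight ODE has no fixed point
  there) and raise errors rather than returning extrapolations.  Boundary
  roots of the activity equation at rates 0 and 1 are not reported as
  equilibria.
* **Bistable labeling.** A phase-diagram cell with two or more stable
  fixed points is labeled `bs` regardless of whether the individual labels
  coincide.
* **Scan boundaries.** In the inflexion-point scans, "high-activity
  collapse" is the last $n_\epsilon$ whose reachable rate is at least 0.5
  (half-maximal), and "memory loss" the last one whose reachable state is
  not `nm`.
* **Discrimination area.** `area_disc` reports the *fraction* of the
  admissible activity square $(F^T, 1)^2$ classified as discrimination
  (the natural dimensionless choice; the source material leaves the unit
  unstated).
* **Background folding.** When placing full-network runs on the reduced
  input plane, the background contribution can be folded either as printed
  ($I_p = \tilde F_p^{ex} w^{ex} + (n_B/n_P^{ex})\tilde F_B w_{pB}$,
  the default) or inhibition-corrected (subtracting $\tilde\theta$ from
  $w_{pB}$), selected by `background_inhibition_corrected`.  The corrected
  variant is the one consistent with the full-network drive algebra and is
  used when comparing reduced predictions against full simulations.

## Problem sizes and timescale acceleration

Because $\omega^{max}$ depends only on the ratio $\mu/\gamma$, multiplying
both plasticity rates by a common factor leaves every equilibrium quantity
unchanged and only contracts transients; a deterministic test verifies
this directly (factor 20 vs 50 agree to 2%).  The package's test and
reproduction runs use this property: full-network protocols run at
acceleration 10 (three seeds) for the headline association and
inhibitory-plasticity results, and at acceleration 25 for the 5×5-grid
comparison between full-network end states and reduced-model predictions.
These are the package's own choices of problem size; larger factors begin
to interact with the 1 ms Euler step on the fastest weight transients.

## Known limitations

* The inflexion-point integers quoted above depend on the drive-gain
  convention; the reconstruction here reproduces them to within ±1 and
  both conventions are retained, but the exact constant used to produce
  the original figures cannot be recovered from the printed material.
* The reduced framework treats the background population as a folded
  input, not as a third dynamical variable; agreement with the full
  network degrades near label boundaries (separatrices and memory
  bounds), where small rate differences flip the classification.
* Inhibitory plasticity is modeled as a gated attractor rule between two
  set points; it is not a mechanistic model of interneuron plasticity.
* Populations are non-overlapping and connectivity is all-to-all; spiking
  dynamics, STDP, and consolidation are out of scope.
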