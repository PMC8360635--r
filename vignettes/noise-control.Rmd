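---
title: "Noise suppression in bursty gene circuits with PID feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise suppression in bursty gene circuits with PID feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pidnoise)
```

## The model

Gene expression is modelled as a bursty birth-death Markov jump process. The
target protein Y is produced in *bursts*: burst events arrive at a Poisson
frequency and each event adds a random number of molecules $B_y \ge 1$ drawn
from a shifted geometric distribution with mean $\langle B_y\rangle$
(`burst_dist("shifted_geometric", m)`), the law observed for protein bursts in
*E. coli*; a deterministic burst size is also supported. Each molecule decays
independently at rate $\gamma_y$, so the open-loop stationary mean is
$\bar{y} = k_y \langle B_y\rangle / \gamma_y$.

Two further species enter:

* a **disturbance** X (its own bursty birth-death process) that multiplies the
  burst frequency of Y by $x(t)/\bar{x}$, modelling a fluctuating upstream
  environment;
* a **controller** Z that closes a feedback loop around Y. Three biochemical
  controller architectures are implemented:

| topology | Z reactions | Y burst frequency | gain |
|---|---|---|---|
| proportional | births $k_z y$ (bursts $B_z$), decay $\gamma_z z$ | $k_y\,g(z)\,x/\bar{x}$, $g(z) = 1/(1+(z/z_c)^h)$ | $f_p = h\,(1 - g(\bar z))$ |
| integral | births $k_z y/\langle B_z\rangle$ (bursts $B_z$), **zero-order** decay at constant propensity $k_z y_{set}$ | $k_y\,g(z)\,x/\bar{x}$ | $f_i = h\,(1 - g(\bar z))$ |
| derivative | as proportional | $k_y\,(x/\bar{x})\,(z/y)^h$ | $f_d = h\,\gamma_y/\gamma_z$ |

The integral controller's net drift in $z$ is $k_z(y - y_{set})$: a stochastic
integrator of the set-point error, which forces $\bar{y} = y_{set}$ exactly
(perfect adaptation). The derivative controller is an incoherent feedforward
loop — delayed activation by Z combined with instantaneous self-repression —
which differentiates the input on timescales slower than $1/\gamma_z$.

All protein counts are whole molecules; the simulator convention
$(z/\max(y,1))^h$ keeps the derivative propensity finite at $y = 0$, which is
invisible in the small-noise regime where the analysis applies.

## Three routes to the stationary noise

The package computes the stationary squared coefficient of variation
$CV^2_Y = \sigma^2_y/\bar{y}^2$ three independent ways, and the test suite
holds them against each other:

1. **Closed forms** (`cv2_open_loop()`, `cv2_proportional()`,
   `cv2_integral()`, `cv2_derivative()`): analytic decompositions of $CV^2_Y$
   into an *intrinsic* part (bursty expression of Y itself), an *external*
   part (transmitted disturbance), and a *controller* part (noise injected by
   the stochastic controller species), plus optimal-gain formulas
   (`optimal_gain_proportional()`, `optimal_gain_integral()`) and the
   burst-event noise floor (`noise_floor_burst_events()`).
2. **A linear noise approximation (LNA) moment solver**
   (`assemble_moment_system()`, `decompose_noise()`). The only approximation
   is the linearization of the Y burst frequency about the steady means; after
   it, every event rate is affine in the state, so the first- and second-order
   moment equations close *exactly* and are assembled term by term from the
   infinitesimal generator. The stationary moments solve the linear system
   $A\mu = -\hat a$ after a Hurwitz stability check.
3. **Exact stochastic simulation** (`ssa_simulate()`): a direct-method SSA of
   the full nonlinear jump process in C++, with no linearization. Identical
   `(circuit, t_end, seed)` give bit-identical trajectories; the RNG is R's
   own stream, used in a private scope.

### Noise decomposition by source silencing

`decompose_noise()` attributes the noise by re-solving the moment system with
sources silenced: (i) full system; (ii) disturbance frozen at $\bar{x}$;
(iii) additionally the controller's *jump variance* removed — both its birth
and death channels keep their mean drift but stop contributing second-moment
shot terms, so Z follows a deterministic flow conditioned on the state.
Because the stationary covariance is linear in the per-event jump-variance
sources, the differences (i)−(ii), (ii)−(iii) and (iii) are an exact additive
split into external, controller and intrinsic components.

### The autocatalytic integrator

The alternative integral design (`design = "autocatalytic"`: Z produced
autocatalytically and removed by Y at propensity $k_z z y$) is supported in
the moment solver and closed forms but is *analysis-only*: its linearization
is stable only when Z activates Y (the self-activating integrator inverts the
error sign), and the nonlinear jump process has an absorbing state at $z = 0$,
so naive simulation is not meaningful. `ssa_simulate()` refuses it.

## Worked example

```{r example}
ci <- fixture_circuit("fig3b")     # integral controller working point
solve_steady_means(ci)
decompose_noise(ci)                # LNA moment solver
cv2_integral(noise_inputs(ci))     # closed form; equal to ~1e-13
static_sensitivity(ci)             # 0: perfect adaptation
```

Gain sweeps reproduce the figure-level experiments as tables:

```{r sweep}
res <- run_sweep(sweep_config("fig3b", "gain", c(0.2, 0.5, 1, 2),
                              engines = c("formulas", "lna")))
res
```

And the simulation-versus-theory validation of the derivative controller:

```{r fig5, eval = FALSE}
reproduce_fig5(seed = 1)   # ~15 s: 6 gamma_z points x 12 SSA replicates
```

## Parameter choices and defaults

* **Burn-in**: `ssa_simulate()` defaults to no burn-in (raw trajectories);
  the validation helpers discard `10 / min(relaxation rates)` — ten times the
  slowest relaxation timescale among $\gamma_y$, $\gamma_x$ (if the
  disturbance is bursty) and $\gamma_z$ (if the sensor decays in first order;
  the zero-order integrator has no linear relaxation rate of its own).
* **Initialization**: simulations start at the rounded deterministic steady
  means (`init = "means"`), which shortens the transient; `init = "zeros"` is
  available for burn-in studies.
* **Estimators**: stationary means and $CV^2$ are *time-weighted* averages
  over the post-burn-in window, pooled across replicates. Standard errors come
  from a replicate-level jackknife of the pooled estimators, because states
  within a trajectory are time-correlated and i.i.d. errors would be invalid.
* **Gain sweeps** (`run_sweep()` with `variable = "gain"`): the gain is driven
  through the Hill coefficient $h$ at a fixed working point. The repression
  level $g(\bar z)$ — and with it all means and $CV^2$ inputs — is held at its
  base value by re-placing $z_c$ so that $(\bar z/z_c)^h$ stays constant. At
  the bundled working points with $\bar z = z_c$ the re-placement is the
  identity.
* **Validation runs** (`validate_against_lna()`, `reproduce_fig5()`): default
  8–12 replicates, horizons of a few hundred target lifetimes after burn-in,
  flagging at $|z| > 3$ standard errors. These run in seconds to a few tens of
  seconds on one CPU.

## Limitations

* The closed forms and the moment solver share the LNA premise of small
  fluctuations around a stable operating point; they degrade when $CV^2_Y$ is
  of order one, when the integral controller operates near the $z = 0$
  boundary (where the zero-order decay switches off), or when means are so
  small that discreteness matters.
* The static sensitivities are derivatives of the *deterministic* steady
  means; stochastic corrections to the means themselves are second order and
  neglected.
* Only shifted-geometric and deterministic burst laws, first-order (or
  zero-order, for the integrator) decays, and the three controller
  architectures above are implemented; Ornstein–Uhlenbeck disturbances,
  hybrid simulation, and parameter inference from trajectories are out of
  scope.
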