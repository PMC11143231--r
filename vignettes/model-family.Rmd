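---
title: "A family of single-gene autoinhibitory circuit models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A family of single-gene autoinhibitory circuit models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecircuit)
```

## The circuit and why description level matters

The package models a gene encoding a transcription factor (TF) that represses
its own transcription — the core negative-feedback motif of, for example, the
her/hes genes driving the vertebrate segmentation clock. All variants share
the same biology: transcription at rate $\alpha_m$ gated by a monotone
decreasing regulatory function $R(c)$, first-order degradation of transcript
($\gamma_m$) and protein ($\gamma$), and translation at rate $\alpha$. They
differ only in how many intermediate steps are resolved, and that choice alone
changes the predicted phenotype.

The two-variable instantaneous model (variant `"I"`),
$$\dot m = \alpha_m R(c) - \gamma_m m, \qquad \dot c = \alpha m - \gamma c,$$
can never oscillate: its vector-field divergence is $-\gamma_m - \gamma < 0$
everywhere, so the Bendixson–Dulac criterion excludes periodic orbits
regardless of how nonlinear $R$ is. Variant `"II"` adds an open-DNA state and
a translation-initiation complex (effective elongation rates $\beta_1,
\beta_2$); the extra phase lag turns the steady state into a spiral, but with
a Hill regulatory function of exponent $n_H$ and all four linear rates equal,
a Hopf bifurcation requires $n_H$ to exceed the secant bound
$\sec(\pi/4)^4 = 4$ — biologically implausible for three binding sites.
Resolving elongation step by step (variant `"chain"`, $N$ transcript and $M$
peptide stages at rates $r_1, r_2$) and letting the stage count grow at fixed
mean delay leads to discrete lags $\tau_N = N/r_1$, $\tau_M = M/r_2$ (variant
`"III"`), which sustain oscillations at $n_H = 2$.

The bridge between chains and delays is the linear chain trick: a chain of
$k$ identical first-order stages of rate $r$ is exactly equivalent to a
distributed delay with the Erlang (Gamma) kernel
$$K(\tau) = \frac{r^k \tau^{k-1} e^{-r\tau}}{(k-1)!},$$
mean $k/r$ and variance $k/r^2$. Shape 1 is the *weak* kernel, shape 2 the
*strong* kernel, and the discrete lag is the $k \to \infty$ limit at fixed
mean. `expand_chain()` performs the expansion; it is a rewriting, not an
approximation, and the tests hold it to a $10^{-4}$ sup-norm against direct
quadrature of the integro-differential form. (Note one convention choice: we
use the normalized Erlang density of shape $k$ — the form under which $k$
first-order stages reduce exactly and the mean is $k/r$ — rather than a
density with an extra factor of $\tau$, which would not integrate to one.)

## Explicit promoter kinetics and the two cooperativity mechanisms

The second axis of the package replaces the phenomenological $R(c)$ with
mass-action kinetics of a cis-regulatory system (CRS) of three identical
binding sites; transcription proceeds only from the empty state $a_0$.
Cooperativity of intensity $\epsilon \ge 1$ can enter two ways:

* **Recruitment (RM)** — bound TFs help the next one bind:
  $k_{i,i+1} = \epsilon^i (3-i) p$, $k_{i+1,i} = (i+1) q$;
* **Stabilization (SM)** — bound TFs hold each other on the DNA:
  $k_{i,i+1} = (3-i) p$, $k_{i+1,i} = (i+1) q / \epsilon^i$.

Both give the same equilibrium constants $K_1 = 3p/q$, $K_2 = \epsilon p/q$,
$K_3 = \epsilon^2 p/(3q)$, hence the same quasi-steady-state regulatory
function — the Adair equation
$$R^{qss}(c) = \left(1 + cK_1 + c^2 K_1 K_2 + c^3 K_1 K_2 K_3\right)^{-1}$$
— and the same fixed point. Dose-response data therefore cannot distinguish
them. The dynamical models can: variants `"IV_full"`/`"IV"`/`"V"` carry the
promoter explicitly, and `"DDE_CRS"` couples it to the rescaled transcript
$m' = (\alpha/\gamma)m$ through a delay kernel. With a discrete lag, slow
promoter kinetics make the recruitment circuit oscillate while the
stabilization circuit spirals back to rest, and where both oscillate the
recruitment circuit is faster — a phenotype difference invisible to any
Hill-function model.

`effective_hill()` maps an Adair curve to the phenomenological pair
$(K_d, n_H)$. $K_d$ is the half-repression point, the unique root of
$R^{qss}(c) = 1/2$, found by bracketed bisection (bracket doubled upward from
$1/K_1$; absolute tolerance $10^{-10}$ molecules — the function is monotone,
so the root is unique). The curve has no single Hill exponent, so an
estimator must be chosen: we use the magnitude of the Hill-plot slope
$-\mathrm{d}\log[R/(1-R)]/\mathrm{d}\log c$ *at the half-repression point*,
which is constant and equal to $n_H$ for a true Hill function and available
in closed form for the Adair curve. It reproduces the three reference
parameterizations — $(p, q, \epsilon) = (0.1, 31.3, 5.5) \to (40, 1.96)$,
$(0.1, 43, 8.5) \to (40.1, 2.21)$, $(0.1, 6.26, 5.5) \to (8, 1.96)$ — and is
bounded by the site count, $1 \le n_H^{eff} \le 3$. Anti-cooperativity
($\epsilon < 1$) is rejected rather than extrapolated.

## Parameters, units, defaults

All rates are per minute, concentrations in molecules. The scenario registry
(`scenario_registry()`) stores the reference regimes with provenance strings;
the main ones:

| scenario | key values | role |
|---|---|---|
| `fig2_*` | $\alpha_m = 33$, $\gamma_m = \gamma = 0.23$, $\alpha = 4.5$, Hill $K_d = 40$, $n_H = 2$ | description-level comparison |
| `fig5_*` | $p = 0.246$, $q = 30$, $\epsilon = 10$, $\gamma = 4.6$ | kernel-order comparison |
| `fig6_a/b/c` | $f = 0.03/0.06/0.09$: $p = 0.1f$, $q = 43f$, $\epsilon = 8.5$, $\tau = 3.5$ | CRS kinetic-scale scan |
| `fig7_a/b` | $f = 1.5$, $\tau = 3.5/5.5$ | fast-kinetics limit |

The kinetic scale factor $f$ moves the binding/unbinding rates without
touching the regulatory curve (only ratios enter $R^{qss}$); the TF residence
time is $q^{-1} = 60/(43f)$ seconds, spanning 46.5 s to 15.5 s across the
scan — inside the 2–100 s range reported for specific TF-DNA residence by
single-molecule tracking, which is also the sampling range of the synthetic
fixture generator `sample_crs_params()`.

Three registry values are package choices where the source regime leaves them
open, each marked "assumed" in its provenance string:

* **Elongation lags for `fig2_II`/`fig2_III`** ($\tau_N = 20.8$,
  $\tau_M = 2.8$ min; initiation rates $r_1 = r_2 = 10$/min, so the
  initiation stages are fast relative to the lags). With these the three
  description levels reproduce the expected phenotype triple: convergence,
  damped spiral (leading pair $-0.053 \pm 0.117i$), sustained ~69-min
  oscillation.
* **$\gamma$ for the kinetic-scale scan** (`fig6_*`, `fig7_*`): the source
  states only that synthesis/degradation rates are "similar to" the
  description-level regime. We take $\gamma = 0.23$/min; this reproduces
  every ordering (RM oscillates at $f = 0.03$ while SM damps; SM's threshold
  falls at $f \approx 0.083$, inside $(0.06, 0.09]$; RM is the faster
  oscillator at $f = 0.09$; frequency rises with $f$). The alternative
  $\gamma = 4.6$/min suppresses all of these oscillations, so it cannot be
  the intended regime; it remains available through
  `run_scenario(..., overrides = list(gamma = 4.6))` for sensitivity work.
* **The discrete lag of `fig5_discrete`** ($\tau = 3.5$ min). Under the
  `fig5` rates ($\gamma = 4.6$) this gives a slowly *damped* oscillation;
  sustained oscillation in that regime requires $\tau \gtrsim 4.5$ min. We
  keep the stated 3.5-min default rather than tune it; no headline result
  depends on this panel sustaining.

For the strong kernel the registry keeps the per-stage rate at $\gamma$
(mean $2/\gamma$ — "one more identical process"); a mean-preserving variant
(rate $2\gamma$) is selectable because the convention is genuinely open.

## Numerical choices

* **Integration** is delegated to deSolve: `ode()` (default `lsoda`, which
  switches itself to an implicit method under stiffness) for ordinary
  variants, `dede()` — the method of steps with continuous interpolation of
  the stored solution — for discrete lags. Histories default to constant
  continuation of the initial state. Default tolerances `atol = 1e-10`,
  `rtol = 1e-8`; the analytic oracle $\dot x = -x(t-\pi/2)$ with cosine
  history is reproduced to ~$10^{-12}$. Erlang kernels are always integrated
  through their exact chain expansion. A zero lag degenerates to the plain
  initial-value solve.
* **Non-negativity** is not enforced by clipping; a post-hoc check treats any
  excursion below $-10^{-8}$ as an integration failure.
* **Fixed points** come from bracketed bisection of the scalar balance
  $c = A\,R(c)$ (unique root by monotonicity); the promoter occupancies
  follow from detailed balance.
* **Characteristic roots.** Delay-free variants use Jacobian eigenvalues
  (analytic Jacobians, validated against central differences). Discrete-delay
  variants get damped Newton iteration on
  $\chi(\lambda) = \det(\lambda I - A - \sum_j B_j e^{-\lambda\tau_j})$ from
  a seed grid over $\mathrm{Re} \in [-20, 5]$, $\mathrm{Im} \in [0, 60]$
  per minute (periods down to ~6 s), deduplicated at $10^{-6}$; conjugates
  follow by symmetry. A root pair with $|\mathrm{Im}| > 10^{-8}$ counts as a
  spiral; $|\mathrm{Re}| < 10^{-7}$ is marginal and defers to simulation.
  `classify()` always offers a trajectory cross-check, and a disagreement
  between the root-based and simulation-based views is reported as
  `inconclusive`, never resolved silently. `hopf_scan()` bisects the leading
  real part, warm-starting Newton from the roots found at the bracket
  endpoints so only the endpoints pay for a full grid.
* **Oscillation metrics.** `summarize_oscillation()` discards the first half
  of the span (default), finds peaks as discrete local maxima with quadratic
  refinement and a prominence floor of $10^{-6}$ of the signal range, and
  requires at least four peaks. Sustainedness uses the per-cycle geometric
  amplitude ratio with band $\delta = 0.02$, which cleanly separates the
  damped and sustained members of the kinetic-scale scan at the default
  integration settings. The estimator is unbiased to <0.5% on synthetic
  sinusoids with periods 5–100 min.

## What the synthetic fixtures do and do not show

`sample_crs_params()` draws $(p, q, \epsilon)$ log-uniformly over
biologically anchored ranges (residence time 2–100 s, $p \in [0.001, 1]$/min,
$\epsilon \in [1, 20]$), alternating mechanisms, reproducibly per seed;
`perturbed_initials()` multiplies a fixed point componentwise by
$1 + \mathrm{U}(-a, a)$ (renormalizing the occupancy block of the full
promoter model so the conserved total stays 1). These fixtures exercise every
code path without external data, but they are parameter draws for a
deterministic model family: passing tests demonstrates correctness of the
mathematics, not that any real promoter follows three-site mass action with
identical sites, and the models deliberately exclude intrinsic noise,
multi-gene coupling, space, and non-identical binding sites.

Problem sizes used by the test suite are desk-scale by design: trajectories
of $10^4$–$4\times10^4$ points, a 200-point Latin-hypercube stability sample
for the reduced promoter model (the claim was originally checked over a much
denser sample; 200 points keep the default suite quick while still covering
the ranges), and Erlang shapes up to 64 for the discrete-limit check.

## Known limitations

* The symbolic (Routh–Hurwitz-style) stability analysis of the explicit-CRS
  models is replaced by numeric verification; a symbolic layer could be added
  on top of `linearize()`.
* The DDE solver relies on deSolve's interpolation accuracy rather than
  explicit discontinuity tracking; for the smooth histories used here that
  is ample, but propagated derivative breaks from non-smooth histories are
  not tracked.
* `rightmost_roots()` is a seeded local search: it can in principle miss a
  root between seeds, which is why classifications are cross-checked by
  simulation.
* State-dependent delays and stochastic (chemical-master-equation) versions
  are out of scope.
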