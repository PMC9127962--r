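---
title: "Models and methods behind genecircuit"
author: "genecircuit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind genecircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecircuit)
```

## The abstraction

`genecircuit` models a synthetic genetic network as a set of **operators**
wired to **gene products**. A gene product $p_i$ is an expressed molecular
species — a *regulator* if it feeds operator inputs, a *reporter* if it is
measured (a fluorescence-like signal). An operator is the abstraction of a
promoter together with its upstream elements and RBS: it maps the
concentration of zero, one or two inputs to the synthesis rate of its
output products. Collecting the products into a vector $p$ the network
dynamics are

$$\frac{dp}{dt} = \Psi(r) - (\Gamma + \mu(t) I)\,p ,$$

where $\Psi$ is the sum of the operators' transfer functions $\Phi_k$
evaluated on the regulator sub-vector $r$, $\Gamma$ the diagonal matrix of
first-order degradation rates $\gamma_i$ (1/h), and $\mu(t)$ the
instantaneous growth rate, which dilutes every product equally.

Four operator kinds are implemented:

* **source** — constitutive, constant rate $\alpha$;
* **hill1** — one regulator input,
  $\phi(r) = \dfrac{\alpha_0 + \alpha_1 (r/K)^n}{1 + (r/K)^n}$, with
  non-regulated rate $\alpha_0$, regulated rate $\alpha_1$, switching
  concentration $K$ and cooperativity $n$;
* **receiver** — the same form, but the input is an external chemical
  *supplement* (e.g. an acyl-homoserine lactone) fixed by the assay
  conditions rather than a network species;
* **hill2** — two promoters in tandem, with $x_j = (r_j/K_j)^{n_j}$,
  $\phi(r_1, r_2) = \dfrac{\alpha_0 + \alpha_1 x_1 + \alpha_2 x_2 +
  \alpha_3 x_1 x_2}{1 + x_1 + x_2 + x_1 x_2}$.

The product-form denominator of the two-input operator is our reading of
the two-promoters-in-tandem picture: the two binding events are
independent, and $\alpha_3$ alone captures the jointly regulated rate.
Parameter orderings induce discrete logic labels (`classify_logic()`):
$\alpha_0 > \alpha_1$ is a NOT gate, $\alpha_0 < \alpha_1$ a buffer, and
$\alpha_0 > \alpha_1, \alpha_2, \alpha_3$ a NOR gate. Exact ties are
labelled `OTHER`: the defining inequalities are strict, and we prefer an
explicit "undecided" to an arbitrary side.

Two representational limits are enforced rather than worked around: no
operator may have more than two inputs, and all outputs of one operator
are expressed at the same rate. Concentrations are unitless
"molecules-per-cell equivalents"; no fluorescence calibration (e.g. MEFL)
is attempted.

## Growth and dilution

A `growth_profile` supplies biomass $B(t)$ and
$\mu(t) = d\ln B/dt$ in closed form: constant (exponential), logistic and
Gompertz kinds cover the batch-culture curves typical of plate-reader
assays. $\mu$ is derived analytically from $B$, never numerically, so ODE
right-hand sides stay smooth. Supplements are held at fixed external
concentrations — they are assay conditions, not dynamic species — and are
neither diluted nor consumed.

## Simulation

`simulate_ode()` integrates the network ODEs with `deSolve::ode` (lsoda)
at relative tolerance $10^{-8}$; undershoots below zero smaller than
$10^{-12}$ are clipped to exactly zero. `simulate_ssa()` runs the
Gillespie direct method over synthesis reactions $* \to p_i$ with
propensity $a_i = \sum_k \Phi_{k,i}(r)$ and extinction reactions
$p_i \to *$ with propensity $b_i = (\gamma_i + \mu(t))\,p_i$. All
propensities are recomputed after every event; $\mu(t)$ is evaluated at
the current time and frozen until the next event. This quasi-static
treatment of growth is an approximation, justified because the growth
timescale (hours) is far slower than the inter-event time at the copy
numbers we simulate; growth itself is deterministic in both methods. The
SSA core is compiled (Rcpp) and draws from R's RNG, so a fixed seed gives
a bit-identical event list. ODE and SSA share parameter values directly —
concentrations are read as molecules per cell, with no volume conversion.

An `assay()` wraps samples (network + growth + supplements), a duration
and a measurement interval, and `run_assay()` emits a tidy table
(`assay, sample, signal, time, value`) with one row per reporter signal
per timepoint plus a `biomass` signal — the same shape the datastore
stores and the characterization workflow queries back.

## The oscillator fixture

`network_oscillator()` follows a positive-plus-negative feedback
topology: a two-input operator activated by its own product A and
repressed by C, and two activated one-input operators relaying
A → B → C; each operator also expresses a fluorescent reporter. No
published parameter set accompanies this topology at our abstraction
level, so the fixture's parameters are the package's own choice, made
once: strong self-activation ($\alpha_1 = 30$, $n_1 = 4$) with weak basal
expression ($\alpha_0 = 1.2$) so the off state is unstable when C is low,
near-complete repression by C ($\alpha_2 = \alpha_3 = 0.05$, $n_2 = 4$),
a fast A ($\gamma = 2$/h) against a slow relay
($\gamma_B = \gamma_C = 0.3$/h) to provide the delay, and zero dilution.
This yields a stable limit cycle of period ≈ 13.3 h; initial conditions
are placed on the cycle so amplitude is stationary from the start. Tests
assert oscillation properties (sustained amplitude, period stability
against a 10×-tighter-tolerance reference integration), not specific
amplitudes, which are a consequence of this parameter choice rather than
a claim about any organism.

## Characterization

The fitting workflow runs from data to parameters in stages. Degradation
rates $\gamma$ are treated as known inputs (separately measured or taken
from literature), not co-fitted: at quasi-steady state $\alpha$ and
$\gamma$ only appear through their ratio, so co-fitting is degenerate.

1. **Sources** (`fit_source()`): the model
   $dp/dt = \alpha - (\gamma + \mu(t))p$ is linear in $\alpha$, so the
   least-squares estimate is closed-form (clipped at 0).
2. **Receivers** (`fit_receiver()`): dose-response assays of
   supplement → receiver → reporter circuits over a concentration range;
   $(\alpha_0, \alpha_1, K, n)$ are fitted jointly to the trajectories
   of all concentrations.
3. **Downstream operators** (`fit_hill1()`, `fit_hill2()`): the cascade
   receiver(s) → regulator(s) → operator → reporter is simulated with
   the receiver parameters held fixed and only the downstream
   parameters fitted. Characterizing a two-input operator therefore
   takes three auxiliary networks: the two receiver circuits and the
   composed circuit.

The objective is trajectory-level nonlinear least squares against the
full kinetic solution — not a steady-state shortcut — because kinetic
time courses are what assays produce, and trajectory fitting uses all of
them. The optimizer is bounded Levenberg–Marquardt (`minpack.lm`) with
rates and $K$ log-parametrized, 10 random restarts (the first start is a
deterministic data-driven guess; $K$ starts log-uniform over the tested
concentration range, $n$ in $[1, 4]$) and a fixed default seed (42).

Model trajectories during fitting are evaluated by an integrating-factor
formulation rather than a generic ODE solver: every species in the
characterization circuits obeys a linear ODE
$dp/dt = f(t) - (\gamma + \mu(t))p$, whose exact solution is
$p(t) = \big(p(0) + \int_0^t f\,w\,d\tau\big)/w(t)$ with
$w(t) = e^{\gamma t} B(t)/B(0)$ — the dilution integral is analytic
because $\mu = d\ln B/dt$. The remaining quadrature uses composite
Simpson with 20 substeps per observation interval (midpoint-refined for
the regulator stages), vectorised over all dose conditions; against the
lsoda reference this agrees to well below the fit tolerances and makes
multi-start fitting of an 8×8 concentration grid a matter of seconds.

**Identifiability** is reported per parameter, two ways combined: a
response-spread heuristic ($K$ and $n$ are flagged when the response
spread across concentrations is below 5% of its mean — a flat dose
response cannot place a threshold), and profile-likelihood-style probes
(refits started from each parameter perturbed ±50%; a parameter that
moves >20% while reproducing the optimal SSE within 1% is flagged).

When no parametric growth profile is passed, the biomass channel is used
to reconstruct one (`fit_growth()`): a log-linear constant-rate fit and a
logistic fit are both tried and the better residual wins.

`characterize()` is the single-call entry point: it queries a local
datastore by selectors (study/assay/vector/signal/media/strain/
supplement), assembles the dose-response dataset from the stored sample
supplement metadata — replicate assays combine as separate residual
blocks, so all available data contribute — and dispatches to the right
fit.

## Datastore and exporters

The datastore is a directory: `manifest.json` (studies → assays →
samples with vector/strain/media/supplement metadata, plus a signal
registry) and one measurement CSV per assay, written with 17 significant
digits so values round-trip bit-exactly. It is deliberately desk-scale,
inspectable and diffable; the selector vocabulary mirrors web-based
measurement databases so a remote backend could replace it behind the
same queries. Matching is exact (no partial names), and re-uploading an
assay replaces it with a warning.

`to_graph()` renders operators and products as a directed igraph
(production edges operator → product; regulation edges
regulator → operator, signed activation/repression from the parameter
ordering), serializable as GraphML or DOT; `operators_only = TRUE`
contracts products away for the compact network view. `to_sbol()` builds
a hierarchical SBOL3-style design document — transcriptional-unit
components of type DNA with role engineered region, part subcomponents
kept in order by precedes constraints (placeholder parts when no
sequences are given), genetic-production interactions per output,
inhibition/stimulation interactions per regulator (direction from the
parameter ordering; ties warn and default to stimulation), and one model
reference with source, language and framework. The document is rendered
as structured JSON with exactly this shape; an RDF serializer could be
attached to the same structure. Design save/load uses a versioned JSON
format that reproduces the network object exactly.

## Numerical choices and degenerate inputs

* ODE tolerances: rtol $10^{-8}$, atol $10^{-10}$; fitting quadrature:
  Simpson, 20 substeps/interval.
* Hill evaluation caps $(r/K)^n$ at $10^{12}$ inside the fitting path to
  avoid overflow; the public `hill1_rate()`/`hill2_rate()` return exact
  saturation limits instead.
* Dose-response designs need ≥ 4 distinct concentrations per axis and
  ≥ 5 timepoints; fewer is an explicit insufficient-design error.
* An all-zero source series returns $\alpha = 0$ with the rate flagged
  non-identifiable.
* Equal $\alpha_0 = \alpha_1$: logic `OTHER`; exporters warn and default
  the interaction to stimulation.

## Problem sizes used in tests

The test-suite and the acceptance script use: 20 random draws for the
steady-state check; 1000 SSA runs for the pure-death and Poisson law
checks; a 500-run ensemble of a source/NOT cascade at copy numbers
around 1000 against the ODE mean; a 120 h oscillator integration on a
0.05 h grid; 8-concentration receiver assays and an 8×8 two-input grid
(17 timepoints each) for the staged recovery. These sizes were chosen so
every stochastic check has comfortable statistical power while the whole
suite runs in well under a minute per component.

## What the synthetic data do and do not show

All characterization tests run on data the package itself generated
(plus, for the stochastic tests, exact distributional laws as oracles).
That demonstrates correctness of the fitting machinery — the estimator
recovers the generator — but not robustness to everything real
plate-reader data contain: autofluorescence backgrounds, calibration
drift, mRNA dynamics, resource competition between circuit and host, or
context effects between adjacent parts. Those phenomena are outside the
model class by design (the abstraction is one-step synthesis with shared
dilution), so passing tests certify the software and the inference
procedure, not the adequacy of the model for any particular biological
dataset. Stochastic-model parametrization and Bayesian uncertainty are
likewise out of scope; the identifiability flags are a frequentist
screen, not a posterior.
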