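---
title: "Modelling infection fate with post-entry failure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling infection fate with post-entry failure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virofate)
```

## The model

`virofate` studies the fate — extinction versus establishment — of a
within-host virus infection seeded by a small number of infectious virions
(`V0`) or infectious cells (`I0`) in a well-mixed population of `N_cells`
susceptible target cells in volume `s`.

Free infectious virions `V` are lost in two ways: infectivity decay at rate
`c`, and irreversible commitment to cell entry at rate `beta * T / s`
(entry is treated as the point of no return, after the reversible
attach/detach kinetics). The distinctive ingredient is the probability
`gamma` in (0, 1] that an entry actually yields a productive infection:
endosomal fusion failure, nuclear-import failure, lethal replication errors
and semi-infectious (entry-competent but replication-defective) particles
all make `gamma < 1` biologically plausible. A failed entry consumes the
virion but leaves the cell susceptible.

Newly infected cells traverse an eclipse phase and then an infectious phase
during which they produce virions at rate `p`. Both phase durations are
Erlang distributed — a chain of `n_E` (resp. `n_I`) exponential
sub-compartments with total mean `tau_E` (resp. `tau_I`) — which spans
exponential (`n = 1`), log-normal-like (`n ~ 2-7`) and normal-like
(`n >~ 10`) duration distributions with a single integer knob. The
mean-field limit is the ordinary differential equation system implemented
in `mfm_derivatives()` / `solve_mfm()`; the stochastic model advances
integer occupancies with per-step random event counts (below).

Three derived quantities organise everything:

* the **per-virion infection probability**
  `P_VI = gamma / (1 + c/(beta*N_cells/s))` — the outcome of the race
  between decay and (successful) entry;
* the **burst size** law: Poisson production over an Erlang lifespan
  marginalises to a negative binomial with mean `B = p * tau_I` and shape
  `n_I` (geometric when `n_I = 1`, Poisson as `n_I -> Inf`);
* the **basic reproduction number** `R0 = B * P_VI`.

The extinction probability from one virion is the smallest root in [0, 1)
of the branching-process fixed point

```
P = (1 - P_VI) + P_VI * [B (1 - P)/n_I + 1]^(-n_I),
```

computed by `extinction_prob_single_virion()`; an inoculum multiplies
independent lineage probabilities (`extinction_prob_inoculum()`). The final
size of established infections follows a Lambert-W relation
(`fraction_consumed()`) governed by the critical uninfected fraction
`T*/N_cells = [c/(beta*N_cells/s)] / (gamma*p*tau_I - 1)`, the fraction of
cells still uninfected when the running reproduction number `R(t)`
(`reproductive_number_at()`) crosses 1.

Antivirals are modelled as multiplying exactly one of `beta`, `p`, `gamma`
by `(1 - efficacy)` (`apply_antiviral()`). Because `gamma` appears only in
the numerator of `P_VI` while `beta` appears in numerator and denominator,
and because `gamma` also scales the establishment probability linearly at
fixed `R0` (the identity `establishment_gamma(eps) = (1 - eps) *
establishment_p(eps)` for a single-virion inoculum), a post-entry antiviral
is always at least as effective as the other two modes — a property the
test suite asserts on randomized parameter grids.

## The stochastic simulator

The simulator is a tau-leaping scheme with bounded draws, so populations
can never go negative. Each step:

1. `dt = P_events / max(beta*T/s, c, n_E/tau_E, n_I/tau_I)` — the most
   likely single event has probability `P_events` (default 0.05);
2. compartment exits are `Binomial(E_i, dt*n_E/tau_E)` and
   `Binomial(I_j, dt*n_I/tau_I)`; production is
   `Poisson(dt * p * sum(I))`; free virions split by a trinomial into
   decayed / entered / persisting, realized exactly as
   `V_decay ~ Binomial(V, p1)` then
   `V_enter ~ Binomial(V - V_decay, p2/(1 - p1))`;
3. entries are thinned to successes with probability `gamma`, and the
   number of *distinct* cells infected is counted by placing the successes
   uniformly with replacement among the `T` cells — two successful virions
   in one cell make one infection, the exact rule rather than the common
   `N_inf = V_suc` approximation.

A run ends when no event can ever fire again (`V = 0` and all infected
compartments empty); a safety horizon (default `1e4` h) flags rather than
silently truncates runaway runs. The hot loop is compiled; a pure-R engine
(`advance()` and friends) makes the identical sequence of RNG draws, so the
two engines are bit-identical from the same seed — the test suite uses this
as an end-to-end check of the compiled kernel. Ensembles derive one child
seed per run from the master seed by a fixed linear-congruential mix, so
results are reproducible and order-independent.

`sample_burst_size()` shortcuts the per-cell lifetime: residence in each
infectious sub-compartment lasts `1 + Geometric(p_I)` steps (the exact law
of repeated Bernoulli exit draws) and production over the total step count
is a single Poisson draw. This is distributionally identical to stepping
the cell while keeping the finite-`dt` discretization that validation
targets.

## Numerical choices

* **Extinction root**: bracketed search on `[0, 1 - 1e-9]` (the trivial
  fixed point at exactly 1 always satisfies the relation, so the bracket
  must exclude it), then Newton polishing to residual `<= 1e-13`; certain
  extinction (`R0 <= 1`) is returned without solving. The same bracketing
  is used for the alternative burst laws in `extinction_prob_burst()`.
* **Series truncation**: test oracles that sum the negative binomial burst
  law directly truncate at cumulative mass `1 - 1e-12`.
* **Lambert W**: `pracma`'s principal-branch implementation behind a
  validated wrapper (`lambert_w0()`) with a residual contract of `1e-12`
  and domain checking at `-1/e`.
* **Kronecker-delta burst law with non-integer mean**: the generating
  function is extended continuously as `G(P) = P^B`; published examples
  use integer `B`.
* **Critical efficacies**: closed form `1 - 1/R0` for the `p` and `gamma`
  modes; one-dimensional root solve for the `beta` mode. `epsilon_50()`
  bisects to `|delta eps| <= 1e-8`. Published whole-percent efficacies are
  rounded; where a condition is stated exactly (e.g. "efficacy such that
  `T*/N = 0.5`"), `efficacy_for_critical_fraction()` solves it exactly and
  the package uses the exact condition.
* **Mean-field integration**: `deSolve::lsoda` with `rtol = 1e-8`,
  `atol = 1e-10`; "infinite time" means integrating in chunks until
  `V < 1e-6` and the infected cell mass is `< 1e-6`.
* **State ordering**: `[T, E_1..E_nE, I_1..I_nI, V]` everywhere.

## Classifying extinction versus establishment

Two classification rules exist and they are *not* equivalent near
criticality:

* the **absolute threshold**: established iff more than 0.01% of cells are
  consumed (default of `classify_outcome()`, `threshold_frac = 1e-4`);
* the **gap rule**: cut at the midpoint between the extinct cluster (near
  zero) and the established cluster (near the Lambert-W final size),
  i.e. `threshold_frac = fraction_consumed(params)/2`.

Without antivirals the two agree, because a lineage that survives its first
few generations almost surely establishes. Under an antiviral that pushes
`R0` toward 1, however, the subcritical tail fattens: lineages can infect
tens to thousands of cells and still die out. At the setting with
`T*/N = 0.5` the probability that a single-virion infection infects at most
4 cells is 0.815 (computable in closed form from the total-progeny law of
the branching process), while the extinction probability proper is 0.848 —
the 0.01% threshold misattributes about 3% of runs. Statistics that are
compared against the branching-process extinction probability therefore use
the gap rule (as `reproduce_tables()` does); the absolute threshold remains
the default for single-run classification, where it matches the biological
question "did this infection consume a meaningful number of cells".

## What the simulator emulates — and what it does not

The generator's defaults are the published within-host SARS-CoV-2
conditions (`sars2_baseline_params()`): `p = 11.2/24` IV/cell/h,
`c = 10/24` /h, `tau_E = 24/5` h, `tau_I = 24/0.595` h, `N_cells = 4e4`,
`s = 1` mL, `n_E = n_I = 1`, `gamma = 1`, and `beta` fixed from
`R0 = 7.69`, giving a burst size of 18.8 IV/cell and `P_VI = 0.409`.

The model assumes a well-mixed, cell-free-transmission system with a fixed
target-cell pool: no immune response, no cell regeneration, no spatial
structure, no co-infection or superinfection (virions cannot enter
already-infected cells), no defective-interfering particles, and no
rescue/complementation between semi-infectious particles. Antivirals have
constant efficacy (no pharmacokinetics, no concentration-efficacy curve,
no cytotoxicity) and act on one parameter at a time. Passing tests
therefore demonstrate internal consistency between the stochastic rules,
the branching-process analytics and the mean-field equations under these
idealisations — not that any of these idealisations hold for a particular
real infection.

## Problem sizes and tolerances used in the checks

The package's own validation runs at desk scale: stochastic ensembles of
10^4 runs (binomial standard error ~0.0036 on an extinction probability of
0.85), burst and virion-fate samplers at 10^5 draws, chi-square goodness of
fit accepted at p > 0.001, ensemble frequencies compared within 3 binomial
standard errors, and analytic identities at 1e-10 or tighter. The
established-run median is compared through a bootstrap 95% confidence
interval of the sample median. These sizes make the whole suite run in
about a minute while keeping every comparison statistically sharp enough to
catch the failure modes we care about (wrong rates, wrong burst law, wrong
root, biased classification).

## Known limitations

* Near the critical efficacy the establishment probability is tiny and the
  extinct/established clusters merge; gap classification (and any
  classification) loses meaning there, which is itself one of the
  scientific points the package illustrates.
* `fraction_consumed()` interprets the mean-field final size as the median
  of established stochastic runs; the correspondence is excellent away from
  criticality (absolute error ~1e-4 at the published settings) but is an
  approximation, not a theorem.
* The expected-value stepper (`solve_expected_value()`) is not an exact
  mean of the stochastic model — moments beyond the first are closed by
  substitution — and tracks the differential equations to about 1% at
  `P_events = 0.05`.
* Efficacies quoted in whole percent are reproduced within +-1 percentage
  point; one published table entry (entry-rate mode, 10-virion inoculum,
  exponential infectious phase) is quoted there from earlier literature and
  differs by about half a point from direct evaluation of the model's own
  formulas, so it is not asserted.
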