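---
title: "Fluctuation theorems for driven Markov chains: model, conventions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation theorems for driven Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaintherm)
```

## The model

`chaintherm` treats nonequilibrium thermodynamics as a statement about
finite, discrete-time, inhomogeneous Markov chains and nothing else. A
driven chain is a tuple `(S, p0, M1..MN, β)`: a finite state set, an initial
distribution, one column-stochastic transition matrix per step, and an
inverse temperature. No external energy function is presupposed — energies
are *derived* from the chain. Each step has a reference distribution: `p0`
at step 0, and for `n ≥ 1` the stationary distribution `pn` of `Mn`, which
is unique and strictly positive whenever `Mn` is irreducible. Writing
`pn(x) = e^{−βEn(x)} / Zn` defines the step energies up to a shared additive
constant per step (the *gauge* `cn`), the partition functions `Zn`, and the
free energies `Fn = −(1/β) log Zn`.

Work and heat then split the energy change of a realization
`x = (x0, ..., xN)` into the part caused by the *environment switching the
energy function underneath the system* and the part caused by the *system
moving*:

$$W(x) = \sum_{n=0}^{N-1} E_{n+1}(x_n) - E_n(x_n), \qquad
  Q(x) = \sum_{n=1}^{N} E_n(x_n) - E_n(x_{n-1}),$$

so `W + Q = E_N(x_N) − E_0(x_0)` holds term by term (the first law — tested
to `1e-12` on full enumerations). Under a gauge change `W` shifts by exactly
`c_N − c_0`, `ΔF` shifts by the same amount, and `Q` and the dissipated work
`W_d = W − ΔF` are invariant. This symmetric definition of work — the same
formula applied to a process and to its reversal — is the package's central
convention; the more common physics conventions make the forward and
backward definitions differ at the boundary steps, which is exactly what the
work-reversal identity below keeps track of.

### Matrix orientation

Entry `(x, y)` of `Mn` is `P(X_n = x | X_{n-1} = y)`: columns index the
source state and sum to one. This keeps every formula in the package
literally parallel to the probabilistic definitions; readers of the JSON
formats who prefer row-stochastic matrices can declare
`"convention": "from_to"` and the reader transposes on load.

## Reversal

Two backward objects matter, and they coincide exactly when they should:

* the **time reversal**: start at `pN`, apply `MN, ..., M1`;
* the **auxiliary reversed chain**: start at `pN`, with matrices
  `M̂_{n+1}(x,y) = p_{N−n}(x)/p_{N−n}(y) · M_{N−n}(y,x)`. Column sums are 1
  *because* each `p_n` is stationary for `M_n`; the constructor re-verifies
  this at `1e-12` rather than trusting the algebra against solver error.

The auxiliary chain is the object that makes the fluctuation identities
unconditional: for every trajectory,
`P(X = x) = P(Y = x^R) e^{β(W(x) − ΔF)}`, with a conditional variant in
which heat replaces work. The two backward objects coincide entrywise — and
the chain is *microscopically reversible* — precisely when every `Mn`
satisfies detailed balance with respect to its stationary distribution.
`is_microscopically_reversible()` computes both criteria independently and
raises if they ever disagree, treating disagreement as a numerical fault
rather than a result.

The reversed process carries the energies `Ê_n = E_{N−(n−1)}` for
`n = 1..N` with `Ê_0 = Ê_1`: the same physical energy functions, traversed
backwards, with no freedom to re-pick constants between the two runs. Under
this convention the work-reversal identity reads

$$W_Y(x^R) = -W_X(x) + \big(E_1(x_0) - E_0(x_0)\big) + k,$$

with `k = (Ê_N − E_1) − (Ê_0 − E_N) = 0`. The boundary term
`E_1(x_0) − E_0(x_0)` is the one genuine asymmetry of discrete time: the
forward process may *begin* with an energy switch, the backward one cannot.
It vanishes iff `p0` is stationary for `M1`, and then work is odd under
time reversal. `work_reversal_constant()` does not assume the differences
defining `k` are constant across states — it checks them at `1e-10`, so an
inconsistent user-supplied family is caught instead of silently absorbed.

## The fluctuation identities, and when they fail

`jarzynski_exact()` evaluates `⟨e^{−β(W−ΔF)}⟩ = 1` by exhaustive
enumeration: at desk scale (`|S| ≤ 5`, `N ≤ 4`, ≤ 3 125 trajectories) the
identity holds to `1e-9` under *any* gauge, for *any* chain with positive
`p0` and irreducible matrices. The hypotheses are enforced because the
identity is only guaranteed under them. Jensen's inequality then gives the
second-law bound `ΔF ≤ ⟨W⟩`, exposed as `second_law_gap()`.

The ratio identity for work *distributions*,
`P_F(W = w) / P_B(W = −w + k) = e^{β(w−ΔF)}`, needs one more hypothesis in
discrete time: `p0` must be stationary for `M1`. `crooks_report()` checks
the hypothesis but never refuses to run without it, because the failure
mode is itself informative. `crooks_counterexample()` builds the canonical
offender: three states, one step, `p0 = (a, b, c)` with `b < c`, a rank-one
reversible matrix with stationary `(a, c, b)`. Its time reversal does no
work at all — the backward distribution is a point mass at zero — so the
ratio is undefined at two of the three forward atoms and equals `a ≠ 1` at
the third. The report exhibits all of this with `defined` flags and
`holds = FALSE`.

### Numerical choices

* **Work atoms.** Work is a discrete random variable; equal atoms computed
  through different floating-point routes differ by roundoff. Support
  values are therefore grouped by single-linkage with gap threshold
  `tol_group = 1e-9` (configurable via `options(chaintherm.tol_group=)`),
  so roundoff can never split an atom and the ratio identity is evaluated
  on genuine support points.
* **Zeros.** Ratio identities degenerate at zero-probability trajectories:
  trajectories with probability zero on both sides are skipped; a zero on
  one side only is reported as a violation (infinite error), never ignored.
* **Log domain.** Partition functions and Boltzmann policies are evaluated
  with log-sum-exp, so large `β` or extreme utilities cannot overflow.
* **Stationary solve.** Least-squares null-space solve of `(M − I)` with
  the normalisation row appended, residual-checked at `1e-10`; reducible
  matrices are refused because uniqueness underpins every downstream
  definition. Aperiodicity is deliberately *not* required — only
  stationarity is ever used, so permutation cycles are legitimate inputs.
* **Tolerances.** `tol_stochastic = 1e-9` (validation),
  `tol_stationary = 1e-10` (solver), both global options. Exact identities
  are asserted at `1e-9`–`1e-12`; Monte Carlo assertions use fixed seeds
  and five-standard-error bands.

## The decision-making layer

Reading energy as negative utility turns the machinery into a model of
bounded-rational choice. The max-entropy policy under an expected-utility
constraint is the Boltzmann distribution `p ∝ e^{βU}`; `β` is the
trade-off between exploiting utility and retaining uncertainty. A learner
that can only improve — whose every update keeps the optimal policy
invariant — is exactly a stochastic matrix with that policy as stationary
distribution. The package's default learner is the plain Metropolis rule
over a symmetric proposal (`uniform` over all states, or `always_swap` for
two states): the construction is a *choice* — any matrix with the right
stationary law would do, and gradient-style learners fit the same frame —
but Metropolis guarantees detailed balance by construction, which is what
lets the adaptation experiment compare forward and reversed environment
schedules through the genuine time reversal. The Hastings correction for
asymmetric proposals is intentionally out of scope.

`run_adaptation()` drives the learner through a schedule of environments
(each with a dwell time), equilibrated by default to the first environment
so the Crooks hypothesis `p0 = p1` holds by construction; a
non-equilibrated start reproduces the counterexample's failure mode on
demand. Work becomes cumulative surprise (`surprise_steps()` gives the
per-switch decomposition), the second-law gap bounds expected surprise
above `ΔF`, and the per-trajectory log-probability gap between the forward
schedule and the reversed one equals `β W_d` — the package's quantitative
measure of hysteresis.

## What the generators emulate — and what they do not

Test properties run over seeded random chains of three classes: `generic`
(entries floored at `1e-3`, hence irreducible; strictly positive random
`p0`), `detailed_balance` (Metropolis matrices against random positive
targets, optionally equilibrated so `p0 = p1`), and `permutation`
(deterministic single cycles: irreducible, periodic, maximally
non-reversible). Default problem sizes are 2–5 states and 1–4 steps —
chosen so full enumeration stays in the hundreds-to-thousands of
trajectories and every identity can be asserted at numerical rather than
statistical precision; the Monte Carlo estimator is exercised at
`n = 10^5` draws.

These generators probe the *identities*, which are exact for every valid
chain, so passing them is strong evidence of correctness of the
implementation. They do not emulate features of empirical decision or
physical data: state spaces here are small and fully observed, the
environment schedule is known, matrices are exactly stochastic, and no
measurement noise or model misspecification enters. Conclusions about real
systems additionally require that the Markov model fit — in particular,
learners with long-term memory or abstraction are outside this frame.

## Known limitations

* Discrete time, finite state spaces only; no continuous-time generators,
  Markov kernels on continuous spaces, or hidden/partially observed states.
* One `β` per chain; temperature schedules are not modelled.
* Exact mode is exponential in `N`: `|S|^(N+1)` trajectories. The
  enumeration cap (default `1e6`) makes the cost explicit;
  `run_adaptation()` degrades to Monte Carlo with a notice beyond it.
* The exact-arithmetic mode for work atoms stops at grouping in floating
  point; probabilities are not carried as rationals.
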