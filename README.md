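# chaintherm

Stochastic thermodynamics for finite, discrete-time, inhomogeneous Markov
chains — and for the bounded-rational decision-makers they can model.

A *driven chain* `X = (X0, ..., XN)` is a finite-state chain with an initial
distribution `p0` and a possibly different column-stochastic transition matrix
`Mn` at each step, at inverse temperature `β`. Each step has a reference
distribution — `p0` at step 0, the unique stationary distribution `pn` of each
irreducible `Mn` afterwards — and an energy function `En = -(1/β) log pn` (up
to an additive gauge). Along a realization `x = (x0, ..., xN)`:

- **work** `W(x) = Σ_{n=0}^{N-1} [E_{n+1}(x_n) − E_n(x_n)]` — the energy
  change due to the external switch of the energy function;
- **heat** `Q(x) = Σ_{n=1}^{N} [E_n(x_n) − E_n(x_{n-1})]` — the energy change
  due to internal transitions (gauge-invariant);
- **first law** `W + Q = E_N(x_N) − E_0(x_0)`, exactly, per trajectory;
- **dissipated work** `W_d = W − ΔF` with `ΔF = F_N − F_0`,
  `F_n = −(1/β) log Σ_x e^{−βE_n(x)}`.

Because every state space here is finite and every horizon short, the
fluctuation theorems are *identities checkable by exhaustive enumeration*,
not asymptotic statements:

- **Jarzynski**: `⟨e^{−β(W−ΔF)}⟩ = 1` for any chain with strictly positive
  `p0` and irreducible matrices — `jarzynski_exact()` computes the left side
  as an exact sum over all `|S|^(N+1)` trajectories;
- **Crooks**: `P_F(W = w) / P_B(W = −w) = e^{β(w−ΔF)}` at every support
  point, where the backward process is the time reversal (initial `pN`,
  matrices reversed) — but in discrete time only under the extra hypothesis
  that `p0` is stationary for `M1`. `crooks_report()` verifies the identity
  and, when the hypothesis fails, documents exactly how it breaks
  (`crooks_counterexample()` packages the chain on which it is false at
  every work value);
- **second law** `ΔF ≤ ⟨W⟩`, by Jensen's inequality on Jarzynski.

The decision layer reads energy as negative utility: `boltzmann_policy()` is
the max-entropy policy under an expected-utility constraint,
`policy_transition_matrix()` builds a Metropolis learner with that policy as
its stationary distribution, and `run_adaptation()` drives the learner
through a schedule of environments, reporting surprise (work), the
second-law bound on expected surprise, and hysteresis under the reversed
schedule.

## Worked example

```r
library(chaintherm)

fx <- two_state_chain()     # 2 states, 2 steps, p0 stationary for M1
jarzynski_exact(fx$chain, fx$family)
#> [1] 1

rep <- crooks_report(fx$chain, fx$family)
tidy(rep)
#> # A tibble: 2 x 7
#>     work p_forward p_backward observed_ratio predicted_ratio defined rel_error
#>    <dbl>     <dbl>      <dbl>          <dbl>           <dbl> <lgl>       <dbl>
#> 1 -0.405     0.333        0.5          0.667           0.667 TRUE     1.67e-16
#> 2  0.288     0.667        0.5          1.33            1.33  TRUE     1.67e-16
```

Both work atoms (`±log 4/3` shifted by the energy switch) satisfy the
forward/backward ratio identity to machine precision, so `glance(rep)$holds`
is `TRUE`. On the counterexample chain the same call returns `holds = FALSE`
with the backward distribution a point mass at zero:

```r
ce <- crooks_counterexample(a = 0.5, b = 0.2, c = 0.3)
glance(crooks_report(ce$chain, ce$family))[, c("p0_is_stationary_of_M1", "n_defined", "holds")]
#> # A tibble: 1 x 3
#>   p0_is_stationary_of_M1 n_defined holds
#>   <lgl>                      <int> <lgl>
#> 1 FALSE                          1 FALSE
```

and the one defined ratio is 0.5 where the identity predicts 1.

A thin command-line front end over the same functions lives at
`inst/cli/chaintherm.R` (`validate`, `stationary`, `reverse`, `work-dist`,
`jarzynski`, `crooks`, `second-law`, `counterexample`, `simulate`), with
exit code 0 when an identity holds, 1 when it fails, 2 on a precondition
violation.

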