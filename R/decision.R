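#' Boltzmann (maximum-entropy) policy
#'
#' The optimal bounded-rational choice distribution: the maximizer of entropy
#' subject to an expected-utility constraint is the Boltzmann distribution
#' `p(x) = exp(beta U(x)) / Z`. Utility plays the role of negative energy
#' (`U = -E`); `beta` trades off utility against uncertainty — large `beta`
#' concentrates on the best option, `beta -> 0` approaches indifference.
#' Evaluated in the log domain, so extreme `beta * U` cannot overflow.
#'
#' @param U named numeric vector of utilities (one per state).
#' @param beta positive trade-off parameter.
#' @return a strictly positive probability vector over the states.
#' @export
boltzmann_policy <- function(U, beta = 1) {
  if (beta <= 0) abort("beta must be positive")
  if (any(!is.finite(U))) abort("utilities must be finite")
  lw <- beta * U
  p <- exp(lw - logsumexp(lw))
  p / sum(p)
}

.named_proposal <- function(proposal, k) {
  if (is.character(proposal)) {
    proposal <- switch(proposal,
      uniform = matrix(1 / k, k, k),
      always_swap = {
        if (k != 2) abort("the always_swap proposal is defined for 2 states")
        matrix(c(0, 1, 1, 0), 2, 2)
      },
      abort(sprintf("unknown proposal '%s'", proposal))
    )
  }
  proposal
}

#' Metropolis transition matrix with a prescribed stationary distribution
#'
#' Builds a transition matrix whose stationary distribution is exactly the
#' target policy `p`, via the Metropolis rule over a symmetric proposal:
#' off-diagonal entry `(x, y) = proposal(x, y) * min(1, p(x) / p(y))`, with
#' the rejected mass absorbed on the diagonal. The result is
#' column-stochastic and satisfies detailed balance with respect to `p`
#' (both verified on construction). This is the package's model of a learner
#' whose updates never move away from the optimal policy — exactly the
#' matrices allowed by majorization toward `p`. Asymmetric proposals (the
#' Hastings correction) are not supported.
#'
#' @param p strictly positive target probability vector.
#' @param proposal a symmetric column-stochastic matrix, or one of
#'   `"uniform"`, `"always_swap"`.
#' @return a column-stochastic matrix `M` with `M p = p` and detailed balance.
#' @export
policy_transition_matrix <- function(p, proposal = "uniform") {
  if (any(p <= 0)) abort("the target policy must be strictly positive")
  k <- length(p)
  prop <- .named_proposal(proposal, k)
  if (!isTRUE(all.equal(prop, t(prop), tolerance = 1e-12))) {
    abort("the proposal must be symmetric (Hastings correction not supported)")
  }
  if (max(abs(colSums(prop) - 1)) > ct_tol("stochastic")) {
    abort("the proposal must be column-stochastic")
  }
  acc <- pmin(1, outer(p, 1 / p)) # acc[x, y] = min(1, p(x)/p(y))
  M <- prop * acc
  diag(M) <- 0
  diag(M) <- 1 - colSums(M)
  if (!satisfies_detailed_balance(M, p, 1e-12)) {
    abort("internal error: Metropolis output failed detailed balance")
  }
  if (max(abs(as.numeric(M %*% p) - p)) > 1e-12) {
    abort("internal error: Metropolis output failed stationarity")
  }
  dimnames(M) <- list(names(p), names(p))
  M
}

#' Per-step surprise along a trajectory
#'
#' The driving signal of adaptation: at each environment switch the
#' decision-maker experiences `w_n = E_{n+1}(x_n) - E_n(x_n)`, the change of
#' the (negative-utility) energy evaluated at its current state. The steps
#' sum exactly to the work of the trajectory.
#'
#' @inheritParams work
#' @return numeric vector of length `N` with the per-step surprises.
#' @export
surprise_steps <- function(x, family) {
  idx <- .family_index(family, x)
  E <- family$energies
  vapply(seq_len(family$n_steps),
         function(i) E[[i + 1]][[idx[i]]] - E[[i]][[idx[i]]],
         numeric(1))
}

#' A decision environment
#'
#' One environmental condition: a utility function over the shared state set
#' and the number of decision steps (`dwell`) the learner spends in it before
#' the environment switches.
#'
#' @param utility named numeric vector of utilities.
#' @param dwell integer `>= 1`.
#' @return a `decision_environment` list.
#' @export
decision_environment <- function(utility, dwell = 1L) {
  if (dwell < 1) abort("dwell must be >= 1")
  structure(list(utility = utility, dwell = as.integer(dwell)),
            class = "decision_environment")
}

#' An adaptation protocol
#'
#' A sequence of environments presented to a Metropolis learner sharing one
#' state set and one `beta`. By default the learner starts equilibrated to
#' the first environment (`p0` equal to its Boltzmann policy), so the initial
#' distribution is stationary for the first transition matrix and the Crooks
#' hypothesis holds by construction; `equilibrated = FALSE` with an explicit
#' `p0` reproduces the failure mode where the ratio identity breaks.
#'
#' @param states character vector of state labels.
#' @param beta positive trade-off parameter shared by all environments.
#' @param environments list of [decision_environment()]s (at least 2).
#' @param proposal proposal for the Metropolis learner (see
#'   [policy_transition_matrix()]).
#' @param equilibrated start from the first environment's Boltzmann policy?
#' @param p0 explicit initial distribution when `equilibrated = FALSE`.
#' @param seed integer seed recorded for Monte Carlo summaries.
#' @return an `adaptation_protocol` list.
#' @export
adaptation_protocol <- function(states, beta, environments,
                                proposal = "uniform", equilibrated = TRUE,
                                p0 = NULL, seed = 1L) {
  if (length(environments) < 2) abort("at least 2 environments are required")
  for (e in environments) {
    if (length(e$utility) != length(states)) {
      abort("every environment must assign a utility to every state")
    }
  }
  structure(
    list(states = as.character(states), beta = beta,
         environments = environments, proposal = proposal,
         equilibrated = isTRUE(equilibrated), p0 = p0, seed = as.integer(seed)),
    class = "adaptation_protocol"
  )
}

#' Run an adaptation experiment
#'
#' Builds the driven chain of the protocol — for each environment, the
#' Metropolis matrix targeting its Boltzmann policy, repeated `dwell` times —
#' plus the zero-gauge energy family, and summarises it thermodynamically:
#' the Jarzynski expectation (exact when enumeration fits under `cap`,
#' otherwise Monte Carlo with a notice), the second-law gap (expected
#' surprise above the free-energy bound), and, in exact mode, the Crooks
#' report against the reversed-environment schedule.
#'
#' @param protocol an [adaptation_protocol()].
#' @param cap enumeration cap; above it the summary degrades to Monte Carlo.
#' @param mc_n Monte Carlo sample size used when enumeration is infeasible.
#' @return an `adaptation_result` list: `chain`, `family`, `summary` (with
#'   elements `mode`, `jarzynski`, `second_law_gap`, and `crooks` in exact
#'   mode).
#' @export
run_adaptation <- function(protocol, cap = 1e6, mc_n = 1e5) {
  beta <- protocol$beta
  policies <- lapply(protocol$environments,
                     function(e) boltzmann_policy(setNames(e$utility, protocol$states), beta))
  mats <- list()
  for (i in seq_along(protocol$environments)) {
    M <- policy_transition_matrix(policies[[i]], protocol$proposal)
    mats <- c(mats, rep(list(M), protocol$environments[[i]]$dwell))
  }
  p0 <- if (protocol$equilibrated) policies[[1]] else protocol$p0
  if (is.null(p0)) abort("p0 must be supplied when equilibrated = FALSE")
  chain <- driven_chain(protocol$states, p0, mats, beta)
  family <- energy_family(chain)

  n_traj <- length(protocol$states)^(chain$n_steps + 1)
  exact <- n_traj <= cap
  if (exact) {
    summary <- list(
      mode = "exact",
      jarzynski = jarzynski_exact(chain, family, cap),
      second_law_gap = second_law_gap(chain, family, cap),
      crooks = crooks_report(chain, family, cap)
    )
  } else {
    warn("enumeration cap exceeded; summary degrades to Monte Carlo estimates")
    mc <- jarzynski_mc(chain, family, mc_n, protocol$seed)
    ens <- thermo_functionals(sample_trajectories(chain, mc_n, protocol$seed + 1L),
                              family)
    summary <- list(
      mode = "monte_carlo",
      jarzynski = mc$estimate,
      jarzynski_se = mc$se,
      second_law_gap = mean(ens$dissipated)
    )
  }
  structure(list(chain = chain, family = family, summary = summary),
            class = "adaptation_result")
}

#' @export
print.adaptation_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<adaptation_result> N = %d steps over %d states (%s mode)\n",
              x$chain$n_steps, length(x$chain$states), s$mode))
  cat(sprintf("  Jarzynski expectation: %.10g\n", s$jarzynski))
  cat(sprintf("  second-law gap <W> - dF: %.10g\n", s$second_law_gap))
  if (!is.null(s$crooks)) {
    cat(sprintf("  Crooks holds: %s\n", s$crooks$holds))
  }
  invisible(x)
}

#' @rdname run_adaptation
#' @param x an `adaptation_result`.
#' @param ... unused.
#' @export
glance.adaptation_result <- function(x, ...) {
  s <- x$summary
  tibble(
    n_steps = x$chain$n_steps,
    n_states = length(x$chain$states),
    mode = s$mode,
    jarzynski = s$jarzynski,
    second_law_gap = s$second_law_gap,
    crooks_holds = if (is.null(s$crooks)) NA else s$crooks$holds
  )
}
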