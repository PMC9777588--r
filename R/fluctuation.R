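#' Jarzynski's equality by exact enumeration
#'
#' Computes `sum_x P(X = x) exp(-beta (W(x) - delta_F))` over all
#' trajectories. For any chain with strictly positive `p0` and irreducible
#' matrices, and any energy family (any gauge), the sum equals 1 exactly —
#' this is Jarzynski's equality, and the function is primarily a verification
#' device: departures from 1 expose an invalid input or a solver defect.
#'
#' @param chain a [driven_chain()] with strictly positive `p0` and irreducible
#'   matrices (the identity is only guaranteed under these hypotheses, which
#'   are checked).
#' @param family an [energy_family()]; defaults to the zero-gauge family.
#' @param cap enumeration cap.
#' @return the exact expectation, a real equal to 1 up to roundoff.
#' @export
jarzynski_exact <- function(chain, family = energy_family(chain), cap = 1e6) {
  .check_theorem_hypotheses(chain)
  ens <- thermo_functionals(enumerate_trajectories(chain, cap), family)
  sum(ens$prob * exp(-family$beta * ens$dissipated))
}

.check_theorem_hypotheses <- function(chain) {
  if (any(chain$p0 <= 0)) {
    abort("hypothesis violated: p0 must have strictly positive entries")
  }
  for (n in seq_len(chain$n_steps)) {
    if (!is_irreducible(chain$matrices[[n]])) {
      abort(sprintf("hypothesis violated: M%d is reducible", n))
    }
  }
  invisible(TRUE)
}

#' Jarzynski's equality by Monte Carlo
#'
#' Sample mean and standard error of `exp(-beta (W - delta_F))` over `n`
#' sampled trajectories. A separate estimator, never silently substituted for
#' the exact sum.
#'
#' @inheritParams jarzynski_exact
#' @param n number of sampled trajectories (`>= 2`).
#' @param seed integer seed.
#' @return a one-row tibble with columns `estimate`, `se`, `n`, `seed`.
#' @export
jarzynski_mc <- function(chain, family = energy_family(chain), n = 1e5,
                         seed = 1) {
  if (n < 2) abort("n must be >= 2")
  ens <- thermo_functionals(sample_trajectories(chain, n, seed), family)
  vals <- exp(-family$beta * ens$dissipated)
  tibble(
    estimate = mean(vals),
    se = stats::sd(vals) / sqrt(n),
    n = as.integer(n),
    seed = as.integer(seed)
  )
}

#' Per-trajectory forward/backward probability ratio check
#'
#' Verifies, over the full enumeration, the path-level identity
#' `P(X = x) = P(Y = x^R) exp(beta (W(x) - delta_F))` with `Y` the auxiliary
#' reversed chain, together with its conditional form with heat in place of
#' work, `P(x1..xN | x0) = P(Y path reversed | Y0 = xN) exp(-beta Q(x))`.
#' Both hold for every trajectory under valid inputs; the returned number is
#' the worst relative error over trajectories with `P(X = x) > 0`. A
#' trajectory with positive probability on one side and zero on the other is
#' reported as an infinite violation.
#'
#' @inheritParams jarzynski_exact
#' @return max relative violation over the enumeration.
#' @export
trajectory_ratio_check <- function(chain, family = energy_family(chain),
                                   cap = 1e6) {
  .check_theorem_hypotheses(chain)
  aux <- auxiliary_reverse_chain(chain)
  ens <- thermo_functionals(enumerate_trajectories(chain, cap), family)
  idx <- attr(ens, "index")
  ridx <- idx[, rev(seq_len(ncol(idx))), drop = FALSE]
  p_back <- .path_probs(aux, ridx)
  dF <- delta_free_energy(family)
  beta <- family$beta

  live <- ens$prob > 0
  one_sided <- xor(live, p_back > 0)
  if (any(one_sided)) return(Inf)

  pf <- ens$prob[live]
  pb <- p_back[live]
  err_path <- abs(pf - pb * exp(beta * (ens$work[live] - dF))) / pf

  # conditional form: divide out the initial masses
  cf <- pf / chain$p0[idx[live, 1]]
  cb <- pb / aux$p0[ridx[live, 1]]
  err_cond <- abs(cf - cb * exp(-beta * ens$heat[live])) / cf

  max(err_path, err_cond)
}

#' Hysteresis of a single trajectory
#'
#' Under microscopic reversibility (detailed balance of every matrix), the
#' dissipated work measures how much likelier a realization is than its
#' reversal in the time-reversed chain:
#' `log P(X = x) - log P(Y = x^R) = beta * Wd(x)`. Both sides are computed
#' independently and must agree; the common value is returned. It vanishes
#' exactly when `W(x) = delta_F` (no hysteresis).
#'
#' @inheritParams work
#' @param chain a microscopically reversible [driven_chain()].
#' @return `beta * Wd(x)`, the log-probability gap.
#' @export
hysteresis <- function(chain, family = energy_family(chain), x) {
  if (!is_microscopically_reversible(chain)) {
    abort(c(
      "the chain is not microscopically reversible (some matrix lacks detailed balance)",
      i = "for a non-reversible chain use trajectory_ratio_check(), which compares against the auxiliary reversed chain"
    ))
  }
  tr <- time_reversal(chain)
  v1 <- family$beta * dissipated_work(x, family)
  idx <- .traj_index(chain, x)
  v2 <- log(trajectory_probability(chain, x)) -
    log(trajectory_probability(tr, rev(idx)))
  if (!isTRUE(abs(v1 - v2) <= 1e-10 * max(1, abs(v1)))) {
    abort(sprintf("hysteresis routes disagree: beta*Wd = %.12g, log-ratio = %.12g", v1, v2))
  }
  v1
}

# single-linkage grouping of sorted values: new atom whenever the gap > tol
.group_values <- function(values, tol) {
  o <- order(values)
  v <- values[o]
  grp_sorted <- cumsum(c(1, diff(v) > tol))
  grp <- integer(length(values))
  grp[o] <- grp_sorted
  grp
}

#' Exact work distribution
#'
#' The distribution of the work functional under the chain's path measure,
#' computed by full enumeration. Work is a discrete random variable here;
#' floating-point work values are grouped into atoms by single-linkage at
#' `tol_group`, so roundoff never splits an atom.
#'
#' @inheritParams jarzynski_exact
#' @param tol_group grouping tolerance for work atoms.
#' @return a `work_distribution` tibble with columns `work` (sorted atom
#'   locations, probability-weighted means within each group) and `prob`
#'   (summing to 1).
#' @export
work_distribution <- function(chain, family = energy_family(chain),
                              cap = 1e6, tol_group = ct_tol("group")) {
  ens <- thermo_functionals(enumerate_trajectories(chain, cap), family)
  grp <- .group_values(ens$work, tol_group)
  p <- as.numeric(tapply(ens$prob, grp, sum))
  w <- as.numeric(tapply(ens$prob * ens$work, grp, sum)) / ifelse(p > 0, p, 1)
  # zero-probability atoms can arise only from all-zero trajectories; keep the
  # plain mean there so the support stays well defined
  w0 <- as.numeric(tapply(ens$work, grp, mean))
  w[p == 0] <- w0[p == 0]
  keep <- p > 0
  out <- tibble(work = w[keep], prob = p[keep])
  out <- out[order(out$work), ]
  attr(out, "provenance") <- list(type = "exact", tol_group = tol_group)
  attr(out, "beta") <- family$beta
  class(out) <- c("work_distribution", class(out))
  out
}

# look up P(W = target) in a work distribution, matching atoms at tol
.dist_prob_at <- function(dist, target, tol) {
  hit <- which(abs(dist$work - target) <= tol)
  if (length(hit) == 0) 0 else sum(dist$prob[hit])
}

#' Crooks fluctuation report
#'
#' Builds the forward work distribution `PF` and the backward distribution
#' `PB` of the reversed process (genuine time reversal under detailed
#' balance, otherwise the auxiliary chain), then tests, at every forward
#' support point `w`, the ratio identity
#' `PF(W = w) / PB(W = -w + k) = exp(beta (w - delta_F))`,
#' with `k` the work-reversal constant (0 with reversal energies under
#' detailed balance). The theorem guarantees the identity only when `p0` is
#' the stationary distribution of `M1`; when that hypothesis fails the report
#' is still produced — undefined ratios (backward probability zero) and
#' failed support points are first-class results, not errors.
#'
#' @inheritParams work_distribution
#' @param tol relative tolerance for declaring a support point to hold.
#' @return a `crooks_report` object; see [tidy.crooks_report()] and
#'   [glance.crooks_report()].
#' @export
crooks_report <- function(chain, family = energy_family(chain), cap = 1e6,
                          tol = 1e-9, tol_group = ct_tol("group")) {
  .check_theorem_hypotheses(chain)
  pair <- reversal_pair(chain, family)
  p1 <- stationary_distribution(chain$matrices[[1]])
  p0_is_stationary <- max(abs(chain$p0 - p1)) <= ct_tol("stochastic")

  fwd <- work_distribution(chain, family, cap, tol_group)
  bwd <- work_distribution(pair$backward$chain, pair$backward$family, cap, tol_group)
  dF <- delta_free_energy(family)
  beta <- family$beta

  rows <- purrr::map_dfr(seq_len(nrow(fwd)), function(i) {
    w <- fwd$work[i]
    pb <- .dist_prob_at(bwd, -w + pair$k, tol_group)
    defined <- pb > 0
    observed <- if (defined) fwd$prob[i] / pb else NA_real_
    predicted <- exp(beta * (w - dF))
    tibble(
      work = w,
      p_forward = fwd$prob[i],
      p_backward = pb,
      observed_ratio = observed,
      predicted_ratio = predicted,
      defined = defined,
      rel_error = if (defined) abs(observed - predicted) / predicted else NA_real_
    )
  })
  holds <- all(rows$defined) && all(rows$rel_error <= tol)
  structure(
    list(
      table = rows,
      k = pair$k,
      delta_F = dF,
      beta = beta,
      kind = pair$kind,
      p0_is_stationary_of_M1 = p0_is_stationary,
      holds = holds,
      tol = tol
    ),
    class = "crooks_report"
  )
}

#' @export
print.crooks_report <- function(x, ...) {
  cat(sprintf(
    "<crooks_report> %s reversal, k = %g, delta_F = %g, p0 stationary for M1: %s\n",
    x$kind, x$k, x$delta_F, x$p0_is_stationary_of_M1
  ))
  cat(sprintf("holds: %s (tol %.1e)\n", x$holds, x$tol))
  print(x$table)
  invisible(x)
}

#' Second-law gap
#'
#' `<W> - delta_F`, the expected dissipated work (expected surprise above the
#' free-energy bound in the decision reading), computed by exact enumeration.
#' Nonnegative for every valid chain by Jensen's inequality applied to
#' Jarzynski's equality; zero exactly when the work is almost surely equal to
#' `delta_F`. Gauge-invariant.
#'
#' @inheritParams jarzynski_exact
#' @return the scalar gap `<W> - delta_F`.
#' @export
second_law_gap <- function(chain, family = energy_family(chain), cap = 1e6) {
  .check_theorem_hypotheses(chain)
  ens <- thermo_functionals(enumerate_trajectories(chain, cap), family)
  sum(ens$prob * ens$work) - delta_free_energy(family)
}
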