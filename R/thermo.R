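#' Energy function of a strictly positive distribution
#'
#' Inverts the Boltzmann form `p(x) = exp(-beta E(x)) / Z`: with gauge 0 the
#' returned energies are exactly `-(1/beta) log p(x)`, so the induced
#' partition function is `Z = 1` and the free energy `F = 0` (the zero-gauge
#' convention). Energies are defined only up to a shared additive constant;
#' `gauge` shifts the whole function by that constant.
#'
#' @param p probability vector with strictly positive entries, named by state.
#' @param beta positive inverse temperature.
#' @param gauge additive constant (default 0).
#' @return named numeric vector `E` with `p` proportional to `exp(-beta E)`.
#' @export
energy_of <- function(p, beta = 1, gauge = 0) {
  if (any(p <= 0)) {
    abort("energy_of requires strictly positive probabilities (positivity hypothesis)")
  }
  -log(p) / beta + gauge
}

new_energy_family <- function(energies, beta, gauges, states, refs = NULL) {
  structure(
    list(
      energies = lapply(energies, function(e) setNames(as.numeric(e), states)),
      beta = as.numeric(beta),
      gauges = as.numeric(gauges),
      states = states,
      n_steps = length(energies) - 1,
      refs = refs
    ),
    class = "energy_family"
  )
}

#' @export
print.energy_family <- function(x, ...) {
  cat(sprintf(
    "<energy_family> E0..E%d over {%s}, beta = %g, gauges = (%s)\n",
    x$n_steps, paste(x$states, collapse = ", "), x$beta,
    paste(signif(x$gauges, 4), collapse = ", ")
  ))
  invisible(x)
}

#' Energy family of a driven chain
#'
#' Builds the per-step energies `E0..EN`, where `En` is an energy function of
#' the step-`n` reference distribution: `p0` for `n = 0` and the unique
#' stationary distribution of `Mn` for `n >= 1` (unique and strictly positive
#' because each `Mn` is irreducible). Defaults to the zero-gauge convention,
#' `En = -(1/beta) log pn`, under which every `Zn = 1` and `Fn = 0`; all the
#' fluctuation identities are gauge-covariant, so this loses no generality.
#'
#' @param chain a [driven_chain()] with strictly positive `p0` and irreducible
#'   matrices.
#' @param gauges numeric vector `c0..cN` of additive constants (default all 0).
#' @return an `energy_family` object with the reference distributions cached.
#' @export
energy_family <- function(chain, gauges = NULL) {
  if (any(chain$p0 <= 0)) {
    abort("p0 must be strictly positive to define E0")
  }
  N <- chain$n_steps
  if (is.null(gauges)) gauges <- rep(0, N + 1)
  if (length(gauges) != N + 1) abort("gauges must have length N + 1")
  refs <- vector("list", N + 1)
  refs[[1]] <- chain$p0
  for (n in seq_len(N)) {
    if (!is_irreducible(chain$matrices[[n]])) {
      abort(sprintf("M%d is reducible: no unique stationary reference p%d", n, n))
    }
    refs[[n + 1]] <- stationary_distribution(chain$matrices[[n]])
  }
  energies <- Map(function(p, g) energy_of(p, chain$beta, g), refs, gauges)
  new_energy_family(energies, chain$beta, gauges, chain$states, refs)
}

#' Partition functions and free energies of an energy family
#'
#' Computes `Zn = sum_x exp(-beta En(x))` in the log domain (no overflow at
#' large beta), `Fn = -(1/beta) log Zn`, and the free energy difference
#' `delta_F = FN - F0`. Under the zero gauge all `Zn = 1`, all `Fn = 0` and
#' `delta_F = 0`; shifting gauge `cn` shifts `Fn` by exactly `cn`.
#'
#' @param family an [energy_family()].
#' @return a tibble with columns `n`, `log_Z`, `Z`, `F`; the scalar
#'   `delta_F` is stored as an attribute (see [delta_free_energy()]).
#' @export
free_energy_summary <- function(family) {
  logZ <- vapply(family$energies,
                 function(E) logsumexp(-family$beta * E), numeric(1))
  Fn <- -logZ / family$beta
  out <- tibble(n = seq_along(logZ) - 1, log_Z = logZ, Z = exp(logZ), F = Fn)
  attr(out, "delta_F") <- Fn[length(Fn)] - Fn[1]
  out
}

#' Free energy difference `FN - F0`
#'
#' @param family an [energy_family()].
#' @return the scalar free energy difference associated with the family.
#' @export
delta_free_energy <- function(family) {
  attr(free_energy_summary(family), "delta_F")
}

.family_index <- function(family, x) {
  if (is.numeric(x)) idx <- as.integer(x) else idx <- match(as.character(x), family$states)
  if (anyNA(idx) || any(idx < 1 | idx > length(family$states))) {
    abort("trajectory label(s) not in the family's state set")
  }
  if (length(idx) != family$n_steps + 1) {
    abort(sprintf("trajectory has length %d; the family needs N + 1 = %d states",
                  length(idx), family$n_steps + 1))
  }
  idx
}

#' Work along a trajectory
#'
#' `W(x) = sum_{n=0}^{N-1} E_{n+1}(x_n) - E_n(x_n)`: the energy change due to
#' the external switch of the energy function while the system sits at its
#' current state — the driving signal. Under a gauge change the work shifts by
#' exactly `cN - c0`.
#'
#' @param x trajectory: vector of `N + 1` state labels or indices.
#' @param family an [energy_family()].
#' @return the work, a real in units of `1/beta`.
#' @export
work <- function(x, family) {
  idx <- .family_index(family, x)
  E <- family$energies
  s <- 0
  for (i in seq_len(family$n_steps)) {
    s <- s + E[[i + 1]][[idx[i]]] - E[[i]][[idx[i]]]
  }
  s
}

#' Heat along a trajectory
#'
#' `Q(x) = sum_{n=1}^{N} E_n(x_n) - E_n(x_{n-1})`: the energy change due to
#' internal state transitions under the (then-current) energy function.
#' Gauge-independent.
#'
#' @inheritParams work
#' @return the heat, a real in units of `1/beta`.
#' @export
heat <- function(x, family) {
  idx <- .family_index(family, x)
  E <- family$energies
  s <- 0
  for (i in seq_len(family$n_steps)) {
    s <- s + E[[i + 1]][[idx[i + 1]]] - E[[i + 1]][[idx[i]]]
  }
  s
}

#' Dissipated work along a trajectory
#'
#' `Wd(x) = W(x) - delta_F`; gauge-independent, and (under detailed balance)
#' the log-ratio of forward to time-reversed path probabilities — the
#' quantitative hysteresis measure.
#'
#' @inheritParams work
#' @return the dissipated work.
#' @export
dissipated_work <- function(x, family) {
  work(x, family) - delta_free_energy(family)
}

#' First-law residual of a trajectory
#'
#' Work plus heat must equal the total energy change,
#' `W(x) + Q(x) = EN(xN) - E0(x0)`; the residual is zero up to floating-point
#' roundoff for every trajectory and every family.
#'
#' @inheritParams work
#' @return `W + Q - (EN(xN) - E0(x0))`.
#' @export
first_law_residual <- function(x, family) {
  idx <- .family_index(family, x)
  E <- family$energies
  work(x, family) + heat(x, family) -
    (E[[length(E)]][[idx[length(idx)]]] - E[[1]][[idx[1]]])
}

#' Per-trajectory thermodynamic functionals of an ensemble
#'
#' Vectorised work/heat/dissipated-work over every trajectory of an ensemble
#' (enumerated or sampled), returned as added columns.
#'
#' @param ensemble a `trajectory_ensemble` from [enumerate_trajectories()] or
#'   [sample_trajectories()].
#' @param family a matching [energy_family()].
#' @return the ensemble tibble with columns `work`, `heat`, `dissipated`.
#' @export
thermo_functionals <- function(ensemble, family) {
  idx <- attr(ensemble, "index")
  if (is.null(idx)) abort("ensemble is missing its trajectory index attribute")
  if (ncol(idx) != family$n_steps + 1) {
    abort("ensemble and energy family disagree on the number of steps")
  }
  E <- family$energies
  w <- numeric(nrow(idx))
  q <- numeric(nrow(idx))
  for (i in seq_len(family$n_steps)) {
    w <- w + (E[[i + 1]] - E[[i]])[idx[, i]]
    q <- q + E[[i + 1]][idx[, i + 1]] - E[[i + 1]][idx[, i]]
  }
  ensemble$work <- unname(w)
  ensemble$heat <- unname(q)
  ensemble$dissipated <- unname(w) - delta_free_energy(family)
  ensemble
}
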