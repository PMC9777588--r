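# stationary distributions p1..pN of a chain's matrices (list indexed by step)
.step_stationaries <- function(chain) {
  lapply(chain$matrices, stationary_distribution)
}

#' Auxiliary reversed chain
#'
#' Constructs the chain `Y` used in the proofs of both fluctuation theorems:
#' initial distribution `pN` (stationary of the last forward matrix) and
#' transition matrices
#' `Mhat_{n+1}(x, y) = p_{N-n}(x) / p_{N-n}(y) * M_{N-n}(y, x)`.
#' Each `Mhat_n` is column-stochastic because `p_n` is stationary for `M_n`;
#' this is re-verified on construction. `Mhat_n` has stationary distribution
#' `p_{N-(n-1)}`. When every forward matrix satisfies detailed balance the
#' auxiliary chain coincides with the genuine time reversal.
#'
#' @param chain a [driven_chain()] with strictly positive `p0` and irreducible
#'   matrices.
#' @return the auxiliary reversed [driven_chain()].
#' @export
auxiliary_reverse_chain <- function(chain) {
  if (any(chain$p0 <= 0)) abort("p0 must be strictly positive")
  ps <- .step_stationaries(chain) # p1..pN
  N <- chain$n_steps
  rev_mats <- vector("list", N)
  for (n in 0:(N - 1)) {
    p <- ps[[N - n]]
    M <- chain$matrices[[N - n]]
    Mhat <- t(M) * outer(p, 1 / p) # Mhat[x, y] = p(x)/p(y) * M[y, x]
    cs <- colSums(Mhat)
    if (max(abs(cs - 1)) > 1e-12) {
      abort("auxiliary matrix failed column-stochasticity; stationary solve suspect")
    }
    Mhat <- sweep(Mhat, 2, cs, "/") # remove roundoff so the result validates
    rev_mats[[n + 1]] <- Mhat
  }
  driven_chain(chain$states, ps[[N]], rev_mats, beta = chain$beta)
}

#' Time reversal of a driven chain
#'
#' The chain started at the stationary distribution `pN` of the last forward
#' matrix and running the forward matrices in reversed order
#' `(MN, MN-1, ..., M1)`.
#'
#' @param chain a [driven_chain()] whose last matrix is irreducible.
#' @return the time-reversed [driven_chain()].
#' @export
time_reversal <- function(chain) {
  pN <- stationary_distribution(chain$matrices[[chain$n_steps]])
  driven_chain(chain$states, pN, rev(chain$matrices), beta = chain$beta)
}

#' Microscopic reversibility
#'
#' A chain is microscopically reversible when the path-probability identity
#' linking it to its time reversal holds — equivalently (Lemma-2-style), when
#' every `Mn` satisfies detailed balance with respect to its stationary
#' distribution, and equivalently again when the auxiliary reversed chain
#' coincides entrywise with the time reversal. Both criteria are computed and
#' must agree; disagreement signals a solver problem and raises.
#'
#' @param chain a [driven_chain()].
#' @param tol entrywise tolerance.
#' @return `TRUE` iff the chain is microscopically reversible.
#' @export
is_microscopically_reversible <- function(chain, tol = ct_tol("stochastic")) {
  ps <- .step_stationaries(chain)
  by_db <- all(vapply(
    seq_len(chain$n_steps),
    function(n) satisfies_detailed_balance(chain$matrices[[n]], ps[[n]], tol),
    logical(1)
  ))
  aux <- auxiliary_reverse_chain(chain)
  tr <- time_reversal(chain)
  gap <- max(vapply(
    seq_len(chain$n_steps),
    function(n) max(abs(aux$matrices[[n]] - tr$matrices[[n]])),
    numeric(1)
  ))
  by_coincidence <- gap <= max(tol, 1e-10)
  if (by_db != by_coincidence) {
    abort(sprintf(
      "internal inconsistency: detailed-balance criterion says %s but auxiliary-vs-reversal gap is %.3g",
      by_db, gap
    ))
  }
  by_db
}

#' Reversal energy family
#'
#' The energies of the reversed process, fixed by the convention that the same
#' physical energy function keeps its constant when the dynamics are run
#' backwards: `Ehat_n = E_{N-(n-1)}` for `n = 1..N`, and `Ehat_0 = Ehat_1`
#' (`= EN`). This family is valid for the auxiliary chain — whose step-`n`
#' matrix has stationary distribution `p_{N-(n-1)}` — and, under detailed
#' balance, for the genuine time reversal.
#'
#' @param family the forward [energy_family()].
#' @return the reversed `energy_family`.
#' @export
reversal_energy_family <- function(family) {
  N <- family$n_steps
  E <- family$energies
  rev_E <- vector("list", N + 1)
  for (n in seq_len(N)) rev_E[[n + 1]] <- E[[N - (n - 1) + 1]]
  rev_E[[1]] <- rev_E[[2]]
  g <- family$gauges
  rev_g <- c(g[N + 1], rev(g)[seq_len(N)]) # gauges ride along with their energies
  refs <- NULL
  if (!is.null(family$refs)) {
    refs <- c(list(family$refs[[N + 1]]), rev(family$refs)[seq_len(N)])
  }
  new_energy_family(rev_E, family$beta, rev_g, family$states, refs)
}

#' Work-reversal constant
#'
#' The constant `k` in the work-reversal identity
#' `W_Y(x^R) = -W_X(x) + E1(x0) - E0(x0) + k`, computed as
#' `k = (EhatN - E1) - (Ehat0 - EN)` evaluated at any state. Both differences
#' are constant across states when the reversed family genuinely matches the
#' reversed chain's references; constancy is verified rather than assumed, to
#' catch inconsistent user-supplied families. With [reversal_energy_family()]
#' energies `k = 0`, and when additionally `p0` is stationary for `M1` the
#' residual `E1(x0) - E0(x0)` vanishes too, making work odd under time
#' reversal.
#'
#' @param family forward [energy_family()].
#' @param rev_family reversed [energy_family()].
#' @param tol tolerance on across-state constancy.
#' @return the scalar `k`.
#' @export
work_reversal_constant <- function(family, rev_family,
                                   tol = ct_tol("stationary")) {
  N <- family$n_steps
  d1 <- rev_family$energies[[N + 1]] - family$energies[[2]]     # EhatN - E1
  d2 <- rev_family$energies[[1]] - family$energies[[N + 1]]     # Ehat0 - EN
  if (diff(range(d1)) > tol || diff(range(d2)) > tol) {
    abort("rev_family is inconsistent: the energy differences defining k vary across states")
  }
  mean(d1) - mean(d2)
}

#' Forward/backward reversal pair
#'
#' Bundles a chain and energy family with its reversed counterpart: the
#' genuine time reversal when the chain is microscopically reversible (or when
#' forced with `kind = "time_reversal"`), otherwise the auxiliary chain. The
#' reversed energies follow [reversal_energy_family()] and the work-reversal
#' constant `k` is attached.
#'
#' @param chain forward [driven_chain()].
#' @param family forward [energy_family()]; defaults to the zero-gauge family.
#' @param kind `"auto"`, `"auxiliary"` or `"time_reversal"`.
#' @return a `reversal_pair` list: `forward`, `backward` (each `chain` +
#'   `family`), `kind`, `k`.
#' @export
reversal_pair <- function(chain, family = energy_family(chain),
                          kind = c("auto", "auxiliary", "time_reversal")) {
  kind <- match.arg(kind)
  if (kind == "auto") {
    kind <- if (is_microscopically_reversible(chain)) "time_reversal" else "auxiliary"
  }
  backward_chain <- switch(kind,
    time_reversal = time_reversal(chain),
    auxiliary = auxiliary_reverse_chain(chain)
  )
  rev_family <- reversal_energy_family(family)
  structure(
    list(
      forward = list(chain = chain, family = family),
      backward = list(chain = backward_chain, family = rev_family),
      kind = kind,
      k = work_reversal_constant(family, rev_family)
    ),
    class = "reversal_pair"
  )
}

#' @export
print.reversal_pair <- function(x, ...) {
  cat(sprintf("<reversal_pair> kind = %s, k = %g, N = %d\n",
              x$kind, x$k, x$forward$chain$n_steps))
  invisible(x)
}

#' Verify the work-reversal identity by enumeration
#'
#' Enumerates every trajectory `x` and measures the worst violation of
#' `W_Y(x^R) = -W_X(x) + (E1(x0) - E0(x0)) + k`. The identity is
#' unconditional for consistent families, so the returned maximum is zero up
#' to roundoff; when `p0 = p1` and detailed balance holds with reversal
#' energies, it reduces to `W_Y(x^R) = -W_X(x)` (work odd under time
#' reversal).
#'
#' @param pair a [reversal_pair()].
#' @param cap enumeration cap.
#' @return max over trajectories of the absolute violation.
#' @export
verify_work_reversal <- function(pair, cap = 1e6) {
  fwd <- pair$forward
  bwd <- pair$backward
  ens <- enumerate_trajectories(fwd$chain, cap)
  idx <- attr(ens, "index")
  w_fwd <- thermo_functionals(ens, fwd$family)$work
  # reverse each trajectory and evaluate the backward work
  ridx <- idx[, rev(seq_len(ncol(idx))), drop = FALSE]
  rens <- ens
  attr(rens, "index") <- ridx
  w_bwd <- thermo_functionals(rens, bwd$family)$work
  E1 <- fwd$family$energies[[2]]
  E0 <- fwd$family$energies[[1]]
  resid <- (E1 - E0)[idx[, 1]]
  max(abs(w_bwd + w_fwd - resid - pair$k))
}
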