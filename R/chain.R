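#' Driven (inhomogeneous) finite Markov chain
#'
#' A driven chain is a finite-state, discrete-time Markov chain
#' `X = (X0, ..., XN)` specified by an initial distribution `p0` and an ordered
#' sequence of per-step transition matrices `M1, ..., MN`, together with an
#' inverse temperature `beta`. A possibly different matrix acts at each step,
#' modelling a system pushed through a sequence of environments.
#'
#' Transition matrices are column-stochastic with entry `(x, y)` equal to
#' `P(X_n = x | X_{n-1} = y)`: columns index the source state and each column
#' sums to one. Files or matrices written in the row-stochastic `"from_to"`
#' orientation are transposed on input when `convention = "from_to"`.
#'
#' @param states character vector of distinct state labels, length at least 2.
#' @param p0 numeric probability vector over `states` (the distribution of X0).
#' @param matrices a list of square numeric matrices over `states`, in time
#'   order `M1..MN`; a single matrix is promoted to a length-one list. `N >= 1`
#'   is required: with no transition steps, work and heat are empty sums and
#'   none of the fluctuation identities has content.
#' @param beta positive inverse temperature (dimensionless).
#' @param convention `"to_from"` (column-stochastic, the default) or
#'   `"from_to"` (row-stochastic input, transposed internally).
#' @return an object of class `driven_chain`: a list with elements `states`,
#'   `p0` (named), `matrices` (list of named matrices), `beta`, `n_steps`.
#' @examples
#' M <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)
#' x <- driven_chain(c("0", "1"), c(2 / 3, 1 / 3), list(M), beta = 1)
#' stationary_distribution(M)
#' @export
driven_chain <- function(states, p0, matrices, beta = 1,
                         convention = c("to_from", "from_to")) {
  convention <- match.arg(convention)
  states <- as.character(states)
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (length(states) < 2) abort("a driven chain needs at least 2 states")
  if (anyDuplicated(states)) abort("state labels must be distinct")
  if (length(matrices) < 1) {
    abort("a driven chain needs at least one transition step (N >= 1)")
  }
  matrices <- lapply(matrices, function(M) {
    M <- as.matrix(M)
    if (nrow(M) != length(states) || ncol(M) != length(states)) {
      abort("every transition matrix must be |S| x |S|")
    }
    if (convention == "from_to") M <- t(M)
    dimnames(M) <- list(states, states)
    M
  })
  obj <- structure(
    list(
      states = states,
      p0 = setNames(as.numeric(p0), states),
      matrices = matrices,
      beta = as.numeric(beta),
      n_steps = length(matrices)
    ),
    class = "driven_chain"
  )
  bad <- validate_chain(obj)
  if (nrow(bad) > 0) {
    abort(c("invalid driven chain:", bad$message))
  }
  obj
}

#' @export
print.driven_chain <- function(x, ...) {
  cat(sprintf(
    "<driven_chain> |S| = %d states (%s), N = %d step(s), beta = %g\n",
    length(x$states), paste(x$states, collapse = ", "), x$n_steps, x$beta
  ))
  cat("p0:", paste(signif(x$p0, 4), collapse = " "), "\n")
  invisible(x)
}

#' Validate a driven chain
#'
#' Checks the structural invariants — each column of each transition matrix
#' sums to one, `p0` is a probability vector, `beta > 0` — and reports every
#' violation instead of raising, so a partially broken specification can be
#' diagnosed in one pass.
#'
#' @param chain a [driven_chain()] (or an unclassed list with the same
#'   elements, so the constructor can self-check).
#' @param tol numeric tolerance on the stochasticity checks; defaults to
#'   `ct_tol("stochastic")`.
#' @return a tibble of violations with columns `where` and `message`;
#'   zero rows when the chain is valid.
#' @export
validate_chain <- function(chain, tol = ct_tol("stochastic")) {
  out <- list()
  note <- function(where, message) {
    out[[length(out) + 1]] <<- tibble(where = where, message = message)
  }
  if (any(chain$p0 < 0)) note("p0", "p0 has negative entries")
  if (abs(sum(chain$p0) - 1) > tol) {
    note("p0", sprintf("p0 sums to %.12g, not 1", sum(chain$p0)))
  }
  if (!is.finite(chain$beta) || chain$beta <= 0) {
    note("beta", "beta must be a positive real")
  }
  for (n in seq_along(chain$matrices)) {
    M <- chain$matrices[[n]]
    if (any(M < 0)) note(sprintf("M%d", n), sprintf("M%d has negative entries", n))
    cs <- colSums(M)
    off <- which(abs(cs - 1) > tol)
    for (j in off) {
      note(
        sprintf("M%d[, %d]", n, j),
        sprintf("column %d (source state %s) of M%d sums to %.12g, not 1",
                j, chain$states[j], n, cs[j])
      )
    }
  }
  if (length(out) == 0) {
    tibble(where = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Irreducibility of a transition matrix
#'
#' A matrix is irreducible when every state can reach every other: for each
#' pair `(x, y)` some power `m` has `(M^m)[x, y] > 0`. For finite matrices
#' this is strong connectivity of the directed graph with an edge `y -> x`
#' whenever `M[x, y] > 0`.
#'
#' @param M a square nonnegative (column-stochastic) matrix.
#' @return `TRUE` iff the positive-entry digraph is strongly connected.
#' @export
is_irreducible <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) abort("M must be square")
  g <- igraph::graph_from_adjacency_matrix(t(M) > 0, mode = "directed")
  igraph::is_connected(g, mode = "strong")
}

#' Stationary distribution of an irreducible transition matrix
#'
#' Solves `M p = p` by a least-squares null-space solve of `(M - I)` with the
#' normalisation `sum(p) = 1` appended, then cross-checks the residual. An
#' irreducible matrix has a unique stationary distribution with strictly
#' positive entries; reducible input is refused rather than returning an
#' arbitrary element of the stationary set, because uniqueness underpins the
#' energy-family construction downstream. Aperiodicity is not required:
#' permutation cycles are first-class inputs.
#'
#' @param M square column-stochastic matrix.
#' @param tol residual tolerance; defaults to `ct_tol("stationary")`.
#' @return a probability vector `p` (named like `M`'s rows) with `M p = p`.
#' @export
stationary_distribution <- function(M, tol = ct_tol("stationary")) {
  M <- as.matrix(M)
  if (!is_irreducible(M)) {
    abort("M is reducible: the stationary distribution is not unique")
  }
  k <- nrow(M)
  A <- rbind(M - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  p <- as.numeric(qr.solve(A, b))
  p <- p / sum(p)
  resid <- max(abs(as.numeric(M %*% p) - p))
  if (resid > tol) {
    abort(sprintf("stationary solve residual %.3g exceeds tol %.3g", resid, tol))
  }
  if (any(p <= 0)) {
    abort("stationary solve produced non-positive entries on an irreducible matrix")
  }
  setNames(p, rownames(M))
}

#' Detailed balance of a matrix with respect to a distribution
#'
#' Checks the pairwise flow balance `M[y, x] p(x) = M[x, y] p(y)` for all
#' state pairs. A distribution satisfying detailed balance is stationary for
#' `M`; detailed balance is what turns a steady state into an equilibrium
#' state, and (per matrix) is equivalent to microscopic reversibility of the
#' whole chain.
#'
#' @param M square column-stochastic matrix.
#' @param p probability vector of matching length.
#' @param tol absolute tolerance on each flow difference.
#' @return `TRUE` iff all pairwise flows balance within `tol`.
#' @export
satisfies_detailed_balance <- function(M, p, tol = ct_tol("stochastic")) {
  M <- as.matrix(M)
  if (length(p) != nrow(M) || nrow(M) != ncol(M)) {
    abort("dimension mismatch between M and p")
  }
  flow <- M * matrix(p, nrow(M), ncol(M), byrow = TRUE) # flow[x, y] = M[x,y] p(y)
  max(abs(flow - t(flow))) <= tol
}

# map state labels (or indices) to validated integer indices
.traj_index <- function(chain, x) {
  if (is.numeric(x)) {
    idx <- as.integer(x)
    if (any(idx < 1 | idx > length(chain$states))) {
      abort("trajectory state index out of range")
    }
  } else {
    idx <- match(as.character(x), chain$states)
    if (anyNA(idx)) {
      abort(sprintf(
        "trajectory label(s) not in the state set: %s",
        paste(unique(x[is.na(idx)]), collapse = ", ")
      ))
    }
  }
  if (length(idx) != chain$n_steps + 1) {
    abort(sprintf(
      "trajectory has length %d; the chain needs N + 1 = %d states",
      length(idx), chain$n_steps + 1
    ))
  }
  idx
}

#' Probability of a single trajectory
#'
#' Returns `p0(x0) * prod_n M_n(x_n, x_{n-1})`, the path probability of the
#' realization `x = (x0, ..., xN)` under the chain.
#'
#' @param chain a [driven_chain()].
#' @param x a vector of `N + 1` state labels (or integer state indices).
#' @return the path probability, in `[0, 1]`.
#' @export
trajectory_probability <- function(chain, x) {
  idx <- .traj_index(chain, x)
  p <- chain$p0[[idx[1]]]
  for (n in seq_len(chain$n_steps)) {
    p <- p * chain$matrices[[n]][idx[n + 1], idx[n]]
  }
  unname(p)
}

# integer index matrix (rows = trajectories, cols = time 0..N) -> probabilities
.path_probs <- function(chain, idx) {
  p <- chain$p0[idx[, 1]]
  for (n in seq_len(chain$n_steps)) {
    p <- p * chain$matrices[[n]][cbind(idx[, n + 1], idx[, n])]
  }
  unname(p)
}

.ensemble_tibble <- function(chain, idx, weights, provenance) {
  cols <- lapply(seq_len(ncol(idx)), function(j) chain$states[idx[, j]])
  names(cols) <- paste0("x", seq_len(ncol(idx)) - 1)
  out <- as_tibble(cols)
  out[[attr(provenance, "weight_col")]] <- weights
  attr(out, "provenance") <- provenance
  attr(out, "index") <- idx
  class(out) <- c("trajectory_ensemble", class(out))
  out
}

#' Exhaustive trajectory enumeration
#'
#' Enumerates all `|S|^(N+1)` trajectories of the chain with their exact path
#' probabilities. This is the workhorse behind every exact expectation in the
#' package (Jarzynski sums, work distributions, Crooks reports).
#'
#' @param chain a [driven_chain()].
#' @param cap refuse enumeration when the trajectory count exceeds this.
#' @return a `trajectory_ensemble` tibble with state columns `x0..xN` and a
#'   `prob` column summing to 1; provenance is recorded in an attribute.
#' @export
enumerate_trajectories <- function(chain, cap = 1e6) {
  k <- length(chain$states)
  n_traj <- k^(chain$n_steps + 1)
  if (n_traj > cap) {
    abort(sprintf(
      "enumeration needs %.0f trajectories, above cap = %.0f", n_traj, cap
    ))
  }
  idx <- as.matrix(expand.grid(rep(list(seq_len(k)), chain$n_steps + 1),
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(idx) <- NULL
  prov <- structure(list(type = "enumerated"), weight_col = "prob")
  .ensemble_tibble(chain, idx, .path_probs(chain, idx), prov)
}

#' Monte Carlo trajectory sampling
#'
#' Draws `n` independent trajectories: `x0 ~ p0`, then `x_n` from column
#' `x_{n-1}` of `M_n`. Reproducible: the seed is applied locally and recorded
#' in the ensemble's provenance.
#'
#' @param chain a [driven_chain()].
#' @param n number of draws (`>= 1`).
#' @param seed integer seed.
#' @return a `trajectory_ensemble` tibble with one row per draw and a
#'   `weight` column of ones.
#' @export
sample_trajectories <- function(chain, n, seed) {
  if (n < 1) abort("n must be >= 1")
  k <- length(chain$states)
  idx <- withr::with_seed(seed, {
    out <- matrix(0L, n, chain$n_steps + 1)
    out[, 1] <- sample.int(k, n, replace = TRUE, prob = chain$p0)
    for (step in seq_len(chain$n_steps)) {
      M <- chain$matrices[[step]]
      cur <- out[, step]
      nxt <- integer(n)
      for (s in seq_len(k)) {
        hit <- which(cur == s)
        if (length(hit)) {
          nxt[hit] <- sample.int(k, length(hit), replace = TRUE, prob = M[, s])
        }
      }
      out[, step + 1] <- nxt
    }
    out
  })
  prov <- structure(list(type = "sampled", seed = seed, n = n),
                    weight_col = "weight")
  .ensemble_tibble(chain, idx, rep(1, n), prov)
}
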