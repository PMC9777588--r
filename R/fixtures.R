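#' Two-state equilibrium fixture
#'
#' A minimal two-step, two-state chain on which every identity in the package
#' can be checked by hand: `p0 = (2/3, 1/3)` is stationary for
#' `M1 = [[0.9, 0.2], [0.1, 0.8]]`, and `M2 = [[0.7, 0.3], [0.3, 0.7]]` is
#' symmetric with stationary `(1/2, 1/2)`. Both matrices satisfy detailed
#' balance (every irreducible 2-state matrix does), `p0 = p1`, so the Crooks
#' identity holds with `k = 0` and the time reversal is the genuine backward
#' process. Zero-gauge energies: `E0 = E1 = (log 3/2, log 3)`,
#' `E2 = (log 2, log 2)`.
#'
#' @return a list with elements `chain` ([driven_chain()]) and `family`
#'   ([energy_family()]).
#' @export
two_state_chain <- function() {
  M1 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)
  M2 <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  chain <- driven_chain(c("0", "1"), c(2 / 3, 1 / 3), list(M1, M2), beta = 1)
  list(chain = chain, family = energy_family(chain))
}

#' Crooks counterexample chain
#'
#' The constructed chain on which the discrete-time Crooks identity fails at
#' every work value, showing that `p0` being stationary for `M1` is a genuine
#' hypothesis and not a convenience. Three states `{A, B, C}`, one step,
#' `beta = 1`, `p0 = (a, b, c)` with `b < c`, and the rank-one matrix `M1`
#' with rows `(a, a, a)`, `(c, c, c)`, `(b, b, b)` (column-stochastic since
#' `a + b + c = 1`). `M1` has stationary distribution `p1 = (a, c, b)` and
#' satisfies detailed balance with respect to it, yet `p0 != p1`. The
#' zero-gauge energies are `E0 = (log 1/a, log 1/b, log 1/c)` and `E1` with
#' the `B`/`C` values of `E0` swapped, so the three possible work values are
#' `wA = 0`, `wB = log(b/c) < 0`, `wC = log(c/b) > 0`, while the time
#' reversal's work is identically zero — the backward distribution is a point
#' mass at 0, leaving the ratio undefined at `wB`, `wC` and false (equal to
#' `a`, not 1) at `wA`.
#'
#' @param a,b,c strictly positive reals with `b < c` and `a + b + c = 1`.
#' @return a list with elements `chain` and `family`.
#' @export
crooks_counterexample <- function(a = 0.5, b = 0.2, c = 0.3) {
  if (any(c(a, b, c) <= 0)) abort("a, b, c must be strictly positive")
  if (!(b < c)) abort("the construction requires b < c (strict)")
  if (abs(a + b + c - 1) > 1e-12) abort("a + b + c must equal 1")
  M1 <- rbind(rep(a, 3), rep(c, 3), rep(b, 3))
  chain <- driven_chain(c("A", "B", "C"), c(a, b, c), list(M1), beta = 1)
  family <- energy_family(chain)
  # construction guarantees: p1 = (a, c, b), detailed balance, p0 != p1,
  # E1 = E0 with the B and C values swapped
  p1 <- stationary_distribution(M1)
  stopifnot(max(abs(p1 - c(a, c, b))) <= 1e-12,
            satisfies_detailed_balance(M1, p1, 1e-12))
  list(chain = chain, family = family)
}

#' Cyclic permutation fixture
#'
#' A deterministic 3-state cycle `A -> B -> C -> A` repeated `n_steps` times,
#' with uniform `p0`. Irreducible but periodic and maximally non-reversible:
#' the auxiliary reversed chain is the transposed (reverse) cycle.
#'
#' @param n_steps number of steps.
#' @return a list with elements `chain` and `family`.
#' @export
cycle_chain <- function(n_steps = 2) {
  M <- matrix(0, 3, 3)
  M[2, 1] <- M[3, 2] <- M[1, 3] <- 1 # A -> B -> C -> A
  chain <- driven_chain(c("A", "B", "C"), rep(1 / 3, 3),
                        rep(list(M), n_steps), beta = 1)
  list(chain = chain, family = energy_family(chain))
}

#' Seeded random driven chains
#'
#' Generates reproducible chains of three classes used throughout the test
#' properties:
#' \describe{
#'   \item{`generic`}{column-stochastic matrices with every entry at least
#'     `floor` (hence irreducible), random strictly positive `p0`;}
#'   \item{`detailed_balance`}{each matrix is a Metropolis matrix against a
#'     random strictly positive target, hence reversible;
#'     `p0_stationary = TRUE` sets `p0` to the stationary distribution of the
#'     first matrix, satisfying the Crooks hypothesis `p0 = p1`;}
#'   \item{`permutation`}{a random single-cycle permutation matrix at every
#'     step (irreducible, periodic, non-reversible for `|S| > 2`), uniform
#'     `p0`.}
#' }
#'
#' @param n_states number of states (`>= 2`).
#' @param n_steps number of steps (`>= 1`).
#' @param seed integer seed; the same spec always returns the same chain.
#' @param mode one of `"generic"`, `"detailed_balance"`, `"permutation"`.
#' @param floor positivity floor for `generic` entries and probabilities.
#' @param p0_stationary for `detailed_balance` mode, equilibrate `p0` to `M1`.
#' @param beta inverse temperature of the generated chain.
#' @return a [driven_chain()].
#' @export
random_chain <- function(n_states, n_steps, seed,
                         mode = c("generic", "detailed_balance", "permutation"),
                         floor = 1e-3, p0_stationary = FALSE, beta = 1) {
  mode <- match.arg(mode)
  if (n_states < 2 || n_steps < 1) abort("need n_states >= 2 and n_steps >= 1")
  states <- LETTERS[seq_len(n_states)]
  if (n_states > 26) states <- paste0("s", seq_len(n_states))
  withr::with_seed(seed, {
    rand_prob <- function() {
      p <- stats::runif(n_states) + floor
      p / sum(p)
    }
    mats <- switch(mode,
      generic = replicate(n_steps, {
        M <- matrix(stats::runif(n_states^2) + floor, n_states, n_states)
        sweep(M, 2, colSums(M), "/")
      }, simplify = FALSE),
      detailed_balance = replicate(n_steps, {
        policy_transition_matrix(rand_prob(), "uniform")
      }, simplify = FALSE),
      permutation = replicate(n_steps, {
        perm <- c(sample(seq_len(n_states))) # a random cycle order
        M <- matrix(0, n_states, n_states)
        for (i in seq_len(n_states)) {
          M[perm[i %% n_states + 1], perm[i]] <- 1
        }
        M
      }, simplify = FALSE)
    )
    p0 <- switch(mode,
      generic = rand_prob(),
      detailed_balance = if (p0_stationary) {
        stationary_distribution(mats[[1]])
      } else {
        rand_prob()
      },
      permutation = rep(1 / n_states, n_states)
    )
    driven_chain(states, p0, mats, beta = beta)
  })
}
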