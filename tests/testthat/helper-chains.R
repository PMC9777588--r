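# shared fixtures and small generators for the suite

db2 <- two_state_chain()
prop3 <- crooks_counterexample(0.5, 0.2, 0.3)
cyc <- cycle_chain(2)

# a chain whose energies are all identical: every matrix shares p0 as its
# stationary distribution (Metropolis against p0), p0 equilibrated
all_equal_chain <- function(n_steps = 2) {
  p <- c(0.5, 0.3, 0.2)
  names(p) <- c("A", "B", "C")
  M <- policy_transition_matrix(p, "uniform")
  chain <- driven_chain(names(p), p, rep(list(M), n_steps), beta = 1)
  list(chain = chain, family = energy_family(chain))
}

# random sizes drawn reproducibly for property loops
random_case <- function(seed, mode = "generic", p0_stationary = FALSE) {
  withr::with_seed(seed * 7919L, {
    k <- sample(2:5, 1)
    N <- sample(1:4, 1)
    beta <- stats::runif(1, 0.5, 2)
    list(
      chain = random_chain(k, N, seed, mode = mode,
                           p0_stationary = p0_stationary, beta = beta),
      seed = seed
    )
  })
}

random_gauges <- function(n, seed) {
  withr::with_seed(seed, stats::runif(n, -3, 3))
}
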