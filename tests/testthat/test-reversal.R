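test_that("the auxiliary chain of a uniform cycle is the reverse cycle", {
  aux <- auxiliary_reverse_chain(cyc$chain)
  for (n in seq_len(cyc$chain$n_steps)) {
    expect_equal(unname(aux$matrices[[n]]),
                 t(unname(cyc$chain$matrices[[cyc$chain$n_steps - n + 1]])),
                 tolerance = 1e-12)
  }
  expect_equal(unname(aux$p0), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("under detailed balance the auxiliary matrices are the reversed forward ones", {
  aux <- auxiliary_reverse_chain(db2$chain)
  expect_equal(unname(aux$matrices[[1]]), unname(db2$chain$matrices[[2]]),
               tolerance = 1e-12)
  expect_equal(unname(aux$matrices[[2]]), unname(db2$chain$matrices[[1]]),
               tolerance = 1e-12)
})

test_that("auxiliary matrices are stochastic and inherit the right stationary laws", {
  for (seed in 1:100) {
    case <- random_case(seed)
    chain <- case$chain
    ps <- lapply(chain$matrices, stationary_distribution)
    aux <- auxiliary_reverse_chain(chain)
    N <- chain$n_steps
    for (n in seq_len(N)) {
      Mhat <- aux$matrices[[n]]
      expect_lt(max(abs(colSums(Mhat) - 1)), 1e-12)
      p <- ps[[N - (n - 1)]]
      expect_lt(max(abs(as.numeric(Mhat %*% p) - p)), 1e-10)
    }
  }
})

test_that("time reversal starts at pN and reverses the matrix order", {
  tr <- time_reversal(db2$chain)
  expect_equal(unname(tr$p0), c(0.5, 0.5), tolerance = 1e-12)
  expect_identical(unname(tr$matrices[[1]]), unname(db2$chain$matrices[[2]]))
  expect_identical(unname(tr$matrices[[2]]), unname(db2$chain$matrices[[1]]))

  tr3 <- time_reversal(prop3$chain)
  expect_equal(unname(tr3$p0), c(0.5, 0.3, 0.2), tolerance = 1e-12)
  expect_identical(unname(tr3$matrices[[1]]),
                   unname(prop3$chain$matrices[[1]]))

  ae <- all_equal_chain()
  trae <- time_reversal(ae$chain)
  expect_equal(unname(trae$matrices[[1]]), unname(ae$chain$matrices[[1]]),
               tolerance = 1e-12)
  expect_equal(trae$p0, ae$chain$p0, tolerance = 1e-12)

  # involution under detailed balance with all matrices equal
  twice <- time_reversal(time_reversal(ae$chain))
  for (n in seq_len(ae$chain$n_steps)) {
    expect_equal(unname(twice$matrices[[n]]), unname(ae$chain$matrices[[n]]),
                 tolerance = 1e-12)
  }
})

test_that("microscopic reversibility is detected by both criteria", {
  expect_true(is_microscopically_reversible(db2$chain))
  expect_true(is_microscopically_reversible(prop3$chain))
  expect_false(is_microscopically_reversible(cyc$chain))
})

test_that("detailed balance and auxiliary-equals-reversal are equivalent over random chains", {
  n_diff <- 0
  for (seed in 1:100) {
    chain_db <- random_case(seed, mode = "detailed_balance")$chain
    expect_true(is_microscopically_reversible(chain_db, tol = 1e-10))

    chain_g <- random_case(seed, mode = "generic")$chain
    db <- all(vapply(chain_g$matrices, function(M) {
      satisfies_detailed_balance(M, stationary_distribution(M), 1e-10)
    }, logical(1)))
    if (!db) {
      n_diff <- n_diff + 1
      aux <- auxiliary_reverse_chain(chain_g)
      tr <- time_reversal(chain_g)
      gap <- max(vapply(seq_len(chain_g$n_steps), function(n) {
        max(abs(aux$matrices[[n]] - tr$matrices[[n]]))
      }, numeric(1)))
      expect_gt(gap, 1e-10)
    }
  }
  expect_gt(n_diff, 50) # generic chains are overwhelmingly non-reversible
})

test_that("reversal energies reuse the forward functions in reversed order", {
  # N = 2: (E0, E1, E2) -> (E2, E2, E1)
  rf <- reversal_energy_family(db2$family)
  expect_equal(rf$energies[[1]], db2$family$energies[[3]])
  expect_equal(rf$energies[[2]], db2$family$energies[[3]])
  expect_equal(rf$energies[[3]], db2$family$energies[[2]])

  # N = 1: reversal fixes both steps to E1
  rf3 <- reversal_energy_family(prop3$family)
  expect_equal(rf3$energies[[1]], prop3$family$energies[[2]])
  expect_equal(rf3$energies[[2]], prop3$family$energies[[2]])

  ae <- all_equal_chain()
  rfe <- reversal_energy_family(ae$family)
  for (E in rfe$energies) expect_equal(E, ae$family$energies[[1]])
})

test_that("the work-reversal constant is zero with reversal energies, linear in gauges", {
  rf <- reversal_energy_family(db2$family)
  expect_equal(work_reversal_constant(db2$family, rf), 0, tolerance = 1e-12)

  shifted <- rf
  N <- db2$family$n_steps
  shifted$energies[[N + 1]] <- shifted$energies[[N + 1]] + 3
  expect_equal(work_reversal_constant(db2$family, shifted), 3,
               tolerance = 1e-12)

  # an inconsistent family (not constant against the references) is refused
  bad <- rf
  bad$energies[[N + 1]] <- bad$energies[[N + 1]] + c(0, 1)
  expect_error(work_reversal_constant(db2$family, bad), "inconsistent")
})

test_that("work is odd under time reversal on the equilibrated fixture", {
  pair <- reversal_pair(db2$chain, db2$family)
  expect_equal(pair$kind, "time_reversal")
  expect_equal(pair$k, 0, tolerance = 1e-12)
  expect_lt(verify_work_reversal(pair), 1e-12)
})

test_that("the general work-reversal identity carries the E1 - E0 boundary term", {
  # non-equilibrated start: E1(x0) != E0(x0) in general
  for (seed in 1:25) {
    case <- random_case(seed)
    pair <- reversal_pair(case$chain, energy_family(case$chain))
    expect_lt(verify_work_reversal(pair), 1e-11)
  }

  # explicit per-trajectory check of the boundary term on one generic chain
  chain <- random_chain(3, 2, 5)
  fam <- energy_family(chain)
  pair <- reversal_pair(chain, fam, kind = "auxiliary")
  ens <- enumerate_trajectories(chain)
  idx <- attr(ens, "index")
  E1 <- fam$energies[[2]]
  E0 <- fam$energies[[1]]
  for (i in seq_len(nrow(idx))) {
    x <- idx[i, ]
    lhs <- work(rev(x), pair$backward$family)
    rhs <- -work(x, fam) + E1[[x[1]]] - E0[[x[1]]] + pair$k
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }

  ae <- all_equal_chain()
  expect_lt(verify_work_reversal(reversal_pair(ae$chain, ae$family)), 1e-12)
})
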