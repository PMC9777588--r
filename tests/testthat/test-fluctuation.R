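test_that("the exact Jarzynski expectation is 1 on the fixtures", {
  # hand sums: 0.5*1 + 0.2*(3/2) + 0.3*(2/3) and (2/3)(3/4) + (1/3)(3/2)
  expect_equal(jarzynski_exact(prop3$chain, prop3$family), 1, tolerance = 1e-12)
  expect_equal(jarzynski_exact(db2$chain, db2$family), 1, tolerance = 1e-12)
  expect_equal(jarzynski_exact(cyc$chain, cyc$family), 1, tolerance = 1e-12)
})

test_that("the Jarzynski identity is gauge-covariant and hypothesis-guarded", {
  for (seed in 1:50) {
    case <- random_case(seed)
    g <- random_gauges(case$chain$n_steps + 1, seed + 500)
    fam <- energy_family(case$chain, gauges = g)
    expect_equal(jarzynski_exact(case$chain, fam), 1, tolerance = 1e-9)
  }
  reducible <- driven_chain(c("A", "B"), c(0.5, 0.5), list(diag(2)))
  expect_error(jarzynski_exact(reducible), "reducible")
})

test_that("the Monte Carlo Jarzynski estimator is unbiased and reproducible", {
  est <- jarzynski_mc(db2$chain, db2$family, n = 1e5, seed = 3)
  expect_lt(abs(est$estimate - 1), 5 * est$se)

  est2 <- jarzynski_mc(db2$chain, db2$family, n = 1e5, seed = 3)
  expect_identical(est$estimate, est2$estimate)

  # degenerate work: on the uniform cycle every trajectory has W = 0, so the
  # estimator is exactly 1 with zero standard error
  est_cyc <- jarzynski_mc(cyc$chain, cyc$family, n = 100, seed = 1)
  expect_equal(est_cyc$estimate, 1, tolerance = 1e-12)
  expect_equal(est_cyc$se, 0, tolerance = 1e-12)
})

test_that("the per-trajectory ratio identity holds against the auxiliary chain", {
  # hand values: P(X=(0,0,0)) = 0.42, P(Y=(0,0,0)) = 0.315, ratio 4/3
  aux <- auxiliary_reverse_chain(db2$chain)
  expect_equal(trajectory_probability(db2$chain, c("0", "0", "0")), 0.42,
               tolerance = 1e-12)
  expect_equal(trajectory_probability(aux, c("0", "0", "0")), 0.315,
               tolerance = 1e-12)
  expect_lt(trajectory_ratio_check(db2$chain, db2$family), 1e-12)

  # all energies and references equal: P(X = x) = P(Y = xR) exactly
  ae <- all_equal_chain()
  ens <- enumerate_trajectories(ae$chain)
  idx <- attr(ens, "index")
  aux_ae <- auxiliary_reverse_chain(ae$chain)
  for (i in seq_len(nrow(idx))) {
    expect_equal(trajectory_probability(ae$chain, idx[i, ]),
                 trajectory_probability(aux_ae, rev(idx[i, ])),
                 tolerance = 1e-12)
  }

  for (seed in 1:100) {
    case <- random_case(seed)
    expect_lt(trajectory_ratio_check(case$chain, energy_family(case$chain)),
              1e-10)
  }
})

test_that("hysteresis equals the dissipated work through both routes", {
  expect_equal(hysteresis(db2$chain, db2$family, c("0", "0", "0")), log(4 / 3),
               tolerance = 1e-12)
  # no hysteresis when W(x) = delta_F
  ae <- all_equal_chain()
  expect_equal(hysteresis(ae$chain, ae$family, c("A", "B", "C")), 0,
               tolerance = 1e-12)
  expect_error(hysteresis(cyc$chain, cyc$family, c("A", "B", "C")),
               "not microscopically reversible")
})

test_that("work distributions match the hand-derived atoms", {
  wd <- work_distribution(prop3$chain, prop3$family)
  expect_equal(wd$work, sort(c(log(2 / 3), 0, log(3 / 2))), tolerance = 1e-12)
  expect_equal(wd$prob[order(wd$work)], c(0.2, 0.5, 0.3), tolerance = 1e-12)
  expect_equal(sum(wd$prob), 1, tolerance = 1e-12)

  # the time reversal of the counterexample does no work at all
  tr <- time_reversal(prop3$chain)
  wd_rev <- work_distribution(tr, reversal_energy_family(prop3$family))
  expect_equal(nrow(wd_rev), 1)
  expect_equal(wd_rev$work, 0, tolerance = 1e-12)
  expect_equal(wd_rev$prob, 1, tolerance = 1e-12)

  wd2 <- work_distribution(db2$chain, db2$family)
  expect_equal(wd2$work, sort(c(log(2 / 3), log(4 / 3))), tolerance = 1e-12)
  expect_equal(wd2$prob, c(1 / 3, 2 / 3), tolerance = 1e-12)

  # forward support maps onto backward support under w -> -w (equilibrated)
  bwd2 <- work_distribution(time_reversal(db2$chain),
                            reversal_energy_family(db2$family))
  expect_equal(sum(bwd2$prob), 1, tolerance = 1e-12)
  expect_equal(sort(-bwd2$work), wd2$work, tolerance = 1e-12)
})

test_that("the Crooks report certifies the equilibrated fixture", {
  rep <- crooks_report(db2$chain, db2$family)
  expect_true(rep$holds)
  expect_true(rep$p0_is_stationary_of_M1)
  expect_equal(rep$kind, "time_reversal")
  row <- rep$table[abs(rep$table$work - log(4 / 3)) < 1e-9, ]
  expect_equal(row$p_forward, 2 / 3, tolerance = 1e-12)
  expect_equal(row$p_backward, 1 / 2, tolerance = 1e-12)
  expect_equal(row$observed_ratio, 4 / 3, tolerance = 1e-12)
  expect_equal(row$predicted_ratio, exp(log(4 / 3)), tolerance = 1e-12)

  # degenerate case: a single support point at w = 0 with ratio 1
  ae <- all_equal_chain()
  rep_ae <- crooks_report(ae$chain, ae$family)
  expect_true(rep_ae$holds)
  expect_equal(nrow(rep_ae$table), 1)
  expect_equal(rep_ae$table$observed_ratio, 1, tolerance = 1e-12)
})

test_that("the Crooks report exhibits the counterexample instead of refusing", {
  rep <- crooks_report(prop3$chain, prop3$family)
  expect_false(rep$holds)
  expect_false(rep$p0_is_stationary_of_M1)
  tab <- rep$table[order(rep$table$work), ]
  # undefined at wB < 0 and wC > 0, defined-but-false at wA = 0
  expect_identical(tab$defined, c(FALSE, TRUE, FALSE))
  wA_row <- tab[2, ]
  expect_equal(wA_row$observed_ratio, 0.5, tolerance = 1e-12)
  expect_equal(wA_row$predicted_ratio, 1, tolerance = 1e-12)
})

test_that("Crooks holds on random reversible equilibrated chains", {
  for (seed in 1:50) {
    case <- random_case(seed, mode = "detailed_balance", p0_stationary = TRUE)
    rep <- crooks_report(case$chain, energy_family(case$chain))
    expect_true(rep$p0_is_stationary_of_M1)
    expect_true(rep$holds)
  }
})

test_that("the second-law gap is the expected dissipated work and never negative", {
  expect_equal(second_law_gap(prop3$chain, prop3$family), 0.1 * log(3 / 2),
               tolerance = 1e-12)
  ae <- all_equal_chain()
  expect_equal(second_law_gap(ae$chain, ae$family), 0, tolerance = 1e-15)
  for (seed in 1:100) {
    case <- random_case(seed)
    expect_gt(second_law_gap(case$chain, energy_family(case$chain)), -1e-12)
  }
})
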