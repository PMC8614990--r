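test_that("sample_parameters honours the NOR = +/-3 sd convention", {
  ch <- mono_chain()
  # degenerate NOR: every draw equals the set point
  p0 <- process_parameter("x", "UO1", 5, 5, 5, 4, 6)
  ch0 <- process_chain(ch$unit_operations, list(p0), ch$cqas)
  expect_true(all(sample_parameters(ch0, 100, rng_seed = 1) == 5))
  # NOR half-width h: empirical sd over many draws ~ h/3
  draws <- sample_parameters(ch, 1e5, rng_seed = 2)[, "x"]
  h <- 0.25
  expect_equal(stats::sd(draws), h / 3, tolerance = 0.02)
  expect_equal(mean(draws), 5, tolerance = 0.01)
  # fixing contract and screening-range validation
  fx <- sample_parameters(ch, 50, fixed_parameter = "x", fixed_value = 4,
                          rng_seed = 3)
  expect_true(all(fx[, "x"] == 4))
  expect_error(sample_parameters(ch, 10, fixed_parameter = "x",
                                 fixed_value = 3.5),
               "outside screening range")
})

test_that("ooa_probability matches the chi-square/normal-tail oracle", {
  # n = 5, gamma = 0.95, s = 1: s* from the chi-square quantile
  set.seed(4)
  v <- stats::rnorm(5)
  v <- (v - mean(v)) / stats::sd(v)  # exact mean 0, sd 1
  sstar <- sqrt(4 / stats::qchisq(0.05, df = 4))
  expect_equal(sstar, 2.372, tolerance = 1e-3)
  expect_equal(ooa_probability(v, usl = 2),
               100 * stats::pnorm((2 - 0) / sstar, lower.tail = FALSE),
               tolerance = 1e-12)
  # the inflation makes the estimate strictly larger than with plain s
  expect_gt(ooa_probability(v, usl = 2),
            100 * stats::pnorm(2, lower.tail = FALSE))
  # mean exactly at the single upper limit: 50%
  expect_equal(ooa_probability(v, usl = 0), 50)
  # mean far inside wide limits: ~0
  expect_lt(ooa_probability(v, lsl = -100, usl = 100), 1e-10)
  # both limits infinite: exactly 0
  expect_identical(ooa_probability(v, lsl = -Inf, usl = Inf), 0)
  # degenerate sample rule
  expect_equal(ooa_probability(rep(5, 10), usl = 4), 100)
  expect_equal(ooa_probability(rep(5, 10), usl = 6), 0)
  expect_equal(ooa_probability(rep(5, 10), usl = 5), 100)
  # error paths
  expect_error(ooa_probability(1), ">= 2 values")
  expect_error(ooa_probability(c(1, 2)), "at least one acceptance limit")
})

test_that("s* is conservative and shrinks towards s as n grows", {
  ratio <- vapply(3:100, function(n)
    sqrt((n - 1) / stats::qchisq(0.05, df = n - 1)), numeric(1))
  expect_true(all(ratio > 1))
  expect_true(all(diff(ratio) < 0))
  # conservatism of the OOA estimate itself when the mean is inside limits
  set.seed(9)
  for (r in 1:20) {
    v <- stats::rnorm(10, 0, 1)
    plain <- 100 * (stats::pnorm((-3 - mean(v)) / stats::sd(v)) +
                      stats::pnorm((3 - mean(v)) / stats::sd(v),
                                   lower.tail = FALSE))
    expect_gte(ooa_probability(v, lsl = -3, usl = 3), plain)
  }
})

test_that("run_ipm collapses to the deterministic propagation without noise", {
  ch <- fixed_chain(c(0.5, 0.4, 0.9), start_mean = 100, start_sd = 0)
  sim <- run_ipm(ch, n = 10, rng_seed = 1)
  expect_true(all(sim$ds_values[, "imp"] == 18))
  expect_equal(unname(sim$ooa["imp"]), 0)
  expect_equal(sim$clamp_count, 0L)
})

test_that("pass-through chain with limits at +/-2 sd gives OOA near 4.55%", {
  ch <- pass_chain(K = 3, start_mean = 50, start_sd = 2)
  sim <- run_ipm(ch, n = 20000, rng_seed = 6)
  # s* -> s at large n; 2 * pnorm(-2) = 4.55%, mildly inflated by s*
  expect_gt(unname(sim$ooa["imp"]), 3.8)
  expect_lt(unname(sim$ooa["imp"]), 5.6)
  # dual route: empirical fraction outside limits agrees with the
  # parametric value within 3 Monte-Carlo standard errors
  emp <- 100 * mean(sim$ds_values[, "imp"] <= 46 |
                      sim$ds_values[, "imp"] >= 54)
  se <- 100 * sqrt(0.0455 * (1 - 0.0455) / sim$n_cycles)
  expect_lt(abs(emp - unname(sim$ooa["imp"])), 3 * se + 0.2)
})

test_that("identical seeds reproduce simulations bit for bit", {
  gen <- make_chain(synthetic_spec(rng_seed = 5))
  s1 <- run_ipm(gen$chain, n = 200, rng_seed = 99)
  s2 <- run_ipm(gen$chain, n = 200, rng_seed = 99)
  expect_identical(s1$ds_values, s2$ds_values)
  expect_identical(s1$ooa, s2$ooa)
  s3 <- run_ipm(gen$chain, n = 200, rng_seed = 100)
  expect_false(identical(s1$ds_values, s3$ds_values))
})

test_that("simulation results satisfy their structural invariants", {
  gen <- make_chain(synthetic_spec(rng_seed = 2))
  sim <- run_ipm(gen$chain, n = 150, rng_seed = 3)
  expect_equal(dim(sim$ds_values), c(150L, 4L))
  expect_true(all(sim$ooa >= 0 & sim$ooa <= 100))
  expect_equal(dim(sim$pool_conc), c(150L, 8L, 4L))
  # drug substance equals the pool of the last unit operation
  expect_identical(unname(sim$ds_values), unname(sim$pool_conc[, 8L, ]))
})

test_that("plausibility_report compares simulated and observed runs", {
  gen <- make_chain(synthetic_spec(rng_seed = 8))
  sim <- run_ipm(gen$chain, n = 2000, rng_seed = 21)
  obs <- generate_manufacturing_runs(gen$chain, n = 500, rng_seed = 22)
  rep <- plausibility_report(sim, obs)
  # self-consistency: observed data produced by the simulator itself, at
  # large n the per-cell means agree closely
  rel <- abs(rep$by_uo_cqa$sim_mean - rep$by_uo_cqa$obs_mean) /
    rep$by_uo_cqa$sim_mean
  expect_lt(max(rel), 0.02)
  expect_true(all(c("sim_ooa", "obs_ooa", "n_obs") %in% names(rep$ooa)))
  # sparse observed data: the s* inflation at n = 5 is material
  obs5 <- generate_manufacturing_runs(gen$chain, n = 5, rng_seed = 23)
  rep5 <- plausibility_report(sim, obs5)
  expect_true(all(rep5$ooa$n_obs == 5))
  # errors: unknown CQA, empty table
  bad <- obs5; bad$cqa[1] <- "ghost"
  expect_error(plausibility_report(sim, bad), "ghost")
  expect_error(plausibility_report(sim, obs5[0, ]), "empty")
})
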