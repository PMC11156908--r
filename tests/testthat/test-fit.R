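test_that("SSR is the SD-weighted residual sum", {
  net <- toy_chain()
  sim <- simulate_labeling(net, toy_chain_fluxes(), toy_chain_pools,
                           times = c(0, 60, 300))
  d <- as.data.frame(sim)
  meas <- measurement_set(data.frame(
    metabolite = d$metabolite, mass = d$mass, time_s = d$time_s,
    value = d$mole_fraction, sd = 0.01))
  expect_equal(ssr(sim, meas), 0)
  # one residual of 2 sd -> SSR = 4
  meas$mids$value[5] <- meas$mids$value[5] + 0.02
  expect_equal(ssr(sim, meas), 4, tolerance = 1e-9)
  # missing simulated counterpart
  meas$mids$metabolite[1] <- "GHOST"
  expect_error(ssr(sim, meas), "no simulated counterpart")
})

test_that("SSR at the truth is chi-square distributed", {
  net <- toy_chain()
  sim <- simulate_labeling(net, toy_chain_fluxes(), toy_chain_pools,
                           times = c(0, 60, 300))
  d <- as.data.frame(sim)
  sdv <- 0.01
  set.seed(99)
  n <- nrow(d)
  ssrs <- replicate(200, {
    meas <- measurement_set(data.frame(
      metabolite = d$metabolite, mass = d$mass, time_s = d$time_s,
      value = d$mole_fraction + rnorm(n, 0, sdv), sd = sdv))
    ssr(sim, meas)
  })
  expect_equal(mean(ssrs), n, tolerance = 0.05 * n)
  expect_equal(var(ssrs), 2 * n, tolerance = 0.35 * 2 * n)
})

test_that("chi-square acceptance range matches the quantile oracle", {
  r <- chi_square_range(10, 0.05)
  expect_equal(r, c(3.247, 20.483), tolerance = 1e-4)
  # large df: interval mean approaches df
  r2 <- chi_square_range(500, 0.05)
  expect_equal(mean(r2), 500, tolerance = 0.01 * 500)
  # alpha near 1 collapses the interval toward the median
  r3 <- chi_square_range(1, 0.999)
  expect_lt(diff(r3), 0.01)
  expect_equal(mean(r3), qchisq(0.5, 1), tolerance = 0.01)
  expect_error(chi_square_range(0, 0.05), "invalid")
  expect_error(chi_square_range(10, 1.2), "invalid")
})

test_that("profile CI matches the analytic interval on a linear-Gaussian problem", {
  # only extracellular flux measurements carry information (MIDs pinned at
  # t = 0 are parameter-free), so SSR is exactly quadratic in theta and the
  # profile CI must equal the Wald interval.
  scn <- scenario("tg2_micro")
  net <- scn$network
  sim0 <- simulate_labeling(net, scn$fluxes, scn$pools, times = c(0),
                            targets = scn$measured)
  d <- as.data.frame(sim0)
  # the fourth measured flux pins the malic-enzyme cycle, the direction
  # the three sinks leave free
  fm <- data.frame(reaction = c("sink_tp", "sink_pyr", "sink_oaa", "m_me"),
                   value = c(0.41, 0.78, 0.52, 0.45),
                   sd = c(0.03, 0.04, 0.03, 0.05))
  meas <- measurement_set(data.frame(
    metabolite = d$metabolite, mass = d$mass, time_s = d$time_s,
    value = d$mole_fraction, sd = 0.01), flux_meas = fm)
  fit <- fit_fluxes(net, meas,
                    fit_config(starts = 3, seed = 2, fit_pools = FALSE),
                    fixed_pools = scn$pools)
  ci <- profile_ci(fit, "flux:sink_pyr")

  # analytic oracle: weighted least squares in the null-space coordinates
  basis <- free_flux_basis(net)
  rid <- fit$fluxes$id
  A <- basis$N[match(fm$reaction, rid), , drop = FALSE] / fm$sd
  covt <- solve(crossprod(A))
  nvec <- basis$N[match("sink_pyr", rid), ]
  se <- sqrt(drop(t(nvec) %*% covt %*% nvec))
  expect_equal(unname(ci$upper - ci$estimate), 1.96 * se, tolerance = 0.02)
  expect_equal(unname(ci$estimate - ci$lower), 1.96 * se, tolerance = 0.02)
})

test_that("a structurally unidentifiable exchange flux has an unbounded profile", {
  # with measurements only at t = 0 no exchange flux is identifiable
  scn <- scenario("tg2_micro")
  net <- scn$network
  sim0 <- simulate_labeling(net, scn$fluxes, scn$pools, times = c(0),
                            targets = scn$measured)
  d <- as.data.frame(sim0)
  fm <- data.frame(reaction = c("sink_tp", "sink_pyr", "sink_oaa", "m_upt"),
                   value = c(0.4, 0.8, 0.5, 5.6), sd = c(0.03, 0.04, 0.03, 0.2))
  meas <- measurement_set(data.frame(
    metabolite = d$metabolite, mass = d$mass, time_s = d$time_s,
    value = d$mole_fraction, sd = 0.01), flux_meas = fm)
  fit <- fit_fluxes(net, meas,
                    fit_config(starts = 2, seed = 3, fit_pools = FALSE),
                    fixed_pools = scn$pools)
  ci <- profile_ci(fit, "exch:m_mdh", step_frac = 0.1)
  expect_true(ci$upper_at_bound)
  expect_equal(ci$upper, 0.8, tolerance = 1e-6)
})

test_that("flux maps normalize to 100 units of CO2 uptake", {
  fl <- data.frame(id = c("up", "a", "b"), net = c(9.59, 4.2, -1.1))
  nm <- normalize_to_co2(fl, co2_uptake = 9.59)
  expect_equal(nm$normalized[1], 100)
  expect_equal(attr(nm, "divisor"), 0.0959)
  # doubling all fluxes leaves the normalized map unchanged
  fl2 <- fl; fl2$net <- fl2$net * 2
  nm2 <- normalize_to_co2(fl2, co2_uptake = 2 * 9.59)
  expect_equal(nm2$normalized, nm$normalized, tolerance = 1e-12)
  # ratios preserved exactly
  expect_equal(nm$normalized[2] / nm$normalized[3], fl$net[2] / fl$net[3],
               tolerance = 1e-12)
  expect_error(normalize_to_co2(fl, co2_uptake = 0), "positive")
})

test_that("multi-start fitting is deterministic for a fixed seed", {
  scn <- scenario("tg2_micro")
  exp1 <- generate_experiment(scn, seed = 21)
  cfg <- fit_config(starts = 2, seed = 5, maxiter = 60)
  f1 <- fit_fluxes(scn$network, exp1$measurements, cfg)
  f2 <- fit_fluxes(scn$network, exp1$measurements, cfg)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$ssr, f2$ssr)
  expect_equal(f1$df, nrow(exp1$measurements$mids) +
                 nrow(exp1$measurements$flux_meas) - length(f1$par))
})
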