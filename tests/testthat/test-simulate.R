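test_that("initial condition is unlabeled and rows stay on the simplex", {
  net <- toy_chain()
  sim <- simulate_labeling(net, toy_chain_fluxes(), toy_chain_pools,
                           times = c(0, 30, 120, 600))
  for (m in names(sim$mids)) {
    expect_equal(unname(sim$mids[[m]][1, ]), c(1, 0, 0))
    expect_equal(unname(rowSums(sim$mids[[m]])), rep(1, 4), tolerance = 1e-9)
    expect_true(all(sim$mids[[m]] >= -1e-9))
  }
})

test_that("single-pool washout follows the closed-form exponential", {
  # one 1-carbon pool fed fully labeled input; v/P = 2 per time unit
  net <- parse_network(data.frame(
    id = c("src", "out"), equation = c("S.ext (a) -> A (a)", "A ->"),
    reversible = FALSE))
  fl <- data.frame(id = c("src", "out"), net = c(10, 10), exch = 0)
  tt <- c(0, 0.1, 0.3466, 1, 2)
  sim <- simulate_labeling(net, fl, pools = c(A = 5),
                           input = label_input(purity = 1, unlabeled_fraction = 0),
                           times = tt, flux_scale = 1,
                           rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sim$mids$A[, "M1"]), 1 - exp(-2 * tt), tolerance = 1e-7)
  expect_equal(unname(sim$mids$A[3, "M1"]), 0.5, tolerance = 1e-3)
})

test_that("EMU simulation equals the brute-force isotopomer oracle on toys", {
  cases <- list(
    list(net = toy_chain(), fl = toy_chain_fluxes(), pools = toy_chain_pools),
    list(net = toy_condense(), fl = toy_condense_fluxes(),
         pools = toy_condense_pools))
  tt <- c(0, 30, 60, 180, 300, 600)
  for (cs in cases) {
    emu <- simulate_labeling(cs$net, cs$fl, cs$pools, times = tt,
                             rtol = 1e-10, atol = 1e-12)
    bf <- brute_force_isotopomer(cs$net, cs$fl, cs$pools, times = tt)
    expect_mid_equal(emu, bf, tol = 1e-6)
  }
})

test_that("natural abundance convolution and correction are exact inverses", {
  # p13 = 0: identity both ways
  x <- c(0.2, 0.5, 0.3)
  expect_equal(natural_abundance(x, p13 = 0), x)
  expect_equal(natural_abundance(x, p13 = 0, direction = "correct"), x)

  # unlabeled 2-carbon fragment at natural abundance
  obs <- natural_abundance(c(1, 0, 0), p13 = 0.0107)
  expect_equal(obs, c(0.97881, 0.02117, 0.000114), tolerance = 5e-4)
  expect_equal(obs, dbinom(0:2, 2, 0.0107), tolerance = 1e-12)
  back <- natural_abundance(obs, p13 = 0.0107, direction = "correct")
  expect_equal(back, c(1, 0, 0), tolerance = 1e-10)

  # roundtrip identity on random MIDs
  set.seed(5)
  for (i in 1:10) {
    m <- runif(5); m <- m / sum(m)
    rt <- natural_abundance(natural_abundance(m, p13 = 0.0107),
                            p13 = 0.0107, direction = "correct")
    expect_equal(rt, m, tolerance = 1e-10)
  }
})

test_that("steady-state solver matches the long-time transient limit", {
  net <- toy_chain()
  fl <- toy_chain_fluxes()
  # pure tracer: all pools converge to fully labeled
  ss <- steady_state_mids(net, fl,
                         input = label_input(purity = 1, unlabeled_fraction = 0))
  for (m in names(ss)) expect_equal(ss[[m]], c(0, 0, 1), tolerance = 1e-10)

  # dilution mixes in the unlabeled pool at steady state
  ss_d <- steady_state_mids(net, fl,
                            input = label_input(purity = 1, unlabeled_fraction = 0),
                            dilution = c(C = 0.3))
  expect_equal(ss_d$C[3], 0.7, tolerance = 1e-10)
  expect_equal(ss_d$C[1], 0.3, tolerance = 1e-10)

  # transient solution relaxes onto the algebraic steady state
  ss2 <- steady_state_mids(net, fl)
  t_relax <- 50 * max(toy_chain_pools) / (min(fl$net) * picoflux:::FLUX_UMOL_PER_S)
  sim <- simulate_labeling(net, fl, toy_chain_pools, times = c(0, t_relax),
                           rtol = 1e-10, atol = 1e-12)
  for (m in names(ss2))
    expect_equal(unname(sim$mids[[m]][2, ]), ss2[[m]], tolerance = 1e-4)
})

test_that("atom fraction rises monotonically under a pure label step", {
  scn <- scenario("tg2")
  fl <- scn$fluxes
  fl$exch <- 0   # no exchange: enrichment must be monotone
  sim <- simulate_labeling(scn$network, fl, scn$pools,
                           input = label_input(purity = 1, unlabeled_fraction = 0),
                           times = c(0, 15, 30, 60, 120, 300, 600),
                           targets = scn$measured)
  for (m in names(sim$mids)) {
    mm <- sim$mids[[m]]
    enrich <- as.vector(mm %*% (0:(ncol(mm) - 1))) / (ncol(mm) - 1)
    expect_true(all(diff(enrich) > -1e-8), label = m)
  }
})

test_that("CBB intermediates label before TCA-derived amino-acid precursors", {
  scn <- scenario("tg2")
  sim <- simulate_labeling(scn$network, scn$fluxes, scn$pools,
                           times = c(0, 30),
                           targets = c("TP.c", "HP.h", "AKG.c", "CIT.c"))
  atom_frac_30s <- function(m) {
    mm <- sim$mids[[m]]
    sum(mm[2, ] * (0:(ncol(mm) - 1))) / (ncol(mm) - 1)
  }
  # small fast-turnover CBB pools are already half labeled within 30 s
  # while TCA-derived amino-acid precursors have barely started
  expect_gt(atom_frac_30s("TP.c"), 0.5)
  expect_gt(atom_frac_30s("TP.c"), 2 * atom_frac_30s("AKG.c"))
  expect_gt(atom_frac_30s("HP.h"), atom_frac_30s("AKG.c"))
})

test_that("simulation rejects non-steady flux vectors and zero pools", {
  net <- toy_chain()
  fl_bad <- toy_chain_fluxes()
  fl_bad$net[2] <- 2   # breaks S v = 0
  expect_error(simulate_labeling(net, fl_bad, toy_chain_pools),
               "steady state")
  fl <- toy_chain_fluxes()
  expect_error(simulate_labeling(net, fl, c(A = 2, B = 0, C = 5)),
               "positive")
})
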