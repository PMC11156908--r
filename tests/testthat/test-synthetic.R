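test_that("noise-free experiments reproduce the simulator exactly and deterministically", {
  scn <- scenario("tg2_micro", noise_sd = 0)
  e1 <- generate_experiment(scn, seed = 4)
  truth <- as.data.frame(e1$truth$mids)
  m <- merge(e1$measurements$mids, truth,
             by.x = c("metabolite", "mass", "time_s"),
             by.y = c("metabolite", "mass", "time_s"))
  expect_equal(m$value, m$mole_fraction, tolerance = 1e-12)
  expect_equal(e1$measurements$flux_meas$value,
               scn$fluxes$net[match(e1$measurements$flux_meas$reaction,
                                    scn$fluxes$id)])
  # same seed -> identical datasets
  e2 <- generate_experiment(scn, seed = 4)
  expect_identical(e1$replicates, e2$replicates)
  expect_identical(e1$measurements$mids, e2$measurements$mids)
  # different seeds give different noisy datasets
  scn_n <- scenario("tg2_micro", noise_sd = 0.01)
  n1 <- generate_experiment(scn_n, seed = 4)
  n2 <- generate_experiment(scn_n, seed = 5)
  expect_false(identical(n1$measurements$mids$value,
                         n2$measurements$mids$value))
})

test_that("replicate scatter matches the configured noise SD", {
  scn <- scenario("tg2_micro", noise_sd = 0.01, replicates = 1000,
                  times = c(0, 300))
  e <- generate_experiment(scn, seed = 8, noise_model = "gaussian")
  d <- e$replicates
  # pick interior entries (away from the simplex boundary)
  sub <- d[d$metabolite == "MAL.c" & d$time_s == 300 & d$mass == 2, ]
  expect_equal(nrow(sub), 1000)
  expect_equal(sd(sub$mole_fraction), 0.01, tolerance = 0.05)
})

test_that("truncated noise keeps replicate MIDs on the simplex", {
  scn <- scenario("tg2_micro", noise_sd = 0.05)
  e <- generate_experiment(scn, seed = 9)
  d <- e$replicates
  expect_true(all(d$mole_fraction >= 0 & d$mole_fraction <= 1))
  sums <- stats::aggregate(
    mole_fraction ~ metabolite + time_s + replicate, d, sum)
  expect_equal(sums$mole_fraction, rep(1, nrow(sums)), tolerance = 1e-9)
})

test_that("scenario presets encode the contrasting carbon-partitioning regimes", {
  tg1 <- scenario("tg1"); tg2 <- scenario("tg2"); myb <- scenario("myb99")
  upt <- function(s) s$fluxes$net[s$fluxes$id == "r_upt"]
  nrm <- function(s, id) 100 * s$fluxes$net[s$fluxes$id == id] / upt(s)
  # TG1-like routes >= 2x more normalized flux into the carbohydrate sink
  expect_gte(nrm(tg1, "sink_carb"), 2 * nrm(tg2, "sink_carb"))
  expect_gt(nrm(myb, "sink_carb"), nrm(tg1, "sink_carb"))
  # TG2-like exports more triose phosphate and feeds amino-acid sinks harder
  expect_gt(nrm(tg2, "r_tpx"), nrm(tg1, "r_tpx"))
  expect_gt(nrm(tg2, "sink_prot"), nrm(tg1, "sink_prot"))
  # near-zero AKG -> succinate branch everywhere
  for (s in list(tg1, tg2, myb))
    expect_lt(abs(nrm(s, "r_ogd")), 0.5)
  # malic enzyme cycles only in the TG2-like preset
  expect_gt(tg2$fluxes$net[tg2$fluxes$id == "r_me"], 0.1)
  expect_equal(tg1$fluxes$net[tg1$fluxes$id == "r_me"], 0)
  # all presets at metabolic steady state with positive uptake
  for (s in list(tg1, tg2, myb))
    expect_gt(upt(s), 0)
})

test_that("synthetic compositions close to 100 and track the preset means", {
  scn <- scenario("myb99")
  expect_equal(scn$composition$carbohydrate, 56.1)
  rows <- generate_composition(scn, n = 5, seed = 2)
  expect_equal(rowSums(rows[, setdiff(names(rows), "scale_factor")]),
               rep(100, 5), tolerance = 1e-9)
  # zero-SD draws equal the (closed) preset means
  scn0 <- scn
  scn0$composition[c("fame_sd", "protein_sd", "carbohydrate_sd")] <- 0
  r0 <- generate_composition(scn0, n = 2, seed = 2)
  cc <- correct_composition(c(fame = 9.5, protein = 21.0, carbohydrate = 56.1,
                              dna = 3.4, rna = 7.6, chla = 2.3))
  expect_equal(unname(unlist(r0[1, names(cc$fractions)])),
               unname(cc$fractions), tolerance = 1e-9)
  # already-balanced draws pass through composition correction unchanged
  cc2 <- correct_composition(unlist(r0[1, names(cc$fractions)]))
  expect_equal(cc2$scale_factor, 1, tolerance = 1e-9)
})

test_that("bicarbonate bolus arithmetic matches the labeling protocol", {
  # 1 g/L NaH13CO3 at 85.00 g/mol -> 11.76 mM
  expect_equal(bicarbonate_bolus(1), 11.76, tolerance = 0.005)
  expect_equal(bicarbonate_bolus(0), 0)
  expect_equal(bicarbonate_bolus(2), 2 * bicarbonate_bolus(1),
               tolerance = 1e-12)
})
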