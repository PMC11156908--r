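test_that("measured compositions close to 100% AFDW after correction", {
  # strain table row (TG1 HL): raw values already nearly close the balance
  cc <- correct_composition(
    c(fame = 11.8, protein = 29.9, carbohydrate = 44.9),
    assumed = c(dna = 3.4, rna = 7.66, chla = 2.3))
  expect_equal(cc$raw_total, 99.96, tolerance = 1e-9)
  expect_equal(sum(cc$fractions), 100, tolerance = 1e-9)
  expect_equal(cc$scale_factor, 100 / 99.96, tolerance = 1e-12)

  # already-closed input with unit corrections is returned unchanged
  cc2 <- correct_composition(c(a = 60, b = 40))
  expect_equal(unname(cc2$fractions), c(60, 40))
  expect_equal(cc2$scale_factor, 1)

  # hand-arithmetic oracle: (10,40,30) + (4,8,3) scales by 100/95
  cc3 <- correct_composition(c(fame = 10, protein = 40, carbohydrate = 30),
                             assumed = c(dna = 4, rna = 8, chla = 3))
  expect_equal(cc3$scale_factor, 100 / 95, tolerance = 1e-12)
  expect_equal(unname(cc3$fractions["fame"]), 10 * 100 / 95, tolerance = 1e-12)

  # component-specific factors apply before closure
  cc4 <- correct_composition(c(fame = 10, carbohydrate = 40),
                             assumed = c(rest = 40),
                             correction_factors = c(fame = 1.25))
  expect_equal(cc4$raw_total, 12.5 + 40 + 40)

  expect_error(correct_composition(c(a = -1, b = 50)), "nonnegative")
  expect_error(correct_composition(c(a = 0)), "positive")
})

test_that("every strain/light composition row closes to 100 +- 0.1", {
  tab <- composition_table()
  for (i in seq_len(nrow(tab))) {
    cc <- correct_composition(
      c(fame = tab$fame[i], protein = tab$protein[i],
        carbohydrate = tab$carbohydrate[i]),
      assumed = c(dna = tab$dna[i], rna = tab$rna[i], chla = tab$chla[i]))
    expect_equal(sum(cc$fractions), 100, tolerance = 0.1)
    # raw totals are themselves near closure (scaling is a small touch-up)
    expect_lt(abs(cc$raw_total - 100), 2.5)
  }
})

test_that("precursor demands follow monomer stoichiometry and are linear", {
  # 100% carbohydrate at 162 g/mol anhydroglucose -> 1000/162 mmol G1P
  d <- precursor_demands(c(carbohydrate = 100))
  expect_equal(d$mmol_per_gDW[d$species == "G1P.h"], 1000 / 162,
               tolerance = 1e-2)
  # all-zero composition -> zero demands
  d0 <- precursor_demands(c(carbohydrate = 0, protein = 0))
  expect_true(all(d0$mmol_per_gDW == 0))
  # linearity in the fractions
  d1 <- precursor_demands(c(protein = 10, carbohydrate = 20))
  d2 <- precursor_demands(c(protein = 30, carbohydrate = 60))
  m <- merge(d1, d2, by = c("species", "class"))
  expect_equal(3 * m$mmol_per_gDW.x, m$mmol_per_gDW.y, tolerance = 1e-12)
  expect_error(precursor_demands(c(unknown_class = 50)), "missing monomer")
})

test_that("protein-rich composition roughly doubles amino-acid precursor demand", {
  tab <- composition_table()
  tg1 <- tab[tab$strain == "TG1" & tab$light == "HL", ]
  tg2 <- tab[tab$strain == "TG2" & tab$light == "HL", ]
  a1 <- precursor_demands(c(protein = tg1$protein))
  a2 <- precursor_demands(c(protein = tg2$protein))
  ratio <- sum(a2$mmol_per_gDW) / sum(a1$mmol_per_gDW)
  expect_equal(ratio, tg2$protein / tg1$protein, tolerance = 1e-9)
  expect_gt(ratio, 1.5)   # 50.8% vs 29.9% protein
  expect_lt(ratio, 2.0)
})

test_that("growth rate from TOC is the log-linear slope", {
  # constant TOC -> mu = 0
  g0 <- growth_rate_from_toc(c(0, 2, 4, 6), rep(120, 4))
  expect_equal(g0$mu, 0, tolerance = 1e-12)

  # exact doubling over ln2/0.323 h -> mu = 0.323
  dt <- log(2) / 0.323
  g1 <- growth_rate_from_toc(c(0, dt), c(80, 160))
  expect_equal(g1$mu, 0.323, tolerance = 1e-9)

  # noisy exponential recovered within ~2 fit SDs
  set.seed(7)
  tt <- seq(0, 10, by = 0.5)
  toc <- 100 * exp(0.25 * tt) * exp(rnorm(length(tt), 0, 0.02))
  g2 <- growth_rate_from_toc(tt, toc)
  expect_lt(abs(g2$mu - 0.25), 2.5 * g2$sd)

  expect_error(growth_rate_from_toc(1, 100), "two time points")
  expect_error(growth_rate_from_toc(c(0, 1), c(-1, 2)), "positive")
})

test_that("demand carbon times growth rate balances biomass carbon", {
  net <- load_network("tgmini")
  tab <- composition_table()
  mt <- utils::read.csv(system.file("extdata", "monomer_table_tgmini.csv",
                                    package = "picoflux"))
  # per-class carbon content implied by the monomer table itself
  mt$gC_per_g <- species_carbons(net, mt$species) * mt$mmol_per_g * 12.011 / 1000
  class_c <- tapply(mt$gC_per_g, mt$class, sum)
  for (i in seq_len(nrow(tab))) {
    comp <- c(fame = tab$fame[i], protein = tab$protein[i],
              carbohydrate = tab$carbohydrate[i], dna = tab$dna[i],
              rna = tab$rna[i], chla = tab$chla[i])
    cc <- correct_composition(comp)
    dem <- precursor_demands(cc)
    mu <- tab$growth_rate[i]
    dem_c_rate <- demand_carbon(dem, net) * mu * 12.011 / 1000  # gC/gDW/h
    bio_c <- sum(cc$fractions / 100 * class_c[names(comp)])     # gC/gDW
    expect_equal(dem_c_rate, mu * bio_c, tolerance = 0.01 * mu * bio_c)
  }
})
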