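test_that("atom-mapped equations parse with balanced carbon multisets", {
  net <- parse_network(data.frame(
    id = "v1", equation = "A (ab) -> B (ab)", reversible = FALSE))
  expect_s3_class(net, "flux_network")
  expect_equal(length(net$reactions), 1L)
  expect_equal(net$reactions[[1]]$kind, "internal")
  expect_equal(species_carbons(net, c("A", "B")), c(2, 2))

  # decarboxylation: atom multisets on both sides must agree
  net2 <- parse_network(data.frame(
    id = "v2", equation = "OAA (abcd) -> PEP (abc) + CO2 (d)",
    reversible = FALSE))
  r <- net2$reactions[[1]]
  lhs_atoms <- sort(unlist(lapply(r$lhs, `[[`, "atoms")))
  rhs_atoms <- sort(unlist(lapply(r$rhs, `[[`, "atoms")))
  expect_identical(lhs_atoms, rhs_atoms)
  expect_equal(species_carbons(net2, "CO2"), 1)
})

test_that("malformed rows are rejected with informative errors", {
  expect_error(parse_network(data.frame(
    id = "v3", equation = "A (ab) -> B (abc)", reversible = FALSE)),
    "unbalanced|mismatch")
  expect_error(parse_network(data.frame(
    id = c("x", "x"), equation = c("A (a) -> B (a)", "B (a) -> A (a)"),
    reversible = FALSE)), "duplicated reaction id")
  expect_error(parse_network(data.frame(
    id = "v4", equation = "A (aa) -> B (aa)", reversible = FALSE)),
    "atom label used twice")
  # same species declared with two different carbon counts
  expect_error(parse_network(data.frame(
    id = c("v5", "v6"),
    equation = c("A (ab) -> B (ab)", "B (abc) -> C (abc)"),
    reversible = FALSE)), "carbon-count mismatch")
})

test_that("stoichiometric matrix has balanced species rows, externals excluded", {
  net <- parse_network(data.frame(
    id = c("v1", "out"), equation = c("A (a) -> B (a)", "B ->"),
    reversible = FALSE))
  S <- stoichiometric_matrix(net)
  expect_equal(dim(S), c(2L, 2L))
  expect_equal(S["A", "v1"], -1)
  expect_equal(S["B", "v1"], 1)
  expect_equal(S["B", "out"], -1)

  # carbon-weighted column sums vanish for internal reactions (atom
  # conservation oracle: count atoms on each side directly)
  for (nm in c("tgmini", "tgmicro", "pcel")) {
    net <- load_network(nm)
    S <- stoichiometric_matrix(net)
    carb <- species_carbons(net, rownames(S))
    for (j in seq_along(net$reactions)) {
      r <- net$reactions[[j]]
      if (r$kind %in% c("internal", "transport")) {
        expect_equal(sum(S[, j] * carb), 0, tolerance = 1e-12,
                     label = paste(nm, r$id))
      }
    }
  }
})

test_that("free-flux parameterization spans the steady-state solution space", {
  net <- toy_chain()
  basis <- free_flux_basis(net)
  # linear chain with one sink: one free flux
  expect_equal(basis$free_dim, 1L)
  S <- stoichiometric_matrix(net)
  # independent rank oracle
  expect_equal(basis$free_dim, ncol(S) - qr(S)$rank)

  # random draws satisfy S v = 0 exactly
  set.seed(42)
  for (i in 1:20) {
    v <- basis$reconstruct(rnorm(basis$free_dim, 0, 5))
    expect_lt(max(abs(S %*% v)), 1e-10)
  }

  # a network with an internal cycle gains a free dimension
  cyc <- parse_network(data.frame(
    id = c("src", "f", "g", "h", "out"),
    equation = c("S.ext (a) -> A (a)", "A (a) -> B (a)", "B (a) -> C (a)",
                 "C (a) -> A (a)", "B ->"),
    reversible = FALSE))
  bc <- free_flux_basis(cyc)
  Sc <- stoichiometric_matrix(cyc)
  expect_equal(bc$free_dim, ncol(Sc) - qr(Sc)$rank)
  expect_gte(bc$free_dim, 2L)

  # reconstructing an arbitrary feasible vector from its coordinates
  v_target <- bc$reconstruct(c(1.3, -0.4, 2.2)[seq_len(bc$free_dim)])
  theta_back <- crossprod(bc$N, v_target - bc$v0)
  expect_lt(max(abs(bc$reconstruct(as.vector(theta_back)) - v_target)), 1e-10)

  # inconsistent fixed demands raise an infeasibility error naming species
  expect_error(free_flux_basis(net, fixed = c(src = 1, v1 = 2, v2 = 2, out = 2)),
               "infeasible|violated")
})

test_that("biomass sinks scale with composition and growth rate", {
  net <- load_network("tgmini")
  demands <- data.frame(class = c("carbohydrate", "protein", "protein"),
                        species = c("G1P.h", "PYR.c", "AKG.c"),
                        mmol_per_gDW = c(2.77, 1.0, 0.7))
  net2 <- attach_biomass_sink(net, demands, growth_rate = 0.2)
  ids <- vapply(net2$reactions, `[[`, character(1), "id")
  expect_true(all(c("sink_carbohydrate", "sink_protein") %in% ids))
  snk <- net2$reactions[[match("sink_carbohydrate", ids)]]
  expect_equal(snk$kind, "sink")
  expect_equal(snk$lhs[[1]]$coef, 2.77)
  expect_equal(attr(net2, "sink_flux"), 0.2)
  # zero growth rate -> zero sink flux
  net0 <- attach_biomass_sink(net, demands, growth_rate = 0)
  expect_equal(attr(net0, "sink_flux"), 0)
  expect_error(attach_biomass_sink(net, data.frame(
    class = "x", species = "NOPE.c", mmol_per_gDW = 1)), "unknown species")
})

test_that("carbohydrate-rich composition yields larger storage sink than protein-rich", {
  tab <- composition_table()
  tg1 <- tab[tab$strain == "TG1" & tab$light == "HL", ]
  tg2 <- tab[tab$strain == "TG2" & tab$light == "HL", ]
  d1 <- precursor_demands(c(carbohydrate = tg1$carbohydrate))
  d2 <- precursor_demands(c(carbohydrate = tg2$carbohydrate))
  g1 <- d1$mmol_per_gDW[d1$species == "G1P.h"]
  g2 <- d2$mmol_per_gDW[d2$species == "G1P.h"]
  expect_gt(g1, 2 * g2)   # 44.9% vs 16% AFDW carbohydrate

  # swapping the amino-acid profile changes only protein-class coefficients
  base <- precursor_demands(c(protein = 30, carbohydrate = 20))
  skew <- precursor_demands(c(protein = 30, carbohydrate = 20),
                            aa_profile = c(PYR.c = 4, OAA.c = 1,
                                           AKG.c = 1, PEP.c = 1))
  b <- merge(base, skew, by = c("species", "class"))
  moved <- b$class == "protein"
  expect_true(any(abs(b$mmol_per_gDW.x[moved] - b$mmol_per_gDW.y[moved]) > 1e-6))
  expect_equal(b$mmol_per_gDW.x[!moved], b$mmol_per_gDW.y[!moved])
  # total protein precursor mmol preserved by the profile swap
  expect_equal(sum(b$mmol_per_gDW.x[moved]), sum(b$mmol_per_gDW.y[moved]))
})

test_that("bundled networks validate, are feasible, and round-trip through files", {
  for (nm in c("tgmini", "tgmicro", "pcel")) {
    net <- load_network(nm)
    v <- validate_network(net, check_feasibility = TRUE)
    expect_true(v$ok, label = nm)
    expect_true(v$feasible, label = nm)
    # glyoxylate-shunt reactions absent from the default networks
    ids <- vapply(net$reactions, `[[`, character(1), "id")
    expect_false(any(grepl("icl|mals|glyoxylate", ids, ignore.case = TRUE)))
    # round trip
    tmp <- tempfile(fileext = ".tsv")
    write_network(net, tmp)
    net2 <- parse_network(tmp, symmetric = net$species$id[net$species$symmetric])
    expect_equal(stoichiometric_matrix(net2), stoichiometric_matrix(net))
    expect_equal(length(net2$reactions), length(net$reactions))
  }
})
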