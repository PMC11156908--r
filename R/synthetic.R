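# Synthetic transient-labeling experiment generator.
#
# Scenario presets encode the study conditions: a step change to 13C
# inorganic carbon at t = 0, sampling at 0/30/60/180/300/600 s,
# biological triplicates, Gaussian MID noise, and flux regimes
# contrasting carbohydrate-rich (TG1-like) vs protein-rich (TG2-like)
# carbon partitioning, both with a near-zero AKG -> succinate branch.

mini_pools <- c(
  CO2.h = 2, CO2.c = 1, TP.h = 0.6, HP.h = 1.0, G1P.h = 1.5, TP.c = 0.8,
  PEP.c = 1.5, PYR.c = 2.0, ACA.c = 0.5, OAA.c = 1.0, CIT.c = 3.0,
  AKG.c = 2.5, SUC.c = 3.0, FUM.c = 1.2, MAL.c = 2.5)

mini_measured <- c("HP.h", "TP.c", "PEP.c", "PYR.c", "CIT.c", "AKG.c",
                   "SUC.c", "FUM.c", "MAL.c", "OAA.c")

mini_exchange <- c(r_pgm = 0.5, r_tpx = 0.3, r_pep = 0.2, r_fum = 2.0,
                   r_mdh = 0.5)

mini_flux_table <- function(values, exch = mini_exchange) {
  ids <- c("r_upt", "r_tco2", "r_cbb", "r_hpa", "r_pgm", "r_tpx", "r_pep",
           "r_pk", "r_ppc", "r_pdh", "r_cs", "r_idh", "r_ogd", "r_sdh",
           "r_fum", "r_mdh", "r_me", "sink_carb", "sink_prot", "sink_lip")
  stopifnot(length(values) == length(ids))
  data.frame(id = ids, net = unname(values),
             exch = unname(ifelse(ids %in% names(exch), exch[ids], 0)),
             stringsAsFactors = FALSE)
}

#' Construct a synthetic labeling scenario
#'
#' Presets: `"tg1"` (carbohydrate-rich partitioning, malic enzyme
#' inactive), `"tg2"` (protein-rich, active PEP carboxylase anaplerosis
#' and an OAA -> malate -> pyruvate malic-enzyme cycle producing NADPH),
#' `"myb99"` (extreme carbohydrate partitioning), all on the bundled
#' `tgmini` network; and `"tg2_micro"`, a condensed single-compartment
#' TG2-like variant on the `tgmicro` network used for parameter-recovery
#' studies. All presets have a zero AKG -> succinate branch, so succinate
#' stays unlabeled over the 10 min window while fumarate labels through
#' the fumarase exchange flux.
#'
#' @param name preset name.
#' @param noise_sd Gaussian MID noise SD (mole fraction, default 0.01).
#' @param replicates biological replicates (default 3).
#' @param times sampling times in seconds.
#' @param dilution named inactive-pool fractions (default none).
#' @return list of class `flux_scenario` with the network, true fluxes,
#'   pools, measured metabolites, composition preset and growth rate.
#' @export
scenario <- function(name = c("tg1", "tg2", "myb99", "tg2_micro"),
                     noise_sd = 0.01, replicates = 3,
                     times = c(0, 30, 60, 180, 300, 600),
                     dilution = NULL) {
  name <- match.arg(name)
  if (name == "tg2_micro") {
    net <- load_network("tgmicro")
    fluxes <- data.frame(
      id = c("m_upt", "m_cbb", "m_gly", "m_pk", "m_ppc", "m_mdh", "m_me",
             "sink_tp", "sink_pyr", "sink_oaa"),
      net = c(5.6, 1.7, 1.3, 0.3, 1.0, 0.5, 0.5, 0.4, 0.8, 0.5),
      exch = c(0, 0, 0.3, 0, 0, 0.8, 0, 0, 0, 0),
      stringsAsFactors = FALSE)
    pools <- c(CO2.c = 1.5, TP.c = 0.5, PEP.c = 1.0, PYR.c = 1.5,
               OAA.c = 1.0, MAL.c = 2.0)
    measured <- c("TP.c", "PEP.c", "PYR.c", "OAA.c", "MAL.c")
    strain <- "TG2"; mu <- 0.323
  } else {
    net <- load_network("tgmini")
    fluxes <- switch(name,
      tg1 = mini_flux_table(c(6.17, 0.25, 2.14, 0.45, 0.45, 1.24, 1.24,
                              0.69, 0.44, 0.47, 0.22, 0.22, 0, 0, 0, 0, 0,
                              0.45, 0.22, 0.25)),
      tg2 = mini_flux_table(c(9.565, 0.5, 3.355, 0.19, 0.19, 2.975, 2.975,
                              1.27, 1.43, 1.05, 0.55, 0.55, 0, 0, 0, -0.33,
                              0.33, 0.19, 0.55, 0.50)),
      myb99 = mini_flux_table(c(6.28, 0.20, 2.16, 0.62, 0.62, 0.92, 0.92,
                                0.52, 0.32, 0.36, 0.16, 0.16, 0, 0, 0, 0, 0,
                                0.62, 0.16, 0.20)))
    pools <- mini_pools
    measured <- mini_measured
    strain <- switch(name, tg1 = "TG1", tg2 = "TG2", myb99 = "TG1-MYB99")
    mu <- switch(name, tg1 = 0.220, tg2 = 0.323, myb99 = 0.254)
  }
  check_steady_state(net, fluxes)
  comp <- composition_table()
  comp <- comp[comp$strain == strain & comp$light == "HL", , drop = FALSE]
  structure(list(name = name, network = net, fluxes = fluxes, pools = pools,
                 dilution = dilution, measured = measured,
                 strain = strain, growth_rate = mu,
                 composition = comp, noise_sd = noise_sd,
                 replicates = replicates, times = times,
                 input = label_input()),
            class = "flux_scenario")
}

#' @export
print.flux_scenario <- function(x, ...) {
  cat(sprintf("<flux_scenario> '%s' (%s-like): %d reactions, %d measured metabolites,\n",
              x$name, x$strain, nrow(x$fluxes), length(x$measured)))
  cat(sprintf("  noise SD %.3g, %d replicates, times %s s\n", x$noise_sd,
              x$replicates, paste(x$times, collapse = "/")))
  invisible(x)
}

#' Generate a complete synthetic labeling experiment
#'
#' Simulates the scenario's true MID time courses, adds independent
#' Gaussian noise per replicate (truncated to `[0,1]` and renormalized by
#' default, so replicate MIDs stay on the simplex; `noise_model =
#' "gaussian"` keeps the raw Gaussian draws for calibration studies), and
#' returns replicate-level data, a replicate-aggregated measurement set
#' for fitting, and the hidden ground truth.
#'
#' Measurement SDs in the aggregated set are the SDs of the replicate
#' means (`noise_sd / sqrt(replicates)`). Sink (extracellular) fluxes are
#' measured with 5% relative SD.
#'
#' @param scn a [scenario()].
#' @param seed integer master seed; the same seed reproduces the dataset
#'   byte for byte.
#' @param noise_model `"truncnorm"` (default) or `"gaussian"`.
#' @return list of class `synthetic_experiment` with `replicates`
#'   (long-format data.frame), `measurements` (a `measurement_set`), and
#'   `truth`.
#' @export
generate_experiment <- function(scn, seed = 1,
                                noise_model = c("truncnorm", "gaussian")) {
  noise_model <- match.arg(noise_model)
  stopifnot(scn$noise_sd >= 0)
  set.seed(seed)
  sim <- simulate_labeling(scn$network, scn$fluxes, scn$pools,
                           input = scn$input, times = scn$times,
                           targets = scn$measured, dilution = scn$dilution)
  rep_rows <- list()
  agg_rows <- list()
  for (met in names(sim$mids)) {
    m <- sim$mids[[met]]
    nb <- ncol(m)
    reps <- array(NA_real_, c(nrow(m), nb, scn$replicates))
    for (r in seq_len(scn$replicates)) {
      noisy <- m + matrix(rnorm(length(m), 0, scn$noise_sd), nrow(m), nb)
      if (noise_model == "truncnorm") {
        noisy <- pmin(pmax(noisy, 0), 1)
        noisy <- noisy / rowSums(noisy)
      }
      reps[, , r] <- noisy
      rep_rows[[length(rep_rows) + 1]] <- data.frame(
        metabolite = met, mass = rep(0:(nb - 1), each = nrow(m)),
        time_s = rep(scn$times, nb), replicate = r,
        mole_fraction = as.vector(noisy), sd = scn$noise_sd,
        stringsAsFactors = FALSE)
    }
    agg <- apply(reps, c(1, 2), mean)
    agg_rows[[length(agg_rows) + 1]] <- data.frame(
      metabolite = met, mass = rep(0:(nb - 1), each = nrow(m)),
      time_s = rep(scn$times, nb), value = as.vector(agg),
      sd = scn$noise_sd / sqrt(scn$replicates),
      stringsAsFactors = FALSE)
  }
  sinks <- scn$fluxes[grepl("^sink_", scn$fluxes$id), ]
  sink_sd <- pmax(0.05 * abs(sinks$net), 0.02)
  # a fully noise-free scenario also reports exact extracellular fluxes
  flux_noise <- if (scn$noise_sd > 0) rnorm(nrow(sinks), 0, sink_sd) else 0
  flux_meas <- data.frame(
    reaction = sinks$id,
    value = sinks$net + flux_noise,
    sd = sink_sd, stringsAsFactors = FALSE)
  meas <- measurement_set(do.call(rbind, agg_rows), flux_meas,
                          growth_rate = scn$growth_rate)
  structure(list(replicates = do.call(rbind, rep_rows),
                 measurements = meas,
                 truth = list(fluxes = scn$fluxes, pools = scn$pools,
                              dilution = scn$dilution, mids = sim),
                 seed = seed, noise_model = noise_model),
            class = "synthetic_experiment")
}

#' Bundle MID and extracellular-flux measurements for fitting
#'
#' @param mids data.frame with columns `metabolite`, `mass`, `time_s`,
#'   `value`, `sd`.
#' @param flux_meas optional data.frame with columns `reaction`, `value`,
#'   `sd` (measured extracellular/sink fluxes).
#' @param growth_rate optional specific growth rate (1/h), carried as
#'   metadata.
#' @return list of class `measurement_set`.
#' @export
measurement_set <- function(mids, flux_meas = NULL, growth_rate = NA_real_) {
  stopifnot(all(c("metabolite", "mass", "time_s", "value", "sd") %in%
                  names(mids)))
  if (any(mids$sd < 0)) stop("measurement SDs must be nonnegative")
  structure(list(mids = mids, flux_meas = flux_meas,
                 growth_rate = growth_rate),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> %d MID values (%d metabolites, %d times)",
              nrow(x$mids), length(unique(x$mids$metabolite)),
              length(unique(x$mids$time_s))))
  if (!is.null(x$flux_meas))
    cat(sprintf(", %d flux measurements", nrow(x$flux_meas)))
  cat("\n")
  invisible(x)
}

#' Draw synthetic biomass composition rows for a scenario
#'
#' Draws each component around the scenario strain's preset mean with its
#' preset SD (zero where no SD is reported), then closes each draw to
#' 100% AFDW with [correct_composition()].
#'
#' @param scn a [scenario()].
#' @param n number of rows (default 3).
#' @param seed integer seed.
#' @return data.frame of corrected rows (columns fame, protein,
#'   carbohydrate, dna, rna, chla, scale_factor).
#' @export
generate_composition <- function(scn, n = 3, seed = 1) {
  set.seed(seed)
  cp <- scn$composition
  means <- c(fame = cp$fame, protein = cp$protein,
             carbohydrate = cp$carbohydrate, dna = cp$dna, rna = cp$rna,
             chla = cp$chla)
  sds <- c(fame = cp$fame_sd, protein = cp$protein_sd,
           carbohydrate = cp$carbohydrate_sd, dna = 0, rna = 0, chla = 0)
  sds[is.na(sds)] <- 0
  rows <- lapply(seq_len(n), function(i) {
    draw <- pmax(means + rnorm(length(means), 0, sds), 0)
    cc <- correct_composition(draw)
    c(cc$fractions, scale_factor = cc$scale_factor)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Molar concentration of a tracer bolus
#'
#' mM = 1000 x (g/L) / (g/mol). The default molar mass is that of
#' NaH13CO3 (Na 22.990 + H 1.008 + 13C 13.003 + 3 O 47.998 = 85.00
#' g/mol), for which a 1 g/L bolus is 11.76 mM.
#'
#' @param mass_conc_g_per_l mass concentration (g/L).
#' @param molar_mass_g_per_mol tracer molar mass (g/mol).
#' @return molar concentration (mM).
#' @export
bicarbonate_bolus <- function(mass_conc_g_per_l = 1,
                              molar_mass_g_per_mol = 84.999) {
  stopifnot(mass_conc_g_per_l >= 0, molar_mass_g_per_mol > 0)
  1000 * mass_conc_g_per_l / molar_mass_g_per_mol
}
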