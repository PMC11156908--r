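# ATP / NADPH energetics ledgers.
#
# Demand convention: consumption positive, production negative; a net
# producer (e.g. the NADPH-generating malic enzyme) therefore reduces the
# total demand. NADH is tracked as a separate currency and does not enter
# the headline ATP/NADPH ratio (no transhydrogenase assumed).

#' Load the bundled energy cost table for the scenario network
#' @return data.frame with columns reaction, atp, nadph, nadh, pathway.
#' @export
energy_cost_table <- function() {
  utils::read.csv(system.file("extdata", "energy_costs_tgmini.csv",
                              package = "picoflux"),
                  stringsAsFactors = FALSE)
}

#' ATP and NADPH demand ledger from a flux solution
#'
#' ATP = sum(v_i * atp_i) + maintenance; NADPH = sum(v_i * nadph_i).
#' Reactions absent from the cost table contribute zero (with a warning
#' listing them once).
#'
#' @param fluxes data.frame with columns `id`, `net` (mmol gDW^-1 h^-1).
#' @param costs cost table (see [energy_cost_table()]); columns
#'   `reaction`, `atp`, `nadph`, optionally `nadh`, `pathway`.
#' @param maintenance_atp non-growth-associated ATP maintenance,
#'   mmol gDW^-1 h^-1 (default 2.85, the value reported for
#'   *C. reinhardtii*).
#' @param warn_missing warn about flux-carrying reactions without cost
#'   entries.
#' @return list of class `energy_ledger`: `atp`, `nadph`, `nadh`,
#'   `ratio` (ATP/NADPH; `NA` with a `ratio_defined = FALSE` flag when
#'   NADPH <= 0), `maintenance`, `by_pathway` breakdown.
#' @export
atp_nadph_demand <- function(fluxes, costs = energy_cost_table(),
                             maintenance_atp = 2.85, warn_missing = TRUE) {
  stopifnot(maintenance_atp >= 0)
  idx <- match(fluxes$id, costs$reaction)
  missing <- fluxes$id[is.na(idx) & abs(fluxes$net) > 1e-12]
  if (length(missing) && warn_missing)
    warning("no energy costs for flux-carrying reactions (treated as 0): ",
            paste(missing, collapse = ", "))
  atp_c <- ifelse(is.na(idx), 0, costs$atp[idx])
  nadph_c <- ifelse(is.na(idx), 0, costs$nadph[idx])
  nadh_c <- if ("nadh" %in% names(costs))
    ifelse(is.na(idx), 0, costs$nadh[idx]) else rep(0, nrow(fluxes))
  pw <- ifelse(is.na(idx), "other", costs$pathway[idx])
  atp_terms <- fluxes$net * atp_c
  nadph_terms <- fluxes$net * nadph_c
  by_pathway <- stats::aggregate(
    cbind(atp = atp_terms, nadph = nadph_terms),
    by = list(pathway = pw), FUN = sum)
  atp <- sum(atp_terms) + maintenance_atp
  nadph <- sum(nadph_terms)
  nadh <- sum(fluxes$net * nadh_c)
  ratio_defined <- nadph > 0
  structure(list(atp = atp, nadph = nadph, nadh = nadh,
                 ratio = if (ratio_defined) atp / nadph else NA_real_,
                 ratio_defined = ratio_defined,
                 maintenance = maintenance_atp,
                 by_pathway = by_pathway),
            class = "energy_ledger")
}

#' @export
print.energy_ledger <- function(x, ...) {
  cat(sprintf("<energy_ledger> ATP %.3f (incl. maintenance %.2f), NADPH %.3f mmol gDW-1 h-1\n",
              x$atp, x$maintenance, x$nadph))
  if (x$ratio_defined) cat(sprintf("  ATP/NADPH = %.3f\n", x$ratio))
  else cat("  ATP/NADPH undefined (NADPH <= 0)\n")
  invisible(x)
}

#' ATP/NADPH production ratio of linear electron flow
#'
#' Linear electron flow translocates `protons_per_4e` protons and makes
#' `nadph_per_4e` NADPH per 4 electrons, while the ATP synthase makes
#' `atp_per_14h` ATP per 14 protons; the production ratio is
#' `(protons_per_4e * atp_per_14h / 14) / nadph_per_4e`. With the default
#' stoichiometries (12 H+, 3 ATP per 14 H+, 2 NADPH) this is 18/14 =
#' 1.2857, i.e. 1.29 at two decimals.
#'
#' @param protons_per_4e protons pumped per 4 electrons (default 12).
#' @param atp_per_14h ATP per 14 protons (default 3).
#' @param nadph_per_4e NADPH per 4 electrons (default 2).
#' @return scalar ratio.
#' @export
lef_ratio <- function(protons_per_4e = 12, atp_per_14h = 3,
                      nadph_per_4e = 2) {
  stopifnot(protons_per_4e > 0, atp_per_14h > 0, nadph_per_4e > 0)
  (protons_per_4e * atp_per_14h / 14) / nadph_per_4e
}

#' ATP/NADPH consumption ratio of the Calvin-Benson-Bassham cycle
#'
#' @param atp_per_co2 ATP consumed per CO2 fixed (default 3).
#' @param nadph_per_co2 NADPH consumed per CO2 fixed (default 2).
#' @return scalar ratio (defaults give 1.5).
#' @export
cbb_ratio <- function(atp_per_co2 = 3, nadph_per_co2 = 2) {
  stopifnot(atp_per_co2 > 0, nadph_per_co2 > 0)
  atp_per_co2 / nadph_per_co2
}
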