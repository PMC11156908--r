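# Biomass composition handling: mass-balance correction of measured
# macromolecule fractions, translation into precursor sink demands, and
# growth rate from total organic carbon series.

#' Correct a measured biomass composition to satisfy mass balance
#'
#' Measured macromolecular compositions rarely close to 100% of ash-free
#' dry weight: some components (FAME, carbohydrate) are systematically
#' under-recovered and some (DNA, RNA, chlorophyll) are assumed from
#' reference values rather than measured. The correction proceeds in two
#' steps: first component-specific correction factors are applied to the
#' named components, then all components are scaled by a common factor so
#' the total equals 100% AFDW.
#'
#' @param measured named numeric vector of measured fractions (% AFDW),
#'   e.g. `c(fame = 11.8, protein = 29.9, carbohydrate = 44.9)`.
#' @param assumed named numeric vector of assumed fractions (% AFDW) for
#'   unmeasured components (DNA, RNA, chlorophyll).
#' @param correction_factors named numeric vector of component-specific
#'   multipliers applied before closure (default none, i.e. factor 1).
#' @return list of class `biomass_composition`: `fractions` (named, sums
#'   to 100), `scale_factor` (the common closure multiplier), `raw_total`.
#' @export
correct_composition <- function(measured, assumed = NULL,
                                correction_factors = NULL) {
  x <- c(measured, assumed)
  if (any(x < 0)) stop("fractions must be nonnegative")
  if (!is.null(correction_factors)) {
    for (nm in names(correction_factors)) {
      if (!nm %in% names(x)) stop("correction factor for unknown component: ", nm)
      x[nm] <- x[nm] * correction_factors[[nm]]
    }
  }
  if (any(x < 0)) stop("negative fraction after correction")
  total <- sum(x)
  if (total <= 0) stop("total composition must be positive")
  scale <- 100 / total
  structure(list(fractions = x * scale, scale_factor = scale,
                 raw_total = total),
            class = "biomass_composition")
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat("<biomass_composition> (% AFDW, closed to 100)\n")
  print(round(x$fractions, 2))
  cat(sprintf("  closure scale factor: %.4f (raw total %.2f)\n",
              x$scale_factor, x$raw_total))
  invisible(x)
}

#' Load the bundled strain/light composition table
#'
#' Growth rates and macromolecule fractions (% AFDW) for the
#' carbohydrate-rich and protein-rich strains under low and high light.
#' @return data.frame.
#' @export
composition_table <- function() {
  utils::read.csv(system.file("extdata", "composition_table.csv",
                              package = "picoflux"),
                  stringsAsFactors = FALSE)
}

#' Translate a composition into precursor sink demands
#'
#' demand_i = sum over classes of fraction_class/100 x mmol precursor_i
#' per gram of class. The monomer table gives precursor stoichiometries
#' per macromolecule class; an optional per-strain amino-acid profile
#' rescales the protein-class precursor split (entries are relative
#' weights over the protein precursor species).
#'
#' @param composition a `biomass_composition` or named fraction vector
#'   summing to <= 100.
#' @param monomer_table data.frame with columns `class`, `species`,
#'   `mmol_per_g`; defaults to the bundled table for the scenario
#'   network.
#' @param aa_profile optional named numeric vector over the protein
#'   precursor species; relative weights renormalized to preserve total
#'   protein precursor mmol per gram.
#' @return data.frame of class `precursor_demand` with columns `species`,
#'   `mmol_per_gDW`, `class`.
#' @export
precursor_demands <- function(composition, monomer_table = NULL,
                              aa_profile = NULL) {
  if (inherits(composition, "biomass_composition"))
    composition <- composition$fractions
  if (is.null(monomer_table))
    monomer_table <- utils::read.csv(
      system.file("extdata", "monomer_table_tgmini.csv", package = "picoflux"),
      stringsAsFactors = FALSE)
  mt <- monomer_table
  if (!is.null(aa_profile)) {
    pr <- mt$class == "protein"
    if (!all(names(aa_profile) %in% mt$species[pr]))
      stop("aa_profile references species absent from the protein class")
    tot <- sum(mt$mmol_per_g[pr])
    w <- aa_profile[mt$species[pr]]
    w[is.na(w)] <- 0
    mt$mmol_per_g[pr] <- tot * w / sum(w)
  }
  missing_cls <- setdiff(names(composition)[composition > 0],
                         c(mt$class, names(composition)[composition == 0]))
  missing_cls <- setdiff(missing_cls, mt$class)
  if (length(missing_cls))
    stop("missing monomer entries for nonzero classes: ",
         paste(missing_cls, collapse = ", "))
  rows <- lapply(names(composition), function(cls) {
    f <- composition[[cls]]
    d <- mt[mt$class == cls, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    data.frame(species = d$species, mmol_per_gDW = f / 100 * d$mmol_per_g,
               class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- stats::aggregate(mmol_per_gDW ~ species + class, out, sum)
  out <- out[, c("species", "mmol_per_gDW", "class")]
  class(out) <- c("precursor_demand", "data.frame")
  out
}

#' Specific growth rate from a total organic carbon series
#'
#' mu is the least-squares slope of ln(TOC) against time; its SD is the
#' standard error of the slope.
#'
#' @param time_h time points (h).
#' @param toc total organic carbon (mg C / L), strictly positive.
#' @return list with `mu` (1/h) and `sd` (NA with < 3 points).
#' @export
growth_rate_from_toc <- function(time_h, toc) {
  if (length(time_h) < 2) stop("need at least two time points")
  if (any(toc <= 0)) stop("TOC values must be positive")
  fit <- lm(log(toc) ~ time_h)
  mu <- unname(coef(fit)[2])
  # a perfect (e.g. constant) series is a legitimate input; lm warns
  # about its zero residual variance
  se <- if (length(time_h) > 2)
    suppressWarnings(sqrt(diag(vcov(fit)))[2]) else NA_real_
  list(mu = mu, sd = unname(se))
}

#' Carbon content of a precursor demand vector
#'
#' Total mmol carbon per gDW implied by the demands, using the species
#' carbon counts of a network. Multiplied by the growth rate this is the
#' biomass carbon accumulation rate.
#'
#' @param demands a `precursor_demand`.
#' @param net a `flux_network` providing carbon counts.
#' @return scalar, mmol C per gDW.
#' @export
demand_carbon <- function(demands, net) {
  sum(demands$mmol_per_gDW * species_carbons(net, demands$species))
}
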