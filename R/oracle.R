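# Brute-force positional isotopomer simulation.
#
# Verification oracle for the EMU path: integrates all 2^C isotopomer
# fractions of every balanced species (independence of co-substrate pools
# assumed, as in the EMU framework) and marginalizes to MIDs. Deliberately
# implemented with deSolve::lsoda and plain R, independent of the
# compiled EMU integrator.

#' Brute-force isotopomer time-course simulation
#'
#' @inheritParams simulate_labeling
#' @param carbon_cap refuse species with more carbons than this (state
#'   space is 2^C per species).
#' @return a `mid_timecourse` for the requested targets.
#' @export
brute_force_isotopomer <- function(net, fluxes, pools, input = label_input(),
                                   times = c(0, 30, 60, 180, 300, 600),
                                   targets = NULL, dilution = NULL,
                                   p13_natural = 0, carbon_cap = 6,
                                   rtol = 1e-10, atol = 1e-12,
                                   flux_scale = FLUX_UMOL_PER_S) {
  check_steady_state(net, fluxes)
  sp <- net$species[!net$species$external & !is.na(net$species$carbons), ]
  if (any(sp$carbons > carbon_cap))
    stop("carbon cap exceeded: ",
         paste(sp$id[sp$carbons > carbon_cap], collapse = ", "))
  if (is.null(targets)) targets <- sp$id

  nstates <- 2^sp$carbons
  offsets <- cumsum(c(0, head(nstates, -1)))
  names(offsets) <- sp$id
  names(nstates) <- sp$id
  pv <- pools[sp$id]
  if (anyNA(pv)) stop("missing pool sizes for: ",
                      paste(sp$id[is.na(pv)], collapse = ", "))

  urxns <- expand_unidirectional(net)
  uv <- unidirectional_fluxes(net, fluxes, urxns)
  ext_sp <- net$species$id[net$species$external]
  p_src <- source_p13(input, p13_natural)

  iso_dist <- function(nc, p) {
    # independent per-carbon labeling probability p over 2^nc isotopomers
    v <- 1
    for (i in seq_len(nc)) v <- as.vector(outer(v, c(1 - p, p)))
    v
  }

  # Precompute per unidirectional reaction: lhs instance descriptors and,
  # per rhs instance, the map combo index -> product isotopomer index.
  plans <- list()
  for (ur in urxns) {
    w <- uv[[ur$id]] * ur$weight * flux_scale
    has_map <- length(ur$rhs) > 0 &&
      all(vapply(c(ur$lhs, ur$rhs), function(t) !is.null(t$atoms), logical(1)))
    if (!has_map || w == 0) next
    l_sp <- vapply(ur$lhs, `[[`, character(1), "species")
    l_nc <- vapply(ur$lhs, function(t) length(t$atoms), numeric(1))
    ncomb <- prod(2^l_nc)
    # bit value of each lhs letter within the combo index
    letter_bit <- list()
    shift <- 0
    for (k in seq_along(ur$lhs)) {
      at <- ur$lhs[[k]]$atoms
      for (j in seq_along(at)) letter_bit[[at[j]]] <- 2^(shift + j - 1)
      shift <- shift + length(at)
    }
    combos <- 0:(ncomb - 1)
    rhs_maps <- lapply(ur$rhs, function(t) {
      idx <- numeric(ncomb)
      for (j in seq_along(t$atoms)) {
        bit <- letter_bit[[t$atoms[j]]]
        idx <- idx + ifelse(bitwAnd(combos, bit) > 0, 2^(j - 1), 0)
      }
      split(seq_len(ncomb), idx)   # product isotopomer (0-based) -> combo rows
    })
    plans[[length(plans) + 1]] <-
      list(w = w, l_sp = l_sp, l_nc = l_nc,
           l_ext = l_sp %in% ext_sp,
           rhs_sp = vapply(ur$rhs, `[[`, character(1), "species"),
           rhs_maps = rhs_maps)
  }

  # production-weight totals per species (= turnover at steady state)
  totalin <- setNames(numeric(nrow(sp)), sp$id)
  for (pl in plans) for (s in pl$rhs_sp)
    if (s %in% sp$id) totalin[s] <- totalin[s] + pl$w

  ext_dists <- lapply(setNames(nm = ext_sp), function(s) {
    nc <- species_carbons(net, s)
    iso_dist(nc, p_src)
  })

  deriv <- function(t, y, parms) {
    dy <- numeric(length(y))
    for (pl in plans) {
      joint <- 1
      for (k in seq_along(pl$l_sp)) {
        s <- pl$l_sp[k]
        xs <- if (pl$l_ext[k]) ext_dists[[s]]
              else y[(offsets[s] + 1):(offsets[s] + nstates[s])]
        joint <- as.vector(outer(joint, xs))
      }
      for (k in seq_along(pl$rhs_sp)) {
        s <- pl$rhs_sp[k]
        if (!s %in% sp$id) next
        prod_v <- vapply(pl$rhs_maps[[k]], function(rows) sum(joint[rows]),
                         numeric(1))
        iso0 <- as.integer(names(pl$rhs_maps[[k]]))
        rng <- offsets[s] + 1 + iso0
        dy[rng] <- dy[rng] + pl$w * prod_v
      }
    }
    for (s in sp$id) {
      rng <- (offsets[s] + 1):(offsets[s] + nstates[s])
      dy[rng] <- (dy[rng] - totalin[s] * y[rng]) / pv[s]
    }
    list(dy)
  }

  y0 <- unlist(lapply(sp$carbons, iso_dist, p = p13_natural))
  tt <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::lsoda(y0, tt, deriv, parms = NULL, rtol = rtol, atol = atol)
  sol <- sol[match(times, sol[, 1]), -1, drop = FALSE]

  # marginalize isotopomers to MIDs
  out <- list()
  for (nm in targets) {
    nc <- species_carbons(net, nm)
    counts <- vapply(0:(nstates[nm] - 1), function(i)
      sum(bitwAnd(i, 2^(0:(nc - 1))) > 0), numeric(1))
    m <- matrix(0, length(times), nc + 1,
                dimnames = list(NULL, paste0("M", 0:nc)))
    block <- sol[, (offsets[nm] + 1):(offsets[nm] + nstates[nm]), drop = FALSE]
    for (k in 0:nc) m[, k + 1] <- rowSums(block[, counts == k, drop = FALSE])
    d <- if (!is.null(dilution) && nm %in% names(dilution)) dilution[[nm]] else 0
    if (d > 0) {
      unl <- dbinom(0:nc, nc, p13_natural)
      m <- (1 - d) * m + d * matrix(unl, nrow(m), nc + 1, byrow = TRUE)
    }
    out[[nm]] <- m
  }
  structure(list(times = times, mids = out), class = "mid_timecourse",
            iso_state = sol, iso_offsets = offsets, iso_nstates = nstates)
}

#' Per-carbon 13C enrichment from the brute-force isotopomer solution
#'
#' Positional labeling fractions for one species at the final simulated
#' time, computed from the full isotopomer distribution. Used to verify
#' that symmetric metabolites (succinate, fumarate) scramble positions
#' 50/50: their end-to-end mirrored positions must be equally enriched.
#'
#' @inheritParams brute_force_isotopomer
#' @param species species id.
#' @param time evaluation time (s).
#' @return numeric vector, 13C fraction at each carbon position.
#' @export
brute_force_positional <- function(net, fluxes, pools, species, time = 600,
                                   input = label_input(), p13_natural = 0,
                                   flux_scale = FLUX_UMOL_PER_S) {
  res <- brute_force_isotopomer(net, fluxes, pools, input = input,
                                times = c(0, time), targets = species,
                                p13_natural = p13_natural,
                                flux_scale = flux_scale)
  sol <- attr(res, "iso_state")
  offsets <- attr(res, "iso_offsets")
  nc <- species_carbons(net, species)
  x <- sol[nrow(sol), (offsets[species] + 1):(offsets[species] + 2^nc)]
  vapply(seq_len(nc), function(pos)
    sum(x[bitwAnd(0:(2^nc - 1), 2^(pos - 1)) > 0]), numeric(1))
}
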