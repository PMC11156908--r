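# Transient label simulation on the EMU system.
#
# Units: net/exchange fluxes in mmol gDW^-1 h^-1, pool sizes in umol
# gDW^-1, time in seconds. Fluxes are converted at the boundary with the
# factor 1000/3600 (mmol/h -> umol/s), so the labeling rate constant of a
# pool is v * 1000/3600 / P per second.

FLUX_UMOL_PER_S <- 1000 / 3600

#' Describe the step-change label input
#'
#' The tracer (13C bicarbonate) is modeled as an ideal step at t = 0 on
#' the external inorganic-carbon pool: after the bolus a fraction
#' `unlabeled_fraction` of the pool remains unlabeled carbon and the rest
#' is tracer of isotopic purity `purity`.
#'
#' @param purity 13C atom purity of the tracer (default 0.99).
#' @param unlabeled_fraction residual unlabeled fraction of the inorganic
#'   carbon pool after the bolus (default 0.05).
#' @return list of class `label_input`.
#' @export
label_input <- function(purity = 0.99, unlabeled_fraction = 0.05) {
  stopifnot(purity >= 0, purity <= 1,
            unlabeled_fraction >= 0, unlabeled_fraction <= 1)
  structure(list(purity = purity, unlabeled_fraction = unlabeled_fraction),
            class = "label_input")
}

# effective per-atom 13C probability of the source pool after the step
source_p13 <- function(input, p13_background = 0) {
  (1 - input$unlabeled_fraction) * input$purity +
    input$unlabeled_fraction * p13_background
}

#' Simulate transient mass isotopomer distributions after a 13C step
#'
#' Integrates the transient EMU balances d(P x)/dt = sum(v_in * conv) -
#' sum(v_out) * x for the minimal EMU system of the requested targets,
#' with the external inorganic-carbon pool held at its post-bolus MID.
#' The initial condition is unlabeled (or natural abundance when
#' `p13_natural > 0`). Dilution parameters mix each observed MID with the
#' unlabeled MID: observed = (1-d) * active + d * unlabeled.
#'
#' @param net a `flux_network`.
#' @param fluxes data.frame with columns `id`, `net`, and optionally
#'   `exch` (nonnegative exchange fluxes, zero for irreversible
#'   reactions), mmol gDW^-1 h^-1.
#' @param pools named vector of pool sizes (umol gDW^-1) for all balanced
#'   species reached by the decomposition.
#' @param input a [label_input()].
#' @param times sampling times in seconds, sorted, starting at 0.
#' @param targets measured metabolites (species ids or EMU keys); defaults
#'   to all balanced species with atom maps.
#' @param dilution named vector of inactive-pool fractions in `[0,1)` per
#'   measured metabolite (applied to outputs).
#' @param emunet optional precomputed [decompose_emu()] result.
#' @param p13_natural background 13C natural abundance used for initial
#'   condition and dilution pools (0 disables; typical 0.0107).
#' @param steady_tol tolerance on `||S v||` for the metabolic steady
#'   state check.
#' @param rtol,atol integrator tolerances.
#' @param flux_scale conversion factor from flux units to umol/s (default
#'   `1000/3600` for mmol/h); set to 1 for dimensionless toy problems.
#' @return object of class `mid_timecourse`: list with `times` and `mids`,
#'   a named list of matrices (time x mass shift M+0..M+n).
#' @export
simulate_labeling <- function(net, fluxes, pools, input = label_input(),
                              times = c(0, 30, 60, 180, 300, 600),
                              targets = NULL, dilution = NULL, emunet = NULL,
                              p13_natural = 0, steady_tol = 1e-6,
                              rtol = 1e-8, atol = 1e-10,
                              flux_scale = FLUX_UMOL_PER_S) {
  stopifnot(!is.unsorted(times))
  if (is.null(targets)) {
    ok <- !net$species$external & !is.na(net$species$carbons)
    targets <- net$species$id[ok]
  }
  if (is.null(emunet)) emunet <- decompose_emu(net, targets)
  check_steady_state(net, fluxes, tol = steady_tol)

  sysd <- build_emu_system(net, emunet, fluxes, pools, input,
                           p13_natural = p13_natural,
                           flux_scale = flux_scale)
  t0_extra <- times[1] > 0
  tt <- if (t0_extra) c(0, times) else times
  res <- .emu_integrate_cpp(sysd$sizes, sysd$offsets, sysd$pools,
                            sysd$term_emu, sysd$term_w, sysd$term_nsrc,
                            sysd$src_type, sysd$src_idx, sysd$ext_mids,
                            sysd$x0, tt, rtol, atol, sysd$hmax, 400000L)
  if (t0_extra) res <- res[-1, , drop = FALSE]
  extract_mids(emunet, sysd, res, times, targets, dilution, p13_natural)
}

check_steady_state <- function(net, fluxes, tol = 1e-6) {
  S <- stoichiometric_matrix(net)
  v <- fluxes$net[match(colnames(S), fluxes$id)]
  if (anyNA(v)) stop("flux table missing reactions: ",
                     paste(colnames(S)[is.na(v)], collapse = ", "))
  resid <- S %*% v
  if (max(abs(resid)) > tol)
    stop("flux vector is not at metabolic steady state; worst species: ",
         rownames(S)[which.max(abs(resid))],
         sprintf(" (|S v| = %.3g)", max(abs(resid))))
  invisible(TRUE)
}

# Assemble the flattened system description consumed by the C++ kernel.
# The flux-independent structure (EMU indexing, producer-term topology) is
# compiled once and cached inside the emu_network; per call only weights,
# pools and source MIDs are refreshed.
emu_system_static <- function(net, emunet) {
  cache <- emunet$cache
  if (!is.null(cache) && !is.null(cache$static)) return(cache$static)
  emus <- emunet$emus
  n <- nrow(emus)
  sizes <- as.integer(emus$size)
  offsets <- as.integer(cumsum(c(0L, head(sizes + 1L, -1))))
  key_idx <- setNames(seq_len(n), emus$key)
  ext_sp <- net$species$id[net$species$external]
  urxn_ids <- vapply(emunet$urxns, `[[`, character(1), "id")

  nr <- length(emunet$reactions)
  term_emu <- integer(nr); term_urxn <- integer(nr); term_wfac <- numeric(nr)
  term_nsrc <- integer(nr)
  src_type <- integer(); src_idx <- integer()
  ext_keys <- character(); ext_sizes <- integer()
  for (i in seq_len(nr)) {
    r <- emunet$reactions[[i]]
    term_emu[i] <- key_idx[[r$product]] - 1L
    term_urxn[i] <- match(r$urxn, urxn_ids)
    term_wfac[i] <- r$weight
    term_nsrc[i] <- length(r$sources)
    for (s in r$sources) {
      p <- parse_emu_key(s)
      if (p$species %in% ext_sp) {
        if (!s %in% ext_keys) {
          ext_keys <- c(ext_keys, s)
          ext_sizes <- c(ext_sizes, length(p$positions))
        }
        src_type <- c(src_type, 1L)
        src_idx <- c(src_idx, match(s, ext_keys) - 1L)
      } else {
        src_type <- c(src_type, 0L)
        src_idx <- c(src_idx, key_idx[[s]] - 1L)
      }
    }
  }
  static <- list(sizes = sizes, offsets = offsets, key_idx = key_idx,
                 species = emus$species, term_emu = term_emu,
                 term_urxn = term_urxn, term_wfac = term_wfac,
                 term_nsrc = term_nsrc, src_type = src_type,
                 src_idx = src_idx, ext_sizes = ext_sizes)
  if (!is.null(cache)) cache$static <- static
  static
}

build_emu_system <- function(net, emunet, fluxes, pools, input,
                             p13_natural = 0, flux_scale = FLUX_UMOL_PER_S) {
  st <- emu_system_static(net, emunet)
  pv <- pools[st$species]
  if (anyNA(pv))
    stop("missing pool sizes for: ",
         paste(unique(st$species[is.na(pv)]), collapse = ", "))
  if (any(pv <= 0)) stop("pool sizes must be strictly positive")

  uv <- unidirectional_fluxes(net, fluxes, emunet$urxns)
  p_src <- source_p13(input, p13_natural)
  term_w <- uv[st$term_urxn] * st$term_wfac * flux_scale
  ext_list <- lapply(st$ext_sizes, function(sz) dbinom(0:sz, sz, p_src))
  x0 <- unlist(lapply(st$sizes, function(sz) dbinom(0:sz, sz, p13_natural)))
  ti <- tapply(term_w, st$term_emu, sum)
  rates <- ti / pv[as.integer(names(ti)) + 1L]
  hmax <- max(1, min(600, if (length(rates) && max(rates) > 0)
    50 / max(rates) else 600))
  list(sizes = st$sizes, offsets = st$offsets, pools = as.numeric(pv),
       term_emu = st$term_emu, term_w = as.numeric(term_w),
       term_nsrc = st$term_nsrc, src_type = st$src_type,
       src_idx = st$src_idx, ext_mids = ext_list,
       x0 = x0, hmax = hmax, key_idx = st$key_idx)
}

extract_mids <- function(emunet, sysd, res, times, targets, dilution,
                         p13_natural) {
  out <- list()
  for (i in seq_along(emunet$targets)) {
    key <- emunet$targets[i]
    nm <- targets[i]
    idx <- sysd$key_idx[[key]]
    off <- sysd$offsets[idx]; sz <- sysd$sizes[idx]
    m <- res[, (off + 1):(off + sz + 1), drop = FALSE]
    d <- if (!is.null(dilution) && nm %in% names(dilution)) dilution[[nm]] else 0
    if (d < 0 || d >= 1) stop("dilution fractions must be in [0,1)")
    if (d > 0) {
      unl <- dbinom(0:sz, sz, p13_natural)
      m <- (1 - d) * m + d * matrix(unl, nrow(m), sz + 1, byrow = TRUE)
    }
    dimnames(m) <- list(NULL, paste0("M", 0:sz))
    out[[nm]] <- m
  }
  structure(list(times = times, mids = out), class = "mid_timecourse")
}

#' @export
print.mid_timecourse <- function(x, ...) {
  cat(sprintf("<mid_timecourse> %d metabolites x %d time points (%g-%g s)\n",
              length(x$mids), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Long-format view of a simulated MID time course
#' @param x a `mid_timecourse`.
#' @param ... unused.
#' @return data.frame with columns metabolite, mass, time_s, mole_fraction.
#' @export
as.data.frame.mid_timecourse <- function(x, ...) {
  rows <- lapply(names(x$mids), function(nm) {
    m <- x$mids[[nm]]
    data.frame(metabolite = nm,
               mass = rep(0:(ncol(m) - 1), each = nrow(m)),
               time_s = rep(x$times, ncol(m)),
               mole_fraction = as.vector(m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Algebraic steady-state MIDs (t -> infinity limit)
#'
#' Solves the EMU balances with time derivatives set to zero, size block
#' by size block; within a block only single-source transfers couple EMUs
#' of equal size, so each block is a linear solve.
#'
#' @inheritParams simulate_labeling
#' @return named list of steady MID vectors per target.
#' @export
steady_state_mids <- function(net, fluxes, input = label_input(),
                              targets = NULL, dilution = NULL, emunet = NULL,
                              p13_natural = 0) {
  if (is.null(targets)) {
    ok <- !net$species$external & !is.na(net$species$carbons)
    targets <- net$species$id[ok]
  }
  if (is.null(emunet)) emunet <- decompose_emu(net, targets)
  emus <- emunet$emus
  uv <- unidirectional_fluxes(net, fluxes, emunet$urxns)
  ext_sp <- net$species$id[net$species$external]
  p_src <- source_p13(input, p13_natural)
  sol <- list()
  src_mid <- function(key) {
    p <- parse_emu_key(key)
    sz <- length(p$positions)
    if (p$species %in% ext_sp) dbinom(0:sz, sz, p_src) else sol[[key]]
  }
  for (sz in sort(unique(emus$size))) {
    keys <- emus$key[emus$size == sz]
    nb <- sz + 1
    nk <- length(keys)
    A <- matrix(0, nk * nb, nk * nb)
    rhs <- numeric(nk * nb)
    for (ki in seq_len(nk)) {
      key <- keys[ki]
      rows <- ((ki - 1) * nb + 1):(ki * nb)
      prods <- Filter(function(r) r$product == key, emunet$reactions)
      totalin <- sum(vapply(prods, function(r) uv[[r$urxn]] * r$weight,
                            numeric(1)))
      if (totalin <= 0) {
        # no flux through this EMU: stays at initial (unlabeled) MID
        A[rows, rows] <- diag(nb)
        rhs[rows] <- dbinom(0:sz, sz, p13_natural)
        next
      }
      A[rows, rows] <- diag(nb) * totalin
      for (r in prods) {
        w <- uv[[r$urxn]] * r$weight
        if (w == 0) next
        if (length(r$sources) == 1 && r$sources %in% keys &&
            !(parse_emu_key(r$sources)$species %in% ext_sp)) {
          kj <- match(r$sources, keys)
          cols <- ((kj - 1) * nb + 1):(kj * nb)
          A[rows, cols] <- A[rows, cols] - diag(nb) * w
        } else {
          mids <- lapply(r$sources, src_mid)
          conv <- Reduce(convolve_mid, mids)
          rhs[rows] <- rhs[rows] + w * conv
        }
      }
    }
    x <- solve(A, rhs)
    for (ki in seq_len(nk)) sol[[keys[ki]]] <- x[((ki - 1) * nb + 1):(ki * nb)]
  }
  out <- list()
  for (i in seq_along(emunet$targets)) {
    key <- emunet$targets[i]; nm <- targets[i]
    v <- sol[[key]]
    d <- if (!is.null(dilution) && nm %in% names(dilution)) dilution[[nm]] else 0
    if (d > 0) v <- (1 - d) * v + d * dbinom(0:(length(v) - 1),
                                             length(v) - 1, p13_natural)
    out[[nm]] <- v
  }
  out
}

#' Natural isotope abundance convolution and correction
#'
#' Forward mode convolves a tracer MID with the binomial natural-abundance
#' distribution of the fragment's carbons (each non-tracer 13C with
#' probability `p13`); correction inverts the same linear map and
#' renormalizes.
#'
#' @param mid mole-fraction vector (M+0..M+n).
#' @param n_carbons number of carbons in the fragment.
#' @param p13 natural 13C abundance (default 0.0107).
#' @param direction `"forward"` (simulate what the MS sees) or
#'   `"correct"` (recover the tracer MID from a measured one).
#' @param clip negative entries smaller than `-1e-6` after correction
#'   raise a warning and are clipped to zero.
#' @return corrected/convolved mole-fraction vector.
#' @export
natural_abundance <- function(mid, n_carbons = length(mid) - 1, p13 = 0.0107,
                              direction = c("forward", "correct"),
                              clip = TRUE) {
  direction <- match.arg(direction)
  stopifnot(p13 >= 0, p13 <= 0.05, length(mid) == n_carbons + 1)
  A <- nat_ab_matrix(n_carbons, p13)
  if (direction == "forward") {
    as.vector(A %*% mid)
  } else {
    x <- as.vector(solve(A, mid))
    if (any(x < -1e-6)) {
      warning("natural-abundance correction produced negative entries; clipped")
      if (clip) x <- pmax(x, 0)
    } else x <- pmax(x, 0)
    x / sum(x)
  }
}

# A[k+1, m+1] = P(observe M+k | tracer labeling M+m)
nat_ab_matrix <- function(n, p13) {
  A <- matrix(0, n + 1, n + 1)
  for (m in 0:n) for (k in m:n)
    A[k + 1, m + 1] <- dbinom(k - m, n - m, p13)
  A
}
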