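# Flux estimation from transient MID measurements.
#
# Free parameters: steady-state null-space coordinates theta (every
# candidate satisfies S v = 0 exactly by construction), exchange fluxes
# on a bounded [0,1) ratio scale (INCA convention, exch = r / (1 - r)),
# pool sizes on a log10 scale, and optional dilution fractions.
# Optimization is multi-start bounded Levenberg-Marquardt on the
# SD-weighted residual vector; irreversibility is enforced by smooth
# hinge penalty residuals that are zero at any feasible point (they are
# excluded from the reported SSR, which at the optimum equals the pure
# measurement SSR).

#' Fitting configuration
#'
#' @param starts number of random multi-starts (the study protocol uses
#'   at least 100; recovery tests use fewer on reduced networks).
#' @param seed master RNG seed; fixed seed gives identical fits.
#' @param fit_pools fit pool sizes (log10 scale) for all species in the
#'   EMU system not listed in `fixed_pools` of [fit_fluxes()].
#' @param fit_dilution fit an inactive-pool dilution fraction per
#'   measured metabolite.
#' @param pool_bounds pool size bounds, umol gDW^-1.
#' @param pool_start_range log-uniform random start range for pools.
#' @param theta_bound box bound on null-space coordinates.
#' @param exch_ratio_max upper bound of the exchange ratio scale.
#' @param exch_scale flux scale of the exchange transform
#'   (exch = scale * r / (1 - r)).
#' @param sd_floor lower bound applied to measurement SDs (mole
#'   fraction).
#' @param rtol,atol simulation tolerances during fitting.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param penalty_weight weight of the irreversibility hinge penalty.
#' @param init_par optional full parameter vector used as the first start
#'   (e.g. a previous fit of a closely related dataset); remaining starts
#'   are random.
#' @param ftol,ptol Levenberg-Marquardt stopping tolerances (tighten for
#'   noise-free recovery studies).
#' @param epsfcn finite-difference step control for the numerical
#'   Jacobian (minpack semantics: FD steps are ~sqrt(epsfcn) relative).
#'   The default 0 uses machine-precision steps: at tight integrator
#'   tolerances the adaptive step sequence is locally frozen, so the
#'   simulated residuals are smooth at machine scale and exact-step
#'   differences give far cleaner derivatives than coarse ones.
#' @export
fit_config <- function(starts = 20, seed = 1, fit_pools = TRUE,
                       fit_dilution = FALSE, pool_bounds = c(1e-3, 1e3),
                       pool_start_range = c(0.1, 10), theta_bound = 50,
                       exch_ratio_max = 0.8, exch_scale = 1,
                       sd_floor = 0.005, rtol = 1e-9, atol = 1e-11,
                       maxiter = 100, penalty_weight = 1000,
                       init_par = NULL, ftol = 1e-10, ptol = 1e-8,
                       epsfcn = 0) {
  as.list(environment())
}

# Internal: assemble the fit problem (parameter spec + residual closure).
build_fit_problem <- function(net, measurements, config, fixed_pools = NULL) {
  mids <- measurements$mids
  mids$sd <- pmax(mids$sd, config$sd_floor)
  measured <- unique(mids$metabolite)
  emunet <- decompose_emu(net, measured)
  basis <- free_flux_basis(net)
  rid <- reaction_ids(net)
  rev_ids <- rid[vapply(net$reactions, `[[`, logical(1), "reversible")]
  irrev <- !vapply(net$reactions, `[[`, logical(1), "reversible")

  pool_species <- unique(emunet$emus$species)
  fit_pool_sp <- if (config$fit_pools)
    setdiff(pool_species, names(fixed_pools)) else character()
  if (!config$fit_pools || length(setdiff(pool_species, c(fit_pool_sp, names(fixed_pools)))))
    if (length(setdiff(pool_species, c(fit_pool_sp, names(fixed_pools)))))
      stop("missing fixed pools for: ",
           paste(setdiff(pool_species, c(fit_pool_sp, names(fixed_pools))),
                 collapse = ", "))
  dil_mets <- if (config$fit_dilution) measured else character()

  par_names <- c(if (basis$free_dim) paste0("theta", seq_len(basis$free_dim)),
                 if (length(rev_ids)) paste0("exch:", rev_ids),
                 if (length(fit_pool_sp)) paste0("pool:", fit_pool_sp),
                 if (length(dil_mets)) paste0("dil:", dil_mets))
  n_theta <- basis$free_dim
  n_exch <- length(rev_ids)
  n_pool <- length(fit_pool_sp)
  n_dil <- length(dil_mets)
  lower <- c(rep(-config$theta_bound, n_theta), rep(0, n_exch),
             rep(log10(config$pool_bounds[1]), n_pool), rep(0, n_dil))
  upper <- c(rep(config$theta_bound, n_theta),
             rep(config$exch_ratio_max, n_exch),
             rep(log10(config$pool_bounds[2]), n_pool),
             rep(0.95, n_dil))

  times <- sort(unique(mids$time_s))
  # lookup indices from measurement rows into the simulated MID matrices
  mid_sizes <- setNames(species_carbons(net, measured), measured)
  if (any(mids$mass > mid_sizes[mids$metabolite]))
    stop("measurement with no simulated counterpart (mass exceeds carbons)")
  row_t <- match(mids$time_s, times)
  row_met <- mids$metabolite
  row_col <- mids$mass + 1

  fm <- measurements$flux_meas

  # fast simulation path: precompiled system structure, direct kernel call
  static <- emu_system_static(net, emunet)
  urxns <- emunet$urxns
  urxn_base <- match(vapply(urxns, `[[`, character(1), "base"), rid)
  urxn_fwd <- vapply(urxns, `[[`, character(1), "dir") == "f"
  target_keys <- vapply(measured, function(m)
    emu_key(m, seq_len(mid_sizes[[m]])), character(1))
  tk_idx <- vapply(target_keys, function(k) static$key_idx[[k]], numeric(1))
  # flat column index of each measurement row in the kernel output matrix
  flat_col <- static$offsets[tk_idx[match(row_met, measured)]] + row_col
  p_src <- source_p13(label_input())
  ext_mids <- lapply(static$ext_sizes, function(sz) dbinom(0:sz, sz, p_src))
  x0 <- unlist(lapply(static$sizes, function(sz) dbinom(0:sz, sz, 0)))
  t0_extra <- times[1] > 0
  tt <- if (t0_extra) c(0, times) else times
  fast_sim_values <- function(v, exch_named, pools, dil) {
    uv <- ifelse(urxn_fwd, pmax(v[urxn_base], 0), pmax(-v[urxn_base], 0)) +
      exch_named[urxn_base]
    term_w <- uv[static$term_urxn] * static$term_wfac * FLUX_UMOL_PER_S
    pv <- pools[static$species]
    if (anyNA(pv) || any(pv <= 0)) stop("invalid pools")
    # stiffness guard: parameter corners (huge exchange over tiny pools)
    # would cost millions of explicit steps; treat them as infeasible
    ti <- rowsum(term_w, static$term_emu)
    if (max(ti / pv[as.integer(rownames(ti)) + 1L]) > 50)
      stop("turnover too fast for the labeling window")
    res <- .emu_integrate_cpp(static$sizes, static$offsets, as.numeric(pv),
                              static$term_emu, as.numeric(term_w),
                              static$term_nsrc, static$src_type,
                              static$src_idx, ext_mids, x0, tt,
                              config$rtol, config$atol, 600, 30000L)
    if (t0_extra) res <- res[-1, , drop = FALSE]
    simv <- res[cbind(row_t, flat_col)]
    if (!is.null(dil)) {
      d <- dil[row_met]
      d[is.na(d)] <- 0
      unl <- as.numeric(row_col == 1)   # unlabeled MID entry (p13 = 0)
      simv <- (1 - d) * simv + d * unl
    }
    simv
  }

  decode <- function(par) {
    theta <- par[seq_len(n_theta)]
    v <- basis$reconstruct(theta)
    exch <- setNames(numeric(length(rid)), rid)
    if (n_exch) {
      r <- par[n_theta + seq_len(n_exch)]
      exch[rev_ids] <- config$exch_scale * r / (1 - r)
    }
    pools <- unlist(fixed_pools)
    if (n_pool) {
      pp <- 10^par[n_theta + n_exch + seq_len(n_pool)]
      pools <- c(pools, setNames(pp, fit_pool_sp))
    }
    dil <- if (n_dil)
      setNames(par[n_theta + n_exch + n_pool + seq_len(n_dil)], dil_mets)
    else NULL
    fluxes <- data.frame(id = rid, net = unname(v), exch = unname(exch[rid]),
                         stringsAsFactors = FALSE)
    list(fluxes = fluxes, pools = pools, dilution = dil, v = v)
  }

  fm_idx <- if (!is.null(fm)) match(fm$reaction, rid)

  residuals_at <- function(par) {
    theta <- par[seq_len(n_theta)]
    v <- basis$v0 + as.vector(basis$N %*% theta)
    exch_named <- setNames(numeric(length(rid)), rid)
    if (n_exch) {
      r <- par[n_theta + seq_len(n_exch)]
      exch_named[rev_ids] <- config$exch_scale * r / (1 - r)
    }
    pools <- unlist(fixed_pools)
    if (n_pool)
      pools <- c(pools, setNames(10^par[n_theta + n_exch + seq_len(n_pool)],
                                 fit_pool_sp))
    dil <- if (n_dil)
      setNames(par[n_theta + n_exch + n_pool + seq_len(n_dil)], dil_mets)
    else NULL
    simv <- tryCatch(fast_sim_values(v, exch_named, pools, dil),
                     error = function(e) NULL)
    if (is.null(simv)) {
      nres <- nrow(mids) + (if (!is.null(fm)) nrow(fm) else 0)
      return(list(res = rep(1e3, nres), pen = numeric(), ok = FALSE))
    }
    res <- (simv - mids$value) / mids$sd
    if (!is.null(fm)) res <- c(res, (v[fm_idx] - fm$value) / fm$sd)
    pen <- config$penalty_weight * pmin(v[irrev], 0)
    list(res = res, pen = pen, ok = TRUE)
  }

  fn <- function(par, extra_constraint = NULL) {
    r <- residuals_at(par)
    out <- c(r$res, r$pen)
    if (!is.null(extra_constraint)) out <- c(out, extra_constraint(par))
    out
  }

  n_meas <- nrow(mids) + (if (!is.null(fm)) nrow(fm) else 0)
  list(par_names = par_names, lower = lower, upper = upper,
       n_theta = n_theta, n_exch = n_exch, n_pool = n_pool, n_dil = n_dil,
       rev_ids = rev_ids, fit_pool_sp = fit_pool_sp, dil_mets = dil_mets,
       basis = basis, decode = decode, residuals_at = residuals_at,
       fn = fn, n_meas = n_meas, net = net, emunet = emunet,
       measurements = measurements, config = config, rid = rid,
       irrev = irrev, fixed_pools = fixed_pools)
}

meas_ssr <- function(problem, par) {
  r <- problem$residuals_at(par)
  sum(r$res^2)
}

# a feasible-ish starting theta: match measured fluxes, push irreversible
# fluxes positive
feasible_theta <- function(problem) {
  basis <- problem$basis
  fm <- problem$measurements$flux_meas
  irrev <- problem$irrev
  obj <- function(theta) {
    v <- basis$reconstruct(theta)
    s <- sum(pmax(0.05 - v[irrev], 0)^2) * 100
    if (!is.null(fm))
      s <- s + sum((v[match(fm$reaction, problem$rid)] - fm$value)^2)
    s + 1e-4 * sum(theta^2)
  }
  best <- NULL; bestv <- Inf
  for (k in 1:10) {
    th0 <- rnorm(basis$free_dim, 0, 0.5 * k)
    opt <- stats::nlminb(th0, obj, lower = -problem$config$theta_bound,
                         upper = problem$config$theta_bound)
    if (opt$objective < bestv) { bestv <- opt$objective; best <- opt$par }
    if (bestv < 1e-6) break
  }
  best
}

random_start <- function(problem, theta_center, spread) {
  cfg <- problem$config
  th <- theta_center + rnorm(problem$n_theta, 0, spread)
  r <- runif(problem$n_exch, 0, 0.8)
  lp <- runif(problem$n_pool, log10(cfg$pool_start_range[1]),
              log10(cfg$pool_start_range[2]))
  dl <- runif(problem$n_dil, 0, 0.3)
  pmin(pmax(c(th, r, lp, dl), problem$lower), problem$upper)
}

#' Estimate fluxes, pool sizes and dilution fractions from MID time courses
#'
#' Multi-start bounded least squares over free net fluxes (null-space
#' coordinates, so the metabolic steady state holds exactly for every
#' candidate), exchange-flux ratios, log pool sizes and optional dilution
#' fractions. Goodness of fit is assessed against the central 95%
#' chi-square range for df = number of measurements - number of fitted
#' parameters. Net CO2 uptake is read off the fitted sink-constrained
#' solution (the flux of the inorganic-carbon source reactions), never
#' supplied as an input.
#'
#' @param net a `flux_network`.
#' @param measurements a [measurement_set()].
#' @param config a [fit_config()].
#' @param fixed_pools named vector of pool sizes held fixed (required for
#'   species in the EMU system when `fit_pools = FALSE`).
#' @return object of class `flux_fit` with elements `fluxes` (data.frame
#'   id/net/exch), `pools`, `dilution`, `ssr`, `df`, `chisq_range`,
#'   `co2_uptake`, `par`, `start_trace`, `seed`.
#' @export
fit_fluxes <- function(net, measurements, config = fit_config(),
                       fixed_pools = NULL) {
  problem <- build_fit_problem(net, measurements, config, fixed_pools)
  if (config$starts < 1) stop("need at least one start")
  set.seed(config$seed)
  theta_c <- feasible_theta(problem)
  trace <- data.frame(start = seq_len(config$starts), ssr = NA_real_,
                      converged = FALSE)
  run_lm <- function(par0, maxiter) {
    tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par0, lower = problem$lower, upper = problem$upper,
                         fn = problem$fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = config$ptol,
                           ftol = config$ftol, epsfcn = config$epsfcn))),
      error = function(e) NULL)
  }
  # two-phase multistart: short exploratory runs from every start, then a
  # full-budget polish of the best basin
  explore_iter <- min(config$maxiter, 40)
  best <- NULL
  for (s in seq_len(config$starts)) {
    par0 <- if (s == 1 && !is.null(config$init_par))
      pmin(pmax(unname(config$init_par), problem$lower), problem$upper)
    else if (s == 1)
      pmin(pmax(c(theta_c, rep(0.2, problem$n_exch),
                  rep(0, problem$n_pool), rep(0.05, problem$n_dil)),
                problem$lower), problem$upper)
    else random_start(problem, theta_c, spread = 0.3 + 0.4 * (s %% 5))
    fit <- run_lm(par0, explore_iter)
    if (is.null(fit)) next
    ssr_s <- meas_ssr(problem, fit$par)
    trace$ssr[s] <- ssr_s
    trace$converged[s] <- fit$info %in% 1:4
    if (is.null(best) || ssr_s < best$ssr - 1e-12)
      best <- list(par = fit$par, ssr = ssr_s, start = s,
                   hessian = fit$hessian)
  }
  if (is.null(best)) stop("all starts failed to converge")
  if (config$maxiter > explore_iter) {
    polish <- run_lm(best$par, config$maxiter)
    if (!is.null(polish)) {
      ssr_p <- meas_ssr(problem, polish$par)
      if (ssr_p < best$ssr) {
        best$par <- polish$par; best$ssr <- ssr_p
        best$hessian <- polish$hessian
        trace$ssr[best$start] <- ssr_p
      }
    }
  }
  dec <- problem$decode(best$par)
  n_par <- length(problem$par_names)
  df <- problem$n_meas - n_par
  if (df <= 0) stop("non-positive degrees of freedom (df = ", df, ")")
  co2 <- co2_uptake_flux(net, dec$fluxes)
  structure(list(fluxes = dec$fluxes, pools = dec$pools,
                 dilution = dec$dilution,
                 par = setNames(best$par, problem$par_names),
                 ssr = best$ssr, df = df,
                 chisq_range = chi_square_range(df),
                 co2_uptake = co2, start_trace = trace,
                 best_start = best$start, seed = config$seed,
                 hessian = best$hessian, problem = problem),
            class = "flux_fit")
}

co2_uptake_flux <- function(net, fluxes) {
  src <- vapply(net$reactions, function(r) r$kind == "source", logical(1))
  sum(fluxes$net[match(reaction_ids(net)[src], fluxes$id)])
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("<flux_fit> SSR = %.4g [%.4g, %.4g] (df = %d)\n",
              x$ssr, x$chisq_range[1], x$chisq_range[2], x$df))
  cat(sprintf("  net CO2 uptake: %.4g mmol gDW-1 h-1 (estimated from sink demands)\n",
              x$co2_uptake))
  cat(sprintf("  best of %d starts (start %d), seed %d\n",
              nrow(x$start_trace), x$best_start, x$seed))
  invisible(x)
}

#' SD-weighted sum of squared residuals between simulation and data
#'
#' @param simulated a `mid_timecourse`.
#' @param measurements a `measurement_set` (only its MID part is used).
#' @param sd_floor lower bound on SDs.
#' @return scalar SSR.
#' @export
ssr <- function(simulated, measurements, sd_floor = 0) {
  mids <- measurements$mids
  bad <- !mids$metabolite %in% names(simulated$mids) |
    !mids$time_s %in% simulated$times
  if (any(bad))
    stop("measurement with no simulated counterpart: ",
         paste(unique(mids$metabolite[bad]), collapse = ", "))
  simv <- vapply(seq_len(nrow(mids)), function(i) {
    m <- simulated$mids[[mids$metabolite[i]]]
    m[match(mids$time_s[i], simulated$times), mids$mass[i] + 1]
  }, numeric(1))
  sum(((simv - mids$value) / pmax(mids$sd, sd_floor))^2)
}

#' Central chi-square acceptance range for the SSR test
#'
#' A statistically acceptable fit has SSR inside the central `1 - alpha`
#' chi-square interval for the fit's degrees of freedom.
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha significance level (default 0.05).
#' @return numeric vector `c(lo, hi)`.
#' @export
chi_square_range <- function(df, alpha = 0.05) {
  if (df < 1 || alpha <= 0 || alpha >= 1) stop("invalid df or alpha")
  c(qchisq(alpha / 2, df), qchisq(1 - alpha / 2, df))
}

#' Profile-likelihood (parameter continuation) confidence interval
#'
#' Walks the profiled quantity in adaptive steps, re-optimizing all other
#' parameters at each step (warm-started), until the measurement SSR
#' exceeds `SSR_min + qchisq(level, 1)`; the crossing point is located by
#' linear interpolation. A walk that reaches the parameter bounds without
#' crossing reports that side as unbounded (`-Inf`/`Inf`).
#'
#' @param fit a `flux_fit`.
#' @param parameter either a raw parameter name (see `names(fit$par)`) or
#'   `"flux:<reaction id>"` to profile a net reaction flux. The profiled
#'   quantity is pinned exactly by reparameterization (for a flux, the
#'   null-space coordinates are rotated so one axis is the flux and the
#'   optimizer works in the orthogonal complement), so every profile
#'   point still satisfies the steady-state balance exactly.
#' @param level confidence level (default 0.95).
#' @param step_frac initial step as a fraction of the parameter scale
#'   (coarser steps make the walk cheaper at some interpolation cost).
#' @param max_steps cap on continuation steps per direction.
#' @param maxiter re-optimization iteration cap.
#' @return list of class `profile_ci`: `parameter`, `estimate`, `lower`,
#'   `upper`, `level`, plus the profiled SSR traces.
#' @export
profile_ci <- function(fit, parameter, level = 0.95, step_frac = 0.02,
                       max_steps = 40, maxiter = 40) {
  problem <- fit$problem
  # the threshold tracks the lowest SSR seen anywhere along the profile:
  # if a constrained refit improves on the unconstrained fit (an
  # incompletely converged base fit), the reference moves down and the
  # interval stays conservative
  ssr_ref <- fit$ssr
  thr <- ssr_ref + qchisq(level, 1)
  is_flux <- grepl("^flux:", parameter)
  n_theta <- problem$n_theta
  np <- length(problem$par_names)
  if (is_flux) {
    rid0 <- sub("^flux:", "", parameter)
    j <- match(rid0, problem$rid)
    if (is.na(j)) stop("unknown reaction: ", rid0)
    n_vec <- problem$basis$N[j, ]
    if (sum(n_vec^2) < 1e-12)
      stop("flux is fully determined by the steady-state constraints: ", rid0)
    value_of <- function(par) {
      v0j <- problem$basis$v0[j]
      v0j + sum(n_vec * par[seq_len(n_theta)])
    }
    # rotate theta so one axis is the profiled flux; optimize the rest
    nb <- MASS::Null(matrix(n_vec, ncol = 1))          # n_theta x (n_theta-1)
    if (is.null(dim(nb))) nb <- matrix(nb, ncol = max(n_theta - 1, 0))
    reduce <- function(par) c(as.vector(crossprod(nb, par[seq_len(n_theta)])),
                              par[-seq_len(n_theta)])
    expand <- function(x, pr) {
      phi <- pr[seq_len(ncol(nb))]
      theta <- n_vec * (x - problem$basis$v0[j]) / sum(n_vec^2) +
        as.vector(nb %*% phi)
      c(theta, pr[-seq_len(ncol(nb))])
    }
    lower_red <- c(rep(-Inf, ncol(nb)), problem$lower[-seq_len(n_theta)])
    upper_red <- c(rep(Inf, ncol(nb)), problem$upper[-seq_len(n_theta)])
    vbound <- c(-1e3, 1e3)
    if (problem$irrev[j]) vbound[1] <- 0
  } else {
    k <- match(parameter, problem$par_names)
    if (is.na(k)) stop("unknown parameter: ", parameter)
    value_of <- function(par) par[k]
    reduce <- function(par) par[-k]
    expand <- function(x, pr) append(pr, x, after = k - 1)
    lower_red <- problem$lower[-k]
    upper_red <- problem$upper[-k]
    vbound <- c(problem$lower[k], problem$upper[k])
  }
  est <- value_of(fit$par)
  scale <- max(abs(est), 0.05)
  step0 <- step_frac * scale

  refit_at <- function(x, warm) {
    pr0 <- reduce(warm)
    opt <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(pr0, lower = lower_red, upper = upper_red,
                         fn = function(pr) problem$fn(expand(x, pr)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-7, ftol = 1e-8,
                           epsfcn = 0))),
      error = function(e) NULL)
    if (is.null(opt)) return(NULL)
    par_full <- expand(x, opt$par)
    s <- meas_ssr(problem, par_full)
    if (s < ssr_ref) {
      ssr_ref <<- s
      thr <<- ssr_ref + qchisq(level, 1)
    }
    list(par = par_full, ssr = s)
  }

  walk <- function(dir) {
    # start inside the feasible window (a soft-penalty optimum can sit
    # marginally outside an irreversibility bound)
    x <- min(max(est, vbound[1]), vbound[2])
    ssr_prev <- ssr_ref; warm <- fit$par
    step <- step0
    tracex <- numeric(); tracessr <- numeric()
    for (i in seq_len(max_steps)) {
      x_next <- x + dir * step
      hit_bound <- FALSE
      if (x_next < vbound[1]) { x_next <- vbound[1]; hit_bound <- TRUE }
      if (x_next > vbound[2]) { x_next <- vbound[2]; hit_bound <- TRUE }
      rf <- refit_at(x_next, warm)
      if (is.null(rf)) return(list(bound = NA_real_, at_bound = FALSE,
                                   x = tracex, ssr = tracessr,
                                   flagged = TRUE))
      tracex <- c(tracex, x_next); tracessr <- c(tracessr, rf$ssr)
      if (rf$ssr >= thr) {
        # crossing bracketed between (x, ssr_prev) and (x_next, rf$ssr):
        # localize it by regula falsi with a few cheap warm refits
        xlo <- x; slo <- ssr_prev
        xhi <- x_next; shi <- rf$ssr
        warm_lo <- warm
        for (b in 1:5) {
          frac <- (thr - slo) / (shi - slo)
          frac <- min(max(frac, 0.1), 0.9)
          xc <- xlo + frac * (xhi - xlo)
          rfc <- refit_at(xc, warm_lo)
          if (is.null(rfc)) break
          tracex <- c(tracex, xc); tracessr <- c(tracessr, rfc$ssr)
          if (rfc$ssr >= thr) { xhi <- xc; shi <- rfc$ssr }
          else { xlo <- xc; slo <- rfc$ssr; warm_lo <- rfc$par }
          if (abs(shi - thr) < 0.15 || abs(xhi - xlo) < 1e-3 * scale) break
        }
        frac <- (thr - slo) / (shi - slo)
        return(list(bound = xlo + frac * (xhi - xlo), at_bound = FALSE,
                    x = tracex, ssr = tracessr, flagged = FALSE))
      }
      if (hit_bound)
        return(list(bound = x_next, at_bound = TRUE, x = tracex,
                    ssr = tracessr, flagged = FALSE))
      # adaptive doubling while the profile is flat
      if (rf$ssr - ssr_prev < 0.1 * qchisq(level, 1)) step <- step * 2
      x <- x_next; ssr_prev <- rf$ssr; warm <- rf$par
    }
    list(bound = dir * Inf, at_bound = FALSE, x = tracex, ssr = tracessr,
         flagged = TRUE)
  }
  lo <- walk(-1); hi <- walk(1)
  structure(list(parameter = parameter, estimate = est,
                 lower = lo$bound, upper = hi$bound, level = level,
                 lower_at_bound = isTRUE(lo$at_bound),
                 upper_at_bound = isTRUE(hi$at_bound),
                 flagged = isTRUE(lo$flagged) || isTRUE(hi$flagged),
                 trace = list(lower = lo, upper = hi)),
            class = "profile_ci")
}

#' @export
print.profile_ci <- function(x, ...) {
  cat(sprintf("<profile_ci> %s = %.4g, %g%% CI [%.4g%s, %.4g%s]%s\n",
              x$parameter, x$estimate, 100 * x$level,
              x$lower, if (x$lower_at_bound) "*" else "",
              x$upper, if (x$upper_at_bound) "*" else "",
              if (x$flagged) " (flagged)" else ""))
  if (x$lower_at_bound || x$upper_at_bound)
    cat("  (* walk reached the parameter bound without crossing the threshold)\n")
  invisible(x)
}

#' Rescale a flux map so net CO2 uptake equals 100 units
#'
#' @param fluxes data.frame with columns `id`, `net` (a `flux_fit$fluxes`
#'   table), or a `flux_fit` (its own CO2 uptake is used).
#' @param co2_uptake net CO2 uptake in the same units as the fluxes
#'   (required unless `fluxes` is a `flux_fit`).
#' @return data.frame with an added `normalized` column (net flux per 100
#'   CO2 taken up); attribute `divisor` = co2_uptake / 100.
#' @export
normalize_to_co2 <- function(fluxes, co2_uptake = NULL) {
  if (inherits(fluxes, "flux_fit")) {
    if (is.null(co2_uptake)) co2_uptake <- fluxes$co2_uptake
    fluxes <- fluxes$fluxes
  }
  if (is.null(co2_uptake) || !is.finite(co2_uptake) || co2_uptake <= 0)
    stop("co2_uptake must be positive")
  fluxes$normalized <- fluxes$net * 100 / co2_uptake
  attr(fluxes, "divisor") <- co2_uptake / 100
  fluxes
}
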