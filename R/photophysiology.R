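# Chlorophyll fluorescence utilities: non-photochemical quenching, fast
# repetition rate fluorometry flash schedules, inhibitor effect tests.

#' Non-photochemical quenching
#'
#' NPQ = (Fm - Fm') / Fm', where Fm is the dark-adapted and Fm' the
#' light-adapted maximal fluorescence of saturated PSII.
#'
#' @param fm dark-adapted maximal fluorescence.
#' @param fm_prime light-adapted maximal fluorescence (> 0).
#' @return NPQ (vectorized).
#' @export
npq <- function(fm, fm_prime) {
  if (any(fm_prime <= 0)) stop("fm_prime must be positive")
  (fm - fm_prime) / fm_prime
}

#' Per-intensity NPQ means and SDs from replicate fluorescence records
#'
#' @param records data.frame with columns `intensity`, `fm`, `fm_prime`,
#'   and optionally `replicate`, `treatment`.
#' @return data.frame ordered by intensity (and treatment if present)
#'   with columns intensity, (treatment,) n, npq_mean, npq_sd (`NA` for
#'   single records).
#' @export
npq_curve <- function(records) {
  stopifnot(all(c("intensity", "fm", "fm_prime") %in% names(records)))
  records$npq <- npq(records$fm, records$fm_prime)
  keys <- intersect(c("intensity", "treatment"), names(records))
  agg <- stats::aggregate(records$npq, by = records[keys], FUN = function(v)
    c(n = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_))
  out <- cbind(agg[keys], as.data.frame(agg$x))
  names(out) <- c(keys, "n", "npq_mean", "npq_sd")
  out[do.call(order, out[rev(keys)]), , drop = FALSE]
}

#' Single-turnover flashlet schedule
#'
#' An excitation phase of constant-delay flashlets followed by a
#' relaxation phase whose delays grow geometrically: the i-th relaxation
#' delay is `base_delay_us * growth^(i-1)` (first delay = the base, each
#' subsequent one 2.5% longer with the default growth of 1.025). A
#' literal power-of-ten variant `10^(1.6 + 1.025 i)` microseconds is
#' available behind `literal_power_formula = TRUE`; it produces delays
#' that grow by more than a decade per flashlet and is kept only for
#' comparison.
#'
#' @param n_excitation number of excitation flashlets (default 175).
#' @param n_relaxation number of relaxation flashlets (default 127).
#' @param excitation_delay_us constant excitation delay (default 2.5).
#' @param base_delay_us first relaxation delay (default 20).
#' @param growth geometric growth rate of relaxation delays (default
#'   1.025).
#' @param literal_power_formula use the power-of-ten variant for the
#'   relaxation delays.
#' @return data.frame of class `flash_schedule` with columns `index`,
#'   `phase`, `delay_us`.
#' @export
st_flash_schedule <- function(n_excitation = 175, n_relaxation = 127,
                              excitation_delay_us = 2.5, base_delay_us = 20,
                              growth = 1.025,
                              literal_power_formula = FALSE) {
  stopifnot(n_excitation >= 1, n_relaxation >= 1, growth >= 1)
  relax <- if (literal_power_formula)
    10^(1.6 + 1.025 * seq_len(n_relaxation))
  else base_delay_us * growth^(seq_len(n_relaxation) - 1)
  out <- data.frame(
    index = seq_len(n_excitation + n_relaxation),
    phase = rep(c("excitation", "relaxation"), c(n_excitation, n_relaxation)),
    delay_us = c(rep(excitation_delay_us, n_excitation), relax))
  class(out) <- c("flash_schedule", "data.frame")
  out
}

#' Two-sample inhibitor effect test
#'
#' Two-sided t test between control and inhibitor-treated measurements;
#' Welch (unequal-variance) by default, pooled-variance optionally.
#' Degenerate zero-variance groups are flagged rather than raising.
#'
#' @param control,treated numeric vectors (n >= 2 each).
#' @param var_equal pool the variances (classical two-sample t test).
#' @return list with `t`, `df`, `p`, `degenerate` flag.
#' @export
inhibitor_effect_test <- function(control, treated, var_equal = FALSE) {
  if (length(control) < 2 || length(treated) < 2)
    stop("need at least two observations per group")
  if (var(control) == 0 && var(treated) == 0) {
    if (mean(control) == mean(treated))
      return(list(t = 0, df = length(control) + length(treated) - 2, p = 1,
                  degenerate = TRUE))
    return(list(t = Inf, df = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ht <- stats::t.test(control, treated, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}
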