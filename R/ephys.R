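#' Physical constants for Nernst/GHK arithmetic
#'
#' @param temperature_K Absolute temperature (default 298.15 K, 25 degC).
#' @return List with Faraday constant `F` (96485 C/mol), gas constant `R`
#'   (8.314 J/mol/K), `temperature_K`, and the thermal voltage `RT_F_mV`
#'   (about 25.693 mV at 298.15 K).
#' @export
physical_constants <- function(temperature_K = 298.15) {
  F_const <- 96485
  R_const <- 8.314
  list(F = F_const, R = R_const, temperature_K = temperature_K,
       RT_F_mV = 1000 * R_const * temperature_K / F_const)
}

#' Recording solution composition
#'
#' @param na_mM,cl_mM Na+ and Cl- concentrations (mM).
#' @param egta_mM Total EGTA (mM).
#' @param hepes_mM HEPES buffer (mM).
#' @param ca_total_mM Total added Ca2+ (mM).
#' @param ph pH.
#' @param temperature_K Temperature (K).
#' @return A `solution_composition` list.
#' @export
solution <- function(na_mM = 140, cl_mM = na_mM, egta_mM = 0, hepes_mM = 10,
                     ca_total_mM = 0, ph = 7.3, temperature_K = 298.15) {
  stop_if_not(all(c(na_mM, cl_mM, egta_mM, hepes_mM, ca_total_mM) >= 0),
              "concentrations must be >= 0")
  stop_if_not(ph > 0 && ph < 14, "pH must lie in (0, 14)")
  structure(list(na_mM = na_mM, cl_mM = cl_mM, egta_mM = egta_mM,
                 hepes_mM = hepes_mM, ca_total_mM = ca_total_mM, ph = ph,
                 temperature_K = temperature_K),
            class = "solution_composition")
}

#' Current-voltage curve from a step-protocol sweep set
#'
#' For each test level, the steady-state current is the mean over the final
#' fraction of the step (default the last 10%).
#'
#' @param sweep_set A `sweep_set` recorded under a `steps` protocol.
#' @param steady_fraction Final fraction of the step to average.
#' @return Data frame (`iv_curve`) with `voltage_mV` and `current_pA`.
#' @export
build_iv <- function(sweep_set, steady_fraction = 0.1) {
  p <- sweep_set$protocol
  stop_if_not(p$kind == "steps", "build_iv needs a steps protocol")
  stop_if_not(steady_fraction > 0 && steady_fraction <= 1,
              "steady_fraction must be in (0, 1]")
  step_start <- p$pre_duration_ms
  step_end <- p$pre_duration_ms + p$step_duration_ms
  win_start <- step_end - steady_fraction * p$step_duration_ms
  sw <- sweep_set$sweeps
  out <- lapply(p$step_levels_mV, function(v) {
    d <- sw[sw$level_mV == v & sw$time_ms >= win_start &
              sw$time_ms < step_end, ]
    stop_if_not(nrow(d) > 0, "no samples for step level %g mV", v)
    data.frame(voltage_mV = v, current_pA = mean(d$current_pA))
  })
  out <- do.call(rbind, out)
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' Normalized conductance-voltage curve from tail currents
#'
#' For each test level, the tail amplitude is the extreme current (sign set
#' by the dominant tail polarity across levels) within a window after
#' repolarization onset (default 10 ms). All tails are normalized to the
#' maximum so the G-V curve peaks at 1.
#'
#' @param sweep_set A `sweep_set` whose protocol has a repolarization
#'   segment.
#' @param tail_window_ms Search window after repolarization onset.
#' @return Data frame (`gv_curve`) with `voltage_mV`, `tail_pA`,
#'   `g_norm` (in `[0, 1]`, max exactly 1).
#' @export
build_gv <- function(sweep_set, tail_window_ms = 10) {
  p <- sweep_set$protocol
  stop_if_not(p$kind == "steps", "build_gv needs a steps protocol")
  stop_if_not(p$tail_duration_ms > 0, "protocol has no repolarization step")
  t0 <- p$pre_duration_ms + p$step_duration_ms
  sw <- sweep_set$sweeps
  tails <- vapply(p$step_levels_mV, function(v) {
    d <- sw[sw$level_mV == v & sw$time_ms >= t0 &
              sw$time_ms < t0 + tail_window_ms, ]
    stop_if_not(nrow(d) > 0, "no tail samples for level %g mV", v)
    d$current_pA[which.max(abs(d$current_pA))]
  }, numeric(1))
  stop_if_not(any(tails != 0), "all tail currents are zero; G-V undefined")
  sgn <- sign(tails[which.max(abs(tails))])  # dominant tail polarity
  amp <- pmax(sgn * tails, 0)
  out <- data.frame(voltage_mV = p$step_levels_mV, tail_pA = tails,
                    g_norm = amp / max(amp))
  class(out) <- c("gv_curve", "data.frame")
  out
}

#' Reversal potential from the descending phase of an inverted-V ramp
#'
#' Restricts the sweep to the descending (second) ramp phase and finds the
#' membrane potential at which the current crosses zero, linearly
#' interpolated between the bracketing samples. With multiple crossings
#' (noisy ramps) the crossing nearest `previous_erev_mV` is taken, or the
#' median crossing when no previous value exists; the multiplicity is
#' reported.
#'
#' @param sweep_set A `sweep_set` recorded under an `inverted_v_ramp`
#'   protocol (a plain `ramp` is analyzed whole).
#' @param previous_erev_mV Optional anchor for multi-crossing resolution.
#' @return List with `erev_mV`, `n_crossings`, and `phase` (`"descending"`
#'   or `"full"`).
#' @export
measure_erev <- function(sweep_set, previous_erev_mV = NULL) {
  p <- sweep_set$protocol
  sw <- sweep_set$sweeps
  sw <- sw[sw$sweep_id == sw$sweep_id[1], ]
  if (p$kind == "inverted_v_ramp") {
    apex <- which.max(sw$command_mV)
    sw <- sw[apex:nrow(sw), ]
    phase <- "descending"
  } else if (p$kind == "ramp") {
    phase <- "full"
  } else {
    stop("measure_erev needs a ramp protocol", call. = FALSE)
  }
  v <- sw$command_mV
  i <- sw$current_pA
  s <- sign(i)
  cross <- which(s[-1] * s[-length(s)] < 0 | (s[-length(s)] != 0 &
                                                s[-1] == 0))
  if (any(i == 0)) {
    zeroes <- v[i == 0]
  } else {
    zeroes <- numeric(0)
  }
  interp <- vapply(cross, function(k)
    v[k] + (v[k + 1] - v[k]) * (0 - i[k]) / (i[k + 1] - i[k]), numeric(1))
  cand <- unique(c(interp, zeroes))
  stop_if_not(length(cand) > 0, "no reversal in ramp range")
  erev <- if (length(cand) == 1L) {
    cand
  } else if (!is.null(previous_erev_mV)) {
    cand[which.min(abs(cand - previous_erev_mV))]
  } else {
    stats::median(cand)
  }
  list(erev_mV = erev, n_crossings = length(cand), phase = phase)
}

#' Goldman-Hodgkin-Katz potential for Na+ and Cl-
#'
#' Evaluates
#' \deqn{V_m = \frac{RT}{F}\,\ln\frac{P_{Na}[Na]_o + P_{Cl}[Cl]_i}
#'   {P_{Na}[Na]_i + P_{Cl}[Cl]_o}}
#' in mV (RT/F about 25.693 mV at 298.15 K).
#'
#' @param p_na,p_cl Relative permeabilities (>= 0, not both 0).
#' @param out,inn External and internal [solution()] compositions.
#' @param constants Output of [physical_constants()]; defaults to the
#'   temperature of `out`.
#' @return Potential in mV.
#' @export
ghk_potential <- function(p_na, p_cl, out, inn,
                          constants = physical_constants(out$temperature_K)) {
  num <- p_na * out$na_mM + p_cl * inn$cl_mM
  den <- p_na * inn$na_mM + p_cl * out$cl_mM
  stop_if_not(num > 0 && den > 0,
              "GHK numerator and denominator must be positive")
  constants$RT_F_mV * log(num / den)
}

#' Permeability ratio P_Cl/P_Na from a reversal-potential shift
#'
#' Closed-form inversion of the GHK voltage equation for the two-solution
#' dilution design: the measured potential is the reversal shift observed
#' when the internal solution is exchanged (e.g. 140 mM to 14 mM NaCl
#' internal against a constant 140 mM external). Writing
#' `e = exp(Vm F / RT)`, the ratio is
#' `P_Cl/P_Na = (Na_o - e * Na_i) / (e * Cl_o - Cl_i)`.
#' The shift must lie strictly inside the interval attainable for the given
#' solutions (about (-59.16, +59.16) mV for a 10:1 dilution at 25 degC);
#' the endpoints correspond to pure Cl- or pure Na+ selectivity.
#'
#' @param delta_erev_mV Measured reversal-potential shift (mV).
#' @param out,inn External and (post-switch) internal [solution()]s.
#' @param constants Output of [physical_constants()].
#' @return List with `p_cl_over_p_na` and the attainable interval
#'   `limits_mV`.
#' @export
ghk_permeability_ratio <- function(delta_erev_mV, out, inn,
                                   constants =
                                     physical_constants(out$temperature_K)) {
  rtf <- constants$RT_F_mV
  lim_lo <- rtf * log(inn$cl_mM / out$cl_mM)   # pure Cl- selectivity
  lim_hi <- rtf * log(out$na_mM / inn$na_mM)   # pure Na+ selectivity
  stop_if_not(delta_erev_mV > lim_lo && delta_erev_mV < lim_hi,
              paste("ratio not representable: shift %.3f mV outside",
                    "(%.3f, %.3f) mV"), delta_erev_mV, lim_lo, lim_hi)
  e <- exp(delta_erev_mV / rtf)
  ratio <- (out$na_mM - e * inn$na_mM) / (e * out$cl_mM - inn$cl_mM)
  list(p_cl_over_p_na = ratio, limits_mV = c(lim_lo, lim_hi))
}

#' Ca-EGTA binding constant sets
#'
#' Returns the constants used by [free_calcium()]: the EGTA proton
#' association constants (as pKa values, used with the meter pH to compute
#' the protonation correction) and the absolute Ca-EGTA association
#' constant `log_k_ca`, together valid at the stated temperature and ionic
#' strength.
#'
#' Two presets are shipped, reflecting the well-documented spread between
#' tabulated and measured apparent EGTA affinities:
#' \describe{
#'   \item{`"apparent"` (default)}{pKa 9.47 / 8.85 with
#'     `log_k_ca = 10.49` at 25 degC / 0.15 M ionic strength - the
#'     measured-apparent calibration, about 0.4 log units weaker than the
#'     tabulated constant, consistent with direct measurements of Ca-EGTA
#'     buffers and with the MaxChelator family of calculators used to
#'     design physiological solutions.}
#'   \item{`"martell"`}{pKa 9.47 / 8.85 with `log_k_ca = 10.86`, the
#'     association-constant tabulation (20 degC / 0.1 M). Yields roughly
#'     2.5-fold lower free Ca2+ than the apparent set for typical
#'     physiological buffers.}
#' }
#' The chosen set is always echoed in [free_calcium()]'s output metadata.
#'
#' @param set `"apparent"` or `"martell"`.
#' @return List with `name`, `pka1`, `pka2`, `log_k_ca`,
#'   `temperature_K`, `ionic_strength_M`.
#' @export
egta_constants <- function(set = c("apparent", "martell")) {
  set <- match.arg(set)
  switch(set,
    apparent = list(name = "apparent", pka1 = 9.47, pka2 = 8.85,
                    log_k_ca = 10.49, temperature_K = 298.15,
                    ionic_strength_M = 0.15),
    martell = list(name = "martell", pka1 = 9.47, pka2 = 8.85,
                   log_k_ca = 10.86, temperature_K = 293.15,
                   ionic_strength_M = 0.1)
  )
}

#' Free Ca2+ of an EGTA-buffered solution
#'
#' Solves the 1:1 Ca-EGTA binding equilibrium. The apparent dissociation
#' constant at the solution's pH is
#' `Kd' = alpha_H / K_CaL` with the protonation correction
#' `alpha_H = 1 + 10^(pKa1 - pH) + 10^(pKa1 + pKa2 - 2 pH)`,
#' and free Ca2+ is the positive root of
#' `Ca_free^2 + (EGTA_tot - Ca_tot + Kd') Ca_free - Kd' Ca_tot = 0`.
#' With no chelator the free concentration equals the total.
#'
#' @param sol A [solution()] with `egta_mM`, `ca_total_mM` and `ph` set.
#' @param constants A constant set from [egta_constants()].
#' @return List with `ca_free_uM`, `kd_apparent_uM`, and `constants`
#'   (the set used, for the output metadata).
#' @examples
#' # the 2.26 uM internal solution: 5 mM EGTA + 4.64 mM CaCl2 at pH 7.3
#' free_calcium(solution(egta_mM = 5, ca_total_mM = 4.64, ph = 7.3))
#' @export
free_calcium <- function(sol, constants = egta_constants()) {
  stopifnot(inherits(sol, "solution_composition"))
  stop_if_not(!is.null(constants$log_k_ca), "missing chelator constants")
  ca_tot <- sol$ca_total_mM * 1e-3
  egta <- sol$egta_mM * 1e-3
  if (egta == 0 || ca_tot == 0) {
    return(list(ca_free_uM = ca_tot * 1e6, kd_apparent_uM = Inf,
                constants = constants))
  }
  alpha <- 1 + 10^(constants$pka1 - sol$ph) +
    10^(constants$pka1 + constants$pka2 - 2 * sol$ph)
  kd <- alpha / 10^constants$log_k_ca            # apparent Kd', M
  b <- egta - ca_tot + kd
  ca_free <- (-b + sqrt(b^2 + 4 * kd * ca_tot)) / 2  # positive root
  list(ca_free_uM = ca_free * 1e6, kd_apparent_uM = kd * 1e6,
       constants = constants)
}
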