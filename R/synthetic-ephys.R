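#' Voltage-command protocol
#'
#' Describes the command waveform of a patch-clamp recording. The defaults
#' of the `steps` protocol follow the standard I-V design used for these
#' channels: holding at -60 mV, 250-ms test steps from -120 to +140 mV in
#' 20-mV increments, repolarization to -60 mV for the tail currents. The
#' `inverted_v_ramp` rises from `ramp_bounds_mV[1]` to the apex and back;
#' only its descending phase is analyzed for reversal potentials.
#'
#' @param kind `"steps"`, `"ramp"`, or `"inverted_v_ramp"`.
#' @param holding_mV Holding potential.
#' @param step_levels_mV Test-step levels (strictly increasing).
#' @param step_duration_ms Test-step duration.
#' @param repolarization_mV Post-step repolarization level.
#' @param pre_duration_ms Holding time before the step.
#' @param tail_duration_ms Repolarization time after the step.
#' @param ramp_bounds_mV (start, apex, end) for ramp protocols.
#' @param ramp_duration_ms Total ramp time (split evenly over the phases).
#' @return A `voltage_protocol` list.
#' @export
voltage_protocol <- function(kind = c("steps", "ramp", "inverted_v_ramp"),
                             holding_mV = -60,
                             step_levels_mV = seq(-120, 140, by = 20),
                             step_duration_ms = 250,
                             repolarization_mV = -60,
                             pre_duration_ms = 25,
                             tail_duration_ms = 100,
                             ramp_bounds_mV = c(-120, 120, -120),
                             ramp_duration_ms = 1000) {
  kind <- match.arg(kind)
  if (kind == "steps") {
    stop_if_not(all(diff(step_levels_mV) > 0),
                "step levels must be strictly increasing")
    stop_if_not(step_duration_ms > 0 && pre_duration_ms >= 0 &&
                  tail_duration_ms >= 0, "durations must be positive")
  }
  if (kind == "inverted_v_ramp") {
    stop_if_not(length(ramp_bounds_mV) == 3L, "need (start, apex, end)")
  }
  structure(list(kind = kind, holding_mV = holding_mV,
                 step_levels_mV = step_levels_mV,
                 step_duration_ms = step_duration_ms,
                 repolarization_mV = repolarization_mV,
                 pre_duration_ms = pre_duration_ms,
                 tail_duration_ms = tail_duration_ms,
                 ramp_bounds_mV = ramp_bounds_mV,
                 ramp_duration_ms = ramp_duration_ms),
            class = "voltage_protocol")
}

#' Synthetic channel model for sweep generation
#'
#' Linear (optionally rectifying) conductance model
#' `I(t) = g(V_act) * (V(t) - E_rev) * rectification(V) + noise`, where the
#' activating voltage `V_act` is the current command level during holding /
#' steps / ramps and, during the repolarization tail, the preceding test
#' level with exponential deactivation - so tail peaks report the
#' conductance activated by the step, as in tail-current analysis.
#'
#' @param conductance_nS Scalar conductance, or a function of voltage (mV)
#'   returning nS (e.g. a Boltzmann activation curve).
#' @param reversal_mV Reversal potential.
#' @param rectification Optional function of voltage returning a
#'   multiplicative factor (default none).
#' @param noise_sd_pA Gaussian current noise.
#' @param deactivation_tau_ms Tail deactivation time constant.
#' @param protocol A [voltage_protocol()].
#' @param sampling_khz Sampling rate (default 10 kHz).
#' @param seed Integer seed.
#' @return An `ephys_model_spec` list.
#' @export
ephys_model_spec <- function(conductance_nS = 1, reversal_mV = 0,
                             rectification = NULL, noise_sd_pA = 0,
                             deactivation_tau_ms = 20,
                             protocol = voltage_protocol("steps"),
                             sampling_khz = 10, seed = 1L) {
  g <- if (is.function(conductance_nS)) {
    conductance_nS
  } else {
    stop_if_not(conductance_nS >= 0, "conductance must be >= 0")
    function(v) rep(conductance_nS, length(v))
  }
  stop_if_not(noise_sd_pA >= 0, "noise_sd_pA must be >= 0")
  stopifnot(inherits(protocol, "voltage_protocol"))
  structure(list(conductance = g, reversal_mV = reversal_mV,
                 rectification = rectification, noise_sd_pA = noise_sd_pA,
                 deactivation_tau_ms = deactivation_tau_ms,
                 protocol = protocol, sampling_khz = sampling_khz,
                 seed = as.integer(seed)),
            class = "ephys_model_spec")
}

# Command waveform and activating-voltage waveform for one step sweep.
step_waveform <- function(p, level, sampling_khz) {
  dt <- 1 / sampling_khz
  n_pre <- round(p$pre_duration_ms * sampling_khz)
  n_step <- round(p$step_duration_ms * sampling_khz)
  n_tail <- round(p$tail_duration_ms * sampling_khz)
  cmd <- c(rep(p$holding_mV, n_pre), rep(level, n_step),
           rep(p$repolarization_mV, n_tail))
  act <- c(rep(p$holding_mV, n_pre), rep(level, n_step), rep(level, n_tail))
  tail_age_ms <- c(rep(NA_real_, n_pre + n_step),
                   (seq_len(n_tail) - 1) / sampling_khz)
  list(time_ms = (seq_along(cmd) - 1) * dt, command_mV = cmd,
       act_mV = act, tail_age_ms = tail_age_ms)
}

ramp_waveform <- function(p, sampling_khz) {
  b <- p$ramp_bounds_mV
  if (p$kind == "ramp") {
    n <- round(p$ramp_duration_ms * sampling_khz)
    cmd <- seq(b[1], b[2], length.out = n)
  } else {
    n <- round(p$ramp_duration_ms * sampling_khz / 2)
    cmd <- c(seq(b[1], b[2], length.out = n),
             seq(b[2], b[3], length.out = n)[-1])
  }
  list(time_ms = (seq_along(cmd) - 1) / sampling_khz, command_mV = cmd,
       act_mV = cmd, tail_age_ms = rep(NA_real_, length(cmd)))
}

#' Simulate current sweeps under a voltage protocol
#'
#' @param model An [ephys_model_spec()].
#' @return A `sweep_set`: list with `sweeps` (data frame `sweep_id`,
#'   `level_mV`, `time_ms`, `command_mV`, `current_pA`), `protocol`, and
#'   `sampling_khz`.
#' @export
simulate_sweeps <- function(model) {
  stopifnot(inherits(model, "ephys_model_spec"))
  p <- model$protocol
  waves <- if (p$kind == "steps") {
    lapply(p$step_levels_mV, step_waveform, p = p,
           sampling_khz = model$sampling_khz)
  } else {
    list(ramp_waveform(p, model$sampling_khz))
  }
  levels <- if (p$kind == "steps") p$step_levels_mV else NA_real_

  with_seed(model$seed, {
    sweeps <- lapply(seq_along(waves), function(i) {
      w <- waves[[i]]
      g <- model$conductance(w$act_mV)
      decay <- ifelse(is.na(w$tail_age_ms), 1,
                      exp(-w$tail_age_ms / model$deactivation_tau_ms))
      cur <- g * decay * (w$command_mV - model$reversal_mV)
      if (!is.null(model$rectification)) {
        cur <- cur * model$rectification(w$command_mV)
      }
      if (model$noise_sd_pA > 0) {
        cur <- cur + stats::rnorm(length(cur), sd = model$noise_sd_pA)
      }
      data.frame(sweep_id = i, level_mV = levels[min(i, length(levels))],
                 time_ms = w$time_ms, command_mV = w$command_mV,
                 current_pA = cur)
    })
    structure(list(sweeps = do.call(rbind, sweeps), protocol = p,
                   sampling_khz = model$sampling_khz),
              class = "sweep_set")
  })
}

#' Write / read a sweep set as columnar CSV
#'
#' Columns `sweep_id, level_mV, time_ms, command_mV, current_pA`; the
#' protocol goes to a JSON sidecar `<path>.json`.
#'
#' @param sweep_set A `sweep_set`.
#' @param path CSV file path.
#' @export
write_sweeps <- function(sweep_set, path) {
  utils::write.csv(sweep_set$sweeps, path, row.names = FALSE)
  p <- sweep_set$protocol
  jsonlite::write_json(
    list(protocol = unclass(p), sampling_khz = sweep_set$sampling_khz),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(path) {
  sw <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  prot <- meta$protocol
  class(prot) <- "voltage_protocol"
  structure(list(sweeps = sw, protocol = prot,
                 sampling_khz = meta$sampling_khz),
            class = "sweep_set")
}
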