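#' Define a stepped end-tidal CO2 forcing protocol
#'
#' A protocol is a baseline block followed by a sequence of steps, each holding
#' end-tidal CO2 (petCO2) at a fixed offset from baseline while end-tidal O2
#' (petO2) is clamped. The default reproduces the classic cerebrovascular
#' reactivity test: two 2-minute hypocapnic steps (-10, -5 mmHg, by voluntary
#' hyperventilation), a return to baseline, then three 2-minute hypercapnic
#' steps (+5, +10, +15 mmHg), with petO2 clamped at 100 mmHg throughout.
#'
#' @param baseline_petco2 Baseline petCO2 in mmHg.
#' @param baseline_duration Duration of the initial baseline block, seconds.
#' @param steps Data frame with columns `delta_petco2` (mmHg, relative to
#'   baseline; 0 is an interposed baseline block) and `duration` (seconds).
#' @param peto2_clamp Clamped petO2 target in mmHg.
#' @param breath_period Breath duration in seconds (ventilation is prescribed,
#'   not chemoreflex-driven).
#' @param sample_rate Trace sampling rate in Hz.
#' @return An object of class `protocol_spec`.
#' @examples
#' spec <- protocol_spec()
#' protocol_duration(spec)  # 840 s
#' @export
protocol_spec <- function(baseline_petco2 = 41.4,
                          baseline_duration = 120,
                          steps = tibble::tibble(
                            delta_petco2 = c(-10, -5, 0, 5, 10, 15),
                            duration = 120
                          ),
                          peto2_clamp = 100,
                          breath_period = 5,
                          sample_rate = 200) {
  steps <- tibble::as_tibble(steps)
  stopifnot(all(c("delta_petco2", "duration") %in% names(steps)))
  if (nrow(steps) < 1) stop("protocol needs at least one step")
  if (baseline_duration <= 0 || any(steps$duration <= 0)) {
    stop("durations must be positive")
  }
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (breath_period <= 0) stop("breath_period must be positive")
  if (peto2_clamp <= 0) stop("peto2_clamp must be positive")
  structure(
    list(
      baseline_petco2 = baseline_petco2,
      baseline_duration = baseline_duration,
      steps = steps,
      peto2_clamp = peto2_clamp,
      breath_period = breath_period,
      sample_rate = sample_rate
    ),
    class = "protocol_spec"
  )
}

#' @rdname protocol_spec
#' @param spec A `protocol_spec`.
#' @export
protocol_duration <- function(spec) {
  spec$baseline_duration + sum(spec$steps$duration)
}

#' Block-wise petCO2 target of a protocol
#'
#' @param spec A `protocol_spec`.
#' @return Tibble with one row per block: `onset`, `offset` (s) and the
#'   absolute `petco2` target (mmHg).
#' @export
protocol_blocks <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  dur <- c(spec$baseline_duration, spec$steps$duration)
  target <- c(spec$baseline_petco2, spec$baseline_petco2 + spec$steps$delta_petco2)
  offset <- cumsum(dur)
  tibble::tibble(onset = offset - dur, offset = offset, petco2 = target)
}

#' Per-volume petCO2 change schedule for a BOLD acquisition
#'
#' Samples the protocol's petCO2 target at the middle of each imaging volume
#' and returns it as a change from baseline; this is the noiseless stimulus a
#' BOLD phantom responds to and the regressor an ideal analysis would recover.
#'
#' @param spec A `protocol_spec`.
#' @param tr Repetition time, seconds.
#' @param n_volumes Number of volumes; defaults to covering the full protocol.
#' @return Tibble with `volume`, `time` (mid-volume, s), `delta_petco2` (mmHg)
#'   and absolute `petco2` (mmHg).
#' @export
protocol_volume_schedule <- function(spec, tr, n_volumes = NULL) {
  stopifnot(inherits(spec, "protocol_spec"), tr > 0)
  if (is.null(n_volumes)) n_volumes <- floor(protocol_duration(spec) / tr)
  blocks <- protocol_blocks(spec)
  t_mid <- (seq_len(n_volumes) - 0.5) * tr
  if (max(t_mid) > protocol_duration(spec)) {
    stop("acquisition extends beyond the protocol")
  }
  idx <- findInterval(t_mid, blocks$onset)
  tibble::tibble(
    volume = seq_len(n_volumes),
    time = t_mid,
    petco2 = blocks$petco2[idx],
    delta_petco2 = blocks$petco2[idx] - spec$baseline_petco2
  )
}

#' Generate synthetic mouth-sampled gas and flow traces for a protocol
#'
#' Simulates the raw signals a gas analyzer and pneumotachograph record during
#' a forcing protocol. Each breath is one `breath_period`: inspiration (flow
#' positive) then expiration (flow negative), with sinusoidal flow. The PCO2
#' waveform oscillates between the inspired level (about zero at baseline and
#' during hypocapnia, raised during hypercapnia as the forcing system delivers
#' CO2) and the scheduled expired plateau, as a square wave with short linear
#' transitions; only the plateau carries physiological meaning downstream. The
#' PO2 waveform falls from the inspired level to an expired plateau at the
#' clamp value. The exact plateau for every breath is returned as the ground
#' truth schedule.
#'
#' @param spec A [protocol_spec()].
#' @param seed Integer seed for plateau noise; reproducible.
#' @param noise_sd Standard deviation (mmHg) of the per-breath plateau noise
#'   added to both gases. Zero gives exact plateaus.
#' @param tidal_volume Tidal volume in litres used for the flow waveform.
#' @return List with `gas` (tibble: `time_s`, `pco2_mmHg`, `po2_mmHg`),
#'   `flow` (tibble: `time_s`, `flow_L_s`) and `schedule` (tibble: one row per
#'   breath with `breath`, `onset`, `offset`, `plateau_petco2`,
#'   `plateau_peto2`).
#' @examples
#' tr <- generate_protocol_trace(protocol_spec(), seed = 1, noise_sd = 0)
#' head(tr$schedule)
#' @export
generate_protocol_trace <- function(spec, seed = 1L, noise_sd = 0.5,
                                    tidal_volume = 1.0) {
  stopifnot(inherits(spec, "protocol_spec"))
  set.seed(as.integer(seed))
  fs <- spec$sample_rate
  bp <- spec$breath_period
  total <- protocol_duration(spec)
  n_breaths <- floor(total / bp)
  blocks <- protocol_blocks(spec)

  onset <- (seq_len(n_breaths) - 1) * bp
  offset <- onset + bp
  # a breath belongs to the block containing its expiration midpoint
  mid_exp <- onset + 0.75 * bp
  blk <- findInterval(pmin(mid_exp, total - 1e-9), blocks$onset)
  plateau_co2 <- blocks$petco2[blk] + stats::rnorm(n_breaths, 0, noise_sd)
  plateau_o2 <- spec$peto2_clamp + stats::rnorm(n_breaths, 0, noise_sd)

  schedule <- tibble::tibble(
    breath = seq_len(n_breaths),
    onset = onset,
    offset = offset,
    plateau_petco2 = plateau_co2,
    plateau_peto2 = plateau_o2
  )

  n_samp <- floor(total * fs)
  time <- (seq_len(n_samp) - 1) / fs
  phase <- (time %% bp) / bp            # 0..0.5 inspiration, 0.5..1 expiration
  b_idx <- pmin(floor(time / bp) + 1, n_breaths)

  # inspired CO2 rises with hypercapnic forcing, stays ~0 otherwise
  delta <- plateau_co2[b_idx] - spec$baseline_petco2
  insp_co2 <- pmax(0, delta) * 0.9
  insp_o2 <- spec$peto2_clamp + 50

  # square wave with linear transitions over 10% of the breath at each switch
  w <- transition_weight(phase, ramp = 0.1)
  pco2 <- insp_co2 + (plateau_co2[b_idx] - insp_co2) * w
  po2 <- insp_o2 + (plateau_o2[b_idx] - insp_o2) * w

  flow_amp <- tidal_volume * pi / bp    # so each half-cycle integrates to VT
  flow <- flow_amp * sin(2 * pi * phase)

  list(
    gas = tibble::tibble(time_s = time, pco2_mmHg = pco2, po2_mmHg = po2),
    flow = tibble::tibble(time_s = time, flow_L_s = flow),
    schedule = schedule
  )
}

# weight 0 = inspired gas, 1 = expired plateau; expiration occupies the second
# half of the breath, with linear ramps of width `ramp` at each transition
transition_weight <- function(phase, ramp = 0.1) {
  w <- numeric(length(phase))
  w[phase >= 0.5 + ramp] <- 1
  ramp_up <- phase >= 0.5 & phase < 0.5 + ramp
  w[ramp_up] <- (phase[ramp_up] - 0.5) / ramp
  ramp_down <- phase < ramp
  w[ramp_down] <- 1 - phase[ramp_down] / ramp
  w
}

#' Write gas and flow traces as plain CSV
#'
#' Gas traces are written as 3-column CSV (`time_s`, `pco2_mmHg`, `po2_mmHg`)
#' and flow as 2-column CSV (`time_s`, `flow_L_s`).
#'
#' @param trace A list as returned by [generate_protocol_trace()].
#' @param gas_path,flow_path Output file paths.
#' @return Invisibly, the paths written.
#' @export
write_trace_csv <- function(trace, gas_path, flow_path) {
  utils::write.csv(trace$gas, gas_path, row.names = FALSE)
  utils::write.csv(trace$flow, flow_path, row.names = FALSE)
  invisible(c(gas_path, flow_path))
}

#' Read gas and flow traces from CSV
#'
#' @param gas_path Path to a 3-column gas CSV (`time_s`, `pco2_mmHg`,
#'   `po2_mmHg`).
#' @param flow_path Optional path to a 2-column flow CSV.
#' @return List with `gas` and (if given) `flow` tibbles.
#' @export
read_trace_csv <- function(gas_path, flow_path = NULL) {
  gas <- tibble::as_tibble(utils::read.csv(gas_path))
  out <- list(gas = gas)
  if (!is.null(flow_path)) {
    out$flow <- tibble::as_tibble(utils::read.csv(flow_path))
  }
  out
}
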