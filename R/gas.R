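#' Detect breath boundaries from a respiratory flow trace
#'
#' Breaths are delimited at inspiration onsets: the zero-crossing preceding
#' each excursion of flow above the positive hysteresis threshold, after flow
#' has been below the negative threshold (expiration). Hysteresis rejects
#' noise-driven chatter around zero. Breaths shorter than
#' `min_breath_duration` are merged into their successor.
#'
#' @param flow Tibble with `time_s` (uniformly sampled) and `flow_L_s`
#'   (positive = inspiration).
#' @param min_breath_duration Minimum credible breath duration, seconds.
#' @param hysteresis Threshold as a fraction of the maximum absolute flow.
#' @return Tibble with one row per breath: `breath`, `onset`, `offset`
#'   (seconds).
#' @export
detect_breaths <- function(flow, min_breath_duration = 1, hysteresis = 0.05) {
  stopifnot(all(c("time_s", "flow_L_s") %in% names(flow)))
  t <- flow$time_s
  f <- flow$flow_L_s
  if (length(t) < 2) stop("no breaths detected: trace too short")
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * stats::median(dt)) {
    stop("flow trace must be uniformly sampled")
  }
  amp <- max(abs(f))
  if (!is.finite(amp) || amp == 0) stop("no breaths detected: constant flow")
  thr <- hysteresis * amp

  # state machine over samples: arm on expiration (f < -thr), fire an onset at
  # the first subsequent crossing above +thr; starting armed catches a trace
  # that opens mid-inspiration
  above <- f > thr
  below <- f < -thr
  onsets <- integer(0)
  armed <- TRUE
  for (i in seq_along(f)) {
    if (below[i]) armed <- TRUE
    if (armed && above[i]) {
      j <- i
      while (j > 1 && f[j - 1] > 0) j <- j - 1  # walk back to the zero-crossing
      onsets <- c(onsets, j)
      armed <- FALSE
    }
  }
  if (length(onsets) == 0) stop("no breaths detected")
  onset_t <- t[onsets]
  # merge breaths shorter than the minimum into their successor
  keep <- c(TRUE, diff(onset_t) >= min_breath_duration)
  onset_t <- onset_t[keep]
  offset_t <- c(onset_t[-1], t[length(t)])
  tibble::tibble(
    breath = seq_along(onset_t),
    onset = onset_t,
    offset = offset_t
  )
}

#' Reduce gas and flow traces to a per-breath end-tidal table
#'
#' For each detected breath, expiration is the set of samples with negative
#' flow; end-tidal PCO2 (petCO2) is the expiratory maximum of PCO2, end-tidal
#' PO2 (petO2) the expiratory minimum of PO2 (the standard end-tidal
#' convention). Inspired and expired tidal volumes integrate the positive and
#' negative flow respectively, and the instantaneous breathing frequency is
#' 60 / breath duration. Breaths without expiratory samples are excluded and
#' flagged in the `excluded` attribute.
#'
#' @param gas Tibble with `time_s`, `pco2_mmHg`, `po2_mmHg`.
#' @param flow Tibble with `time_s`, `flow_L_s` on the same grid.
#' @param breaths Breath boundaries from [detect_breaths()].
#' @return Tibble with one row per breath: `breath`, `onset`, `offset`,
#'   `petco2`, `peto2`, `vt_insp`, `vt_exp` (L), `fb` (breaths per minute).
#' @export
extract_end_tidal <- function(gas, flow, breaths) {
  stopifnot(nrow(gas) == nrow(flow))
  if (min(breaths$onset) < min(gas$time_s) - 1e-9 ||
      max(breaths$offset) > max(gas$time_s) + 1e-9) {
    stop("breath boundaries outside the trace span")
  }
  dt <- stats::median(diff(gas$time_s))
  rows <- purrr::pmap(breaths, function(breath, onset, offset) {
    sel <- gas$time_s >= onset & gas$time_s < offset
    fl <- flow$flow_L_s[sel]
    expi <- fl < 0
    if (!any(expi)) {
      return(tibble::tibble(
        breath = breath, onset = onset, offset = offset,
        petco2 = NA_real_, peto2 = NA_real_,
        vt_insp = NA_real_, vt_exp = NA_real_, fb = NA_real_
      ))
    }
    tibble::tibble(
      breath = breath, onset = onset, offset = offset,
      petco2 = max(gas$pco2_mmHg[sel][expi]),
      peto2 = min(gas$po2_mmHg[sel][expi]),
      vt_insp = sum(pmax(fl, 0)) * dt,
      vt_exp = sum(pmax(-fl, 0)) * dt,
      fb = 60 / (offset - onset)
    )
  })
  out <- dplyr::bind_rows(rows)
  excluded <- out$breath[is.na(out$petco2)]
  out <- dplyr::filter(out, !is.na(.data$petco2))
  attr(out, "excluded") <- excluded
  out
}

#' Oxyhemoglobin saturation from PO2 (Severinghaus equation)
#'
#' The classic one-equation fit of the human oxyhemoglobin dissociation
#' curve: `S = 1 / (23400 / (po2^3 + 150 * po2) + 1)`, with PO2 in mmHg and
#' saturation as a fraction. Strictly increasing in PO2, bounded in (0, 1).
#'
#' @param po2 PO2 in mmHg; must be positive.
#' @return Saturation fraction(s) in (0, 1).
#' @examples
#' severinghaus_spo2(100)  # 0.9775
#' @export
severinghaus_spo2 <- function(po2) {
  if (any(po2 <= 0)) stop("po2 must be positive")
  1 / (23400 / (po2^3 + 150 * po2) + 1)
}

#' Resample per-breath end-tidal values onto the imaging volume grid
#'
#' End-tidal values are step-like between breaths, so the default holds the
#' value of the last completed breath at each volume's midpoint. The linear
#' mode interpolates through the expiration midpoints instead.
#'
#' @param breaths Per-breath table from [extract_end_tidal()].
#' @param tr Repetition time, seconds.
#' @param n_volumes Number of imaging volumes.
#' @param method `"hold"` (default) or `"linear"`.
#' @return Tibble with `volume`, `time`, `petco2`, `peto2`.
#' @export
resample_to_tr <- function(breaths, tr, n_volumes, method = c("hold", "linear")) {
  method <- match.arg(method)
  stopifnot(tr > 0, n_volumes >= 1, nrow(breaths) >= 1)
  t_vol <- (seq_len(n_volumes) - 0.5) * tr
  if (max(t_vol) > max(breaths$offset) + tr) {
    stop("acquisition extends beyond the gas trace")
  }
  if (method == "hold") {
    # each breath's end-tidal value stands for the alveolar gas over that
    # breath, so it is held over the volumes the breath covers (volumes after
    # the last breath keep its value)
    idx <- pmax(findInterval(t_vol, breaths$onset), 1)
    pet <- breaths$petco2[idx]
    po <- breaths$peto2[idx]
  } else {
    mid <- (breaths$onset + 3 * breaths$offset) / 4  # expiration midpoint
    pet <- stats::approx(mid, breaths$petco2, xout = t_vol, rule = 2)$y
    po <- stats::approx(mid, breaths$peto2, xout = t_vol, rule = 2)$y
  }
  tibble::tibble(volume = seq_len(n_volumes), time = t_vol,
                 petco2 = pet, peto2 = po)
}

#' Align an end-tidal series to the BOLD acquisition by cross-correlation
#'
#' Gas reaches the analyzer, and the vascular response reaches the brain,
#' some seconds after the stimulus; both are corrected in one step by lagging
#' the end-tidal series to maximize its Pearson correlation with the
#' whole-brain mean BOLD time course. The search is exhaustive over integer
#' volume shifts in `[0, max_lag]` (the response cannot precede the
#' stimulus), ties broken toward the smallest lag. petO2 is shifted by the
#' same lag so the saturation nuisance regressor is delay-corrected too.
#'
#' @param series End-tidal series from [resample_to_tr()].
#' @param global_bold Per-volume mean BOLD signal (see [global_signal()]).
#' @param tr Repetition time, seconds.
#' @param max_lag_s Largest lag searched, seconds.
#' @return List with `series` (lagged, same length; leading values padded with
#'   the first observation), `lag_s`, `lag_volumes`, and `correlations`
#'   (tibble of lag vs correlation).
#' @export
align_to_bold <- function(series, global_bold, tr, max_lag_s = 20) {
  n <- nrow(series)
  stopifnot(length(global_bold) == n)
  if (stats::sd(series$petco2) == 0 || stats::sd(global_bold) == 0) {
    stop("cross-correlation undefined for constant inputs")
  }
  max_k <- min(floor(max_lag_s / tr), n - 3)
  cors <- vapply(0:max_k, function(k) {
    stats::cor(series$petco2[seq_len(n - k)], global_bold[(1 + k):n])
  }, numeric(1))
  k_best <- (0:max_k)[which.max(cors)]  # which.max takes the first maximum
  shift <- function(v, k) if (k == 0) v else c(rep(v[1], k), v[seq_len(n - k)])
  out <- series
  out$petco2 <- shift(series$petco2, k_best)
  out$peto2 <- shift(series$peto2, k_best)
  out$lag_s <- k_best * tr
  list(
    series = out,
    lag_s = k_best * tr,
    lag_volumes = k_best,
    correlations = tibble::tibble(lag_volumes = 0:max_k, correlation = cors)
  )
}

#' Summarize resting breathing over a time window
#'
#' Means over the breaths falling in the window: breathing frequency `fb`
#' (per minute), tidal volume `vt` (expiratory, L), minute ventilation
#' `ve = mean(vt * fb)` (L per minute), end-tidal gases (mmHg), and SpO2 (the
#' Severinghaus saturation of the mean petO2, as a percentage).
#'
#' @param breaths Per-breath table from [extract_end_tidal()].
#' @param window Two-element numeric, start and end time in seconds.
#' @return One-row tibble: `n_breaths`, `fb`, `vt`, `ve`, `peto2`, `petco2`,
#'   `spo2`.
#' @export
summarize_rest <- function(breaths, window = range(breaths$onset)) {
  sel <- breaths$onset >= window[1] & breaths$offset <= window[2] + 1e-9
  if (!any(sel)) stop("no breaths in the requested window")
  b <- breaths[sel, ]
  tibble::tibble(
    n_breaths = nrow(b),
    fb = mean(b$fb),
    vt = mean(b$vt_exp),
    ve = mean(b$vt_exp * b$fb),
    peto2 = mean(b$peto2),
    petco2 = mean(b$petco2),
    spo2 = 100 * severinghaus_spo2(mean(b$peto2))
  )
}
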