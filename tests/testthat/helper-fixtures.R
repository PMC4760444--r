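# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# noiseless default-protocol trace with its per-breath reduction
fix_trace <- function() {
  fixture("trace", function() {
    spec <- protocol_spec()
    trc <- generate_protocol_trace(spec, seed = 1, noise_sd = 0)
    breaths <- detect_breaths(trc$flow)
    et <- extract_end_tidal(trc$gas, trc$flow, breaths)
    list(spec = spec, trace = trc, breaths = breaths, end_tidal = et,
         series = resample_to_tr(et, tr = 2, n_volumes = 420),
         schedule = protocol_volume_schedule(spec, tr = 2))
  })
}

# small noiseless BOLD phantom and its fitted CVR map
fix_noiseless_fit <- function() {
  fixture("noiseless_fit", function() {
    fx <- fix_trace()
    ph <- bold_phantom_spec(dims = c(24, 28, 24), noise_sd = 0,
                            n_neg_foci = 2, focus_radius_mm = 6, seed = 11)
    series <- generate_bold_phantom(ph, fx$schedule, tr = 2, seed = 1)
    fit <- map_cvr(series, fx$series, fwhm_mm = 0, highpass_sigma_s = NULL)
    list(phantom = ph, series = series, fit = fit)
  })
}

# small noisy (1% of GM baseline) phantom fit, full preprocessing
fix_noisy_fit <- function() {
  fixture("noisy_fit", function() {
    fx <- fix_trace()
    ph <- bold_phantom_spec(dims = c(24, 28, 24), noise_sd = 10,
                            n_neg_foci = 2, focus_radius_mm = 6, seed = 11)
    series <- generate_bold_phantom(ph, fx$schedule, tr = 2, seed = 21)
    fit <- map_cvr(series, fx$series, fwhm_mm = 0, highpass_sigma_s = 50)
    list(phantom = ph, series = series, fit = fit)
  })
}

# sinusoidal flow trace helper
sine_flow <- function(freq_per_min = 12, duration_s = 60, fs = 50,
                      amplitude = 1, noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  f <- amplitude * sin(2 * pi * freq_per_min / 60 * t) +
    stats::rnorm(length(t), 0, noise_sd)
  tibble::tibble(time_s = t, flow_L_s = f)
}
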