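# Time-domain and Welch frequency-domain HRV measures for one analysis
# window: cubic-spline resampling to a uniform 4 Hz grid, quadratic
# detrending, Welch periodogram averaging with 150-s Hann segments, and
# band-power integration over the VLF / LF / HF bands.

#' Resample a beat series to a uniform grid
#'
#' Cubic-spline interpolation of RR interval versus beat time, evaluated on
#' a uniform grid over the recorded span.
#'
#' @param beats A `beat_series`.
#' @param rate Grid rate in Hz (default 4).
#' @return A `uniform_rr` object: `values` (RR, ms), `times` (s), `rate`,
#'   `detrended` flag.
#' @export
resample_uniform <- function(beats, rate = 4) {
  bt <- beats$beat_times
  if (length(bt) < 4) stop("need at least 4 beats for cubic-spline resampling")
  if (diff(range(bt)) < 10) stop("need at least 10 s of beats")
  grid <- seq(bt[1], bt[length(bt)], by = 1 / rate)
  # RR attributed to the later beat of each pair
  sf <- stats::splinefun(bt[-1], beats$rr_ms, method = "fmm")
  structure(
    list(values = sf(grid), times = grid, rate = rate, detrended = FALSE),
    class = "uniform_rr"
  )
}

#' Remove a least-squares quadratic trend
#'
#' Fits and removes a quadratic polynomial in time; the residual is
#' orthogonal to the \{1, t, t^2\} design.
#'
#' @param series A `uniform_rr`.
#' @return The detrended `uniform_rr` (mean-zero residual).
#' @export
detrend_quadratic <- function(series) {
  y <- series$values
  if (length(y) < 3) stop("need at least 3 samples")
  t <- series$times - series$times[1]
  fit <- stats::lm.fit(cbind(1, t, t^2), y)
  series$values <- as.numeric(fit$residuals)
  series$detrended <- TRUE
  series
}

#' Welch power spectral density of a uniform RR series
#'
#' Averaged modified periodograms: Hann-tapered segments of `window_s`
#' seconds with 50% overlap, one-sided density normalized so that the
#' integral over frequency recovers the signal power (density in ms^2/Hz
#' when `values` are in ms).
#'
#' @param series A detrended `uniform_rr`.
#' @param window_s Segment length in seconds (default 150).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A `psd` object: `freq` (Hz), `density`, `rate`, `n_segments`.
#' @export
welch_psd <- function(series, window_s = 150, overlap = 0.5) {
  fs <- series$rate
  x <- series$values
  nseg <- round(window_s * fs)
  if (length(x) < nseg) {
    stop(sprintf(
      "series (%.0f s) shorter than the Welch window (%.0f s); use a shorter window",
      length(x) / fs, window_s
    ))
  }
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)) # Hann
  u <- sum(w^2)
  nf <- nseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    p <- Mod(stats::fft(seg)[seq_len(nf)])^2
    acc <- acc + p
  }
  dens <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (nseg %% 2 == 0) scale2[nf] <- 1
  dens <- dens * scale2
  structure(
    list(
      freq = (seq_len(nf) - 1L) * fs / nseg,
      density = dens,
      rate = fs,
      n_segments = length(starts)
    ),
    class = "psd"
  )
}

#' Band powers and spectral summary from a PSD
#'
#' Trapezoidal integration of the density over the VLF (0.0033-0.04 Hz),
#' LF (0.04-0.15 Hz), and HF (0.15-0.5 Hz) bands, the total power over
#' 0-0.5 Hz, natural-log transforms (a zero power yields `NA`, never
#' `-Inf`), and the LF/HF and VLF/(LF + HF) ratios.
#'
#' @param psd A `psd` object covering at least 0-0.5 Hz.
#' @return A `spectral_summary` (named list).
#' @export
band_powers <- function(psd) {
  if (max(psd$freq) < 0.5) stop("psd must cover [0, 0.5] Hz")
  bands <- hrv_bands()
  p <- vapply(bands, function(b) band_integral(psd$freq, psd$density, b[1], b[2]), numeric(1))
  total <- band_integral(psd$freq, psd$density, 0, 0.5)
  # powers below 1e-12 ms^2 are numerical dust from an effectively
  # constant window; their log is reported missing rather than a large
  # negative artifact
  safe_ln <- function(v) if (is.na(v) || v <= 1e-12) NA_real_ else log(v)
  lfhf <- if (p[["HF"]] > 0) p[["LF"]] / p[["HF"]] else NA_real_
  vlf_ratio <- if ((p[["LF"]] + p[["HF"]]) > 0) p[["VLF"]] / (p[["LF"]] + p[["HF"]]) else NA_real_
  structure(
    list(
      power_vlf = p[["VLF"]], power_lf = p[["LF"]], power_hf = p[["HF"]],
      power_total = total,
      ln_vlf = safe_ln(p[["VLF"]]), ln_lf = safe_ln(p[["LF"]]),
      ln_hf = safe_ln(p[["HF"]]), ln_total = safe_ln(total),
      lf_hf_ratio = lfhf,
      vlf_over_lf_plus_hf = vlf_ratio
    ),
    class = "spectral_summary"
  )
}

#' Time-domain summary of a beat series window
#'
#' Mean heart rate is `60000 / mean(rr_ms)`; maximum heart rate is the
#' maximum of the 10-s rolling-mean heart rate (suppressing single-beat
#' spikes; the raw per-beat maximum is also reported); SDNN is the
#' population standard deviation of the accepted (non-corrected when
#' `accepted_only`) RR intervals.
#'
#' @param beats A `beat_series`.
#' @param accepted_only Drop corrected intervals from SDNN (default FALSE:
#'   corrected values are already interpolated NN estimates).
#' @return A `time_domain_summary`: `mean_hr`, `max_hr`, `max_hr_beat`
#'   (b/min), `sdnn` (ms), `n_intervals`.
#' @export
time_domain <- function(beats, accepted_only = FALSE) {
  rr <- beats$rr_ms
  if (accepted_only && any(beats$corrected)) rr <- rr[!beats$corrected]
  if (length(rr) < 10) {
    warning("fewer than 10 intervals: time-domain summary unavailable")
    return(structure(
      list(mean_hr = NA_real_, max_hr = NA_real_, max_hr_beat = NA_real_,
           sdnn = NA_real_, n_intervals = length(rr)),
      class = "time_domain_summary"
    ))
  }
  mean_hr <- 60000 / mean(rr)
  # 10-s rolling mean of RR, centred on each interval midpoint
  mid <- (beats$beat_times[-1] + beats$beat_times[-length(beats$beat_times)]) / 2
  mid <- mid[seq_along(beats$rr_ms)]
  roll <- vapply(seq_along(beats$rr_ms), function(i) {
    sel <- abs(mid - mid[i]) <= 5
    mean(beats$rr_ms[sel])
  }, numeric(1))
  structure(
    list(
      mean_hr = mean_hr,
      max_hr = max(60000 / roll),
      max_hr_beat = max(60000 / rr),
      sdnn = sd_pop(rr),
      n_intervals = length(rr)
    ),
    class = "time_domain_summary"
  )
}
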