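# Morlet continuous-wavelet band-power time courses over a full episode
# and their linear trends.
#
# The transform is computed in the Fourier domain with the analytic Morlet
# wavelet (center frequency parameter omega0 = 6). Power is reported as a
# one-sided spectral density so that the trapezoidal integral over
# frequency, averaged over time, recovers the series variance
# (reconstruction constant C_delta = 0.776 for omega0 = 6). RR input in ms
# is converted to seconds, so densities are in s^2/Hz.

#' Continuous Morlet wavelet transform of a uniform RR series
#'
#' @param series A detrended `uniform_rr` (4 Hz grid).
#' @param fmin,fmax Frequency span in Hz (defaults cover the VLF-HF range).
#' @param voices Voices per octave (default 12).
#' @param omega0 Morlet center frequency parameter (default 6).
#' @return A `tf_map`: `times` (s), `freq` (Hz, ascending), `power`
#'   (matrix, frequency x time, s^2/Hz), `coi` (cone-of-influence e-folding
#'   time per frequency, s), `unreliable_freqs` (frequencies with fewer
#'   than two full periods in the record).
#' @export
cwt_morlet <- function(series, fmin = 0.0033, fmax = 0.5, voices = 12,
                       omega0 = 6) {
  fs <- series$rate
  x <- series$values / 1000 # ms -> s
  n <- length(x)
  dt <- 1 / fs
  n_oct <- log2(fmax / fmin)
  freq <- fmin * 2^(seq(0, n_oct, by = 1 / voices))
  fourier_factor <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi) # scale * freq
  scales <- fourier_factor / freq
  xf <- stats::fft(x)
  omega_k <- 2 * pi * ifelse(seq_len(n) - 1L <= n / 2,
    (seq_len(n) - 1L) / (n * dt),
    -(n - seq_len(n) + 1L) / (n * dt)
  )
  c_delta <- 0.776
  power <- matrix(0, nrow = length(freq), ncol = n)
  for (j in seq_along(freq)) {
    s <- scales[j]
    psi_hat <- numeric(n)
    pos <- omega_k > 0
    psi_hat[pos] <- pi^(-1 / 4) * exp(-((s * omega_k[pos] - omega0)^2) / 2) *
      sqrt(2 * pi * s / dt)
    w <- stats::fft(xf * psi_hat, inverse = TRUE) / n
    # |W|^2 / s summed over log-spaced scales recovers variance up to
    # dj * dt / C_delta (Torrence & Compo normalization); dividing by the
    # log-bin width f * ln 2 * dj turns the sum into a density in 1/Hz.
    power[j, ] <- (dt / (c_delta * log(2))) * Mod(w)^2 / (s * freq[j])
  }
  duration <- n * dt
  structure(
    list(
      times = series$times,
      freq = freq,
      power = power,
      coi = sqrt(2) * scales,
      unreliable_freqs = freq[duration < 2 / freq],
      omega0 = omega0
    ),
    class = "tf_map"
  )
}

#' Band-power time course from a time-frequency map
#'
#' Per-time trapezoidal integral of the power density over one band's
#' frequency range.
#'
#' @param map A `tf_map`.
#' @param band `"VLF"`, `"LF"`, or `"HF"`.
#' @return A `band_power_series`: `band`, `times`, `power` (s^2/Hz
#'   integrated over the band, i.e., s^2), `coi_mask` (TRUE where every
#'   in-band frequency is outside its cone of influence).
#' @export
band_power_timecourse <- function(map, band = c("VLF", "LF", "HF")) {
  band <- match.arg(band)
  edges <- hrv_bands()[[band]]
  sel <- map$freq >= edges[1] & map$freq <= edges[2]
  if (!any(sel)) stop("band outside the map's frequency span")
  f <- map$freq[sel]
  p <- map$power[sel, , drop = FALSE]
  series <- apply(p, 2, function(col) trapz(f, col))
  t_rel <- map$times - map$times[1]
  t_end <- map$times[length(map$times)] - map$times[1]
  worst_coi <- max(map$coi[sel])
  structure(
    list(
      band = band,
      times = map$times,
      power = series,
      coi_mask = t_rel >= worst_coi & (t_end - t_rel) >= worst_coi
    ),
    class = "band_power_series"
  )
}

#' VLF / (LF + HF) ratio time course
#'
#' @param map A `tf_map`.
#' @return List with `times` and `ratio`.
#' @export
vlf_ratio_timecourse <- function(map) {
  vlf <- band_power_timecourse(map, "VLF")$power
  lf <- band_power_timecourse(map, "LF")$power
  hf <- band_power_timecourse(map, "HF")$power
  denom <- lf + hf
  list(times = map$times, ratio = ifelse(denom > 0, vlf / denom, NA_real_))
}

#' Linear trend of a band-power time course
#'
#' Ordinary least squares of power on time in seconds, with the intercept,
#' both standard errors, the model F-ratio, the slope p-value, R^2, and the
#' 95% confidence interval for the time coefficient from the t
#' distribution with n - 2 degrees of freedom. VLF fits restrict to
#' samples outside the cone of influence by default.
#'
#' @param series A `band_power_series`, or a list with `times` and `power`.
#' @param use_coi Restrict to `coi_mask` samples when available (default
#'   TRUE).
#' @return A `trend_fit` (named list mirroring a regression table row).
#' @export
linear_trend <- function(series, use_coi = TRUE) {
  t <- series$times
  y <- series$power
  if (use_coi && !is.null(series$coi_mask) && sum(series$coi_mask) >= 3) {
    t <- t[series$coi_mask]
    y <- y[series$coi_mask]
  }
  n <- length(t)
  if (n < 3) stop("need at least 3 time points")
  if (stats::var(t) == 0) stop("zero-variance time vector")
  fit <- stats::lm(y ~ t)
  beta <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  sxx <- sum((t - mean(t))^2)
  df <- n - 2
  sigma2 <- rss / df
  se_slope <- sqrt(sigma2 / sxx)
  se_int <- sqrt(sigma2 * (1 / n + mean(t)^2 / sxx))
  r2 <- if (tss > 0) 1 - rss / tss else 0
  f_ratio <- if (tss == 0) 0 else if (rss > 0) (tss - rss) / sigma2 else Inf
  p <- if (se_slope > 0) 2 * stats::pt(-abs(beta[2] / se_slope), df) else 0
  tcrit <- stats::qt(0.975, df)
  structure(
    list(
      band = series$band %||% NA_character_,
      intercept = unname(beta[1]), se_intercept = se_int,
      time_coefficient = unname(beta[2]), se_time_coefficient = se_slope,
      f_ratio = f_ratio, p_value = unname(p), r_squared = r2,
      ci95_low = unname(beta[2] - tcrit * se_slope),
      ci95_high = unname(beta[2] + tcrit * se_slope),
      n = n
    ),
    class = "trend_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regression table of band-power trends for one episode
#'
#' Runs the wavelet transform on a full-episode uniform RR series and fits
#' the linear trend of each band's power time course.
#'
#' @param series A detrended `uniform_rr` spanning the episode.
#' @param condition Optional condition label carried into the table.
#' @param use_coi Passed to [linear_trend()].
#' @return data.frame with one row per band (VLF, LF, HF) and the
#'   regression-table columns.
#' @export
band_trend_table <- function(series, condition = NA_character_, use_coi = TRUE) {
  map <- cwt_morlet(series)
  rows <- lapply(c("VLF", "LF", "HF"), function(b) {
    fit <- linear_trend(band_power_timecourse(map, b), use_coi = use_coi)
    data.frame(
      component = b, condition = condition,
      intercept = fit$intercept, se_intercept = fit$se_intercept,
      time_coefficient = fit$time_coefficient,
      se_time_coefficient = fit$se_time_coefficient,
      f_ratio = fit$f_ratio, p_value = fit$p_value,
      r_squared = fit$r_squared,
      ci95_low = fit$ci95_low, ci95_high = fit$ci95_high,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
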