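# Synthetic episode generation.
#
# Labeled 1800-s episodes (RR series, optionally an ECG waveform) with the
# autonomic structure the downstream analysis assumes: a heart-rate ramp at
# episode onset, band-limited VLF/LF/HF oscillations whose amplitudes decay
# linearly in time, and a tunable white / 1-f noise mixture that controls
# the entropy of the tachogram.

#' Specify a synthetic episode
#'
#' Builds the parameter set for one synthetic episode. Defaults reproduce
#' the contrast between PSH episodes (autonomic storms: heart rate ramping
#' from about 97 to 123 b/min at onset, steep loss of spectral power with a
#' relatively larger HF loss, reduced complexity) and noPSH control events
#' (mild rise from about 95 to 100 b/min, shallow power decline, preserved
#' complexity).
#'
#' @param condition `"PSH"` or `"noPSH"`. Chooses the default parameter set;
#'   every default can be overridden.
#' @param duration Episode length in seconds.
#' @param hr_baseline Baseline heart rate, b/min. Must lie in \[20, 250\].
#' @param hr_peak Post-onset plateau heart rate, b/min; `>= hr_baseline`.
#' @param onset_time Event onset in seconds from the start of the recording.
#' @param band_amplitudes Named numeric (`VLF`, `LF`, `HF`): initial RR
#'   modulation amplitude of each band-limited oscillator, in seconds.
#' @param band_slopes Named numeric (`VLF`, `LF`, `HF`): linear amplitude
#'   change per second; the amplitude envelope is clipped at zero.
#' @param band_freqs Named numeric: oscillator center frequencies in Hz,
#'   each inside its band.
#' @param noise_mix Fraction in \[0, 1\] of white noise in the white / 1-f
#'   modulation-noise mixture; higher values raise sample entropy.
#' @param noise_sd Standard deviation of the RR modulation noise, seconds.
#' @param phase_jitter Brownian phase-diffusion rate of the band
#'   oscillators (rad per sqrt(s) at the HF reference frequency; each
#'   band's rate scales with the square root of its center frequency).
#'   Low values give rigid, nearly deterministic oscillations (the
#'   low-complexity autonomic output seen during PSH storms); higher
#'   values give the broader-band, more irregular modulation of ordinary
#'   heart-rate variability.
#' @param hr_tau Time constant (s) of the sigmoid heart-rate transition at
#'   onset.
#' @param seed Integer seed; fixed seed gives bitwise-identical beat times.
#'
#' @return An object of class `episode_spec`.
#' @export
episode_spec <- function(condition = c("PSH", "noPSH"),
                         duration = 1800,
                         hr_baseline = NULL,
                         hr_peak = NULL,
                         onset_time = 1200,
                         band_amplitudes = NULL,
                         band_slopes = NULL,
                         band_freqs = c(VLF = 0.010, LF = 0.095, HF = 0.25),
                         noise_mix = NULL,
                         noise_sd = NULL,
                         phase_jitter = NULL,
                         hr_tau = 60,
                         seed = 1L) {
  condition <- match.arg(condition)
  if (condition == "PSH") {
    if (is.null(hr_baseline)) hr_baseline <- 97
    if (is.null(hr_peak)) hr_peak <- 123
    if (is.null(band_amplitudes)) band_amplitudes <- c(VLF = 0.040, LF = 0.030, HF = 0.025)
    # All negative, steeper than noPSH, HF loses relatively more than LF.
    if (is.null(band_slopes)) band_slopes <- c(VLF = -1.8e-5, LF = -1.0e-5, HF = -1.1e-5)
    if (is.null(noise_mix)) noise_mix <- 0.10
    if (is.null(noise_sd)) noise_sd <- 0.006
    if (is.null(phase_jitter)) phase_jitter <- 0.25
  } else {
    if (is.null(hr_baseline)) hr_baseline <- 95
    if (is.null(hr_peak)) hr_peak <- 100
    if (is.null(band_amplitudes)) band_amplitudes <- c(VLF = 0.040, LF = 0.030, HF = 0.025)
    if (is.null(band_slopes)) band_slopes <- c(VLF = -4e-6, LF = -3e-6, HF = -2e-6)
    if (is.null(noise_mix)) noise_mix <- 0.80
    if (is.null(noise_sd)) noise_sd <- 0.015
    if (is.null(phase_jitter)) phase_jitter <- 0.55
  }
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (onset_time < 0 || onset_time >= duration) stop("onset_time must lie in [0, duration)")
  if (hr_baseline < 20 || hr_baseline > 250) stop("hr_baseline outside [20, 250] b/min")
  if (hr_peak < 20 || hr_peak > 250) stop("hr_peak outside [20, 250] b/min")
  if (hr_peak < hr_baseline) stop("hr_peak must be >= hr_baseline")
  if (noise_mix < 0 || noise_mix > 1) stop("noise_mix must lie in [0, 1]")
  bands <- c("VLF", "LF", "HF")
  band_amplitudes <- band_amplitudes[bands]
  band_slopes <- band_slopes[bands]
  band_freqs <- band_freqs[bands]
  if (anyNA(band_amplitudes) || anyNA(band_slopes) || anyNA(band_freqs)) {
    stop("band_amplitudes, band_slopes and band_freqs need VLF, LF and HF entries")
  }
  structure(
    list(
      condition = condition, duration = duration,
      hr_baseline = hr_baseline, hr_peak = hr_peak,
      onset_time = onset_time,
      band_amplitudes = band_amplitudes, band_slopes = band_slopes,
      band_freqs = band_freqs,
      noise_mix = noise_mix, noise_sd = noise_sd,
      phase_jitter = phase_jitter,
      hr_tau = hr_tau, seed = as.integer(seed)
    ),
    class = "episode_spec"
  )
}

# Instantaneous RR function (seconds) on a fine time grid.
instantaneous_rr <- function(spec, t, phases, noise) {
  hr <- spec$hr_baseline +
    (spec$hr_peak - spec$hr_baseline) * sigmoid((t - spec$onset_time) / spec$hr_tau)
  rr <- 60 / hr
  for (b in c("VLF", "LF", "HF")) {
    amp <- pmax(0, spec$band_amplitudes[[b]] + spec$band_slopes[[b]] * t)
    rr <- rr + amp * sin(2 * pi * spec$band_freqs[[b]] * t + phases[[b]])
  }
  rr + noise
}

#' Generate a synthetic RR-interval series
#'
#' Produces beat times by integrate-and-fire (IPFM-style) over the
#' instantaneous heart rate implied by the spec: a sigmoid baseline ramp at
#' onset plus one band-limited oscillator per VLF/LF/HF band with a linearly
#' decaying amplitude envelope, plus a white / 1-f noise mixture. A beat is
#' emitted each time the integrated instantaneous rate crosses an integer,
#' which keeps beat times, RR intervals, and any derived ECG mutually
#' consistent.
#'
#' @param spec An [episode_spec()].
#' @return An object of class `synthetic_episode` with fields `beat_times`
#'   (s), `rr_ms` (RR intervals, ms, clamped to the physiological range
#'   \[250, 2000\] ms), `condition`, and `truth` (the spec used).
#' @export
generate_rr_series <- function(spec) {
  stopifnot(inherits(spec, "episode_spec"))
  set.seed(spec$seed)
  dt <- 0.25
  t <- seq(0, spec$duration, by = dt)
  n <- length(t)
  # band oscillator phases: uniform start plus Brownian drift whose rate
  # scales with sqrt(center frequency / 0.25 Hz)
  phases <- lapply(c(VLF = "VLF", LF = "LF", HF = "HF"), function(b) {
    sigma <- spec$phase_jitter * sqrt(spec$band_freqs[[b]] / 0.25)
    phi0 <- stats::runif(1, 0, 2 * pi)
    if (sigma > 0) {
      phi0 + cumsum(stats::rnorm(n, 0, sigma * sqrt(dt)))
    } else {
      rep(phi0, n)
    }
  })
  noise <- if (spec$noise_sd > 0) {
    w <- stats::rnorm(n)
    p <- one_over_f_noise(n)
    z <- spec$noise_mix * w + (1 - spec$noise_mix) * p
    s <- stats::sd(z)
    if (s > 0) spec$noise_sd * z / s else z * 0
  } else {
    numeric(n)
  }
  rr_t <- instantaneous_rr(spec, t, phases, noise)
  rr_t <- pmin(pmax(rr_t, 0.250), 2.000)
  rate <- 1 / rr_t # beats per second
  # cumulative trapezoidal integral of the rate
  cum <- c(0, cumsum((rate[-1] + rate[-n]) / 2 * dt))
  n_beats <- floor(cum[n])
  if (n_beats < 2L) stop("spec produces fewer than 2 beats")
  # invert the (monotone) integrated rate at integer crossings
  beat_times <- stats::approx(cum, t, xout = seq_len(n_beats))$y
  rr_ms <- diff(beat_times) * 1000
  rr_ms <- pmin(pmax(rr_ms, 250), 2000)
  structure(
    list(
      beat_times = beat_times,
      rr_ms = rr_ms,
      condition = spec$condition,
      truth = spec
    ),
    class = "synthetic_episode"
  )
}

#' Generate a synthetic single-lead ECG from beat times
#'
#' Places a stereotyped P-QRS-T template (sum of Gaussian bumps) at each
#' beat time on a uniform grid and adds Gaussian noise at the requested
#' signal-to-noise ratio.
#'
#' @param beat_times Strictly increasing beat (R-peak) times in seconds.
#' @param fs Sampling rate in Hz.
#' @param snr_db Signal-to-noise ratio in dB; `Inf` for a noise-free trace.
#' @param duration Record length in seconds; defaults to the last beat plus
#'   one second.
#' @return An `ecg_record`: list with `samples` (mV), `fs`, `start_time`,
#'   and `n_beats` (0 flags a beatless, noise-only record).
#' @export
generate_ecg <- function(beat_times, fs = 250, snr_db = 20, duration = NULL) {
  if (is.unsorted(beat_times, strictly = TRUE)) stop("beat_times must be strictly increasing")
  if (is.null(duration)) {
    duration <- if (length(beat_times)) max(beat_times) + 1 else 10
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  # P-QRS-T morphology: (offset s, width s, amplitude mV) per wave
  waves <- list(
    P = c(-0.17, 0.025, 0.12),
    Q = c(-0.025, 0.010, -0.15),
    R = c(0.000, 0.012, 1.00),
    S = c(0.025, 0.010, -0.20),
    T = c(0.22, 0.060, 0.25)
  )
  for (bt in beat_times) {
    for (w in waves) {
      sel <- which(abs(t - (bt + w[1])) < 5 * w[2])
      if (length(sel)) {
        x[sel] <- x[sel] + w[3] * exp(-((t[sel] - bt - w[1])^2) / (2 * w[2]^2))
      }
    }
  }
  if (is.finite(snr_db)) {
    sig_pow <- mean(x^2)
    if (sig_pow == 0) sig_pow <- 1e-6
    noise_sd <- sqrt(sig_pow / 10^(snr_db / 10))
    x <- x + stats::rnorm(n, sd = noise_sd)
  }
  structure(
    list(samples = x, fs = fs, start_time = 0, n_beats = length(beat_times)),
    class = "ecg_record"
  )
}

#' Generate a labeled synthetic cohort
#'
#' Draws per-episode specs around the PSH and noPSH defaults (lognormal
#' jitter on oscillator amplitudes, Gaussian jitter on heart rates and
#' oscillator frequencies, bounded jitter on the noise mixture) and
#' generates each episode's RR series.
#'
#' @param n_psh,n_nopsh Number of episodes per condition (each `>= 1`).
#' @param seed Integer master seed; per-episode seeds are derived from it so
#'   the whole cohort is reproducible.
#' @return List with `episodes` (list of `synthetic_episode`) and
#'   `manifest` (data.frame: episode_id, condition, seed).
#' @export
generate_cohort <- function(n_psh = 24, n_nopsh = 24, seed = 1L) {
  if (n_psh < 1 || n_nopsh < 1) stop("counts must be >= 1")
  set.seed(seed)
  conditions <- c(rep("PSH", n_psh), rep("noPSH", n_nopsh))
  n <- length(conditions)
  ep_seeds <- sample.int(.Machine$integer.max - 1L, n)
  episodes <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(ep_seeds[i])
    base <- episode_spec(conditions[i], seed = ep_seeds[i])
    # overall autonomic tone varies together across episodes; band-specific
    # deviations on top
    amp_jit <- exp(stats::rnorm(1, 0, 0.45) + stats::rnorm(3, 0, 0.25))
    hb <- min(250, max(20, base$hr_baseline + stats::rnorm(1, 0, 4)))
    hp <- min(250, max(hb, base$hr_peak + stats::rnorm(1, 0, 4)))
    spec <- episode_spec(
      condition = conditions[i],
      hr_baseline = hb,
      hr_peak = hp,
      band_amplitudes = base$band_amplitudes * amp_jit,
      band_slopes = base$band_slopes * amp_jit,
      band_freqs = c(
        VLF = stats::runif(1, 0.006, 0.02),
        LF = stats::runif(1, 0.07, 0.12),
        HF = stats::runif(1, 0.20, 0.32)
      ),
      noise_mix = min(1, max(0, base$noise_mix + stats::runif(1, -0.05, 0.05))),
      noise_sd = base$noise_sd * exp(stats::rnorm(1, 0, 0.2)),
      phase_jitter = base$phase_jitter * exp(stats::rnorm(1, 0, 0.2)),
      seed = ep_seeds[i]
    )
    episodes[[i]] <- generate_rr_series(spec)
  }
  manifest <- data.frame(
    episode_id = sprintf("ep%03d", seq_len(n)),
    condition = conditions,
    seed = ep_seeds,
    stringsAsFactors = FALSE
  )
  list(episodes = episodes, manifest = manifest)
}
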