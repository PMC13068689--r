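# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package internals.

# Brute-force sample entropy by direct template counting: for each pair of
# template start positions, compare the windows element by element.
brute_sampen <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m # template count used for both lengths
  a <- 0
  b <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      d_m <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (d_m <= r) {
        b <- b + 1
        if (abs(x[i + m] - x[j + m]) <= r) a <- a + 1
      }
    }
  }
  if (b == 0 || a == 0) return(NA_real_)
  -log(a / b)
}

# Semi-vectorized variant (same counting rule) for larger fixtures.
brute_sampen_fast <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m
  a <- 0
  b <- 0
  for (i in seq_len(nt - 1)) {
    js <- (i + 1):nt
    ok <- rep(TRUE, length(js))
    for (k in 0:(m - 1)) {
      ok <- ok & abs(x[i + k] - x[js + k]) <= r
    }
    b <- b + sum(ok)
    a <- a + sum(ok & abs(x[i + m] - x[js + m]) <= r)
  }
  if (b == 0 || a == 0) return(NA_real_)
  -log(a / b)
}

# Plain one-sided FFT periodogram (no taper, no averaging); density
# normalized so the integral over frequency approximates the variance.
fft_periodogram <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  nf <- n %/% 2 + 1
  p <- Mod(fft(x)[seq_len(nf)])^2 / (n * fs)
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / n, density = p * scale2)
}

# Dominant periodogram frequency.
peak_freq <- function(x, fs) {
  pg <- fft_periodogram(x, fs)
  pg$freq[which.max(pg$density)]
}

# Textbook simple-regression statistics from the normal equations.
ols_oracle <- function(t, y) {
  n <- length(t)
  X <- cbind(1, t)
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - 2)
  covb <- sigma2 * solve(crossprod(X))
  se <- sqrt(diag(covb))
  tcrit <- qt(0.975, n - 2)
  list(
    intercept = unname(beta[1]), slope = unname(beta[2]),
    se_intercept = unname(se[1]), se_slope = unname(se[2]),
    r_squared = unname(1 - rss / tss),
    f_ratio = unname((tss - rss) / sigma2),
    p_value = unname(2 * pt(-abs(beta[2] / se[2]), n - 2)),
    ci95 = unname(c(beta[2] - tcrit * se[2], beta[2] + tcrit * se[2]))
  )
}

# Fraction of the periodogram power falling inside [lo, hi] Hz.
band_power_fraction <- function(x, fs, lo, hi) {
  pg <- fft_periodogram(x, fs)
  sel <- pg$freq >= lo & pg$freq <= hi
  sum(pg$density[sel]) / sum(pg$density)
}

# Match detected event times to truth within a tolerance; each truth time
# may be claimed once. Returns tp / fp / fn counts and the F1 score.
match_events <- function(detected, truth, tol = 0.020) {
  used <- rep(FALSE, length(truth))
  tp <- 0
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol)
    if (length(j)) {
      used[j[1]] <- TRUE
      tp <- tp + 1
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(tp = tp, fp = fp, fn = fn, f1 = f1,
       sensitivity = tp / length(truth),
       precision = if (length(detected)) tp / length(detected) else NA_real_)
}

# Small deterministic episode helpers used across test files.
quiet_spec <- function(hr = 60, duration = 120, seed = 1, ...) {
  episode_spec(
    condition = "PSH", duration = duration, onset_time = duration / 2,
    hr_baseline = hr, hr_peak = hr,
    band_amplitudes = c(VLF = 0, LF = 0, HF = 0),
    band_slopes = c(VLF = 0, LF = 0, HF = 0),
    noise_mix = 0, noise_sd = 0, phase_jitter = 0, seed = seed, ...
  )
}

single_tone_spec <- function(band = "HF", freq = 0.25, amp = 0.03,
                             hr = 70, duration = 660, seed = 1,
                             phase_jitter = 0) {
  amps <- c(VLF = 0, LF = 0, HF = 0)
  amps[band] <- amp
  episode_spec(
    condition = "PSH", duration = duration, onset_time = duration / 2,
    hr_baseline = hr, hr_peak = hr,
    band_amplitudes = amps,
    band_slopes = c(VLF = 0, LF = 0, HF = 0),
    band_freqs = replace(c(VLF = 0.01, LF = 0.1, HF = 0.25), band, freq),
    noise_mix = 0, noise_sd = 0, phase_jitter = phase_jitter, seed = seed
  )
}
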