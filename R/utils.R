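# Internal numerical helpers shared across modules.

#' Standard HRV frequency bands (Hz)
#'
#' Band edges used throughout the package: VLF 0.0033-0.04 Hz,
#' LF 0.04-0.15 Hz, HF 0.15-0.5 Hz.
#'
#' @return Named list of length-2 numeric vectors `c(low, high)`.
#' @export
hrv_bands <- function() {
  list(
    VLF = c(0.0033, 0.04),
    LF  = c(0.04, 0.15),
    HF  = c(0.15, 0.50)
  )
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Trapezoidal band integral with linear interpolation at the band edges,
# so that adjacent bands partition the integral without double counting.
band_integral <- function(freq, dens, lo, hi) {
  if (hi <= freq[1] || lo >= freq[length(freq)]) return(0)
  lo <- max(lo, freq[1])
  hi <- min(hi, freq[length(freq)])
  inside <- freq > lo & freq < hi
  f_lo <- stats::approx(freq, dens, xout = lo, rule = 2)$y
  f_hi <- stats::approx(freq, dens, xout = hi, rule = 2)$y
  trapz(c(lo, freq[inside], hi), c(f_lo, dens[inside], f_hi))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Population standard deviation (divide by n, not n - 1).
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin so folds differ in size by at most one per class.
stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  fold <- integer(length(labels))
  classes <- unique(labels)
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    idx <- sample(idx)
    # rotate the dealing order per class so remainder members spread over
    # different folds and fold sizes differ by at most one overall
    order_k <- ((seq_len(k) - 1L + (ci - 1L) * (k %/% 2L)) %% k) + 1L
    fold[idx] <- rep_len(order_k, length(idx))
  }
  fold
}

# 1/f (pink-like) Gaussian noise via spectral shaping of white noise.
one_over_f_noise <- function(n) {
  white <- stats::rnorm(n)
  xf <- stats::fft(white)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) # two-sided frequency index
  shape <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(stats::fft(xf * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}
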