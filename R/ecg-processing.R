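# ECG preprocessing: R-peak detection (Pan-Tompkins), beat-series
# construction, artifact correction, and ECG-derived respiration.

#' Construct a beat series
#'
#' @param beat_times Strictly increasing R-peak times, seconds.
#' @param rr_ms Optional RR intervals (ms); defaults to successive
#'   differences of `beat_times`.
#' @param corrected Logical vector flagging corrected intervals.
#' @param source One of `"detected"`, `"annotated"`, `"synthetic"`.
#' @return A `beat_series` object.
#' @export
beat_series <- function(beat_times, rr_ms = NULL,
                        corrected = NULL,
                        source = c("detected", "annotated", "synthetic")) {
  source <- match.arg(source)
  if (length(beat_times) >= 2 && is.unsorted(beat_times, strictly = TRUE)) {
    stop("beat_times must be strictly increasing")
  }
  if (is.null(rr_ms)) rr_ms <- diff(beat_times) * 1000
  if (length(rr_ms) != max(0L, length(beat_times) - 1L)) {
    stop("rr_ms must have length(beat_times) - 1 entries")
  }
  if (is.null(corrected)) corrected <- rep(FALSE, length(rr_ms))
  structure(
    list(
      beat_times = as.numeric(beat_times),
      rr_ms = as.numeric(rr_ms),
      corrected = as.logical(corrected),
      source = source,
      low_quality = FALSE
    ),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf(
    "<beat_series> %d beats over %.1f s (%s)%s\n",
    length(x$beat_times),
    if (length(x$beat_times)) diff(range(x$beat_times)) else 0,
    x$source,
    if (isTRUE(x$low_quality)) " [low quality]" else ""
  ))
  invisible(x)
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic Pan-Tompkins stages: 5-15 Hz band-pass, five-point derivative,
#' squaring, 150-ms moving-window integration, then adaptive dual
#' thresholds on the integrated signal with a 200-ms refractory period and
#' a search-back pass at half threshold when an expected beat is missed.
#' Detected peaks are refined to the local maximum of the raw signal within
#' +/- 25 ms. Detection is invariant to a constant voltage offset.
#'
#' @param ecg An `ecg_record` (fields `samples`, `fs`).
#' @return Numeric vector of R-peak times (s); empty (with a warning) for a
#'   flat or beatless signal.
#' @export
detect_r_peaks <- function(ecg) {
  fs <- ecg$fs
  x <- ecg$samples
  if (fs < 100) stop("sampling rate must be >= 100 Hz")
  if (length(x) < 10 * fs) stop("record must be at least 10 s long")
  if (stats::sd(x) == 0) {
    warning("flat signal: no beats detected")
    return(numeric(0))
  }
  x <- x - mean(x)
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  # five-point derivative (Pan-Tompkins kernel), then squaring
  h <- c(1, 2, 0, -2, -1) * fs / 8
  xd <- stats::filter(xf, h, sides = 2)
  xd[is.na(xd)] <- 0
  xs <- as.numeric(xd)^2
  # moving-window integration, 150 ms
  w <- max(1L, round(0.150 * fs))
  mwi <- stats::filter(xs, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  refractory <- as.integer(round(0.200 * fs))
  # candidate local maxima of the integrated signal, with non-maximum
  # suppression inside the refractory window (the MWI envelope carries
  # side lobes around each QRS complex)
  n <- length(mwi)
  is_peak <- c(FALSE, mwi[2:(n - 1)] > mwi[1:(n - 2)] & mwi[2:(n - 1)] >= mwi[3:n], FALSE)
  cand <- which(is_peak)
  if (!length(cand)) {
    warning("no candidate peaks found")
    return(numeric(0))
  }
  keep <- logical(length(cand))
  suppressed <- logical(length(cand))
  for (o in order(mwi[cand], decreasing = TRUE)) {
    if (suppressed[o]) next
    keep[o] <- TRUE
    suppressed[abs(cand - cand[o]) < refractory] <- TRUE
  }
  cand <- cand[keep]
  # adaptive thresholds (initialized on the first 2 s)
  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  rr_hist <- numeric(0)
  last <- -Inf
  for (p in cand) {
    if (p - last < refractory) next
    if (mwi[p] > thr1) {
      # search-back: did we miss a beat in a long gap?
      if (length(rr_hist) >= 2 && is.finite(last)) {
        rr_avg <- mean(utils::tail(rr_hist, 8))
        if ((p - last) > 1.66 * rr_avg) {
          gap <- cand[cand > last + refractory & cand < p - refractory]
          if (length(gap)) {
            thr2 <- thr1 / 2
            gb <- gap[mwi[gap] > thr2]
            if (length(gb)) {
              best <- gb[which.max(mwi[gb])]
              peaks <- c(peaks, best)
              rr_hist <- c(rr_hist, best - last)
              spki <- 0.25 * mwi[best] + 0.75 * spki
              last <- best
              if (p - last < refractory) next
            }
          }
        }
      }
      peaks <- c(peaks, p)
      if (is.finite(last)) rr_hist <- c(rr_hist, p - last)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      last <- p
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (!length(peaks)) {
    warning("no beats exceeded the detection threshold")
    return(numeric(0))
  }
  # refine to the raw-signal local maximum within +/- 25 ms
  half <- as.integer(round(0.025 * fs))
  refined <- vapply(as.integer(peaks), function(p) {
    lo <- max(1L, p - half)
    hi <- min(length(x), p + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # drop refinements collapsing within the refractory period
  keep <- c(TRUE, diff(refined) >= refractory)
  refined <- refined[keep]
  ecg$start_time + (refined - 1L) / fs
}

#' Correct artifact and ectopic intervals in a beat series
#'
#' An interval is flagged when it deviates from the local running median
#' (window of 11 intervals) by more than `threshold` (relative). Flagged
#' intervals are replaced by cubic-spline interpolation over the accepted
#' neighbours, and each contiguous corrected run is rescaled so its summed
#' duration matches the original beat-time span: the beat count and total
#' duration are preserved. If more than 20% of intervals are flagged the
#' series is marked low-quality (processing continues).
#'
#' @param beats A `beat_series`.
#' @param threshold Relative deviation from the local median that flags an
#'   interval (default 0.25).
#' @param mode `"interpolate"` (default) replaces flagged intervals;
#'   `"exclude"` leaves values untouched but flags them so downstream
#'   time-domain summaries can drop them.
#' @return List with `beats` (corrected `beat_series`) and `report` (counts,
#'   fraction corrected, method, low-quality flag).
#' @export
correct_artifacts <- function(beats, threshold = 0.25,
                              mode = c("interpolate", "exclude")) {
  mode <- match.arg(mode)
  rr <- beats$rr_ms
  if (length(rr) < 10) stop("need at least 10 intervals")
  med <- stats::runmed(rr, k = 11, endrule = "median")
  flag <- abs(rr - med) / med > threshold
  report <- list(
    n_detected_artifacts = sum(flag),
    fraction_corrected = mean(flag),
    method = sprintf("local-median(11) %.0f%% rule, %s", 100 * threshold, mode),
    low_quality = mean(flag) > 0.20
  )
  out <- beats
  out$low_quality <- report$low_quality
  if (!any(flag)) {
    return(list(beats = out, report = report))
  }
  out$corrected <- flag
  if (mode == "interpolate") {
    mid <- (beats$beat_times[-1] + beats$beat_times[-length(beats$beat_times)]) / 2
    ok <- which(!flag)
    if (length(ok) >= 4) {
      sf <- stats::splinefun(mid[ok], rr[ok], method = "fmm")
      new_rr <- rr
      new_rr[flag] <- sf(mid[flag])
      # rescale each corrected run so the spanned duration is unchanged
      runs <- rle(flag)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (j in which(runs$values)) {
        idx <- starts[j]:ends[j]
        span <- sum(rr[idx])
        s <- sum(new_rr[idx])
        if (s > 0) new_rr[idx] <- new_rr[idx] * span / s
      }
      out$rr_ms <- new_rr
      out$beat_times <- beats$beat_times[1] + c(0, cumsum(new_rr)) / 1000
    }
  }
  list(beats = out, report = report)
}

#' Estimate the respiratory rate from ECG-derived respiration
#'
#' Builds the EDR signal from beat-to-beat R-wave amplitude modulation:
#' the raw ECG amplitude at each detected beat, cubic-spline resampled to
#' 4 Hz, mean-removed, and scanned for the dominant spectral peak in
#' 0.1-0.7 Hz. The rate is reported in breaths/min; if no peak rises above
#' the in-band noise floor the result is `NA` with a warning.
#'
#' @param ecg An `ecg_record`.
#' @param beats A `beat_series` detected on `ecg`.
#' @param peak_factor Dominance required of the peak relative to the median
#'   in-band periodogram power (default 5).
#' @return Respiratory rate in breaths/min, or `NA_real_`.
#' @export
derive_respiration <- function(ecg, beats, peak_factor = 5) {
  bt <- beats$beat_times
  if (length(bt) < 8 || diff(range(bt)) < 60) stop("need >= 60 s of detected beats")
  idx <- pmax(1L, pmin(length(ecg$samples), round((bt - ecg$start_time) * ecg$fs) + 1L))
  amp <- ecg$samples[idx]
  fs_u <- 4
  grid <- seq(min(bt), max(bt), by = 1 / fs_u)
  edr <- stats::splinefun(bt, amp, method = "fmm")(grid)
  edr <- edr - mean(edr)
  if (stats::sd(edr) == 0) {
    warning("no amplitude modulation: respiratory rate unavailable")
    return(NA_real_)
  }
  n <- length(edr)
  spec <- Mod(stats::fft(edr))^2 / n
  freq <- (seq_len(n) - 1L) * fs_u / n
  band <- freq >= 0.1 & freq <= 0.7
  if (!any(band)) return(NA_real_)
  pband <- spec[band]
  fband <- freq[band]
  if (max(pband) < peak_factor * stats::median(pband)) {
    warning("no dominant respiratory peak above the noise floor")
    return(NA_real_)
  }
  60 * fband[which.max(pband)]
}
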