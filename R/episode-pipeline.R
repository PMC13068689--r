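# Episode orchestration: the Pre20 / Pre10 / Event windowing around an
# annotated onset, per-window feature assembly, group statistics with the
# Bonferroni-corrected t-test battery, and PSH-AM scoring.

#' Split a beat series into the Pre20 / Pre10 / Event windows
#'
#' Three adjacent 600-s blocks around the annotated onset:
#' Pre20 = \[onset - 1200, onset - 600), Pre10 = \[onset - 600, onset),
#' Event = \[onset, onset + 600). A beat on a boundary belongs to the later
#' window.
#'
#' @param beats A `beat_series` covering `[onset - 1200, onset + 600]`.
#' @param onset Event onset time in seconds.
#' @param window_s Block length in seconds (default 600).
#' @param tol Coverage tolerance in seconds (default 2, about one beat at
#'   the low end of the physiological range).
#' @return Named list (`Pre20`, `Pre10`, `Event`) of `beat_series`, with a
#'   `windows` attribute holding the interval bounds.
#' @export
segment_windows <- function(beats, onset, window_s = 600, tol = 2) {
  bt <- beats$beat_times
  lo <- onset - 2 * window_s
  hi <- onset + window_s
  if (bt[1] > lo + tol || bt[length(bt)] < hi - tol) {
    stop(sprintf(
      "recording covers [%.1f, %.1f] s but [%.1f, %.1f] s is required",
      bt[1], bt[length(bt)], lo, hi
    ))
  }
  bounds <- list(
    Pre20 = c(lo, onset - window_s),
    Pre10 = c(onset - window_s, onset),
    Event = c(onset, hi)
  )
  out <- lapply(bounds, function(b) {
    sel <- which(bt >= b[1] & bt < b[2])
    sub <- beat_series(
      bt[sel],
      corrected = if (length(sel) > 1) beats$corrected[sel[-length(sel)]] else logical(0),
      source = beats$source
    )
    sub$low_quality <- beats$low_quality
    sub
  })
  attr(out, "windows") <- bounds
  attr(out, "onset") <- onset
  out
}

#' Extract the HRV feature vector for one window
#'
#' Assembles the time-domain, Welch spectral, and multiscale-entropy
#' features for one 600-s window: SDNN, natural-log band powers, the
#' LF/HF and VLF/(LF + HF) ratios, the complexity indices, and mean and
#' maximum heart rate. Raw band-power skewness across windows typically
#' justifies the log transform; missing upstream values propagate as `NA`.
#'
#' @param beats A `beat_series` for the window.
#' @param episode_id,window,condition Identifiers carried into the row.
#' @param welch_window_s Welch segment length in seconds (default 150).
#' @param mse_scales Scales for the entropy profile (default 1:10).
#' @return One-row data.frame (a feature vector).
#' @export
extract_features <- function(beats, episode_id = NA_character_,
                             window = NA_character_,
                             condition = NA_character_,
                             welch_window_s = 150,
                             mse_scales = 1:10) {
  td <- suppressWarnings(time_domain(beats))
  spec <- tryCatch({
    u <- detrend_quadratic(resample_uniform(beats))
    band_powers(welch_psd(u, window_s = welch_window_s))
  }, error = function(e) NULL)
  mse <- tryCatch(
    complexity_indices(multiscale_entropy(beats$rr_ms, scales = mse_scales)),
    error = function(e) list(ci_short = NA_real_, ci_long = NA_real_)
  )
  g <- function(v) if (is.null(v) || length(v) == 0) NA_real_ else v
  data.frame(
    episode_id = episode_id, window = window, condition = condition,
    mean_hr = g(td$mean_hr), max_hr = g(td$max_hr), sdnn = g(td$sdnn),
    power_vlf = g(spec$power_vlf), power_lf = g(spec$power_lf),
    power_hf = g(spec$power_hf),
    ln_vlf = g(spec$ln_vlf), ln_lf = g(spec$ln_lf), ln_hf = g(spec$ln_hf),
    lf_hf_ratio = g(spec$lf_hf_ratio),
    vlf_over_lf_plus_hf = g(spec$vlf_over_lf_plus_hf),
    ci_short = g(mse$ci_short), ci_long = g(mse$ci_long),
    stringsAsFactors = FALSE
  )
}

#' Per-window feature table for a cohort of episodes
#'
#' Windows each episode around its onset and extracts one feature row per
#' (episode, window): 3 rows per episode.
#'
#' @param cohort A list as returned by [generate_cohort()], or a list with
#'   `episodes` (each having `beat_times`, `rr_ms`, `condition`) and a
#'   `manifest` data.frame.
#' @param onset Onset time in seconds (default 1200, the synthetic
#'   convention).
#' @return data.frame with one row per episode-window.
#' @export
cohort_features <- function(cohort, onset = 1200) {
  rows <- vector("list", length(cohort$episodes))
  for (i in seq_along(cohort$episodes)) {
    ep <- cohort$episodes[[i]]
    bs <- beat_series(ep$beat_times, source = "synthetic")
    wins <- segment_windows(bs, onset = onset)
    id <- cohort$manifest$episode_id[i]
    cond <- cohort$manifest$condition[i]
    rows[[i]] <- do.call(rbind, lapply(names(wins), function(w) {
      extract_features(wins[[w]], episode_id = id, window = w, condition = cond)
    }))
  }
  do.call(rbind, rows)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param n_comparisons Number of planned pairwise comparisons (default 44).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The per-test threshold `alpha / n_comparisons`.
#' @export
bonferroni_alpha <- function(n_comparisons = 44, alpha = 0.05) {
  alpha / n_comparisons
}

#' Compare a measure between conditions or windows
#'
#' Shapiro-Wilk normality assessment (per group for independent designs,
#' on the paired differences otherwise), a two-sided t-test, the effect
#' size r^2 = t^2 / (t^2 + df), and a significance flag at the
#' Bonferroni-adjusted threshold. A non-normal result is still returned,
#' flagged.
#'
#' @param x,y Numeric vectors (matched order for paired designs).
#' @param measure Name carried into the result.
#' @param design `"independent"` or `"paired"`.
#' @param n_comparisons Bonferroni divisor (default 44).
#' @return A `group_comparison` (named list).
#' @export
compare_conditions <- function(x, y, measure = NA_character_,
                               design = c("independent", "paired"),
                               n_comparisons = 44) {
  design <- match.arg(design)
  x <- as.numeric(x); y <- as.numeric(y)
  if (design == "paired" && length(x) != length(y)) {
    stop("paired design requires matched observations")
  }
  if (sum(is.finite(x)) < 3 || sum(is.finite(y)) < 3) {
    stop("need at least 3 observations per group")
  }
  sw_safe <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  if (design == "paired") {
    normality_p <- sw_safe(x - y)
  } else {
    normality_p <- min(sw_safe(x), sw_safe(y), na.rm = TRUE)
  }
  tt <- tryCatch(
    stats::t.test(x, y, paired = design == "paired", var.equal = design == "independent"),
    error = function(e) NULL
  )
  if (is.null(tt)) {
    tstat <- 0; df <- length(x) - 1; p <- 1
  } else {
    tstat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  if (!is.finite(tstat)) { tstat <- 0; p <- 1 }
  alpha_b <- bonferroni_alpha(n_comparisons)
  structure(
    list(
      measure = measure, design = design,
      t = tstat, df = df, p_value = p,
      effect_r2 = tstat^2 / (tstat^2 + df),
      normality_p = normality_p,
      non_normal = is.finite(normality_p) && normality_p < 0.05,
      alpha_bonferroni = alpha_b,
      significant = p < alpha_b
    ),
    class = "group_comparison"
  )
}

#' Run the pairwise t-test battery over a cohort feature table
#'
#' For each measure: paired within-condition comparisons (Pre20 vs Pre10,
#' Pre10 vs Event, per condition) and independent between-condition
#' comparisons (PSH vs noPSH, per window).
#'
#' @param features Output of [cohort_features()].
#' @param measures Feature columns to test.
#' @param n_comparisons Bonferroni divisor (default 44).
#' @return data.frame, one row per comparison.
#' @export
condition_stats <- function(features,
                            measures = c("mean_hr", "max_hr", "sdnn",
                                         "ln_vlf", "ln_lf", "ln_hf",
                                         "lf_hf_ratio", "ci_short", "ci_long"),
                            n_comparisons = 44) {
  get <- function(cond, win, m) {
    sel <- features$condition == cond & features$window == win
    o <- order(features$episode_id[sel])
    features[[m]][sel][o]
  }
  rows <- list()
  for (m in measures) {
    for (cond in c("PSH", "noPSH")) {
      for (pair in list(c("Pre20", "Pre10"), c("Pre10", "Event"))) {
        cmp <- compare_conditions(get(cond, pair[1], m), get(cond, pair[2], m),
          measure = m, design = "paired", n_comparisons = n_comparisons)
        rows[[length(rows) + 1L]] <- data.frame(
          measure = m, scope = cond,
          contrast = paste(pair, collapse = " vs "),
          t = cmp$t, df = cmp$df, p_value = cmp$p_value,
          effect_r2 = cmp$effect_r2, normality_p = cmp$normality_p,
          significant = cmp$significant, stringsAsFactors = FALSE
        )
      }
    }
    for (win in c("Pre20", "Pre10", "Event")) {
      cmp <- compare_conditions(get("PSH", win, m), get("noPSH", win, m),
        measure = m, design = "independent", n_comparisons = n_comparisons)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, scope = win, contrast = "PSH vs noPSH",
        t = cmp$t, df = cmp$df, p_value = cmp$p_value,
        effect_r2 = cmp$effect_r2, normality_p = cmp$normality_p,
        significant = cmp$significant, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' PSH-AM score (Clinical Features Scale + Diagnosis Likelihood Tool)
#'
#' The CFS rates six domains (heart rate, respiratory rate, systolic blood
#' pressure, temperature, sweating, posturing) 0-3 each; a total above 13
#' flags severe features. The DLT is eleven binary indicators. A combined
#' score of 19 or more is categorized "probable" PSH, 8-18 "possible",
#' below 8 "unlikely".
#'
#' @param cfs_items Six integer severity ratings in 0-3.
#' @param dlt_items Eleven binary indicators (0/1).
#' @return A `psh_am_score`: item vectors, `cfs_total`, `dlt_total`,
#'   `combined`, `severe_features`, `category`.
#' @export
psh_am_score <- function(cfs_items, dlt_items) {
  if (length(cfs_items) != 6) stop("cfs_items must have 6 entries")
  if (length(dlt_items) != 11) stop("dlt_items must have 11 entries")
  bad <- which(!(cfs_items %in% 0:3))
  if (length(bad)) stop(sprintf("CFS item %d out of range 0-3", bad[1]))
  bad <- which(!(dlt_items %in% 0:1))
  if (length(bad)) stop(sprintf("DLT item %d must be 0 or 1", bad[1]))
  cfs_total <- sum(cfs_items)
  dlt_total <- sum(dlt_items)
  combined <- cfs_total + dlt_total
  category <- if (combined >= 19) "probable PSH" else if (combined >= 8) "possible PSH" else "unlikely"
  structure(
    list(
      cfs_items = as.integer(cfs_items), dlt_items = as.integer(dlt_items),
      cfs_total = cfs_total, dlt_total = dlt_total, combined = combined,
      severe_features = cfs_total > 13,
      category = category
    ),
    class = "psh_am_score"
  )
}
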