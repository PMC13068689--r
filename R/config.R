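# Pipeline configuration: one place for the tunable analysis parameters,
# serializable to JSON so a study's settings travel with its outputs.

#' Pipeline configuration
#'
#' Collects the analysis parameters shared across modules. Values default
#' to the package's standard settings; a config can be written to and read
#' from JSON.
#'
#' @param window_s Analysis-window length in seconds.
#' @param welch_window_s Welch segment length in seconds.
#' @param welch_overlap Fractional Welch segment overlap.
#' @param bands Named list of band edges in Hz (see [hrv_bands()]).
#' @param mse_scales Integer scales for multiscale entropy.
#' @param mse_m Embedding dimension.
#' @param mse_r_fraction Tolerance fraction of the scale-1 SD.
#' @param artifact_threshold Relative local-median deviation that flags an
#'   interval.
#' @param bonferroni_n Planned-comparison count for the Bonferroni
#'   threshold.
#' @param seed Default seed for stochastic steps.
#' @return A `pshhrv_config` (named list).
#' @export
pipeline_config <- function(window_s = 600,
                            welch_window_s = 150,
                            welch_overlap = 0.5,
                            bands = hrv_bands(),
                            mse_scales = 1:10,
                            mse_m = 2L,
                            mse_r_fraction = 0.2,
                            artifact_threshold = 0.25,
                            bonferroni_n = 44,
                            seed = 1L) {
  structure(
    list(
      window_s = window_s,
      welch_window_s = welch_window_s,
      welch_overlap = welch_overlap,
      bands = bands,
      mse_scales = as.integer(mse_scales),
      mse_m = as.integer(mse_m),
      mse_r_fraction = mse_r_fraction,
      artifact_threshold = artifact_threshold,
      bonferroni_n = bonferroni_n,
      seed = as.integer(seed)
    ),
    class = "pshhrv_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pshhrv_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  for (nm in names(raw)) {
    if (nm %in% names(cfg)) cfg[[nm]] <- raw[[nm]]
  }
  cfg$mse_scales <- as.integer(cfg$mse_scales)
  cfg$bands <- lapply(cfg$bands, as.numeric)
  cfg
}

#' One-hot encoding of an etiology label
#'
#' Expands a categorical etiology column (e.g. traumatic / hemorrhagic /
#' anoxic) into 0/1 indicator columns that can be appended to a feature
#' table. The classifier excludes etiology by default; this helper is for
#' users who want it carried as a model input.
#'
#' @param etiology Character or factor vector.
#' @param prefix Column-name prefix.
#' @return data.frame of indicator columns, one per level.
#' @export
onehot_etiology <- function(etiology, prefix = "etiology_") {
  f <- factor(etiology)
  m <- stats::model.matrix(~ f - 1)
  colnames(m) <- paste0(prefix, levels(f))
  as.data.frame(m)
}
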