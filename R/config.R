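#' Pipeline run configuration
#'
#' Bundles the preprocessing and decoding parameters of one run. Defaults
#' follow the standard recipe: 50 Hz notch with 4 harmonics, common average
#' reference, downsampling to 500 Hz, 100 ms bins, mean high-gamma
#' (70-150 Hz) band power, 1 Mohm impedance exclusion and a chronological
#' 7:3 train/test split.
#'
#' @param seed integer RNG seed.
#' @param band high-gamma band `(low, high)` in Hz; `0 < low < high <
#'   target_fs/2`.
#' @param bin_ms feature bin duration in milliseconds.
#' @param notch_base mains fundamental in Hz.
#' @param n_harmonics number of notched harmonics (fundamental included).
#' @param target_fs processing rate in Hz after downsampling.
#' @param impedance_threshold exclusion threshold in Mohm.
#' @param split_ratio training fraction of the chronological split, in (0, 1).
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L, band = c(70, 150), bin_ms = 100,
                       notch_base = 50, n_harmonics = 4L, target_fs = 500,
                       impedance_threshold = 1, split_ratio = 0.7) {
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L] ||
      band[2L] >= target_fs / 2)
    stopf("band must satisfy 0 < low < high < target_fs/2")
  if (bin_ms <= 0) stopf("bin_ms must be positive")
  if (split_ratio <= 0 || split_ratio >= 1) stopf("split_ratio must be in (0, 1)")
  structure(
    list(seed = as.integer(seed), band = as.numeric(band), bin_ms = bin_ms,
         notch_base = notch_base, n_harmonics = as.integer(n_harmonics),
         target_fs = target_fs, impedance_threshold = impedance_threshold,
         split_ratio = split_ratio),
    class = "run_config"
  )
}

#' Read / write a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `read_run_config` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  x <- jsonlite::fromJSON(path)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}
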