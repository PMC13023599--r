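# Uniformly sampled physiological channel and its on-disk form
# (two-column CSV `time_s,value` plus a JSON sidecar carrying fs etc.).

#' Construct a uniformly sampled signal
#'
#' @param values numeric vector of samples (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample, seconds.
#' @param channel channel label (e.g. `"resp"`, `"ecg"`).
#' @return an object of class `sampled_signal` with fields `values`,
#'   `fs`, `t0`, `channel`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 0.25 * seq(0, 60, by = 0.01)), fs = 100)
#' s
#' @export
sampled_signal <- function(values, fs, t0 = 0, channel = "signal") {
  values <- as.numeric(values)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive finite number")
  if (length(values) < 2)
    stop("a sampled signal needs at least 2 samples")
  nbad <- sum(!is.finite(values))
  if (nbad > 0)
    stop("signal contains ", nbad, " non-finite sample(s); first at index ",
         which(!is.finite(values))[1])
  structure(list(values = values, fs = fs, t0 = t0, channel = channel),
            class = "sampled_signal")
}

#' Sample times of a signal
#' @param x a `sampled_signal`.
#' @return numeric vector of times, seconds.
#' @export
signal_times <- function(x) {
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' Duration of a signal in seconds
#' @param x a `sampled_signal`.
#' @export
signal_duration <- function(x) {
  (length(x$values) - 1) / x$fs
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal '%s': %d samples @ %g Hz, %.1f s, t0 = %g s>\n",
              x$channel, length(x$values), x$fs, signal_duration(x), x$t0))
  invisible(x)
}

#' @export
plot.sampled_signal <- function(x, ...) {
  graphics::plot(signal_times(x), x$values, type = "l",
                 xlab = "time (s)", ylab = x$channel, ...)
  invisible(x)
}

sidecar_path <- function(path) {
  sub("\\.csv$", "", path, ignore.case = TRUE) |> paste0(".json")
}

#' Write a signal to CSV with a JSON sidecar
#'
#' The CSV holds `time_s,value`; the sidecar records the sampling rate,
#' channel label and any provenance fields (seed, scenario) so the file
#' pair round-trips through [read_signal_csv()].
#'
#' @param x a `sampled_signal`.
#' @param path CSV destination; the sidecar goes to the same path with a
#'   `.json` extension.
#' @param seed,scenario optional provenance recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path, seed = NULL, scenario = NULL) {
  stopifnot(inherits(x, "sampled_signal"))
  df <- data.frame(time_s = signal_times(x), value = x$values)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = x$fs, t0 = x$t0, channel = x$channel,
               n_samples = length(x$values))
  if (!is.null(seed)) meta$seed <- seed
  if (!is.null(scenario)) meta$scenario <- scenario
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a signal CSV with its JSON sidecar
#'
#' Validates the file pair: the sidecar must carry `fs`; samples must be
#' finite; the time column must be uniform at `1/fs` (a gap is rejected
#' with its location).
#'
#' @param path CSV path (`time_s,value`).
#' @param sidecar sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @return a `sampled_signal`.
#' @export
read_signal_csv <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(sidecar))
    stop("sidecar not found for '", path, "' (expected '", sidecar, "')")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs) || !is.finite(as.numeric(meta$fs)))
    stop("sidecar '", sidecar, "' does not define a finite 'fs'")
  fs <- as.numeric(meta$fs)
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("'", path, "' is not a two-column signal CSV")
  tm <- as.numeric(df[[1]]); v <- as.numeric(df[[2]])
  nbad <- sum(!is.finite(v))
  if (nbad > 0)
    stop("'", path, "' contains ", nbad, " non-finite sample(s); first at row ",
         which(!is.finite(v))[1])
  dt <- diff(tm)
  if (any(dt <= 0))
    stop("time column of '", path, "' is not strictly increasing (first at row ",
         which(dt <= 0)[1] + 1, ")")
  gap <- which(abs(dt - 1 / fs) > 0.25 / fs)
  if (length(gap) > 0)
    stop("time column of '", path, "' has a gap at t = ",
         format(tm[gap[1]]), " s (row ", gap[1] + 1, "): spacing ",
         format(dt[gap[1]]), " s, expected ", format(1 / fs), " s")
  sampled_signal(v, fs = fs, t0 = tm[1],
                 channel = if (!is.null(meta$channel)) meta$channel else "signal")
}
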