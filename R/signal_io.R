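#' Construct an EPG recording
#'
#' A `Recording` holds one channel of an electrophytography (EPG) voltage
#' time series together with its sampling rate and condition metadata. All
#' analysis functions in the package consume this container.
#'
#' @param samples numeric vector of voltage values (µV); all finite, length
#'   at least 2.
#' @param fs sampling rate in Hz (default 62.5, the acquisition rate the
#'   analyses assume).
#' @param plant_id text label identifying the source plant.
#' @param treatment one of `"bean"`, `"wheat"`, `"control"`, `"synthetic"`.
#' @param phase one of `"before"`, `"after"`, `"none"`.
#' @param channel small integer channel index.
#' @return An object of class `Recording`: a list with elements `samples`,
#'   `fs`, `n`, `plant_id`, `treatment`, `phase`, `channel`.
#' @examples
#' rec <- recording(rnorm(1000), fs = 62.5, plant_id = "p1")
#' rec$n
#' @export
recording <- function(samples, fs = 62.5, plant_id = "unknown",
                      treatment = c("synthetic", "bean", "wheat", "control"),
                      phase = c("none", "before", "after"), channel = 1L) {
  samples <- as.numeric(samples)
  treatment <- match.arg(treatment)
  phase <- match.arg(phase)
  if (length(samples) < 2L) stop("a Recording needs at least 2 samples")
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples))[1L]
    stop("non-finite sample at position ", bad)
  }
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive sampling rate (Hz)")
  structure(
    list(samples = samples, fs = fs, n = length(samples),
         plant_id = as.character(plant_id), treatment = treatment,
         phase = phase, channel = as.integer(channel)),
    class = "Recording"
  )
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("<Recording> %s | %s/%s | channel %d | n = %d @ %.4g Hz (%.1f s)\n",
              x$plant_id, x$treatment, x$phase, x$channel, x$n, x$fs, x$n / x$fs))
  invisible(x)
}

#' Expected sample count of a recording
#'
#' Number of samples produced by `duration_s` seconds of acquisition at
#' sampling rate `fs`. A standard 2 h segment at 62.5 Hz has 450,000 samples.
#'
#' @param duration_s duration in seconds (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @return Integer sample count, `round(duration_s * fs)`.
#' @examples
#' expected_length(7200, 62.5)  # 450000
#' @export
expected_length <- function(duration_s, fs) {
  if (!is.finite(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0")
  as.integer(round(duration_s * fs))
}

#' Read a recording from delimited text plus a metadata sidecar
#'
#' Reads a comma- or tab-delimited file with one numeric column per channel
#' and an optional leading time column, together with a YAML/JSON sidecar (or
#' inline metadata) carrying `fs`, `plant_id`, `treatment`, `phase`.
#'
#' @param path path to the delimited data file.
#' @param meta path to a YAML or JSON sidecar, or a named list of metadata
#'   fields. Must supply `fs`.
#' @param channel which data column to read (after the time column, if any).
#' @param has_time whether the first column is a time axis (auto-detected
#'   from the sidecar field `has_time` when present).
#' @return A [recording()].
#' @export
read_recording <- function(path, meta, channel = 1L, has_time = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.character(meta)) {
    if (!file.exists(meta)) stop("no such sidecar: ", meta)
    meta <- if (grepl("\\.json$", meta, ignore.case = TRUE))
      jsonlite::read_json(meta, simplifyVector = TRUE)
    else yaml::read_yaml(meta)
  }
  if (is.null(meta$fs)) stop("metadata must supply the sampling rate `fs`")
  if (is.null(has_time)) has_time <- isTRUE(meta$has_time)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  dat <- utils::read.csv(path, header = grepl("[A-Za-z]", first), sep = sep)
  col <- as.integer(channel) + if (has_time) 1L else 0L
  if (col > ncol(dat)) stop("channel ", channel, " not present (", ncol(dat), " columns)")
  x <- suppressWarnings(as.numeric(dat[[col]]))
  if (anyNA(x) || !all(is.finite(x))) {
    bad <- which(!is.finite(x))[1L]
    stop("non-numeric or non-finite value in data row ", bad, " of ", path)
  }
  recording(x, fs = meta$fs,
            plant_id = meta$plant_id %||% "unknown",
            treatment = meta$treatment %||% "synthetic",
            phase = meta$phase %||% "none",
            channel = channel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording to delimited text plus a YAML sidecar
#'
#' Inverse of [read_recording()]: writes one sample per row at full double
#' precision and a `<path>.yaml` sidecar carrying the metadata, so a
#' round-trip reproduces the samples bit-exactly.
#'
#' @param rec a [recording()].
#' @param path output file path for the data; the sidecar is written to
#'   `paste0(path, ".yaml")`.
#' @return Invisibly, the sidecar path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "Recording"))
  writeLines(sprintf("%.17g", rec$samples), path)
  side <- paste0(path, ".yaml")
  yaml::write_yaml(list(fs = rec$fs, plant_id = rec$plant_id,
                        treatment = rec$treatment, phase = rec$phase,
                        channel = rec$channel, n = rec$n, has_time = FALSE),
                   side)
  invisible(side)
}

#' Segment a recording into overlapping windows
#'
#' Divides the series into `n_windows` equal-length windows where consecutive
#' windows overlap by `overlap_fraction` of the window length (the step
#' between starts is `w - round(overlap_fraction * w)`). The window length is
#' `w = floor(n / (n_windows - (n_windows - 1) * overlap_fraction))`; trailing
#' remainder samples are dropped. Indices are 0-based, intervals half-open.
#'
#' @param rec a [recording()].
#' @param n_windows number of windows (default 10).
#' @param overlap_fraction fraction of each window shared with the next, in
#'   `[0, 1)` (default 0.3).
#' @return A `WindowSet`: list with `parent` (the recording), `starts`
#'   (0-based), `length` (window length in samples), `overlap_fraction`.
#' @examples
#' ws <- segment(recording(rnorm(7300)), 10, 0.3)
#' ws$length  # 1000
#' @export
segment <- function(rec, n_windows = 10L, overlap_fraction = 0.3) {
  stopifnot(inherits(rec, "Recording"))
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  n_windows <- as.integer(n_windows)
  if (n_windows < 1L) stop("n_windows must be >= 1")
  # small epsilon guards against floating-point floor (e.g. 7300/7.3)
  w <- floor(rec$n / (n_windows - (n_windows - 1) * overlap_fraction) + 1e-9)
  # rounding of the step can push the last window past n; shrink w until the
  # layout fits
  repeat {
    if (w < 2) stop("series too short for ", n_windows, " windows at overlap ",
                    overlap_fraction)
    step <- w - round(overlap_fraction * w)
    if ((n_windows - 1L) * step + w <= rec$n) break
    w <- w - 1L
  }
  starts <- (seq_len(n_windows) - 1L) * step
  structure(list(parent = rec, starts = as.integer(starts), length = as.integer(w),
                 overlap_fraction = overlap_fraction),
            class = "WindowSet")
}

#' Extract the samples of one window from a WindowSet
#' @param ws a `WindowSet` from [segment()].
#' @param i window index (1-based).
#' @return Numeric vector of the window's samples.
#' @export
window_samples <- function(ws, i) {
  stopifnot(inherits(ws, "WindowSet"), i >= 1, i <= length(ws$starts))
  s <- ws$starts[i]
  ws$parent$samples[(s + 1L):(s + ws$length)]
}

#' Prevalence of a visually detected pattern, as the percentage reported
#'
#' Given a count of recordings showing a pattern out of a total, returns the
#' percentage truncated (not rounded) to one decimal place, the convention
#' used when reporting e.g. 20 of 23 recordings as 86.9%.
#'
#' @param n_detected recordings showing the pattern.
#' @param n_total recordings inspected.
#' @return Percentage, one decimal, truncated toward zero.
#' @examples
#' pattern_prevalence(20, 23)  # 86.9
#' @export
pattern_prevalence <- function(n_detected, n_total) {
  if (n_total <= 0 || n_detected < 0 || n_detected > n_total)
    stop("need 0 <= n_detected <= n_total, n_total > 0")
  trunc(1000 * n_detected / n_total) / 10
}
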