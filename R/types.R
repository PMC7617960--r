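#' Beat-interval series
#'
#' Container for an RR (or NN) interval series: the time of each beat and the
#' interval that ended at it, both in seconds. `time_s` must be strictly
#' increasing and intervals strictly positive.
#'
#' @param time_s numeric vector of beat times (s), strictly increasing.
#' @param rr_s numeric vector of RR intervals (s), same length as `time_s`.
#' @param outlier_flags optional logical vector marking suspect intervals.
#' @return An object of class `rr_series`: a data frame with columns
#'   `time_s`, `rr_s` and `outlier` (logical).
#' @export
#' @examples
#' rr <- rr_series(cumsum(rep(0.8, 10)), rep(0.8, 10))
#' nrow(rr)
rr_series <- function(time_s, rr_s, outlier_flags = NULL) {
  time_s <- as.numeric(time_s)
  rr_s <- as.numeric(rr_s)
  if (length(time_s) != length(rr_s)) {
    stop("`time_s` and `rr_s` must have the same length", call. = FALSE)
  }
  if (length(time_s) == 0L) stop("empty RR series", call. = FALSE)
  if (any(!is.finite(time_s)) || any(!is.finite(rr_s))) {
    stop("RR series must be finite", call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) {
    stop("beat times must be strictly increasing", call. = FALSE)
  }
  if (any(rr_s <= 0)) stop("RR intervals must be positive", call. = FALSE)
  if (is.null(outlier_flags)) outlier_flags <- rep(FALSE, length(rr_s))
  out <- data.frame(time_s = time_s, rr_s = rr_s,
                    outlier = as.logical(outlier_flags))
  class(out) <- c("rr_series", "data.frame")
  out
}

#' R-peak annotations from a beat detector
#'
#' @param sample_indices strictly increasing integer sample indices of
#'   detected R peaks.
#' @param sampling_rate_hz sampling rate of the source ECG (Hz), positive.
#' @return An object of class `peak_annotations` with elements
#'   `sample_indices`, `sampling_rate_hz` and derived `time_s`.
#' @export
peak_annotations <- function(sample_indices, sampling_rate_hz) {
  sample_indices <- as.numeric(sample_indices)
  if (length(sample_indices) > 1 && any(diff(sample_indices) <= 0)) {
    stop("sample indices must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a positive scalar", call. = FALSE)
  }
  structure(list(sample_indices = sample_indices,
                 sampling_rate_hz = sampling_rate_hz,
                 time_s = sample_indices / sampling_rate_hz),
            class = "peak_annotations")
}

#' Uniformly sampled tachogram
#'
#' @param values interval values (s) on a uniform time grid.
#' @param start_time_s time of the first sample (s).
#' @param sampling_rate_hz sampling rate (Hz), positive.
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, start_time_s, sampling_rate_hz) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (sampling_rate_hz <= 0) stop("sampling rate must be positive", call. = FALSE)
  structure(list(values = values,
                 start_time_s = as.numeric(start_time_s),
                 sampling_rate_hz = as.numeric(sampling_rate_hz)),
            class = "uniform_series")
}

#' Frequency band definition
#'
#' Standard short-term HRV analysis places the low-frequency (Mayer wave)
#' band at 0.04--0.15 Hz and the high-frequency (respiratory sinus
#' arrhythmia) band at 0.15--0.4 Hz; [lf_band()] and [hf_band()] return
#' those defaults.
#'
#' @param name band label, e.g. `"LF"` or `"HF"`.
#' @param f_left,f_right band edges in Hz, `0 <= f_left < f_right`.
#' @return An object of class `band_definition`.
#' @export
#' @examples
#' band_definition("LF", 0.04, 0.15)
band_definition <- function(name, f_left, f_right) {
  if (!is.character(name) || length(name) != 1L) {
    stop("`name` must be a single string", call. = FALSE)
  }
  if (f_left < 0 || f_right <= f_left) {
    stop("band edges must satisfy 0 <= f_left < f_right", call. = FALSE)
  }
  structure(list(name = name, f_left = as.numeric(f_left),
                 f_right = as.numeric(f_right)),
            class = "band_definition")
}

#' @rdname band_definition
#' @export
lf_band <- function() band_definition("LF", 0.04, 0.15)

#' @rdname band_definition
#' @export
hf_band <- function() band_definition("HF", 0.15, 0.40)

#' Single-segment power spectral density
#'
#' @param freqs frequency grid (Hz), strictly increasing, nonnegative.
#' @param power power density values (s^2/Hz), nonnegative, same length.
#' @param segment_id integer identifier of the source segment.
#' @return An object of class `psd_spectrum`.
#' @export
psd_spectrum <- function(freqs, power, segment_id = 1L) {
  freqs <- as.numeric(freqs)
  power <- as.numeric(power)
  if (length(freqs) != length(power)) {
    stop("`freqs` and `power` must have equal length", call. = FALSE)
  }
  if (length(freqs) > 1 && any(diff(freqs) <= 0)) {
    stop("`freqs` must be strictly increasing", call. = FALSE)
  }
  if (any(freqs < 0)) stop("`freqs` must be nonnegative", call. = FALSE)
  if (any(!is.finite(power)) || any(power < -1e-12)) {
    stop("`power` must be finite and nonnegative", call. = FALSE)
  }
  structure(list(freqs = freqs, power = pmax(power, 0),
                 segment_id = as.integer(segment_id)),
            class = "psd_spectrum")
}

#' Spectrum matrix: stacked per-segment PSDs on a shared grid
#'
#' Rows are segments, columns are frequency bins. This is the object the
#' completion machinery operates on.
#'
#' @param rows numeric matrix, one row per segment.
#' @param freqs frequency bin centers (Hz), one per column.
#' @param row_ids segment identifiers, one per row.
#' @return An object of class `spectrum_matrix` with elements `rows`,
#'   `freqs`, `row_ids`.
#' @export
spectrum_matrix <- function(rows, freqs, row_ids = seq_len(nrow(rows))) {
  rows <- as.matrix(rows)
  freqs <- as.numeric(freqs)
  if (ncol(rows) != length(freqs)) {
    stop("number of columns must match length of `freqs`", call. = FALSE)
  }
  if (length(freqs) > 1 && any(diff(freqs) <= 0)) {
    stop("`freqs` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(rows))) stop("matrix entries must be finite", call. = FALSE)
  if (length(row_ids) != nrow(rows)) {
    stop("`row_ids` must have one entry per row", call. = FALSE)
  }
  structure(list(rows = rows, freqs = freqs, row_ids = row_ids),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix> %d segments x %d bins, %.4g-%.4g Hz\n",
              nrow(x$rows), ncol(x$rows), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats over %.1f s (%d flagged)\n",
              nrow(x), x$time_s[nrow(x)] - x$time_s[1], sum(x$outlier)))
  invisible(x)
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %g Hz from t=%.2f s\n",
              length(x$values), x$sampling_rate_hz, x$start_time_s))
  invisible(x)
}

# internal: coerce spectrum_matrix | matrix to plain matrix
as_matrix_rows <- function(S) {
  if (inherits(S, "spectrum_matrix")) S$rows else as.matrix(S)
}
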