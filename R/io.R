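#' Read and write RR-interval series
#'
#' Delimited text with header columns `time_s` and `rr_s`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return [read_rr()] returns an [rr_series].
#' @export
read_rr <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("time_s", "rr_s") %in% names(df))) {
    stop("RR file needs columns `time_s` and `rr_s`", call. = FALSE)
  }
  rr_series(df$time_s, df$rr_s)
}

#' @rdname read_rr
#' @param rr an [rr_series].
#' @export
write_rr <- function(rr, path, sep = "\t") {
  stopifnot(inherits(rr, "rr_series"))
  utils::write.table(rr[, c("time_s", "rr_s")], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read R-peak annotations
#'
#' One column `sample_index` (header optional) of strictly increasing
#' integer sample positions.
#'
#' @param path file path.
#' @param sampling_rate_hz ECG sampling rate (Hz).
#' @param sep field separator.
#' @return A [peak_annotations].
#' @export
read_annotations <- function(path, sampling_rate_hz, sep = "\t") {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = has_header, sep = sep)
  peak_annotations(df[[1]], sampling_rate_hz)
}

#' Read and write spectrum matrices
#'
#' Delimited text: first row holds the frequency bin centers (Hz),
#' every following row is one segment's spectrum.
#'
#' @param path file path.
#' @param sep field separator.
#' @return [read_spectrum_matrix()] returns a [spectrum_matrix].
#' @export
read_spectrum_matrix <- function(path, sep = "\t") {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  if (nrow(m) < 2) stop("matrix file needs a frequency row plus data rows", call. = FALSE)
  spectrum_matrix(m[-1, , drop = FALSE], m[1, ])
}

#' @rdname read_spectrum_matrix
#' @param S a [spectrum_matrix].
#' @export
write_spectrum_matrix <- function(S, path, sep = "\t") {
  stopifnot(inherits(S, "spectrum_matrix"))
  m <- rbind(S$freqs, S$rows)
  utils::write.table(m, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write observation masks
#'
#' 0/1 grid as delimited text, 1 = known.
#'
#' @param path file path.
#' @param sep field separator.
#' @return [read_mask()] returns an [observation_mask].
#' @export
read_mask <- function(path, sep = "\t") {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  observation_mask(m != 0)
}

#' @rdname read_mask
#' @param mask an [observation_mask].
#' @export
write_mask <- function(mask, path, sep = "\t") {
  stopifnot(inherits(mask, "observation_mask"))
  utils::write.table(mask$known * 1L, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' From a cleaned RR series to the stacked spectrum matrix
#'
#' Convenience pipeline: segment the series into 5-minute windows (with
#' optional per-beat quality gating), resample each high-quality segment at
#' `fs`, band-pass it, run Welch, and stack the spectra restricted to the
#' analysis band.
#'
#' @param rr a cleaned [rr_series].
#' @param sqi_flags optional per-beat quality values for gating.
#' @param window_s segment length (s).
#' @param threshold segment mean-SQI threshold.
#' @param fs resampling rate (Hz).
#' @param f_min,f_max analysis band (Hz).
#' @param nperseg,nfft Welch parameters.
#' @return A [spectrum_matrix] of the high-quality segments (row ids are
#'   segment indices).
#' @export
hrv_spectrum_matrix <- function(rr, sqi_flags = NULL, window_s = 300,
                                threshold = 0.9, fs = 4,
                                f_min = 0.04, f_max = 0.4,
                                nperseg = 256, nfft = 1024) {
  segs <- segment_and_gate(rr, sqi_flags, window_s = window_s,
                           threshold = threshold)
  segs <- Filter(function(s) s$quality$is_high_quality, segs)
  if (length(segs) == 0) stop("no high-quality segments", call. = FALSE)
  spectra <- lapply(segs, function(s) {
    u <- bandpass_hrv(resample_uniform(s$rr, fs = fs))
    welch_psd(u, nperseg = nperseg, nfft = nfft,
              segment_id = s$quality$segment_index)
  })
  build_spectrum_matrix(spectra, f_min = f_min, f_max = f_max)
}
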