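#' Flag implausible RR intervals
#'
#' Marks intervals that are physiologically too short, too long (gaps from
#' missed beats), or that jump too far from the local median. The input is
#' not modified; flags are returned for [interpolate_outliers()].
#'
#' @param rr an [rr_series].
#' @param min_rr_s lower plausibility bound (s); intervals below are ectopy
#'   or double detections.
#' @param max_rr_s upper bound (s); intervals above indicate missed beats.
#' @param rel_jump maximum tolerated relative deviation from the local
#'   median.
#' @param window odd window length (beats) for the running median.
#' @return Logical vector, one flag per interval.
#' @export
detect_outliers <- function(rr, min_rr_s = 0.3, max_rr_s = 2.0,
                            rel_jump = 0.2, window = 5) {
  stopifnot(inherits(rr, "rr_series"))
  if (nrow(rr) == 0) stop("empty RR series", call. = FALSE)
  x <- rr$rr_s
  if (length(x) >= window) {
    med <- stats::runmed(x, window, endrule = "median")
  } else {
    med <- rep(stats::median(x), length(x))
  }
  flags <- x < min_rr_s | x > max_rr_s
  flags <- flags | (abs(x - med) / med > rel_jump)
  unname(flags)
}

#' Replace flagged intervals by interpolation
#'
#' Flagged intervals are replaced by interpolating the unflagged intervals
#' over beat time: linear by default (no overshoot near gaps), or a natural
#' cubic spline. Flags at the series edges are filled by nearest-unflagged
#' extrapolation. Unflagged values are untouched.
#'
#' @param rr an [rr_series].
#' @param flags logical vector from [detect_outliers()]; defaults to the
#'   series' own `outlier` column.
#' @param method `"linear"` or `"cubic"`.
#' @return A cleaned [rr_series] with all `outlier` flags cleared.
#' @export
interpolate_outliers <- function(rr, flags = rr$outlier,
                                 method = c("linear", "cubic")) {
  stopifnot(inherits(rr, "rr_series"))
  method <- match.arg(method)
  flags <- as.logical(flags)
  if (length(flags) != nrow(rr)) stop("flag length mismatch", call. = FALSE)
  if (!any(flags)) return(rr_series(rr$time_s, rr$rr_s))
  keep <- !flags
  if (sum(keep) < 2) stop("fewer than two clean intervals left", call. = FALSE)
  x <- rr$time_s[keep]
  y <- rr$rr_s[keep]
  new_vals <- rr$rr_s
  if (method == "linear") {
    new_vals[flags] <- stats::approx(x, y, xout = rr$time_s[flags],
                                     method = "linear", rule = 2)$y
  } else {
    f <- stats::splinefun(x, y, method = "natural")
    v <- f(rr$time_s[flags])
    # guard the spline against excursions beyond the clean range
    new_vals[flags] <- pmin(pmax(v, min(y)), max(y))
  }
  rr_series(rr$time_s, new_vals)
}

#' Signal quality index from two beat detectors
#'
#' Greedily matches R-peak annotations from two independent detectors
#' one-to-one within a time tolerance and reports the agreement fraction
#' `SQI = n_matched / (n_a + n_b - n_matched)`, i.e. matched beats over the
#' union of detections. An SQI of 1 means perfect agreement; 0 means no
#' peak pair falls within the tolerance.
#'
#' @param ann_a,ann_b [peak_annotations] from the two detectors.
#' @param tol_s matching tolerance (s), positive.
#' @return A list with `sqi` (scalar in `[0,1]`), `matched_a` and
#'   `matched_b` (per-beat logical match flags).
#' @export
#' @examples
#' a <- peak_annotations(c(100, 350, 600), 250)
#' b <- peak_annotations(c(101, 352, 598), 250)
#' compute_sqi(a, b)$sqi
compute_sqi <- function(ann_a, ann_b, tol_s = 0.15) {
  stopifnot(inherits(ann_a, "peak_annotations"),
            inherits(ann_b, "peak_annotations"))
  if (tol_s <= 0) stop("`tol_s` must be positive", call. = FALSE)
  ta <- ann_a$time_s
  tb <- ann_b$time_s
  na <- length(ta)
  nb <- length(tb)
  if (na == 0 && nb == 0) stop("both annotation lists are empty", call. = FALSE)
  matched_a <- logical(na)
  matched_b <- logical(nb)
  i <- 1L; j <- 1L
  while (i <= na && j <= nb) {
    d <- ta[i] - tb[j]
    if (abs(d) <= tol_s) {
      matched_a[i] <- TRUE
      matched_b[j] <- TRUE
      i <- i + 1L; j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  n_match <- sum(matched_a)
  list(sqi = n_match / (na + nb - n_match),
       matched_a = matched_a, matched_b = matched_b)
}

#' Cut a recording into fixed windows and gate on segment quality
#'
#' Splits the series into consecutive non-overlapping windows by beat time
#' (anchored at the first beat) and computes each window's mean per-beat
#' SQI. Windows whose mean SQI does not exceed the threshold are marked
#' low-quality; they are returned for inspection but should be excluded
#' from spectrum-matrix construction.
#'
#' @param rr an [rr_series].
#' @param sqi_flags per-beat quality indicator: logical match flags or
#'   numeric values in `[0,1]`, one per beat. Defaults to all-good.
#' @param window_s window length (s); 300 s is the conventional short-term
#'   HRV segment.
#' @param threshold mean-SQI threshold a segment must exceed to count as
#'   high quality.
#' @return A list of segments; each has `rr` (the windowed [rr_series]),
#'   `quality` (list with `segment_index`, `mean_sqi`, `is_high_quality`).
#'   Zero-length list (with a warning) if the recording is shorter than one
#'   window.
#' @export
segment_and_gate <- function(rr, sqi_flags = NULL, window_s = 300,
                             threshold = 0.9) {
  stopifnot(inherits(rr, "rr_series"))
  if (window_s <= 0) stop("`window_s` must be positive", call. = FALSE)
  if (is.null(sqi_flags)) sqi_flags <- rep(1, nrow(rr))
  sqi_flags <- as.numeric(sqi_flags)
  if (length(sqi_flags) != nrow(rr)) {
    stop("`sqi_flags` must have one value per beat", call. = FALSE)
  }
  t0 <- rr$time_s[1]
  span <- rr$time_s[nrow(rr)] - t0
  # beats are discrete, so a nominal N-window recording usually ends a few
  # beats short of the last window edge; a trailing shortfall below 2% of
  # the window still counts as a full segment
  n_seg <- floor((span + 0.02 * window_s) / window_s)
  if (n_seg < 1) {
    warning("recording shorter than one window; no segments produced")
    return(list())
  }
  out <- vector("list", n_seg)
  for (k in seq_len(n_seg)) {
    lo <- t0 + (k - 1) * window_s
    hi <- t0 + k * window_s
    idx <- which(rr$time_s >= lo & rr$time_s < hi)
    if (k == 1) idx <- union(1L, idx)   # first beat anchors the first window
    mean_sqi <- mean(sqi_flags[idx])
    out[[k]] <- list(
      rr = rr_series(rr$time_s[idx], rr$rr_s[idx]),
      quality = list(segment_index = k, mean_sqi = mean_sqi,
                     is_high_quality = mean_sqi > threshold))
  }
  out
}

#' Resample a tachogram onto a uniform grid
#'
#' Cubic-spline interpolation of interval value against beat time,
#' evaluated on a uniform grid spanning the recording. 4 Hz is the
#' conventional rate for short-term HRV spectra (Nyquist 2 Hz, well above
#' the 0.4 Hz upper HF edge).
#'
#' @param rr an [rr_series] with at least 4 beats.
#' @param fs target sampling rate (Hz).
#' @return A [uniform_series].
#' @export
resample_uniform <- function(rr, fs = 4) {
  stopifnot(inherits(rr, "rr_series"))
  if (nrow(rr) < 4) stop("need at least 4 beats to resample", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  grid <- seq(rr$time_s[1], rr$time_s[nrow(rr)], by = 1 / fs)
  f <- stats::splinefun(rr$time_s, rr$rr_s, method = "fmm")
  uniform_series(f(grid), grid[1], fs)
}

#' Zero-phase Butterworth band-pass
#'
#' Removes very-low-frequency drift and out-of-band noise with a 4th-order
#' Butterworth band-pass (default 0.03--0.9 Hz) applied forward and
#' backward ([signal::filtfilt]), so LF/HF peak phases are undistorted.
#'
#' @param series a [uniform_series].
#' @param low,high band edges (Hz); `high` must be below Nyquist.
#' @param order filter order passed to [signal::butter].
#' @return The filtered [uniform_series] (same length).
#' @export
bandpass_hrv <- function(series, low = 0.03, high = 0.9, order = 4) {
  stopifnot(inherits(series, "uniform_series"))
  nyq <- series$sampling_rate_hz / 2
  if (high >= nyq) stop("`high` must be below the Nyquist frequency", call. = FALSE)
  if (low <= 0 || low >= high) stop("need 0 < low < high", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  # demean first: the mean lies in the stop band anyway, and removing it
  # up front avoids edge transients leaking DC through filtfilt
  filtered <- signal::filtfilt(bf, series$values - mean(series$values))
  uniform_series(filtered, series$start_time_s, series$sampling_rate_hz)
}
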