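#' Welch power spectral density
#'
#' Averaged modified periodograms: the series is cut into
#' `nperseg`-sample windows with the given overlap, each window is
#' mean-detrended, tapered (Hamming by default), zero-padded to `nfft`,
#' and the one-sided periodograms are averaged with density scaling, so
#' that `sum(power) * df` approximates the variance of the series.
#'
#' With the defaults (4 Hz input, `nperseg = 256`, `nfft = 1024`) the
#' frequency resolution is 1/256 Hz and a 5-minute segment yields about 8
#' averaged windows.
#'
#' @param series a [uniform_series].
#' @param nperseg window length in samples.
#' @param overlap fractional window overlap in `[0, 1)`.
#' @param nfft FFT length (>= `nperseg`); zero-padding interpolates the
#'   spectral grid for narrow LF peaks.
#' @param window taper: `"hamming"` (default) or `"hann"`.
#' @param segment_id identifier stored in the result.
#' @return A [psd_spectrum] with frequencies `0 .. fs/2`.
#' @export
#' @examples
#' u <- uniform_series(sin(2 * pi * 0.25 * seq(0, 300, by = 0.25)), 0, 4)
#' p <- welch_psd(u)
#' p$freqs[which.max(p$power)]
welch_psd <- function(series, nperseg = 256, overlap = 0.5, nfft = 1024,
                      window = c("hamming", "hann"), segment_id = 1L) {
  stopifnot(inherits(series, "uniform_series"))
  window <- match.arg(window)
  x <- series$values
  fs <- series$sampling_rate_hz
  if (length(x) < nperseg) {
    stop("series shorter than `nperseg` (", length(x), " < ", nperseg, ")",
         call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  if (nfft < nperseg) stop("`nfft` must be >= `nperseg`", call. = FALSE)

  w <- switch(window,
              hamming = 0.54 - 0.46 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1)),
              hann = 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1)))
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  scale <- 1 / (fs * sum(w^2))
  n_half <- nfft %/% 2 + 1L

  acc <- numeric(n_half)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, numeric(nfft - nperseg)))
    p <- (Mod(X[seq_len(n_half)])^2) * scale
    # one-sided: double everything except DC and (for even nfft) Nyquist
    dbl <- rep(2, n_half)
    dbl[1] <- 1
    if (nfft %% 2 == 0) dbl[n_half] <- 1
    acc <- acc + p * dbl
  }
  freqs <- (seq_len(n_half) - 1L) * fs / nfft
  psd_spectrum(freqs, acc / length(starts), segment_id = segment_id)
}

#' Stack per-segment PSDs into a spectrum matrix
#'
#' All spectra must share one frequency grid. Columns are restricted to the
#' analysis band (default 0.04--0.4 Hz, the union of the standard LF and HF
#' bands).
#'
#' @param spectra list of [psd_spectrum] objects on identical grids.
#' @param f_min,f_max closed analysis-band limits (Hz).
#' @return A [spectrum_matrix]; `row_ids` carry the segment ids.
#' @export
build_spectrum_matrix <- function(spectra, f_min = 0.04, f_max = 0.4) {
  if (length(spectra) < 1) stop("need at least one spectrum", call. = FALSE)
  ref <- spectra[[1]]$freqs
  for (sp in spectra) {
    if (length(sp$freqs) != length(ref) || any(abs(sp$freqs - ref) > 1e-12)) {
      stop("spectra are not on identical frequency grids", call. = FALSE)
    }
  }
  keep <- which(ref >= f_min - 1e-12 & ref <= f_max + 1e-12)
  if (length(keep) == 0) stop("analysis band contains no bins", call. = FALSE)
  rows <- t(vapply(spectra, function(sp) sp$power[keep], numeric(length(keep))))
  ids <- vapply(spectra, function(sp) sp$segment_id, integer(1))
  spectrum_matrix(rows, ref[keep], row_ids = ids)
}

#' Band power by trapezoidal integration
#'
#' @param spec a [psd_spectrum] (or any list with `freqs` and `power`).
#' @param band a [band_definition] lying within the spectrum's grid.
#' @return Power in the band (s^2).
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(band, "band_definition"))
  f <- spec$freqs
  p <- spec$power
  if (band$f_left < min(f) - 1e-12 || band$f_right > max(f) + 1e-12) {
    stop("band [", band$f_left, ", ", band$f_right,
         "] outside the spectral grid", call. = FALSE)
  }
  idx <- which(f >= band$f_left - 1e-12 & f <= band$f_right + 1e-12)
  if (length(idx) < 2) stop("band contains fewer than two bins", call. = FALSE)
  trapz(f[idx], p[idx])
}

#' LF/HF band metrics
#'
#' @param spec a [psd_spectrum].
#' @param lf,hf [band_definition]s for the two bands.
#' @return List with `lf_power`, `hf_power` (s^2) and `lf_hf_ratio`.
#' @export
lf_hf_metrics <- function(spec, lf = lf_band(), hf = hf_band()) {
  lp <- band_power(spec, lf)
  hp <- band_power(spec, hf)
  list(lf_power = lp, hf_power = hp,
       lf_hf_ratio = if (hp > 0) lp / hp else NA_real_)
}

#' Cumulative singular-value ratio
#'
#' `cumsum(sigma) / sum(sigma)`: the fraction of the nuclear norm captured
#' by the leading singular values. A curve that saturates early diagnoses
#' approximate low rank, the property the completion method exploits.
#'
#' @param S a [spectrum_matrix] or plain matrix.
#' @return Nondecreasing vector in `[0, 1]` ending at 1.
#' @export
cumulative_singular_ratio <- function(S) {
  M <- as_matrix_rows(S)
  if (length(M) == 0) stop("empty matrix", call. = FALSE)
  d <- svd(M, nu = 0, nv = 0)$d
  tot <- sum(d)
  if (tot == 0) stop("zero matrix has no singular-value ratio", call. = FALSE)
  cumsum(d) / tot
}

# trapezoidal rule on an arbitrary grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
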