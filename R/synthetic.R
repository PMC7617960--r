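#' Simulate a tachogram with Mayer-wave and respiratory modulation
#'
#' Generates a beat-interval series whose instantaneous RR interval is a
#' baseline plus two sinusoidal modulations -- one in the LF range
#' (baroreflex / Mayer wave, ~0.1 Hz) and one in the HF range (respiratory
#' sinus arrhythmia, ~0.25 Hz) -- plus white Gaussian jitter:
#' `rr_i = mean_rr + lf_amp sin(2 pi f_lf t) + hf_amp sin(2 pi f_hf t) + e_i`.
#' Beat times accumulate from the generated intervals. Intervals below the
#' physiological floor of 0.2 s are clipped to it so beat times stay
#' strictly increasing without rejection sampling.
#'
#' @param duration_s recording length in seconds, positive.
#' @param mean_rr_s baseline RR interval (s), positive.
#' @param lf_amp,hf_amp modulation amplitudes (s), nonnegative.
#' @param lf_freq_hz,hf_freq_hz modulation frequencies (Hz),
#'   `0 < lf_freq_hz < hf_freq_hz`.
#' @param noise_sd_s standard deviation of additive interval jitter (s).
#' @param seed integer seed; identical seeds give identical series.
#' @return An [rr_series] covering approximately `duration_s` seconds.
#' @export
#' @examples
#' rr <- synth_tachogram(300, seed = 1)
#' head(rr)
synth_tachogram <- function(duration_s = 300, mean_rr_s = 0.8,
                            lf_amp = 0.04, hf_amp = 0.03,
                            lf_freq_hz = 0.1, hf_freq_hz = 0.25,
                            noise_sd_s = 0.01, seed = 1L) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (mean_rr_s <= 0) stop("`mean_rr_s` must be positive", call. = FALSE)
  if (lf_amp < 0 || hf_amp < 0) stop("amplitudes must be nonnegative", call. = FALSE)
  if (lf_freq_hz <= 0 || lf_freq_hz >= hf_freq_hz) {
    stop("need 0 < lf_freq_hz < hf_freq_hz", call. = FALSE)
  }
  if (noise_sd_s < 0) stop("`noise_sd_s` must be nonnegative", call. = FALSE)

  rng <- local_rng(seed)
  n_max <- ceiling(duration_s / 0.2) + 1L   # upper bound on beat count
  noise <- if (noise_sd_s > 0) rng$rnorm(n_max, 0, noise_sd_s) else numeric(n_max)

  t_prev <- 0
  times <- numeric(0)
  intervals <- numeric(0)
  for (i in seq_len(n_max)) {
    rr <- mean_rr_s +
      lf_amp * sin(2 * pi * lf_freq_hz * t_prev) +
      hf_amp * sin(2 * pi * hf_freq_hz * t_prev) +
      noise[i]
    rr <- max(rr, 0.2)
    t_i <- t_prev + rr
    if (t_i > duration_s) break
    times <- c(times, t_i)
    intervals <- c(intervals, rr)
    t_prev <- t_i
  }
  if (length(times) < 2) stop("duration too short for the given mean RR", call. = FALSE)
  rr_series(times, intervals)
}

#' Default Gaussian spectral prototypes
#'
#' A small library of plausible short-term HRV spectral shapes, each the sum
#' of one LF (Mayer wave) and one HF (RSA) Gaussian component. Areas under
#' the components are band powers in ms^2, the conventional HRV reporting
#' unit; typical short-term LF/HF powers of roughly 500--2000 ms^2 are
#' used, with the LF/HF balance and the HF center frequency (breathing
#' rate) varying across prototypes.
#'
#' @param n_prototypes number of prototypes, 1 to 5.
#' @return A list of length `n_prototypes`; each element is a list of
#'   [gaussian_component]s.
#' @export
default_prototypes <- function(n_prototypes = 3) {
  base <- list(
    list(gaussian_component(1600, 0.095, 0.018),   # sympathovagal: LF-dominant
         gaussian_component(800, 0.24, 0.030)),
    list(gaussian_component(700, 0.105, 0.020),    # vagal: HF-dominant, slow breathing
         gaussian_component(1800, 0.21, 0.028)),
    list(gaussian_component(1100, 0.085, 0.016),   # balanced, faster breathing
         gaussian_component(1200, 0.30, 0.035)),
    list(gaussian_component(2000, 0.12, 0.022),    # high LF, mid HF
         gaussian_component(600, 0.26, 0.026)),
    list(gaussian_component(500, 0.09, 0.015),     # low power overall
         gaussian_component(900, 0.33, 0.040))
  )
  if (n_prototypes < 1 || n_prototypes > length(base)) {
    stop("`n_prototypes` must be between 1 and ", length(base), call. = FALSE)
  }
  base[seq_len(n_prototypes)]
}

#' Simulate an approximately low-rank spectrum matrix
#'
#' Each row is a convex combination (symmetric Dirichlet weights) of a small
#' number of prototype spectra, each prototype a sum of Gaussian components
#' evaluated on the frequency grid, plus optional additive noise. With zero
#' additive noise the matrix rank is bounded by the number of prototypes,
#' which is the structural premise the completion method relies on.
#'
#' @param n_rows number of segments (rows).
#' @param prototypes list of component lists as from [default_prototypes()];
#'   its length is the number of prototypes.
#' @param freq_grid frequency bin centers (Hz), strictly increasing,
#'   nonnegative. Default 0--1 Hz in steps of 1/256 Hz, matching the Welch
#'   grid of [welch_psd()] at 4 Hz sampling with `nfft = 1024`.
#' @param dirichlet_alpha concentration of the per-row mixing weights;
#'   `alpha = 1` (default) is uniform on the simplex, small values give
#'   nearly prototype-pure rows.
#' @param mixing_noise_sd standard deviation of jitter applied to the mixing
#'   weights before renormalisation (keeps rows in the prototype span).
#' @param additive_noise_sd standard deviation of entry-wise additive noise
#'   (power-density units); rows are clipped at zero afterwards.
#' @param seed integer seed.
#' @return A list with elements `matrix` (a [spectrum_matrix]) and `weights`
#'   (the `n_rows` x `n_prototypes` mixing matrix, for ground-truth rank
#'   checks).
#' @export
#' @examples
#' sim <- synth_spectrum_matrix(12, default_prototypes(2), seed = 7)
#' sim$matrix
synth_spectrum_matrix <- function(n_rows = 60,
                                  prototypes = default_prototypes(3),
                                  freq_grid = seq(0, 1, by = 1 / 256),
                                  dirichlet_alpha = 1,
                                  mixing_noise_sd = 0,
                                  additive_noise_sd = 0,
                                  seed = 1L) {
  if (length(freq_grid) == 0) stop("`freq_grid` must be non-empty", call. = FALSE)
  if (any(diff(freq_grid) <= 0) || any(freq_grid < 0)) {
    stop("`freq_grid` must be strictly increasing and nonnegative", call. = FALSE)
  }
  n_proto <- length(prototypes)
  if (n_proto < 1) stop("need at least one prototype", call. = FALSE)
  if (n_proto > n_rows) stop("more prototypes than rows", call. = FALSE)
  if (mixing_noise_sd < 0 || additive_noise_sd < 0) {
    stop("noise standard deviations must be nonnegative", call. = FALSE)
  }

  rng <- local_rng(seed)
  proto_mat <- t(vapply(prototypes, function(comps) {
    rowSums(vapply(comps, function(cp) gaussian_eval(cp, freq_grid),
                   numeric(length(freq_grid))))
  }, numeric(length(freq_grid))))            # n_proto x n_freq

  # symmetric Dirichlet(alpha) via normalised gammas
  W <- matrix(rng$rgamma(n_rows * n_proto, shape = dirichlet_alpha, rate = 1),
              nrow = n_rows)
  if (mixing_noise_sd > 0) {
    W <- pmax(W + matrix(rng$rnorm(length(W), 0, mixing_noise_sd), nrow = n_rows), 0)
  }
  rs <- rowSums(W)
  rs[rs == 0] <- 1
  W <- W / rs

  M <- W %*% proto_mat
  if (additive_noise_sd > 0) {
    M <- M + matrix(rng$rnorm(length(M), 0, additive_noise_sd), nrow = n_rows)
  }
  M <- pmax(M, 0)
  list(matrix = spectrum_matrix(M, freq_grid), weights = W)
}

# Self-contained RNG stream: seeds a private .Random.seed and restores the
# caller's state on exit, so generators never disturb global randomness.
local_rng <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  env <- new.env()
  run <- function(expr_fun, ...) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    if (is.null(env$state)) {
      set.seed(seed)
    } else {
      assign(".Random.seed", env$state, envir = globalenv())
    }
    out <- expr_fun(...)
    env$state <- get(".Random.seed", globalenv())
    out
  }
  list(
    rnorm = function(n, mean = 0, sd = 1) run(stats::rnorm, n, mean, sd),
    rgamma = function(n, shape, rate = 1) run(stats::rgamma, n, shape, rate = rate),
    runif = function(n, min = 0, max = 1) run(stats::runif, n, min, max),
    sample = function(x, size) run(sample, x, size)
  )
}
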