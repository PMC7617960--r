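#' Gaussian spectral component
#'
#' One Gaussian lobe of an HRV spectrum model:
#' `A / (sqrt(2 pi) sigma) * exp(-(f - f0)^2 / (2 sigma^2))`,
#' so `A` is the area under the component (the band power, in the
#' spectrum's power units), `f0` its center frequency and `sigma` its
#' width, both in Hz.
#'
#' @param amplitude_weight area under the component (power units), positive.
#' @param center peak frequency f0 (Hz), positive.
#' @param width standard deviation sigma (Hz), positive.
#' @return An object of class `gaussian_component`.
#' @export
#' @examples
#' g <- gaussian_component(1, 0.25, 0.03)
#' gaussian_eval(g, 0.25)          # peak value A / (sqrt(2 pi) sigma)
gaussian_component <- function(amplitude_weight, center, width) {
  if (amplitude_weight <= 0) stop("`amplitude_weight` must be positive", call. = FALSE)
  if (center <= 0) stop("`center` must be positive", call. = FALSE)
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  structure(list(A = as.numeric(amplitude_weight),
                 f0 = as.numeric(center),
                 sigma = as.numeric(width)),
            class = "gaussian_component")
}

#' Evaluate a Gaussian component
#'
#' @param comp a [gaussian_component].
#' @param f frequencies (Hz) at which to evaluate.
#' @return Power density values (strictly positive).
#' @export
gaussian_eval <- function(comp, f) {
  stopifnot(inherits(comp, "gaussian_component"))
  comp$A / (sqrt(2 * pi) * comp$sigma) *
    exp(-(f - comp$f0)^2 / (2 * comp$sigma^2))
}

#' Multi-component spectrum model
#'
#' @param components list of [gaussian_component]s, each optionally tagged
#'   with a `band` attribute naming the band it was fitted in.
#' @param freqs the frequency grid the model is associated with.
#' @return An object of class `spectrum_model`.
#' @export
spectrum_model <- function(components, freqs = NULL) {
  if (length(components) < 1) stop("model needs at least one component", call. = FALSE)
  for (cp in components) stopifnot(inherits(cp, "gaussian_component"))
  structure(list(components = components, freqs = freqs),
            class = "spectrum_model")
}

#' Evaluate a spectrum model on a grid
#'
#' Sum of all components' [gaussian_eval()] values; strictly positive
#' everywhere.
#'
#' @param model a [spectrum_model].
#' @param freqs frequencies (Hz), increasing.
#' @return Numeric vector of modelled power densities.
#' @export
eval_model <- function(model, freqs) {
  stopifnot(inherits(model, "spectrum_model"))
  if (length(freqs) == 0) return(numeric(0))
  out <- numeric(length(freqs))
  for (cp in model$components) out <- out + gaussian_eval(cp, freqs)
  out
}

#' Fit Gaussian components to one band of a spectrum
#'
#' Bounded Levenberg-Marquardt least squares ([minpack.lm::nlsLM]) of
#' `n_components` Gaussians to the band-restricted spectrum. Bins with `NA`
#' power (masked/unknown) are ignored. Initialisation is deterministic:
#' centers at the band's largest local maxima, area at the trapezoidal band
#' power split evenly, width at a sixth of the band width. Bounds keep the
#' center inside the band, the width between one grid step and the band
#' width, and the area positive and below ten times the band power, which
#' prevents degenerate spike fits.
#'
#' @param power spectrum values on `freqs` (may contain `NA`).
#' @param freqs frequency grid (Hz).
#' @param band a [band_definition] containing at least 5 usable grid points.
#' @param n_components 1 (default) to 3 Gaussians.
#' @return List of fitted [gaussian_component]s (tagged with the band name)
#'   with attributes `residual_norm` and `converged`.
#' @export
fit_band_model <- function(power, freqs, band, n_components = 1) {
  stopifnot(inherits(band, "band_definition"))
  if (n_components < 1 || n_components > 3) {
    stop("`n_components` must be 1, 2 or 3", call. = FALSE)
  }
  idx <- which(freqs >= band$f_left - 1e-12 & freqs <= band$f_right + 1e-12 &
                 !is.na(power))
  if (length(idx) < 5) {
    stop("band '", band$name, "' has fewer than 5 usable grid points",
         call. = FALSE)
  }
  f <- freqs[idx]
  y <- power[idx]
  if (any(y < 0)) stop("spectrum must be nonnegative on the band", call. = FALSE)
  bp <- trapz(f, y)
  if (max(y) <= 0 || bp <= 0) {
    cond <- simpleError(paste0("zero spectrum on band '", band$name,
                               "': nothing to fit"))
    class(cond) <- c("hrvrmc_fit_failure", class(cond))
    stop(cond)
  }

  df <- min(diff(freqs))
  width0 <- (band$f_right - band$f_left) / 6
  centers0 <- init_centers(f, y, n_components)
  start <- list()
  lower <- c()
  upper <- c()
  for (m in seq_len(n_components)) {
    start[[paste0("A", m)]] <- max(bp / n_components, 1e-12)
    start[[paste0("f", m)]] <- centers0[m]
    start[[paste0("s", m)]] <- width0
    lower <- c(lower, 1e-12, band$f_left, df)
    upper <- c(upper, 10 * bp, band$f_right, band$f_right - band$f_left)
  }

  form <- stats::as.formula(paste(
    "y ~", paste(sprintf("A%d/(sqrt(2*pi)*s%d)*exp(-(f - f%d)^2/(2*s%d^2))",
                         seq_len(n_components), seq_len(n_components),
                         seq_len(n_components), seq_len(n_components)),
                 collapse = " + ")))

  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(f = f, y = y),
                      start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    cond <- simpleError(paste0("Gaussian fit failed on band '", band$name,
                               "': ", conditionMessage(fit)))
    class(cond) <- c("hrvrmc_fit_failure", class(cond))
    stop(cond)
  }

  cf <- stats::coef(fit)
  comps <- lapply(seq_len(n_components), function(m) {
    cp <- gaussian_component(cf[[paste0("A", m)]], cf[[paste0("f", m)]],
                             cf[[paste0("s", m)]])
    attr(cp, "band") <- band$name
    cp
  })
  attr(comps, "residual_norm") <- sqrt(sum(stats::resid(fit)^2))
  attr(comps, "converged") <- fit$convInfo$isConv %||% TRUE
  comps
}

#' Model a spectrum band by band
#'
#' Fits each band independently with [fit_band_model()] and concatenates
#' the components into one [spectrum_model] evaluable on the full grid.
#' Bands with too few usable bins or a failed fit are skipped with a
#' warning when `require_all = FALSE` (the behaviour the refined-completion
#' pipeline relies on when an entire band of the target row is masked); an
#' error tagged with the band name is raised if no band can be fitted, or
#' if any band fails while `require_all = TRUE`.
#'
#' @param power spectrum values on `freqs` (may contain `NA` for unknown
#'   bins).
#' @param freqs frequency grid (Hz).
#' @param bands list of disjoint [band_definition]s.
#' @param n_components Gaussians per band.
#' @param require_all error on any band failure instead of skipping.
#' @param quiet suppress the skipped-band warning (used by callers for
#'   which a fully masked band is the expected situation).
#' @return A [spectrum_model].
#' @export
model_spectrum <- function(power, freqs, bands = list(lf_band(), hf_band()),
                           n_components = 1, require_all = FALSE,
                           quiet = FALSE) {
  if (length(bands) < 1) stop("need at least one band", call. = FALSE)
  check_disjoint(bands)
  comps <- list()
  failures <- character(0)
  for (b in bands) {
    res <- tryCatch(fit_band_model(power, freqs, b, n_components),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (require_all) stop(res)
      failures <- c(failures, b$name)
    } else {
      comps <- c(comps, res)
    }
  }
  if (length(comps) == 0) {
    cond <- simpleError(paste0("no band could be modelled (",
                               paste(failures, collapse = ", "), ")"))
    class(cond) <- c("hrvrmc_fit_failure", class(cond))
    stop(cond)
  }
  if (length(failures) > 0 && !quiet) {
    warning("band(s) skipped in spectrum model: ",
            paste(failures, collapse = ", "))
  }
  spectrum_model(comps, freqs)
}

#' Serialize model parameters to a data frame
#'
#' @param model a [spectrum_model].
#' @return Data frame with columns `band`, `A`, `f0`, `sigma`, suitable for
#'   writing as delimited text.
#' @export
model_parameters <- function(model) {
  stopifnot(inherits(model, "spectrum_model"))
  do.call(rbind, lapply(model$components, function(cp) {
    data.frame(band = attr(cp, "band") %||% NA_character_,
               A = cp$A, f0 = cp$f0, sigma = cp$sigma)
  }))
}

# centers for multi-start: highest local maxima, fall back to spread
init_centers <- function(f, y, n) {
  if (n == 1) return(f[which.max(y)])
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  is_max <- is_max[order(y[is_max], decreasing = TRUE)]
  centers <- f[is_max]
  if (length(centers) < n) {
    extra <- stats::quantile(f, probs = seq(0.2, 0.8, length.out = n))
    centers <- c(centers, extra)
  }
  centers[seq_len(n)]
}

check_disjoint <- function(bands) {
  if (length(bands) < 2) return(invisible(TRUE))
  iv <- t(vapply(bands, function(b) c(b$f_left, b$f_right), numeric(2)))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-12)) {
    stop("bands must be disjoint", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
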