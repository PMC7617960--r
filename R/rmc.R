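#' Observation mask
#'
#' @param known logical matrix, `TRUE` where the entry is observed; must
#'   contain at least one known entry.
#' @return An object of class `observation_mask`.
#' @export
observation_mask <- function(known) {
  known <- as.matrix(known)
  if (is.numeric(known)) known <- known != 0
  if (!is.logical(known) || any(is.na(known))) {
    stop("`known` must be a logical matrix without NA", call. = FALSE)
  }
  if (!any(known)) stop("mask has no known entries", call. = FALSE)
  structure(list(known = known), class = "observation_mask")
}

#' @export
print.observation_mask <- function(x, ...) {
  cat(sprintf("<observation_mask> %dx%d, %d unknown entries\n",
              nrow(x$known), ncol(x$known), sum(!x$known)))
  invisible(x)
}

#' Hide part of one spectrum row to emulate measurement uncertainty
#'
#' Masks a fraction of the target row's bins, either as a contiguous block
#' centred on a frequency band (the typical situation: respiration-band
#' artefacts corrupt the HF region while the LF region stays usable) or as
#' a seeded uniform random sample. All other entries stay known.
#'
#' @param S a [spectrum_matrix] or plain matrix.
#' @param target_row row index to mask.
#' @param ratio fraction of the row's bins to hide, in (0, 1).
#' @param pattern `"band"` (contiguous, centred on `band`) or `"random"`.
#' @param band a [band_definition] for the band pattern; needs the
#'   spectrum's frequency grid, so `S` must be a [spectrum_matrix] (or
#'   `freqs` supplied).
#' @param seed integer seed for the random pattern.
#' @param freqs optional frequency grid when `S` is a plain matrix.
#' @return An [observation_mask] whose unknown entries are confined to
#'   `target_row`.
#' @export
#' @examples
#' sim <- synth_spectrum_matrix(8, default_prototypes(2), seed = 2)
#' S <- restrict_matrix(sim$matrix)
#' apply_mask(S, 3, 0.3, pattern = "band")
apply_mask <- function(S, target_row, ratio, pattern = c("band", "random"),
                       band = hf_band(), seed = 1L, freqs = NULL) {
  pattern <- match.arg(pattern)
  M <- as_matrix_rows(S)
  if (is.null(freqs) && inherits(S, "spectrum_matrix")) freqs <- S$freqs
  n_fr <- ncol(M)
  if (target_row < 1 || target_row > nrow(M)) {
    stop("`target_row` out of range", call. = FALSE)
  }
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)", call. = FALSE)
  n_hide <- round(ratio * n_fr)
  if (n_hide < 1 || n_hide >= n_fr) {
    stop("masking ratio hides none or all bins of the row", call. = FALSE)
  }

  if (pattern == "band") {
    if (is.null(freqs)) stop("band masking needs the frequency grid", call. = FALSE)
    in_band <- which(freqs >= band$f_left - 1e-12 & freqs <= band$f_right + 1e-12)
    if (length(in_band) == 0) stop("band outside the spectral grid", call. = FALSE)
    center <- in_band[ceiling(length(in_band) / 2)]
    # contiguous block of n_hide bins centred on the band, shifted inside
    start <- center - (n_hide - 1L) %/% 2L
    start <- max(1L, min(start, n_fr - n_hide + 1L))
    hide <- seq(start, length.out = n_hide)
  } else {
    hide <- sort(local_rng(seed)$sample(n_fr, n_hide))
  }
  known <- matrix(TRUE, nrow(M), n_fr)
  known[target_row, hide] <- FALSE
  observation_mask(known)
}

#' Restrict a spectrum matrix to the analysis band
#'
#' Convenience wrapper keeping columns within `[f_min, f_max]` (default
#' the LF+HF analysis range).
#'
#' @param S a [spectrum_matrix].
#' @param f_min,f_max band limits (Hz).
#' @return A [spectrum_matrix].
#' @export
restrict_matrix <- function(S, f_min = 0.04, f_max = 0.4) {
  stopifnot(inherits(S, "spectrum_matrix"))
  keep <- which(S$freqs >= f_min - 1e-12 & S$freqs <= f_max + 1e-12)
  if (length(keep) == 0) stop("no bins in the requested band", call. = FALSE)
  spectrum_matrix(S$rows[, keep, drop = FALSE], S$freqs[keep], S$row_ids)
}

#' Correlation between two modelled spectra on the known bins
#'
#' Pearson correlation of the two models evaluated at the known bin
#' indices. When a whole band of the target row is masked, the opposite
#' band dominates the correlation, which is exactly the mechanism that
#' lets the usable LF region choose donor segments for an HF estimate.
#'
#' @param model_j,model_q [spectrum_model]s.
#' @param freqs shared frequency grid (Hz).
#' @param known_idx indices of the known bins (at least 3).
#' @return Correlation in `[-1, 1]`.
#' @export
modeled_correlation <- function(model_j, model_q, freqs, known_idx) {
  if (length(known_idx) < 3) stop("need at least 3 known bins", call. = FALSE)
  a <- eval_model(model_j, freqs)[known_idx]
  b <- eval_model(model_q, freqs)[known_idx]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance on the known bins; correlation undefined", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Select the K most correlated candidate rows
#'
#' @param correlations named or plain numeric vector of correlations for
#'   the candidate rows (the target row must not be among them).
#' @param K number of rows to select, `1 <= K <= length(correlations)`.
#' @return Integer positions of the K largest correlations in descending
#'   order; ties break toward the smaller position.
#' @export
select_top_k <- function(correlations, K) {
  n <- length(correlations)
  if (K < 1 || K > n) stop("`K` must be between 1 and ", n, call. = FALSE)
  ord <- order(-correlations, seq_len(n), method = "radix")
  ord[seq_len(K)]
}

#' Assemble the refined matrix for a target row
#'
#' Stacks the target row first, followed by the selected donor rows in
#' descending-correlation order, and restricts the observation mask
#' accordingly (only the target row has unknown bins).
#'
#' @param S full matrix ([spectrum_matrix] or plain).
#' @param mask full [observation_mask].
#' @param target_row target row index.
#' @param selected donor row indices (in the full matrix), already ordered
#'   by descending correlation.
#' @return List with `S_ref` (matrix), `mask_ref` ([observation_mask]) and
#'   `row_map` (original row index of every refined row).
#' @export
build_refined_matrix <- function(S, mask, target_row, selected) {
  M <- as_matrix_rows(S)
  known <- as_mask(mask, dim(M))
  if (target_row %in% selected) stop("target row cannot be its own donor", call. = FALSE)
  if (any(selected < 1 | selected > nrow(M))) stop("donor index out of range", call. = FALSE)
  rows <- c(target_row, selected)
  list(S_ref = M[rows, , drop = FALSE],
       mask_ref = observation_mask(known[rows, , drop = FALSE]),
       row_map = rows)
}

#' Refined matrix completion of one spectrum row
#'
#' The refinement pipeline: (1) fit per-band Gaussian models to every row
#' on its known bins; (2) correlate the target row's model with every other
#' row's model on the target's known bins; (3) keep the K best-correlated
#' donor rows; (4) run the nuclear-norm-bisection completion on the small
#' refined matrix; (5) return the completed target row, with its observed
#' bins restored exactly. If the target row's model cannot be fitted at
#' all, correlations fall back to the raw known-bin values with a warning.
#'
#' @param S full data matrix ([spectrum_matrix] or plain matrix); observed
#'   entries are read through the mask.
#' @param mask [observation_mask]; unknown entries must be confined to the
#'   target row.
#' @param target_row index of the row to estimate.
#' @param K number of donor segments (default 9).
#' @param bands list of [band_definition]s for the Gaussian modelling.
#' @param cfg a [completion_config].
#' @param n_components Gaussians per band.
#' @param freqs frequency grid when `S` is a plain matrix.
#' @return List with `estimate` (the full target row), `result` (the
#'   [complete_matrix()] output for the refined matrix), `selection` (list:
#'   `target_row`, `correlations`, `selected`, `K`).
#' @export
rmc_estimate <- function(S, mask, target_row, K = 9,
                         bands = list(lf_band(), hf_band()),
                         cfg = completion_config(), n_components = 1,
                         freqs = NULL) {
  M <- as_matrix_rows(S)
  if (is.null(freqs) && inherits(S, "spectrum_matrix")) freqs <- S$freqs
  if (is.null(freqs)) stop("need the frequency grid (`freqs`)", call. = FALSE)
  known <- as_mask(mask, dim(M))
  n_r <- nrow(M)
  if (K < 1 || K > n_r - 1) stop("`K` must be in [1, n_rows - 1]", call. = FALSE)
  hidden <- !known[target_row, ]
  if (!any(hidden)) stop("target row has no hidden bins", call. = FALSE)
  if (any(!known[-target_row, ])) {
    stop("all rows other than the target must be fully known", call. = FALSE)
  }
  known_idx <- which(!hidden)

  obs <- M
  obs[!known] <- NA_real_

  target_model <- tryCatch(
    model_spectrum(obs[target_row, ], freqs, bands, n_components,
                   quiet = TRUE),
    error = function(e) e)

  candidates <- setdiff(seq_len(n_r), target_row)
  if (inherits(target_model, "error")) {
    warning("target-row model fit failed (",
            conditionMessage(target_model),
            "); falling back to raw known-bin correlation")
    tgt <- obs[target_row, known_idx]
    gam <- vapply(candidates, function(q) {
      stats::cor(tgt, M[q, known_idx])
    }, numeric(1))
  } else {
    gam <- vapply(candidates, function(q) {
      mq <- tryCatch(model_spectrum(M[q, ], freqs, bands, n_components,
                                    quiet = TRUE),
                     error = function(e) NULL)
      if (is.null(mq)) {
        # unfittable donor: correlate raw values instead
        stats::cor(obs[target_row, known_idx], M[q, known_idx])
      } else {
        modeled_correlation(target_model, mq, freqs, known_idx)
      }
    }, numeric(1))
  }
  gam[is.na(gam)] <- -Inf

  sel_pos <- select_top_k(gam, K)
  selected <- candidates[sel_pos]

  refined <- build_refined_matrix(M, known, target_row, selected)
  fit <- complete_matrix(refined$S_ref, refined$mask_ref, cfg)

  est <- fit$X[1, ]
  est[known_idx] <- M[target_row, known_idx]   # observed bins are exact

  list(estimate = est, result = fit,
       selection = list(target_row = target_row,
                        correlations = stats::setNames(gam, candidates),
                        selected = selected, K = K))
}

#' Normalised root-mean-square error on the hidden bins
#'
#' RMSE over the hidden bins divided by the sample standard deviation
#' (denominator `N_f - 1`) of the true hidden values, so errors are
#' comparable across recordings with different absolute power.
#'
#' @param estimate estimated row.
#' @param truth true row.
#' @param hidden_idx indices of the hidden bins (at least 2).
#' @return Nonnegative scalar.
#' @export
#' @examples
#' nrmse(c(1, 2, 4), c(1, 2, 3), 1:3)   # sqrt(1/3) / 1
nrmse <- function(estimate, truth, hidden_idx) {
  if (length(hidden_idx) < 2) stop("need at least 2 hidden bins", call. = FALSE)
  e <- estimate[hidden_idx]
  t <- truth[hidden_idx]
  s <- stats::sd(t)
  if (s == 0) stop("true hidden bins have zero variance; NRMSE undefined", call. = FALSE)
  sqrt(mean((e - t)^2)) / s
}

#' Sweep the donor count K
#'
#' Runs [rmc_estimate()] for every K in `K_range` against the mask and
#' reports the NRMSE on the hidden bins (the unmasked `S` supplies the
#' ground truth, as in a masking experiment). Per-K failures are recorded
#' as `NA` and the sweep continues.
#'
#' @inheritParams rmc_estimate
#' @param K_range integer vector of donor counts within `[1, n_rows - 1]`.
#' @return List with `table` (data frame `K`, `nrmse`) and `best_k` (the
#'   argmin K).
#' @export
sweep_k <- function(S, mask, target_row, K_range,
                    bands = list(lf_band(), hf_band()),
                    cfg = completion_config(), freqs = NULL) {
  M <- as_matrix_rows(S)
  if (is.null(freqs) && inherits(S, "spectrum_matrix")) freqs <- S$freqs
  known <- as_mask(mask, dim(M))
  hidden_idx <- which(!known[target_row, ])
  errs <- vapply(K_range, function(K) {
    r <- tryCatch(
      rmc_estimate(M, known, target_row, K = K, bands = bands, cfg = cfg,
                   freqs = freqs),
      error = function(e) NULL)
    if (is.null(r)) NA_real_
    else nrmse(r$estimate, M[target_row, ], hidden_idx)
  }, numeric(1))
  tab <- data.frame(K = K_range, nrmse = errs)
  best <- if (all(is.na(errs))) NA_integer_ else K_range[which.min(errs)]
  list(table = tab, best_k = best)
}

#' Benchmark completion methods under masking
#'
#' Cross-product evaluation of methods x mask specifications x seeds on one
#' ground-truth matrix, in the style of a masking experiment: each spec
#' hides part of one row, each method estimates it, and the NRMSE on the
#' hidden bins is recorded. Failures leave an `NA` cell rather than
#' aborting the sweep.
#'
#' @param S ground-truth [spectrum_matrix] (or plain matrix with `freqs`).
#' @param mask_specs list of lists with fields `target_row`, `ratio`,
#'   `pattern` (`"band"`/`"random"`), optional `band`.
#' @param methods subset of `c("mc", "izma_full", "rmc")`: SVT baseline on
#'   the full matrix, nuclear-bisection completion on the full matrix, and
#'   the refined method.
#' @param seeds integer vector; seeds the random mask pattern (band masks
#'   are deterministic, so seeds then only label replicates).
#' @param K donor count for the refined method.
#' @param cfg a [completion_config].
#' @param freqs frequency grid for plain-matrix input.
#' @return List with `runs` (data frame: method, pattern, ratio, K, seed,
#'   nrmse) and `summary` (mean and SD of NRMSE per method x ratio).
#' @export
benchmark_methods <- function(S, mask_specs, methods = c("mc", "izma_full", "rmc"),
                              seeds = 1L, K = 9, cfg = completion_config(),
                              freqs = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  M <- as_matrix_rows(S)
  if (is.null(freqs) && inherits(S, "spectrum_matrix")) freqs <- S$freqs
  if (length(mask_specs) < 1 || length(seeds) < 1) {
    stop("need at least one mask spec and one seed", call. = FALSE)
  }
  rows <- list()
  for (spec in mask_specs) {
    for (seed in seeds) {
      mk <- apply_mask(M, spec$target_row, spec$ratio,
                       pattern = spec$pattern %||% "band",
                       band = spec$band %||% hf_band(),
                       seed = seed, freqs = freqs)
      hidden_idx <- which(!mk$known[spec$target_row, ])
      for (m in methods) {
        err <- tryCatch({
          est <- switch(m,
            mc = svt_complete(M, mk)$X[spec$target_row, ],
            izma_full = complete_matrix(M, mk, cfg)$X[spec$target_row, ],
            rmc = rmc_estimate(M, mk, spec$target_row, K = K, cfg = cfg,
                               freqs = freqs)$estimate)
          nrmse(est, M[spec$target_row, ], hidden_idx)
        }, error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, pattern = spec$pattern %||% "band",
          ratio = spec$ratio, K = if (m == "rmc") K else NA_integer_,
          seed = seed, nrmse = err)
      }
    }
  }
  runs <- do.call(rbind, rows)
  summary <- stats::aggregate(nrmse ~ method + ratio, data = runs,
                              FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                                  sd = stats::sd(v)))
  summary <- do.call(data.frame, summary)
  names(summary) <- c("method", "ratio", "mean_nrmse", "sd_nrmse")
  list(runs = runs, summary = summary)
}
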