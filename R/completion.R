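#' Observation-restriction operator
#'
#' Keeps a matrix's entries on the observed set and zeroes the rest. The
#' data-fidelity term of the constrained approximation is
#' `eps(X) = || P(X) - P(H) ||_F` with this operator, so it only compares
#' matrices on the known entries.
#'
#' @param X numeric matrix.
#' @param mask logical matrix of the same shape, `TRUE` where observed.
#' @return Matrix equal to `X` on the mask and 0 elsewhere.
#' @export
project_observed <- function(X, mask) {
  X <- as_matrix_rows(X)
  mask <- as_mask(mask, dim(X))
  X * mask
}

#' Spectral-norm clipping
#'
#' Exact solution of `min ||X - H||_F s.t. ||X||_2 <= lam`: take the SVD of
#' `H` and clip every singular value at `lam`.
#'
#' @param H numeric matrix with finite entries.
#' @param lam nonnegative spectral bound.
#' @return The clipped matrix; its spectral norm is at most `lam`.
#' @export
clip_spectral <- function(H, lam) {
  H <- as_matrix_rows(H)
  if (lam < 0) stop("`lam` must be nonnegative", call. = FALSE)
  if (any(!is.finite(H))) stop("matrix has non-finite entries", call. = FALSE)
  if (lam == 0) return(matrix(0, nrow(H), ncol(H)))
  s <- svd(H)
  if (s$d[1] <= lam) return(H)
  s$u %*% (pmin(s$d, lam) * t(s$v))
}

#' Projection onto the nuclear-norm ball
#'
#' Exact solution of `min ||X - H||_F s.t. ||X||_* <= lam`: soft-threshold
#' the singular values by the unique theta for which the thresholded values
#' sum to `lam` (the simplex-projection construction). This is the "soft
#' imputing" constraint the completion driver bisects over; unlike the
#' spectral clip it strictly shrinks rank, which is what makes hidden-entry
#' recovery possible.
#'
#' @param H numeric matrix with finite entries.
#' @param lam nonnegative nuclear-norm bound.
#' @return Matrix with nuclear norm at most `lam`.
#' @export
project_nuclear <- function(H, lam) {
  H <- as_matrix_rows(H)
  if (lam < 0) stop("`lam` must be nonnegative", call. = FALSE)
  if (any(!is.finite(H))) stop("matrix has non-finite entries", call. = FALSE)
  if (lam == 0) return(matrix(0, nrow(H), ncol(H)))
  s <- svd(H)
  d <- s$d
  if (sum(d) <= lam) return(H)
  css <- cumsum(d)
  k <- max(which(d - (css - lam) / seq_along(d) > 0))
  theta <- (css[k] - lam) / k
  s$u %*% (pmax(d - theta, 0) * t(s$v))
}

#' Known-entry restoration step
#'
#' Overwrites the observed entries of the current estimate with the data's
#' values and leaves estimated (unknown) entries untouched:
#' `X_tilde - P(X_tilde) + P(H)`.
#'
#' @param X_tilde current estimate.
#' @param mask logical observation mask.
#' @param H data matrix supplying the known entries.
#' @return Updated matrix.
#' @export
izma_update <- function(X_tilde, mask, H) {
  X_tilde <- as_matrix_rows(X_tilde)
  H <- as_matrix_rows(H)
  if (!all(dim(X_tilde) == dim(H))) stop("shape mismatch", call. = FALSE)
  mask <- as_mask(mask, dim(H))
  X_tilde[mask] <- H[mask]
  X_tilde
}

#' Configuration for the constrained completion
#'
#' `e_tol` and `lambda_tol` default to 1e-8 and 10, the reference settings
#' of the interest-zone approximation literature. `lambda_tol` is an
#' absolute tolerance in nuclear-norm units; `lambda_rtol` adds a relative
#' guard (effective tolerance `min(lambda_tol, lambda_rtol * ||S_obs||_*)`)
#' so that matrices whose nuclear norm is not large compared to 10 still
#' resolve the feasibility boundary.
#'
#' @param e_tol Frobenius tolerance on the known-entry residual.
#' @param lambda_tol absolute tolerance on the bisection interval.
#' @param lambda_rtol relative interval tolerance (fraction of the observed
#'   matrix's nuclear norm).
#' @param inner_tol stopping tolerance on the change of the residual within
#'   the fixed-point iteration.
#' @param inner_max_iter iteration cap of the fixed-point loop.
#' @param outer_max_iter cap on bisection steps (safety net).
#' @return A list of class `completion_config`.
#' @export
completion_config <- function(e_tol = 1e-8, lambda_tol = 10,
                              lambda_rtol = 1e-4, inner_tol = 1e-10,
                              inner_max_iter = 1000, outer_max_iter = 200) {
  vals <- c(e_tol, lambda_tol, lambda_rtol, inner_tol,
            inner_max_iter, outer_max_iter)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all configuration values must be positive", call. = FALSE)
  }
  structure(list(e_tol = e_tol, lambda_tol = lambda_tol,
                 lambda_rtol = lambda_rtol, inner_tol = inner_tol,
                 inner_max_iter = as.integer(inner_max_iter),
                 outer_max_iter = as.integer(outer_max_iter)),
            class = "completion_config")
}

#' Constrained fixed-point approximation at a fixed norm bound
#'
#' Alternates projection onto the norm ball (nuclear by default, spectral
#' clipping optionally) with restoration of the known entries, starting
#' from the mask-filled matrix (unknown entries 0) or a supplied warm
#' start. Stops when the known-entry residual `eps` changes by less than
#' `inner_tol` or the iteration budget is reached. `eps` is nonincreasing
#' across iterations up to numerical tolerance.
#'
#' @param H data matrix (values outside the mask are ignored).
#' @param mask logical observation mask.
#' @param lam norm bound.
#' @param cfg a [completion_config].
#' @param constraint `"nuclear"` (default) or `"spectral"`.
#' @param X0 optional warm-start matrix.
#' @return List with `X` (the last ball-projected estimate, which satisfies
#'   the norm constraint), `epsilon`, `epsilon_history`, `iterations`,
#'   `converged`.
#' @export
izma_iterate <- function(H, mask, lam, cfg = completion_config(),
                         constraint = c("nuclear", "spectral"), X0 = NULL) {
  H <- as_matrix_rows(H)
  mask <- as_mask(mask, dim(H))
  constraint <- match.arg(constraint)
  proj <- if (constraint == "nuclear") project_nuclear else clip_spectral
  stopifnot(inherits(cfg, "completion_config"))

  if (is.null(X0)) {
    X <- H * mask
  } else {
    X <- as_matrix_rows(X0)
    if (!all(dim(X) == dim(H))) stop("warm start shape mismatch", call. = FALSE)
    X[mask] <- H[mask]
  }
  eps_prev <- Inf
  eps <- Inf
  Xt <- X
  k <- 0L
  converged <- FALSE
  eps_hist <- numeric(0)
  while (k < cfg$inner_max_iter) {
    k <- k + 1L
    Xt <- proj(X, lam)
    eps <- frob((Xt - H) * mask)
    eps_hist[k] <- eps
    if (abs(eps - eps_prev) < cfg$inner_tol) {
      converged <- TRUE
      break
    }
    X <- Xt
    X[mask] <- H[mask]
    eps_prev <- eps
  }
  list(X = Xt, epsilon = eps, epsilon_history = eps_hist,
       iterations = k, converged = converged)
}

#' Complete a matrix by bisection on the nuclear-norm bound
#'
#' Bisects the norm bound `lambda` over `[0, ||S_obs||_*]`: at each
#' midpoint the fixed-point approximation [izma_iterate()] is run
#' (warm-started from the previous step) and the known-entry residual
#' decides the half-interval -- the bound is raised if the residual exceeds
#' `e_tol`, lowered otherwise. The loop stops once the interval is
#' resolved to the lambda tolerance and a feasible estimate exists; the
#' smallest-lambda feasible estimate is returned, i.e. the minimum
#' nuclear-norm completion up to the interval tolerance. The number of
#' bisection steps is bounded by `ceil(log2(||S_obs||_* / lambda_tol)) + 1`.
#'
#' @param S data matrix (a [spectrum_matrix] or plain matrix).
#' @param mask logical observation mask (`TRUE` = known); must have at
#'   least one known entry.
#' @param cfg a [completion_config].
#' @param constraint norm ball used by the inner iteration.
#' @return An object of class `completion_result`: list with `X` (estimated
#'   matrix), `lambda_final`, `epsilon_final`, `epsilon_history`,
#'   `outer_iterations`, `converged`.
#' @export
#' @examples
#' M <- outer(1:4, c(1, 2, 1, 3))          # rank 1
#' mask <- matrix(TRUE, 4, 4); mask[2, 3] <- FALSE
#' fit <- complete_matrix(M, mask)
#' fit$X[2, 3]                              # recovers 2 * 1 = 2
complete_matrix <- function(S, mask, cfg = completion_config(),
                            constraint = c("nuclear", "spectral")) {
  S <- as_matrix_rows(S)
  mask <- as_mask(mask, dim(S))
  constraint <- match.arg(constraint)
  stopifnot(inherits(cfg, "completion_config"))
  if (!any(mask)) stop("mask has no known entries", call. = FALSE)

  S_obs <- S * mask
  nuc <- sum(svd(S_obs, nu = 0, nv = 0)$d)
  if (nuc == 0) {
    # zero observed data: the zero matrix is the exact completion
    return(structure(list(X = S_obs, lambda_final = 0, epsilon_final = 0,
                          epsilon_history = numeric(0), outer_iterations = 0L,
                          converged = TRUE),
                     class = "completion_result"))
  }
  ltol <- min(cfg$lambda_tol, cfg$lambda_rtol * nuc)
  lam_min <- 0
  lam_max <- nuc
  lam <- 0
  lam_prev <- 1e6
  eps <- Inf
  X <- S_obs
  warm <- NULL
  X_feas <- NULL
  eps_feas <- Inf
  lam_feas <- NA_real_
  history <- numeric(0)
  n <- 0L

  while ((eps > cfg$e_tol || abs(lam - lam_prev) > ltol) &&
         n < cfg$outer_max_iter) {
    n <- n + 1L
    lam_prev <- lam
    lam <- (lam_min + lam_max) / 2
    r <- izma_iterate(S_obs, mask, lam, cfg, constraint = constraint, X0 = warm)
    X <- r$X
    eps <- r$epsilon
    warm <- X
    history <- c(history, eps)
    if (eps > cfg$e_tol) {
      lam_min <- lam
    } else {
      lam_max <- lam
      X_feas <- X
      eps_feas <- eps
      lam_feas <- lam
    }
    if (abs(lam - lam_prev) <= ltol) break   # interval resolved
  }

  if (eps > cfg$e_tol && !is.null(X_feas)) {
    # last midpoint was infeasible: report the best feasible iterate
    X <- X_feas
    eps <- eps_feas
    lam <- lam_feas
  }
  structure(list(X = X, lambda_final = lam, epsilon_final = eps,
                 epsilon_history = history, outer_iterations = n,
                 converged = eps <= cfg$e_tol),
            class = "completion_result")
}

#' @export
print.completion_result <- function(x, ...) {
  cat(sprintf(
    "<completion_result> %dx%d, lambda = %.6g, eps = %.3g, %d outer steps, %s\n",
    nrow(x$X), ncol(x$X), x$lambda_final, x$epsilon_final,
    x$outer_iterations, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Singular value thresholding baseline
#'
#' Classic SVT iteration for nuclear-norm matrix completion: soft-threshold
#' the singular values of the dual iterate at `tau`, then take a gradient
#' step on the observed-entry residual. Serves as the conventional
#' matrix-completion comparator for the refined method.
#'
#' @param S data matrix.
#' @param mask logical observation mask.
#' @param tau threshold; default `5 * sqrt(n * p)`.
#' @param step step size; default `1.2 * n * p / |observed|`.
#' @param tol relative observed-entry residual for convergence.
#' @param max_iter iteration cap.
#' @return List with `X` (estimate), `iterations`, `converged`,
#'   `residual`.
#' @export
svt_complete <- function(S, mask, tau = NULL, step = NULL,
                         tol = 1e-4, max_iter = 500) {
  S <- as_matrix_rows(S)
  mask <- as_mask(mask, dim(S))
  if (tol <= 0 || max_iter < 1) stop("invalid `tol` or `max_iter`", call. = FALSE)
  n <- nrow(S)
  p <- ncol(S)
  n_obs <- sum(mask)
  if (n_obs == 0) stop("mask has no known entries", call. = FALSE)
  if (is.null(tau)) tau <- 5 * sqrt(n * p)
  if (is.null(step)) step <- 1.2 * n * p / n_obs
  if (tau <= 0 || step <= 0) stop("`tau` and `step` must be positive", call. = FALSE)

  obs_norm <- frob(S * mask)
  if (obs_norm == 0) {
    return(list(X = matrix(0, n, p), iterations = 0L, converged = TRUE,
                residual = 0))
  }
  Y <- step * (S * mask)     # kick-started dual variable
  X <- matrix(0, n, p)
  res <- Inf
  res_floor <- Inf
  stall <- 0L
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    s <- svd(Y)
    d <- pmax(s$d - tau, 0)
    X <- s$u %*% (d * t(s$v))
    res <- frob((X - S) * mask) / obs_norm
    if (res < tol) {
      converged <- TRUE
      break
    }
    # divergence guard: residual growing 10x above its running floor
    res_floor <- min(res_floor, res)
    if (res > 10 * res_floor) {
      stall <- stall + 1L
      if (stall >= 50L) stop("SVT iteration diverged", call. = FALSE)
    } else {
      stall <- 0L
    }
    Y <- Y + step * ((S - X) * mask)
  }
  list(X = X, iterations = it, converged = converged, residual = res)
}

# --- internals ---

frob <- function(M) sqrt(sum(M^2))

as_mask <- function(mask, dims) {
  if (inherits(mask, "observation_mask")) mask <- mask$known
  mask <- as.matrix(mask)
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask)) stop("mask must be logical or 0/1", call. = FALSE)
  if (!all(dim(mask) == dims)) {
    stop("mask shape does not match the matrix", call. = FALSE)
  }
  if (any(is.na(mask))) stop("mask must not contain NA", call. = FALSE)
  mask
}
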