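#' Solver settings for the robust PCA decomposition
#'
#' Bundles the parameters of the inexact augmented Lagrange multiplier (ALM)
#' solver used by [rpca_decompose()]. The defaults reproduce the widely used
#' reference implementation of the inexact ALM algorithm: the penalty
#' parameter mu starts at `1.25 / ||M||_2` and grows geometrically by `rho`
#' each iteration, and the solver stops when the relative Frobenius residual
#' of the constraint `M = L + S` drops below `tol`.
#'
#' @param lambda_eff Positive sparsity weight multiplying the L1 term. For
#'   k-space despiking use [effective_lambda()]; `NULL` is allowed here so the
#'   config can be completed later by [despike()].
#' @param tol Positive relative-residual stopping threshold
#'   (`||M - L - S||_F / ||M||_F`).
#' @param max_iter Maximum number of ALM iterations (at least 1).
#' @param mu0 Initial penalty parameter, or `"auto"` for `1.25 / ||M||_2`.
#' @param rho Geometric growth factor for mu; must exceed 1.
#' @return An object of class `solver_config`.
#' @seealso [rpca_decompose()], [effective_lambda()]
#' @export
#' @examples
#' solver_config(lambda_eff = 1 / sqrt(40))
solver_config <- function(lambda_eff = NULL, tol = 1e-7, max_iter = 1000L,
                          mu0 = "auto", rho = 1.5) {
  if (!is.null(lambda_eff)) {
    stopifnot(is.numeric(lambda_eff), length(lambda_eff) == 1L)
    if (!is.finite(lambda_eff) || lambda_eff <= 0)
      stop("`lambda_eff` must be a positive finite number", call. = FALSE)
  }
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0)
    stop("`tol` must be a positive number", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    stop("`max_iter` must be a positive integer", call. = FALSE)
  if (!identical(mu0, "auto") &&
      (!is.numeric(mu0) || length(mu0) != 1L || mu0 <= 0))
    stop("`mu0` must be \"auto\" or a positive number", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 1)
    stop("`rho` must be a number greater than 1", call. = FALSE)
  structure(
    list(lambda_eff = lambda_eff, tol = tol, max_iter = max_iter,
         mu0 = mu0, rho = rho),
    class = "solver_config"
  )
}

#' Complex soft-thresholding (proximal operator of the complex L1 norm)
#'
#' Shrinks the magnitude of every entry by `tau` while preserving its phase:
#' entries with modulus at most `tau` become exactly zero. This is the
#' elementwise proximal operator of `tau * sum(|z|)` over complex arguments,
#' and is what places RF spikes in the sparse component with hard zeros
#' elsewhere.
#'
#' @param z Complex (or numeric) scalar, vector or matrix.
#' @param tau Nonnegative shrinkage threshold.
#' @return Object of the same shape as `z` with shrunken magnitudes.
#' @export
#' @examples
#' complex_soft_threshold(3 + 4i, 1)  # 2.4 + 3.2i: modulus 5 -> 4, phase kept
complex_soft_threshold <- function(z, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("`tau` must be a single nonnegative number", call. = FALSE)
  mz <- Mod(z)
  scale <- ifelse(mz > tau, (mz - tau) / mz, 0)
  out <- z * scale
  # z * 0 keeps exact zeros; NaN can only arise from 0/0 which ifelse avoids
  out
}

#' Singular value thresholding (proximal operator of the nuclear norm)
#'
#' Soft-thresholds the singular values of a (complex) matrix: for the SVD
#' `X = U diag(sigma) V^H` it returns `U diag(max(sigma - tau, 0)) V^H`. This
#' is the low-rank update inside the ALM iteration.
#'
#' @param X Complex or numeric matrix with finite entries.
#' @param tau Nonnegative threshold applied to every singular value.
#' @return A matrix of the same shape as `X`.
#' @export
singular_value_threshold <- function(X, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("`tau` must be a single nonnegative number", call. = FALSE)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!all(is.finite(X)))
    stop("`X` must have finite entries", call. = FALSE)
  sv <- svd(X)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0 + 0i, nrow(X), ncol(X)))
  sv$u[, keep, drop = FALSE] %*%
    (d[keep] * Conj(t(sv$v[, keep, drop = FALSE])))
}

frob <- function(x) sqrt(sum(Mod(x)^2))

#' Robust PCA of a complex matrix by the inexact ALM method
#'
#' Decomposes an observed matrix `M` into `L + S`, where `L` has low rank and
#' `S` is sparse, by solving `min ||L||_* + lambda_eff * ||S||_1` subject to
#' `M = L + S`. The solver alternates complex soft-thresholding for `S` and
#' singular-value thresholding for `L` under a growing penalty, following the
#' inexact augmented Lagrange multiplier scheme, extended to complex data:
#' the L1 norm is the sum of entry moduli and the SVD is the complex SVD.
#'
#' The solver is deterministic: identical inputs give identical output.
#' Non-convergence within `max_iter` is reported through the `converged`
#' field, not raised as an error, because a partially despiked decomposition
#' is still usable.
#'
#' @param M Complex (or numeric) matrix with finite entries; at least 1 row
#'   and 1 column.
#' @param config A [solver_config()] with a non-`NULL` `lambda_eff`.
#' @return An object of class `rpca_result`: a list with components
#'   \describe{
#'     \item{L}{low-rank component, same shape as `M`}
#'     \item{S}{sparse component (exact zeros off its support)}
#'     \item{n_iter}{iterations used}
#'     \item{converged}{logical; `final_residual <= tol`}
#'     \item{final_residual}{`||M - L - S||_F / ||M||_F`}
#'     \item{rank_L}{number of singular values retained in the final `L`}
#'   }
#' @export
#' @examples
#' set.seed(7)
#' A <- matrix(complex(real = rnorm(80), imaginary = rnorm(80)), 40, 2)
#' B <- matrix(complex(real = rnorm(80), imaginary = rnorm(80)), 2, 40)
#' M <- A %*% B                      # rank 2, nothing sparse
#' fit <- rpca_decompose(M, solver_config(lambda_eff = 1 / sqrt(40)))
#' fit$rank_L
rpca_decompose <- function(M, config = solver_config()) {
  if (!is.matrix(M)) M <- as.matrix(M)
  if (nrow(M) < 1L || ncol(M) < 1L)
    stop("`M` must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(M)))
    stop("`M` must have finite entries", call. = FALSE)
  if (!inherits(config, "solver_config"))
    stop("`config` must be a solver_config", call. = FALSE)
  if (is.null(config$lambda_eff))
    stop("`config$lambda_eff` must be set for rpca_decompose()", call. = FALSE)
  lambda <- config$lambda_eff

  zero <- matrix(0 + 0i, nrow(M), ncol(M))
  d_norm <- frob(M)
  if (d_norm == 0) {
    return(new_rpca_result(zero, zero, 0L, TRUE, 0, 0L, config))
  }

  if (!is.complex(M)) M <- matrix(as.complex(M), nrow(M), ncol(M))

  norm_two <- svd(M, nu = 0, nv = 0)$d[1]
  norm_inf <- max(Mod(M)) / lambda
  Y <- M / max(norm_two, norm_inf)
  mu <- if (identical(config$mu0, "auto")) 1.25 / norm_two else config$mu0
  mu_bar <- mu * 1e7
  rho <- config$rho

  L <- zero
  S <- zero
  rank_L <- 0L
  converged <- FALSE
  resid <- Inf
  iter <- 0L
  k <- min(dim(M))

  while (iter < config$max_iter) {
    iter <- iter + 1L
    S <- complex_soft_threshold(M - L + Y / mu, lambda / mu)
    sv <- svd(M - S + Y / mu, nu = k, nv = k)
    d <- pmax(sv$d - 1 / mu, 0)
    keep <- which(d > 0)
    rank_L <- length(keep)
    L <- if (rank_L > 0L) {
      sv$u[, keep, drop = FALSE] %*%
        (d[keep] * Conj(t(sv$v[, keep, drop = FALSE])))
    } else zero
    Z <- M - L - S
    Y <- Y + mu * Z
    mu <- min(mu * rho, mu_bar)
    resid <- frob(Z) / d_norm
    if (resid < config$tol) {
      converged <- TRUE
      break
    }
  }

  new_rpca_result(L, S, iter, converged, resid, rank_L, config)
}

new_rpca_result <- function(L, S, n_iter, converged, final_residual, rank_L,
                            config) {
  structure(
    list(L = L, S = S, n_iter = n_iter, converged = converged,
         final_residual = final_residual, rank_L = as.integer(rank_L),
         config = config),
    class = "rpca_result"
  )
}

#' @export
print.rpca_result <- function(x, ...) {
  cat(sprintf(
    "Robust PCA decomposition (%d x %d)\n", nrow(x$L), ncol(x$L)))
  cat(sprintf("  rank(L) = %d; nonzeros in S = %d (%.2f%%)\n",
              x$rank_L, sum(Mod(x$S) > 0),
              100 * mean(Mod(x$S) > 0)))
  cat(sprintf("  %s after %d iterations; relative residual %.3g\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$final_residual))
  invisible(x)
}
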