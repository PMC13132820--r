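#' Elementwise soft-thresholding
#'
#' `sign(w) * pmax(|w| - delta, 0)`, the proximal operator of the l1 norm
#' and the basic shrinkage step behind the sparsity constraint.
#'
#' @param w numeric vector.
#' @param delta threshold, >= 0.
#' @return Numeric vector of the same length.
#' @examples
#' soft_threshold(c(3, -1, 0.5), 1)  # 2, 0, 0
#' @export
soft_threshold <- function(w, delta) {
  stopifnot(is.numeric(w), length(delta) == 1L, delta >= 0)
  as.numeric(cpp_soft_threshold(w, delta))
}

#' Project a vector onto the unit l2 sphere intersected with an l1 ball
#'
#' Returns `s = soft_threshold(w, delta*) / ||soft_threshold(w, delta*)||_2`
#' where `delta* = 0` if the plain l2-normalized vector already satisfies
#' `||.||_1 <= c`, and otherwise the threshold (found by bisection to
#' `|  ||s||_1 - c | <= tol`) that makes `||s||_1 = c`. This is the
#' sparsity projection used for both weight vectors: `c = 1` forces a
#' single nonzero weight, `c = sqrt(length(w))` imposes no sparsity.
#'
#' @param w numeric vector, not all zero (an all-zero input returns an
#'   all-zero output with attribute `zero = TRUE`).
#' @param c l1 budget in `[1, sqrt(length(w))]`.
#' @param tol bisection tolerance on the achieved l1 norm.
#' @return Unit-l2 numeric vector with `||.||_1 <= c + tol`; attributes
#'   `delta` (threshold used) and `zero`.
#' @export
l1l2_project <- function(w, c, tol = 1e-6) {
  stopifnot(is.numeric(w), length(c) == 1L)
  if (c < 1 - 1e-12 || c > sqrt(length(w)) + 1e-12)
    stop(sprintf("l1 budget c = %.4g outside the feasible range [1, sqrt(%d)]",
                 c, length(w)))
  res <- cpp_l1l2_project(w, c, tol)
  out <- as.numeric(res$w)
  attr(out, "delta") <- res$delta
  attr(out, "zero") <- res$zero
  out
}

#' Sparsity budgets for the two blocks
#'
#' @param c_u l1 budget for the predictor-block weights, in `[1, sqrt(p)]`.
#' @param c_v l1 budget for the outcome-block weights, in `[1, sqrt(q)]`.
#' @return An object of class `sparsity_pair`.
#' @export
sparsity_pair <- function(c_u, c_v) {
  stopifnot(is.numeric(c_u), is.numeric(c_v), c_u >= 1, c_v >= 1)
  structure(list(c_u = c_u, c_v = c_v), class = "sparsity_pair")
}

#' Fit one sparse latent-variable pair
#'
#' Extracts one pair of sparse weight vectors (u, v) maximizing the
#' cross-block covariance `u' X' Y v` subject to unit l2 norm and the l1
#' budgets in `sp`. The algorithm is an alternating soft-thresholded power
#' iteration on `M = X'Y`:
#' `u <- l1l2_project(M v, c_u)`, `v <- l1l2_project(M' u, c_v)`,
#' initialized at the leading right singular vector of `M` (deterministic,
#' no seed sensitivity) and iterated until the summed l2 change of the two
#' weight vectors falls below `conv_tol` or `max_iter` is reached
#' (non-convergence is flagged, not fatal).
#'
#' Sign convention: (u, v) are flipped jointly so that the outcome-block
#' weight of largest magnitude is positive, so favorable outcomes carry
#' positive weights in reports.
#'
#' @param X standardized predictor matrix (n x p).
#' @param Y standardized outcome matrix (n x q), row-aligned with `X`.
#' @param sp a [sparsity_pair()].
#' @param conv_tol convergence tolerance on weight change.
#' @param max_iter iteration cap.
#' @return List with `u`, `v` (named numeric vectors), `iterations`,
#'   `converged`, and `objective` (the per-iteration covariance trace,
#'   non-decreasing).
#' @export
spls_fit_pair <- function(X, Y, sp, conv_tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(sp, "sparsity_pair"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must be row-aligned")
  if (sp$c_u > sqrt(ncol(X)) + 1e-12)
    stop("c_u exceeds sqrt(p)")
  if (sp$c_v > sqrt(ncol(Y)) + 1e-12)
    stop("c_v exceeds sqrt(q)")
  M <- crossprod(X, Y)
  fit <- cpp_spls_fit(M, sp$c_u, sp$c_v, 1e-10, conv_tol, as.integer(max_iter))
  u <- as.numeric(fit$u); v <- as.numeric(fit$v)
  # joint sign flip: dominant outcome weight positive
  if (any(v != 0) && v[which.max(abs(v))] < 0) { u <- -u; v <- -v }
  if (!fit$converged)
    warning(sprintf("sparse power iteration did not converge in %d iterations",
                    max_iter))
  names(u) <- colnames(X); names(v) <- colnames(Y)
  list(u = u, v = v, iterations = fit$iterations,
       converged = fit$converged, objective = as.numeric(fit$objective))
}

#' Latent scores and their correlation
#'
#' Projects each block onto its weight vector: `xi = X u`, `omega = Y v`
#' (per-participant latent scores), and reports their Pearson correlation
#' `r` and `R^2 = r^2` — the share of cross-block covariance captured by
#' the latent variable.
#'
#' @param X predictor matrix (n x p), standardized with the training-fold
#'   standardizer of the weights.
#' @param Y outcome matrix (n x q).
#' @param u,v weight vectors.
#' @return List with `xi`, `omega`, `r`, `r_squared`, and `degenerate`
#'   (TRUE when a score vector has zero variance, making `r` undefined;
#'   `r` is then NA).
#' @export
compute_latent_scores <- function(X, Y, u, v) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == length(u), ncol(Y) == length(v),
            nrow(X) == nrow(Y))
  xi <- drop(X %*% u)
  omega <- drop(Y %*% v)
  degenerate <- stats::sd(xi) == 0 || stats::sd(omega) == 0 ||
    !is.finite(stats::sd(xi)) || !is.finite(stats::sd(omega))
  r <- if (degenerate) NA_real_ else stats::cor(xi, omega)
  list(xi = xi, omega = omega, r = r, r_squared = r^2,
       degenerate = degenerate)
}

#' Remove an extracted component by projection deflation
#'
#' Right-multiplies each block with the projector onto the orthogonal
#' complement of its unit weight vector: `X' = X (I - u u')`,
#' `Y' = Y (I - v v')`, so subsequent latent variables capture residual
#' covariance. Idempotent, and `X' u = 0` exactly.
#'
#' @param X,Y data matrices.
#' @param u,v unit-l2 weight vectors (checked to 1e-6).
#' @return List with deflated `X` and `Y`.
#' @export
projection_deflate <- function(X, Y, u, v) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (abs(sum(u^2) - 1) > 1e-6 || abs(sum(v^2) - 1) > 1e-6)
    stop("deflation requires unit-l2 weight vectors")
  list(X = X - (X %*% u) %*% t(u),
       Y = Y - (Y %*% v) %*% t(v))
}
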