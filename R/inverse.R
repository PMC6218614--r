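#' Depth weights from a leadfield
#'
#' Diagonal depth weighting that counteracts the minimum-norm bias
#' toward superficial sources: for source `j`,
#' `Omega_jj = sum_i l_ij' l_ij`, the leadfield column energy summed
#' over channels.  An optional square-root variant (the form common
#' elsewhere in the distributed-imaging literature) is available via
#' `sqrt = TRUE`; the default is the plain energy.
#'
#' @param L leadfield matrix (`n x 3m`).
#' @param sqrt_weights logical; take the square root of the energies.
#' @return numeric vector of `m` positive weights.
#' @export
depth_weights <- function(L, sqrt_weights = FALSE) {
  m <- ncol(L) / 3L
  if (m != round(m)) stop("leadfield must have 3m columns")
  cs <- colSums(unclass(L)^2)
  om <- cs[seq(1L, 3L * m, by = 3L)] + cs[seq(2L, 3L * m, by = 3L)] +
    cs[seq(3L, 3L * m, by = 3L)]
  if (any(om == 0)) stop("source with zero leadfield")
  if (sqrt_weights) sqrt(om) else om
}

#' Source-space weighting matrix
#'
#' The `3m x 3m` weighting matrix `W` of the regularized functional
#' `||L J - D||^2 + alpha J' W J`, stored through its `m x m` scalar
#' core `C` with `W = C (x) I_3` (Kronecker structure over the three
#' orientation coordinates):
#'
#' * `mode = "cortical"`: `C = diag(Omega) (B'B + sigma I) diag(Omega)`
#'   -- cortical LORETA with depth weighting and the regularized
#'   Laplace-Beltrami prior;
#' * `mode = "depth-only"`: `C = diag(Omega^2)` -- depth-weighted
#'   minimum norm (the "no Laplacian" reference);
#' * `mode = "minimum-norm"`: `C = I`.
#'
#' The Cholesky factor of `C` is cached so that applying `W^{-1}` never
#' forms a dense `3m x 3m` matrix.
#'
#' @param omega depth weights (length `m`), required for `cortical` and
#'   `depth-only`.
#' @param B a `stiffness` object (or `m x m` matrix), required for
#'   `cortical`.
#' @param sigma positive Laplacian regularization parameter
#'   (`cortical` only).
#' @param mode one of `"cortical"`, `"depth-only"`, `"minimum-norm"`.
#' @param m number of source nodes (required for `"minimum-norm"` when
#'   `omega` is absent).
#' @return An object of class `weighting`: `core`, `factor` (Cholesky),
#'   `mode`, `sigma`, `m`.
#' @export
build_weighting <- function(omega = NULL, B = NULL, sigma = NULL,
                            mode = c("cortical", "depth-only",
                                     "minimum-norm"),
                            m = length(omega)) {
  mode <- match.arg(mode)
  if (mode != "minimum-norm") {
    if (is.null(omega)) stop("omega required for mode ", mode)
    if (any(omega <= 0)) stop("singular depth weighting")
    m <- length(omega)
  }
  if (m < 1L) stop("need the number of source nodes m")
  core <- switch(
    mode,
    "minimum-norm" = Matrix::Diagonal(m),
    "depth-only" = Matrix::Diagonal(m, x = omega^2),
    "cortical" = {
      if (is.null(B)) stop("stiffness matrix required for cortical mode")
      if (is.null(sigma) || sigma <= 0)
        stop("sigma must be positive in cortical mode")
      Bm <- .stiffness_B(B)
      if (nrow(Bm) != m) stop("dimension mismatch between omega and B")
      Dw <- Matrix::Diagonal(m, x = omega)
      Matrix::forceSymmetric(
        Dw %*% (Matrix::crossprod(Bm) +
                  Matrix::Diagonal(m, x = sigma)) %*% Dw)
    })
  fac <- Matrix::Cholesky(methods::as(
    Matrix::forceSymmetric(methods::as(core, "CsparseMatrix")),
    "dsCMatrix"), LDL = FALSE, perm = TRUE)
  structure(list(core = core, factor = fac, mode = mode,
                 sigma = if (mode == "cortical") sigma else NULL, m = m),
            class = "weighting")
}

# C^{-1} X through the cached factor
.solve_core <- function(w, X) {
  as.matrix(Matrix::solve(w$factor, X, system = "A"))
}

#' Dense weighting matrix (small problems only)
#'
#' Materializes `W = C (x) I_3` for inspection and testing.
#'
#' @param w a `weighting`.
#' @return a dense `3m x 3m` matrix.
#' @export
weighting_matrix <- function(w) {
  if (w$m > 500L) stop("refusing to form a dense W for m > 500")
  kronecker(as.matrix(w$core), diag(3))
}

# shared: K = W^{-1} L' (3m x n) and G = L W^{-1} L' (n x n, symmetric)
.gram_parts <- function(L, w) {
  L <- unclass(L)
  m <- w$m
  if (ncol(L) != 3L * m) stop("leadfield/weighting dimension mismatch")
  n <- nrow(L)
  K <- matrix(0, 3L * m, n)
  G <- matrix(0, n, n)
  for (k in 1:3) {
    idx <- seq(k, 3L * m, by = 3L)
    Xk <- .solve_core(w, t(L[, idx, drop = FALSE]))   # m x n
    K[idx, ] <- Xk
    G <- G + L[, idx, drop = FALSE] %*% Xk
  }
  G <- (G + t(G)) / 2
  list(K = K, G = G)
}

.new_inverse_operator <- function(T, method, n, m, alpha = NULL,
                                  beta = NULL, mu = NULL,
                                  singular_values = NULL,
                                  sci = NULL, scv = NULL) {
  structure(list(T = T, method = method, n = n, m = m, alpha = alpha,
                 beta = beta, mu = mu, singular_values = singular_values,
                 sci = sci, scv = scv),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("inverse operator: 3m x n = %d x %d, method %s\n",
              3L * x$m, x$n, x$method))
  invisible(x)
}

#' Direct (Tikhonov-form) linear inverse operator
#'
#' `T = W^{-1} L' [ L W^{-1} L' + alpha I_n ]^{-1}`, computed through
#' the Cholesky factor of the weighting core and a symmetric solve of
#' the regularized `n x n` Gram matrix -- `W` is never inverted
#' explicitly.
#'
#' @param L leadfield (`n x 3m`).
#' @param w a [build_weighting()] object.
#' @param alpha positive regularization parameter.
#' @return an `inverse_operator` with the `3m x n` matrix `T`.
#' @export
inverse_operator_direct <- function(L, w, alpha) {
  if (!(alpha > 0)) stop("alpha must be positive")
  p <- .gram_parts(L, w)
  n <- nrow(p$G)
  A <- p$G + diag(alpha, n)
  ch <- tryCatch(chol(A), error = function(e) {
    stop("L W^-1 L' + alpha I is numerically singular (rcond ~ ",
         format(rcond(A)), ")")
  })
  T <- p$K %*% chol2inv(ch)
  d <- svd(p$G, nu = 0, nv = 0)$d
  .new_inverse_operator(T, "direct", n, w$m, alpha = alpha,
                        mu = d[1L], singular_values = d)
}

#' Truncated-SVD linear inverse operator
#'
#' `T = W^{-1} L' pinv(L W^{-1} L', beta * mu)` where `mu` is the
#' largest singular value of `L W^{-1} L'` and the pseudoinverse zeroes
#' every singular value strictly below the tolerance `beta * mu`.
#'
#' @param L leadfield (`n x 3m`).
#' @param w a [build_weighting()] object.
#' @param beta relative tolerance in `(0, 1]`.
#' @return an `inverse_operator`; its `singular_values` field holds the
#'   full spectrum of `L W^{-1} L'` (descending).
#' @export
inverse_operator_tsvd <- function(L, w, beta) {
  if (!(beta > 0 && beta <= 1)) stop("beta must be in (0, 1]")
  p <- .gram_parts(L, w)
  sv <- svd(p$G)
  mu <- sv$d[1L]
  keep <- sv$d >= beta * mu & sv$d > 0
  if (!any(keep)) stop("empty spectrum: all singular values truncated")
  pinvG <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  T <- p$K %*% pinvG
  .new_inverse_operator(T, "tsvd", nrow(p$G), w$m, beta = beta, mu = mu,
                        singular_values = sv$d)
}

#' Regularization parameter from the SVD cutoff index
#'
#' The SVD cutoff index (SCI) states how many of the smallest singular
#' values of `L W^{-1} L'` are zeroed: SCI = 1 removes only the
#' smallest.  The corresponding cutoff value (SCV) must lie strictly
#' between the singular values with ranks SCI and SCI+1 (counting from
#' the smallest); it is taken as their geometric mean, which is
#' scale-invariant.  The regularization parameter is then
#' `alpha = SCV / (largest singular value)`, usable as the tSVD
#' tolerance ratio `beta`.
#'
#' @param singular_values positive singular values, any order.
#' @param sci integer cutoff index, `1 <= sci < ` number of positive
#'   singular values.
#' @return list with `scv` and `alpha`.
#' @export
alpha_from_sci <- function(singular_values, sci) {
  s <- sort(singular_values[singular_values > 0])
  r <- length(s)
  if (!(length(sci) == 1L && sci == round(sci) && sci >= 1 && sci < r))
    stop("SCI must be an integer in [1, ", r - 1L, "]")
  if (s[sci] == s[sci + 1L])
    stop("no gap between singular values ", sci, " and ", sci + 1L)
  scv <- sqrt(s[sci] * s[sci + 1L])
  list(scv = scv, alpha = scv / s[r])
}

#' Apply an inverse operator to data
#'
#' `Jhat = T D` per time sample; when the leadfield is supplied the
#' reconstructed data `bhat = L Jhat` and the residual-variance inputs
#' are cached as well.
#'
#' @param inv an `inverse_operator` (or a bare `3m x n` matrix `T`).
#' @param D data: an `n`-vector or `n x t` matrix (microvolts).
#' @param L optional leadfield for reconstruction.
#' @return An object of class `source_estimate`: `J` (`3m x t`),
#'   `bhat` (`n x t` or `NULL`), `m`.
#' @export
estimate_sources <- function(inv, D, L = NULL) {
  T <- if (inherits(inv, "inverse_operator")) inv$T else inv
  D <- as.matrix(D)
  if (nrow(D) != ncol(T))
    stop("dimension mismatch: data has ", nrow(D), " channels, operator ",
         ncol(T))
  J <- T %*% D
  bhat <- if (!is.null(L)) unclass(L) %*% J else NULL
  structure(list(J = J, bhat = bhat, m = nrow(J) / 3L),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("source estimate: %d nodes x %d sample(s)\n",
              x$m, ncol(x$J)))
  invisible(x)
}
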