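#' The four discrete Laplace-Beltrami schemes
#'
#' * `"uw-graph"` -- unweighted graph Laplacian: `w_ij = 1`, `d_i = 1`.
#' * `"w-graph"` -- weighted graph Laplacian: `w_ij = 1 / dist(p_i, p_j)`,
#'   `d_i = sum_j dist(p_i, p_j)` over the 1-ring.
#' * `"uw-geom"` -- unweighted geometric (cotangent) Laplacian:
#'   `w_ij = (cot a_ij + cot b_ij) / 2`, `d_i = 1`.
#' * `"w-geom"` -- geometric Laplacian with mixed-area mass:
#'   cotangent weights, `d_i = A_mixed(i)`.
#'
#' `a_ij`, `b_ij` are the two angles opposite edge `(i, j)`; boundary
#' edges use the single available angle.
#'
#' @return character vector of the four scheme names.
#' @export
laplacian_schemes <- function() {
  c("uw-graph", "w-graph", "uw-geom", "w-geom")
}

.match_scheme <- function(scheme) {
  match.arg(scheme, laplacian_schemes())
}

# vectorized per-edge weights for a scheme
.edge_weights <- function(mesh, geometry, scheme) {
  switch(.match_scheme(scheme),
         "uw-graph" = rep(1, nrow(mesh$edges)),
         "w-graph" = 1 / geometry$edge_lengths,
         "uw-geom" = ,
         "w-geom" = rowSums(geometry$edge_cots, na.rm = TRUE) / 2)
}

# vectorized per-vertex masses for a scheme
.vertex_masses <- function(mesh, geometry, scheme) {
  m <- n_vertices(mesh)
  switch(.match_scheme(scheme),
         "uw-graph" = ,
         "uw-geom" = rep(1, m),
         "w-graph" = {
           d <- numeric(m)
           for (c in 1:2) {
             s <- rowsum(geometry$edge_lengths, group = mesh$edges[, c])
             ids <- as.integer(rownames(s))
             d[ids] <- d[ids] + s[, 1L]
           }
           d
         },
         "w-geom" = geometry$mixed_areas)
}

#' Edge weight of a Laplace-Beltrami scheme
#'
#' @param mesh a [trimesh()].
#' @param geometry the matching [mesh_geometry()].
#' @param scheme one of [laplacian_schemes()].
#' @param edge length-2 vertex index pair.
#' @return the scalar weight `w_ij`.
#' @export
edge_weight <- function(mesh, geometry, scheme, edge) {
  r <- .edge_row(mesh, edge)
  if (geometry$edge_lengths[r] <= 0) stop("zero-length edge")
  .edge_weights(mesh, geometry, scheme)[r]
}

#' Vertex mass of a Laplace-Beltrami scheme
#'
#' @inheritParams edge_weight
#' @param vertex vertex index.
#' @return the scalar mass `d_i`.
#' @export
vertex_mass <- function(mesh, geometry, scheme, vertex) {
  if (length(mesh$adjacency[[vertex]]) == 0L)
    stop("vertex ", vertex, " is isolated")
  .vertex_masses(mesh, geometry, scheme)[vertex]
}

#' Assemble the stiffness matrix of a discrete Laplace-Beltrami operator
#'
#' Builds the sparse `m x m` operator `B` with
#' `B[i, i] = sum_{j in N(i)} w_ij / d_i` and `B[i, j] = -w_ij / d_i`
#' for neighbors `j` (diagonal positive, off-diagonals negative).
#' Negative cotangent weights from obtuse triangles are kept as is.
#' `B` annihilates constants by construction, and `diag(d) %*% B` is
#' symmetric.
#'
#' @param mesh a clean [trimesh()] without isolated vertices.
#' @param scheme one of [laplacian_schemes()].
#' @param geometry optional precomputed [mesh_geometry()].
#' @return An object of class `stiffness`: `B` (a `dgCMatrix`),
#'   `scheme`, `weights` (per edge), `masses` (per vertex `d_i`), and
#'   `mesh`.
#' @export
assemble_stiffness <- function(mesh, scheme, geometry = mesh_geometry(mesh)) {
  stopifnot(inherits(mesh, "trimesh"))
  scheme <- .match_scheme(scheme)
  if (any(lengths(mesh$adjacency) == 0L))
    stop("mesh has isolated vertices")
  m <- n_vertices(mesh)
  w <- .edge_weights(mesh, geometry, scheme)
  d <- .vertex_masses(mesh, geometry, scheme)
  if (any(d <= 0)) stop("non-positive vertex mass")
  i <- mesh$edges[, 1L]; j <- mesh$edges[, 2L]
  # symmetric weight matrix, then row-normalize by the masses
  Wm <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                             dims = c(m, m))
  rs <- Matrix::rowSums(Wm)
  B <- (Matrix::Diagonal(m, x = rs) - Wm) / d
  structure(list(B = methods::as(B, "CsparseMatrix"), scheme = scheme,
                 weights = w, masses = d, mesh = mesh),
            class = "stiffness")
}

#' @export
print.stiffness <- function(x, ...) {
  cat(sprintf("stiffness matrix: %d x %d, scheme '%s', %d edges\n",
              nrow(x$B), ncol(x$B), x$scheme, length(x$weights)))
  invisible(x)
}

.stiffness_B <- function(B) {
  if (inherits(B, "stiffness")) B$B else B
}

#' Largest singular value of a matrix
#'
#' Dense SVD for small matrices, power iteration on the Gram matrix
#' (relative tolerance `1e-10`) for large or sparse ones.
#'
#' @param A numeric or `Matrix` matrix, non-empty.
#' @return the largest singular value.
#' @export
largest_singular_value <- function(A) {
  if (inherits(A, "stiffness")) A <- A$B
  if (any(dim(A) == 0L)) stop("empty matrix")
  if (max(dim(A)) <= 500L && !methods::is(A, "sparseMatrix"))
    return(svd(as.matrix(A), nu = 0L, nv = 0L)$d[1L])
  # power iteration on A'A with deterministic start
  n <- ncol(A)
  v <- rep(1 / sqrt(n), n) + sin(seq_len(n)) * 1e-3
  v <- v / sqrt(sum(v^2))
  s_old <- 0
  for (it in seq_len(5000L)) {
    u <- as.numeric(A %*% v)
    v <- as.numeric(Matrix::crossprod(A, u))
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(0)
    v <- v / nv
    s <- sqrt(nv)
    if (abs(s - s_old) <= 1e-12 * s) break
    s_old <- s
  }
  s
}

#' Regularized smoothness prior
#'
#' The matrix `B' B` of a discrete Laplacian is singular (constants are
#' in the kernel), so it cannot enter the inverse operator directly.
#' The prior replaces it by `B' B + sigma * I`, which is symmetric
#' positive definite for `sigma > 0`.  `sigma` trades smoothing
#' strength against fidelity: large `sigma` makes the prior behave like
#' a scaled identity (the Laplacian's effect attenuates), small `sigma`
#' smooths strongly.
#'
#' @param B a `stiffness` object or an `m x m` matrix.
#' @param sigma positive scalar.  Values above `eta^2`, where `eta` is
#'   the largest singular value of `B' B`, trigger a warning (the
#'   useful range is `(0, eta^2]`).
#' @return An object of class `regularized_prior`: `P` (sparse
#'   symmetric `B'B + sigma I`), `sigma`, `eta`.
#' @export
regularized_prior <- function(B, sigma) {
  Bm <- .stiffness_B(B)
  if (!(is.numeric(sigma) && length(sigma) == 1L && sigma > 0))
    stop("sigma must be a positive scalar (B'B alone is singular)")
  BtB <- Matrix::crossprod(Bm)
  eta <- largest_singular_value(BtB)
  if (eta > 0 && sigma > eta^2)
    warning("sigma = ", sigma, " exceeds eta^2 = ", eta^2,
            "; the prior is essentially a scaled identity")
  P <- Matrix::forceSymmetric(
    BtB + Matrix::Diagonal(ncol(Bm), x = sigma))
  structure(list(P = P, sigma = sigma, eta = eta),
            class = "regularized_prior")
}

#' Spectral property report of a stiffness matrix
#'
#' Checks the textbook properties of a discrete Laplacian: diagonal
#' dominance, symmetry of `diag(d) %*% B`, non-negativity of the
#' spectrum, and the kernel dimension (one zero eigenvalue per
#' connected component).  Because `B` itself is non-symmetric when
#' `d_i != 1`, eigenvalues are computed on the similar symmetric matrix
#' `D^{1/2} B D^{-1/2}`, which has the same (real) spectrum.
#'
#' @param B a `stiffness` object.
#' @param zero_tol eigenvalues below `zero_tol * max(eigenvalue)` count
#'   as zero.
#' @return A list: `eigenvalues` (ascending), `n_zero`,
#'   `all_nonnegative`, `diagonally_dominant`, `mass_symmetric`.
#' @export
spectral_report <- function(B, zero_tol = 1e-8) {
  stopifnot(inherits(B, "stiffness"))
  Bm <- B$B
  d <- B$masses
  m <- nrow(Bm)
  S <- Matrix::Diagonal(m, sqrt(d)) %*% Bm %*% Matrix::Diagonal(m, 1 / sqrt(d))
  S <- as.matrix((S + Matrix::t(S)) / 2)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  lmax <- max(abs(ev))
  n_zero <- sum(abs(ev) <= zero_tol * lmax)
  DB <- Matrix::Diagonal(m, d) %*% Bm
  asym <- max(abs(DB - Matrix::t(DB))) / max(abs(DB))
  Bd <- as.matrix(Bm)
  dom <- all(2 * abs(diag(Bd)) >= rowSums(abs(Bd)) - 1e-10 * max(abs(Bd)))
  list(eigenvalues = ev,
       n_zero = n_zero,
       all_nonnegative = all(ev >= -zero_tol * lmax),
       diagonally_dominant = dom,
       mass_symmetric = asym <= 1e-10)
}
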