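# Synthetic surface generators used as test fixtures and as stand-ins
# for segmented cortical meshes.

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere; `10 * 4^s + 2`
#' vertices and `20 * 4^s` faces at subdivision level `s`.
#'
#' @param subdivisions non-negative integer subdivision level.
#' @param radius sphere radius (mm), positive.
#' @return a closed [trimesh()] whose vertices all lie at distance
#'   `radius` from the origin.
#' @examples
#' make_icosphere(1)   # 42 vertices, 80 faces
#' @export
make_icosphere <- function(subdivisions, radius = 1) {
  if (length(subdivisions) != 1L || subdivisions < 0 ||
      subdivisions != round(subdivisions))
    stop("subdivisions must be a non-negative integer")
  if (radius <= 0) stop("radius must be positive")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    # midpoint cache keyed by sorted endpoint pair
    cache <- new.env(hash = TRUE, parent = emptyenv())
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- cache[[key]]
      if (is.null(id)) {
        newv[[length(newv) + 1L]] <<- (v[i, ] + v[j, ]) / 2
        id <- nv + length(newv)
        cache[[key]] <- id
      }
      id
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; c <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4L * t - 3L, ] <- c(a, ab, ca)
      nf[4L * t - 2L, ] <- c(b, bc, ab)
      nf[4L * t - 1L, ] <- c(c, ca, bc)
      nf[4L * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  v <- v * (radius / sqrt(rowSums(v * v)))
  trimesh(v, f)
}

#' Corrugated cortex-like surface
#'
#' Closed ellipsoid-like surface with sinusoidal radial corrugation
#' standing in for a segmented cortical mesh.  Built on a spherified
#' cube: six `n x n` quad grids (deduplicated along the cube edges)
#' projected to the sphere and split into triangles, so vertex
#' valences stay near 6 as in segmentation meshes and the vertex count
#' `6 n^2 + 2` can approach any target.  Node positions are jittered tangentially with a seeded
#' RNG (the jitter preserves the radius), then displaced radially by
#' the corrugation term, which vanishes for
#' `corrugation_amplitude = 0` -- in that case, with unit
#' `axis_scales`, the surface is an exact sphere.
#'
#' @param target_nodes requested vertex count (>= 12); the result is
#'   within 10 percent of this.
#' @param corrugation_amplitude relative amplitude of the radial folds
#'   (dimensionless, >= 0).
#' @param corrugation_frequency length-2 numeric: angular frequencies
#'   of the folds in the polar and azimuthal directions.
#' @param axis_scales length-3 positive scales turning the sphere into
#'   an ellipsoid.
#' @param radius base radius (mm).  The default places the fold crowns
#'   about 2 cm under an 85 mm scalp sphere, the anatomical
#'   scalp-to-cortex clearance.
#' @param jitter relative tangential jitter of the nodes (fraction of
#'   the local grid spacing).
#' @param seed integer seed; the mesh is bit-reproducible for a fixed
#'   seed.
#' @return a closed [trimesh()].
#' @export
make_cortex_surface <- function(target_nodes = 750,
                                corrugation_amplitude = 0.15,
                                corrugation_frequency = c(6, 8),
                                axis_scales = c(1, 0.8, 0.92),
                                radius = 55,
                                jitter = 0.3,
                                seed = 1) {
  if (target_nodes < 12) stop("target_nodes must be at least 12")
  if (corrugation_amplitude < 0) stop("corrugation_amplitude must be >= 0")
  if (any(axis_scales <= 0)) stop("axis_scales must be positive")
  n <- max(2L, round(sqrt((target_nodes - 2) / 6)))  # count = 6 n^2 + 2
  cs <- .cube_sphere(n)
  v <- cs$vertices
  m <- nrow(v)
  .with_seed(seed, {
    # tangential jitter, radius-preserving
    spacing <- (pi / 2) / n
    rnd <- matrix(stats::rnorm(3L * m), m, 3L)
    tang <- rnd - v * rowSums(rnd * v)      # v has unit rows
    tn <- sqrt(rowSums(tang^2))
    tang <- tang / ifelse(tn > 0, tn, 1)
    amt <- stats::runif(m, 0, jitter) * spacing
    v <- v * cos(amt) + tang * sin(amt)
    v <- v / sqrt(rowSums(v^2))
  })
  theta <- acos(pmin(pmax(v[, 3L], -1), 1))
  phi <- atan2(v[, 2L], v[, 1L])
  f1 <- corrugation_frequency[1]
  f2 <- corrugation_frequency[2]
  r <- radius * (1 + corrugation_amplitude *
                   sin(f1 * theta) * cos(f2 * phi) * sin(theta))
  v <- sweep(v * r, 2L, axis_scales, "*")
  trimesh(v, cs$triangles)
}

# Unit cube-sphere: 6 n x n face grids, shared edge/corner vertices
# deduplicated, quads split into triangles, all vertices projected to
# the unit sphere.
.cube_sphere <- function(n) {
  g <- seq(-1, 1, length.out = n + 1L)
  # the 6 faces as (constant axis, sign); (u, v) fill the other two
  face_pts <- function(axis, sgn) {
    uv <- expand.grid(u = g, v = g)
    p <- matrix(0, nrow(uv), 3L)
    others <- setdiff(1:3, axis)
    p[, axis] <- sgn
    p[, others[1L]] <- uv$u
    p[, others[2L]] <- if (sgn > 0) uv$v else -uv$v  # outward orientation
    p
  }
  verts <- list(); faces <- list(); off <- 0L
  for (fc in 1:6) {
    axis <- ((fc - 1L) %% 3L) + 1L
    sgn <- if (fc <= 3L) 1 else -1
    p <- face_pts(axis, sgn)
    verts[[fc]] <- p
    idx <- function(i, j) off + (j - 1L) * (n + 1L) + i  # column-major grid
    qf <- matrix(0L, 2L * n * n, 3L)
    q <- 0L
    for (j in seq_len(n)) for (i in seq_len(n)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      qf[q + 1L, ] <- c(a, b, c); qf[q + 2L, ] <- c(a, c, d)
      q <- q + 2L
    }
    faces[[fc]] <- qf
    off <- off + nrow(p)
  }
  allv <- do.call(rbind, verts)
  key <- apply(round(allv, 9L), 1L, paste, collapse = "/")
  uid <- match(key, key[!duplicated(key)])
  first <- which(!duplicated(key))
  vtx <- allv[first, , drop = FALSE]
  tri <- matrix(uid[do.call(rbind, faces)], ncol = 3L)
  vtx <- vtx / sqrt(rowSums(vtx^2))
  list(vertices = vtx, triangles = tri)
}
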