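# Shared fixtures, all built in code.

# regular tetrahedron, edge length sqrt(2)
tetrahedron <- function() {
  trimesh(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
          rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

# tetrahedron scaled to unit edge length
unit_tetrahedron <- function() {
  tet <- tetrahedron()
  trimesh(tet$vertices / sqrt(8), tet$triangles)
}

two_tetrahedra <- function() {
  t1 <- tetrahedron()
  trimesh(rbind(t1$vertices, t1$vertices + 10),
          rbind(t1$triangles, t1$triangles + 4L))
}

# planar triangulated unit square, (n+1)^2 vertices, diagonal split
planar_square <- function(n = 6) {
  g <- seq(0, 1, length.out = n + 1L)
  v <- as.matrix(expand.grid(x = g, y = g))
  v <- cbind(v, 0)
  idx <- function(i, j) (j - 1L) * (n + 1L) + i
  f <- list()
  for (j in seq_len(n)) for (i in seq_len(n)) {
    a <- idx(i, j); b <- idx(i + 1L, j)
    c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    f[[length(f) + 1L]] <- rbind(c(a, b, c), c(a, c, d))
  }
  mesh <- trimesh(v, do.call(rbind, f))
  interior <- which(v[, 1L] > 0 & v[, 1L] < 1 & v[, 2L] > 0 & v[, 2L] < 1)
  attr(mesh, "interior") <- interior
  mesh
}

# two obtuse triangles sharing the edge (1,2); both opposite angles are
# obtuse, so the shared cotangent weight is negative
obtuse_pair <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.05, 0), c(0.5, -0.05, 0)),
          rbind(c(1, 2, 3), c(2, 1, 4)))
}

# Legendre polynomials P_1..P_N at scalar x (three-term recurrence)
legendre_p <- function(N, x) {
  p <- numeric(N)
  pm1 <- 1; p0 <- x
  p[1] <- x
  if (N >= 2) for (n in 2:N) {
    p[n] <- ((2 * n - 1) * x * p0 - (n - 1) * pm1) / n
    pm1 <- p0; p0 <- p[n]
  }
  p
}

# independent oracle: monopole surface potential of a point source in a
# homogeneous sphere, via its Legendre series
monopole_series <- function(r_e, r0, a, conductivity, N = 250) {
  b <- sqrt(sum(r0^2))
  if (b == 0) return(0)
  cg <- sum(r_e * r0) / (a * b)
  n <- seq_len(N)
  sum((2 * n + 1) / n * (b / a)^n * legendre_p(N, cg)) /
    (4 * pi * conductivity * a)
}

# dipole potential by central differences of the series monopole
dipole_series_fd <- function(r_e, r0, m, a, conductivity, h = 1e-6) {
  g <- vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- h
    (monopole_series(r_e, r0 + e, a, conductivity) -
       monopole_series(r_e, r0 - e, a, conductivity)) / (2 * h)
  }, numeric(1))
  sum(g * m)
}

# small dense leadfield + sphere setup reused across inverse tests
small_inverse_fixture <- function(n_sensors = 16, nodes = 80, seed = 3) {
  montage <- make_montage(n_sensors, 85, 150)
  mesh <- make_cortex_surface(nodes, seed = seed)
  L <- spherical_leadfield(montage, mesh)
  list(montage = montage, mesh = mesh, L = L,
       omega = depth_weights(L, sqrt_weights = TRUE))
}
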