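test_that("depth weights are leadfield column energies", {
  # orthonormal-ish columns: unit-norm lead field vectors give omega = n
  n <- 10L
  L <- matrix(0, n, 6L)
  for (j in 1:6) L[, j] <- 1 / sqrt(n)
  expect_equal(unname(depth_weights(L)), c(3, 3))
  expect_equal(unname(depth_weights(4 * L)), 16 * c(3, 3))
  expect_equal(unname(depth_weights(L, sqrt_weights = TRUE)), sqrt(c(3, 3)))
  L[, 4:6] <- 0
  expect_error(depth_weights(L), "zero leadfield")
})

test_that("weighting matrix has the Kronecker block structure", {
  # zero stiffness, sigma = 1, omega = 1 -> identity
  z <- Matrix::Matrix(0, 4, 4, sparse = TRUE)
  w <- build_weighting(omega = rep(1, 4), B = z, sigma = 1,
                       mode = "cortical")
  expect_equal(weighting_matrix(w), diag(12))
  # cortical core eigenvalues appear with multiplicity 3 in W
  ico <- make_icosphere(0)
  st <- assemble_stiffness(ico, "w-geom")
  om <- runif(12, 0.5, 2)
  wc <- build_weighting(omega = om, B = st, sigma = 0.3,
                        mode = "cortical")
  W <- weighting_matrix(wc)
  expect_equal(dim(W), c(36L, 36L))
  ev_core <- eigen(as.matrix(wc$core), symmetric = TRUE,
                   only.values = TRUE)$values
  ev_full <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev_full), sort(rep(ev_core, each = 3)),
               tolerance = 1e-10)
  expect_error(build_weighting(omega = c(1, 0, 1), mode = "depth-only"),
               "singular")
  expect_error(build_weighting(omega = rep(1, 4), B = z, sigma = 0,
                               mode = "cortical"), "sigma")
})

test_that("direct operator reduces to the pseudoinverse limit", {
  set.seed(7)
  # L with orthonormal rows, W = I: T = L' / (1 + alpha)
  L <- qr.Q(qr(matrix(rnorm(36), 12, 3)))[, 1:3]
  L <- t(L)
  w <- build_weighting(mode = "minimum-norm", m = 4L)
  op <- inverse_operator_direct(L, w, alpha = 1e-12)
  expect_equal(op$T, t(L), tolerance = 1e-9)
  est <- estimate_sources(op, rnorm(3))
  expect_length(est$J, 12L)
})

test_that("direct operator equals the normal-equations form", {
  # T2 = (L'L + alpha W)^{-1} L' on a dense well-conditioned fixture
  set.seed(8)
  tet <- tetrahedron()
  st <- assemble_stiffness(tet, "uw-graph")
  om <- runif(4, 0.8, 1.5)
  w <- build_weighting(omega = om, B = st, sigma = 0.5, mode = "cortical")
  L <- matrix(rnorm(6 * 12), 6, 12)
  alpha <- 0.05
  op <- inverse_operator_direct(L, w, alpha)
  W <- weighting_matrix(w)
  T2 <- solve(crossprod(L) + alpha * W, t(L))
  expect_equal(op$T, T2, tolerance = 1e-8)
})

test_that("truncated-SVD operator matches a dense SVD oracle", {
  set.seed(9)
  tet <- tetrahedron()
  st <- assemble_stiffness(tet, "w-graph")
  om <- runif(4, 0.8, 1.5)
  w <- build_weighting(omega = om, B = st, sigma = 0.2, mode = "cortical")
  L <- matrix(rnorm(6 * 12), 6, 12)
  W <- weighting_matrix(w)
  G <- L %*% solve(W, t(L))
  sv <- svd(G)
  for (beta in c(1e-6, 0.2, 1)) {
    keep <- sv$d >= beta * sv$d[1]
    pinvG <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
    T_or <- solve(W, t(L)) %*% pinvG
    op <- inverse_operator_tsvd(L, w, beta)
    expect_equal(op$T, T_or, tolerance = 1e-8)
    expect_equal(op$mu, sv$d[1], tolerance = 1e-10)
  }
  # beta = 1 keeps only the largest singular value
  op1 <- inverse_operator_tsvd(L, w, 1)
  expect_equal(qr(op1$T)$rank, 1L)
  # small beta converges to the alpha -> 0 direct solution
  opd <- inverse_operator_direct(L, w, alpha = 1e-10 * sv$d[1])
  opt <- inverse_operator_tsvd(L, w, 1e-10)
  expect_equal(opt$T, opd$T, tolerance = 1e-6)
  expect_error(inverse_operator_tsvd(L, w, 2), "beta")
})

test_that("SCI -> alpha arithmetic uses the geometric-mean cutoff", {
  r <- alpha_from_sci(c(0.001, 5, 10), 1)
  expect_equal(r$scv, sqrt(0.001 * 5))
  expect_equal(r$alpha, sqrt(0.001 * 5) / 10)
  expect_error(alpha_from_sci(c(0.001, 5, 10), 0), "SCI")
  expect_error(alpha_from_sci(c(0.001, 5, 10), 3), "SCI")
  expect_error(alpha_from_sci(c(2, 2, 5), 1), "no gap")
  # betweenness for random spectra
  set.seed(10)
  for (i in 1:20) {
    s <- sort(runif(8, 1e-4, 10))
    k <- sample(7, 1)
    if (s[k] == s[k + 1]) next
    scv <- alpha_from_sci(s, k)$scv
    expect_true(s[k] < scv && scv < s[k + 1])
  }
})

test_that("source estimation is linear and guards dimensions", {
  set.seed(12)
  T <- matrix(rnorm(12 * 5), 12, 5)
  d1 <- rnorm(5); d2 <- rnorm(5)
  expect_equal(estimate_sources(T, d1 + d2)$J,
               estimate_sources(T, d1)$J + estimate_sources(T, d2)$J)
  expect_equal(estimate_sources(T, 3 * d1)$J, 3 * estimate_sources(T, d1)$J)
  expect_true(all(estimate_sources(T, rep(0, 5))$J == 0))
  expect_error(estimate_sources(T, rnorm(4)), "dimension mismatch")
})

test_that("all methods localize a node source within two edge lengths", {
  # inverse crime deliberately allowed: identifiability check
  mesh <- make_icosphere(3, radius = 55)
  mon <- make_montage(64, 85, 140)
  L <- spherical_leadfield(mon, mesh)
  om <- depth_weights(L, sqrt_weights = TRUE)
  medge <- mean(mesh_geometry(mesh)$edge_lengths)
  ws <- list(build_weighting(omega = om, mode = "depth-only"))
  for (scheme in laplacian_schemes()) {
    st <- assemble_stiffness(mesh, scheme)
    eta <- largest_singular_value(Matrix::crossprod(st$B))
    ws[[scheme]] <- build_weighting(omega = om, B = st,
                                    sigma = 0.01 * eta, mode = "cortical")
  }
  set.seed(4)
  js <- sample(n_vertices(mesh), 3)
  for (w in ws) {
    op <- inverse_operator_tsvd(L, w, beta = .Machine$double.eps)
    for (j in js) {
      b <- unclass(L)[, (3 * j - 2):(3 * j)] %*% c(2, -1, 1.5)
      ma <- max_amplitude_location(mesh$vertices,
                                   node_power(estimate_sources(op, b)))
      expect_lt(localization_error(ma$point, mesh$vertices[j, ]),
                2 * medge)
    }
  }
})
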