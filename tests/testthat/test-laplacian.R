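test_that("edge weights follow the four schemes", {
  h <- sqrt(3) / 2
  mesh <- trimesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 2 * h, 0),
                        c(1, -2 * h, 0)),
                  rbind(c(1, 2, 3), c(2, 1, 4)))   # equilateral, side 2
  g <- mesh_geometry(mesh)
  expect_equal(edge_weight(mesh, g, "uw-graph", c(1, 2)), 1)
  expect_equal(edge_weight(mesh, g, "w-graph", c(1, 2)), 0.5)
  expect_equal(edge_weight(mesh, g, "uw-geom", c(1, 2)), 1 / sqrt(3),
               tolerance = 1e-12)
  expect_equal(edge_weight(mesh, g, "w-geom", c(1, 2)),
               edge_weight(mesh, g, "uw-geom", c(1, 2)))
})

test_that("vertex masses follow the four schemes", {
  # star: center 1 with neighbors at distances 1, 2, 3
  mesh <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(-3, 0, 0)),
                  rbind(c(1, 2, 3), c(1, 3, 4)))
  g <- mesh_geometry(mesh)
  expect_equal(vertex_mass(mesh, g, "uw-graph", 1), 1)
  expect_equal(vertex_mass(mesh, g, "uw-geom", 1), 1)
  expect_equal(vertex_mass(mesh, g, "w-graph", 1), 6)
  # icosahedron: all faces equilateral and non-obtuse -> A_mixed = 5 area/3
  ico <- make_icosphere(0)
  gi <- mesh_geometry(ico)
  expect_equal(vertex_mass(ico, gi, "w-geom", 1),
               5 * gi$triangle_areas[1] / 3, tolerance = 1e-10)
})

test_that("stiffness matrix matches the four-node worked example", {
  tet <- tetrahedron()
  B <- as.matrix(assemble_stiffness(tet, "uw-graph")$B)
  for (i in 1:4) {
    expect_equal(B[i, i], 3)
    expect_equal(sort(B[i, -i]), rep(-1, 3))
  }
  # unit-edge tetrahedron, weighted graph: d_i = 3, w = 1
  Bw <- as.matrix(assemble_stiffness(unit_tetrahedron(), "w-graph")$B)
  for (i in 1:4) {
    expect_equal(Bw[i, i], 1, tolerance = 1e-12)
    expect_equal(unname(Bw[i, -i]), rep(-1 / 3, 3), tolerance = 1e-12)
  }
})

test_that("constants lie in the kernel and diag(d) B is symmetric", {
  mesh <- make_cortex_surface(300, seed = 8)
  for (scheme in laplacian_schemes()) {
    st <- assemble_stiffness(mesh, scheme)
    expect_lt(max(abs(st$B %*% rep(1, n_vertices(mesh)))),
              1e-10 * max(abs(Matrix::diag(st$B))))
    DB <- Matrix::Diagonal(length(st$masses), st$masses) %*% st$B
    expect_lt(max(abs(DB - Matrix::t(DB))), 1e-10 * max(abs(DB)))
  }
})

test_that("spectral report finds one zero eigenvalue per component", {
  ico <- make_icosphere(1)
  for (scheme in laplacian_schemes()) {
    r <- spectral_report(assemble_stiffness(ico, scheme))
    expect_equal(r$n_zero, 1L)
    expect_true(r$all_nonnegative)
    expect_true(r$mass_symmetric)
  }
  r2 <- spectral_report(assemble_stiffness(two_tetrahedra(), "uw-graph"))
  expect_equal(r2$n_zero, 2L)
})

test_that("cotangent scheme is exact on linear functions (harmonicity)", {
  mesh <- planar_square(6)
  interior <- attr(mesh, "interior")
  B <- assemble_stiffness(mesh, "uw-geom")$B
  for (k in 1:2) {
    r <- as.numeric(B %*% mesh$vertices[, k])
    expect_lt(max(abs(r[interior])), 1e-10)
  }
})

test_that("negative cotangent weights on obtuse meshes are not clipped", {
  mesh <- obtuse_pair()
  g <- mesh_geometry(mesh)
  w12 <- edge_weight(mesh, g, "uw-geom", c(1, 2))
  expect_lt(w12, 0)
  B <- as.matrix(assemble_stiffness(mesh, "uw-geom", g)$B)
  expect_gt(B[1, 2], 0)   # -w/d with w < 0
})

test_that("regularized prior shifts the spectrum by exactly sigma", {
  tet <- tetrahedron()
  st <- assemble_stiffness(tet, "uw-graph")
  expect_error(regularized_prior(st, 0), "positive")
  p <- regularized_prior(st, 2.5)
  ev_p <- eigen(as.matrix(p$P), symmetric = TRUE, only.values = TRUE)$values
  ev_b <- eigen(as.matrix(Matrix::crossprod(st$B)), symmetric = TRUE,
                only.values = TRUE)$values
  expect_equal(ev_p, ev_b + 2.5, tolerance = 1e-10)
  expect_gt(min(ev_p), 2.5 - 1e-10)
  # zero stiffness: prior is sigma * identity
  z <- Matrix::Matrix(0, 3, 3, sparse = TRUE)
  expect_equal(as.matrix(regularized_prior(z, 1)$P), diag(3))
  expect_warning(regularized_prior(st, 1e12), "eta")
})

test_that("largest singular value is exact on known matrices", {
  expect_equal(largest_singular_value(diag(5)), 1)
  expect_equal(largest_singular_value(diag(c(3, 2))), 3)
  set.seed(2)
  A <- matrix(rnorm(30), 5, 6)
  expect_equal(largest_singular_value(3 * A),
               3 * largest_singular_value(A), tolerance = 1e-10)
  expect_error(largest_singular_value(matrix(numeric(), 0, 0)), "empty")
  # sparse power-iteration path vs dense svd
  st <- assemble_stiffness(make_cortex_surface(700, seed = 2), "uw-geom")
  expect_equal(largest_singular_value(st$B),
               svd(as.matrix(st$B), nu = 0, nv = 0)$d[1],
               tolerance = 1e-8)
})
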