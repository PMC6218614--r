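test_that("stabilized Heron area matches closed forms", {
  expect_equal(triangle_area_stable(3, 4, 5), 6)
  expect_equal(triangle_area_stable(2, 2, 2), sqrt(3), tolerance = 1e-14)
  expect_error(triangle_area_stable(1, 1, 3), "triangle inequality")
  expect_error(triangle_area_stable(0, 1, 1), "positive")
})

test_that("Heron-stable area agrees with the cross-product formula", {
  crossprod_area <- function(p) {
    u <- p[2, ] - p[1, ]; v <- p[3, ] - p[1, ]
    w <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    0.5 * sqrt(sum(w^2))
  }
  set.seed(11)
  ok <- 0L
  while (ok < 1000L) {
    p <- matrix(rnorm(9), 3L, 3L)
    a <- sqrt(sum((p[2, ] - p[3, ])^2))
    b <- sqrt(sum((p[1, ] - p[3, ])^2))
    c <- sqrt(sum((p[1, ] - p[2, ])^2))
    cr <- crossprod_area(p)
    if (cr < 1e-3) next   # keep the batch well-conditioned
    expect_equal(triangle_area_stable(a, b, c), cr,
                 tolerance = 1e-12)
    ok <- ok + 1L
  }
})

test_that("needle triangles keep 10 significant digits", {
  # isoceles needles (s, s, eps*s): exact area (eps*s^2/4)*sqrt(4 - eps^2)
  for (eps in c(1e-8, 1e-6, 1e-4)) for (s in c(1, 3.7, 120)) {
    exact <- (eps * s^2 / 4) * sqrt(4 - eps^2)
    expect_equal(triangle_area_stable(s, s, eps * s), exact,
                 tolerance = 1e-10)
  }
  # right needles (a, eps, hyp): area a*eps/2
  for (eps in c(1e-8, 1e-5)) {
    a <- 2
    hyp <- sqrt(a^2 + eps^2)
    expect_equal(triangle_area_stable(a, eps, hyp), a * eps / 2,
                 tolerance = 1e-10)
  }
})

test_that("cotangent pairs follow the opposite angles of an edge", {
  # two equilateral triangles sharing edge (1,2)
  h <- sqrt(3) / 2
  mesh <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, h, 0),
                        c(0.5, -h, 0)),
                  rbind(c(1, 2, 3), c(2, 1, 4)))
  g <- mesh_geometry(mesh)
  ct <- cotangent_pair(mesh, g, c(1, 2))
  expect_equal(ct, rep(1 / sqrt(3), 2), tolerance = 1e-12)
  # boundary edge: single cotangent, right angle -> 0
  right <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                   rbind(c(1, 2, 3)))
  gr <- mesh_geometry(right)
  expect_equal(cotangent_pair(right, gr, c(2, 3)), 0, tolerance = 1e-12)
  expect_length(cotangent_pair(right, gr, c(1, 2)), 1L)
  expect_error(cotangent_pair(right, gr, c(2, 30)), "not in mesh")
})

test_that("mixed area follows the Voronoi / obtuse branches", {
  # lone equilateral triangle: by symmetry each vertex gets area / 3
  eq <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                rbind(c(1, 2, 3)))
  ge <- mesh_geometry(eq)
  for (i in 1:3)
    expect_equal(mixed_area(eq, ge, i), ge$triangle_areas / 3,
                 tolerance = 1e-12)
  # obtuse AT vertex 1 -> area/2 there, area/4 at the other two corners
  ob <- trimesh(rbind(c(0.5, 0.05, 0), c(0, 0, 0), c(1, 0, 0)),
                rbind(c(1, 2, 3)))
  go <- mesh_geometry(ob)
  expect_equal(mixed_area(ob, go, 1), go$triangle_areas / 2)
  expect_equal(mixed_area(ob, go, 2), go$triangle_areas / 4)
  expect_equal(mixed_area(ob, go, 3), go$triangle_areas / 4)
})

test_that("mixed areas tile closed surfaces exactly", {
  for (mesh in list(make_icosphere(2, radius = 70),
                    make_cortex_surface(400, seed = 6))) {
    g <- mesh_geometry(mesh)
    expect_true(all(g$mixed_areas > 0))
    expect_lt(abs(sum(g$mixed_areas) - g$total_area) / g$total_area,
              1e-10)
  }
})

test_that("geometry invariants hold on generated meshes", {
  mesh <- make_cortex_surface(300, seed = 4)
  g <- mesh_geometry(mesh)
  expect_true(all(g$edge_lengths > 0))
  expect_true(all(g$triangle_areas > 0))
  # closed mesh: every edge has exactly two opposite angles
  expect_false(anyNA(g$edge_cots))
})
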