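test_that("residual variance and GOF follow their definitions", {
  b <- c(3, 4)
  expect_equal(residual_variance(b, b), 0)
  expect_equal(goodness_of_fit(b, b), 100)
  expect_equal(residual_variance(b, c(0, 0)), 1)
  expect_equal(goodness_of_fit(b, c(0, 0)), 0)
  expect_equal(residual_variance(b, c(3, 0)), 16 / 25)
  expect_equal(goodness_of_fit(b, c(3, 0)), 36)
  expect_error(residual_variance(c(0, 0), b), "zeros")
  expect_error(residual_variance(b, 1), "length")
})

test_that("solution similarity is an RV-style deviation on powers", {
  expect_equal(solution_similarity(c(1, 0, 0.5), c(1, 0, 0.5)), 0)
  expect_equal(solution_similarity(c(1, 0), c(0, 1)), 200)
  expect_equal(solution_similarity(c(1, 0.5), c(0, 0)), 100)
  expect_error(solution_similarity(c(0, 0), c(1, 0)), "zeros")
})

test_that("node power is the max-normalized squared moment norm", {
  J <- rep(0, 9); J[4:6] <- c(3, 4, 0)
  expect_equal(node_power(J), c(0, 1, 0))
  J2 <- c(c(3, 4, 0), c(6, 8, 0), numeric(3))
  expect_equal(node_power(J2), c(0.25, 1, 0))
  expect_equal(node_power(J2, type = "amplitude"), c(0.5, 1, 0))
  expect_equal(node_power(rep(0, 6)), c(0, 0))
  expect_equal(node_power(J2, normalize = FALSE)[2], 100)
})

test_that("the 50% mask keeps the boundary and is idempotent", {
  expect_equal(threshold_mask(c(1, 0.6, 0.4)), c(1, 0.6, 0))
  expect_equal(threshold_mask(c(1, 0.5)), c(1, 0.5))
  expect_equal(threshold_mask(c(0.3, 0.3, 0.3)), c(0.3, 0.3, 0.3))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(30)
    m <- threshold_mask(p)
    expect_equal(threshold_mask(m), m)            # idempotent
    expect_equal(which.max(m), which.max(p))      # argmax preserved
    expect_true(all(m <= p))                      # never increases
  }
})

test_that("COM and MA locations follow their definitions", {
  pos <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 4, 0))
  expect_equal(center_of_mass(pos, c(0, 1, 0)), c(2, 0, 0))
  expect_equal(center_of_mass(pos, c(1, 1, 0)), c(1, 0, 0))
  expect_equal(center_of_mass(pos, c(1, 0.6, 0)),
               (c(0, 0, 0) + 0.6 * c(2, 0, 0)) / 1.6)
  expect_error(center_of_mass(pos, c(0, 0, 0)), "all-zero")
  ma <- max_amplitude_location(pos, c(0.2, 0.9, 0.9))
  expect_equal(ma$index, 2L)  # first of the tied maxima
  expect_equal(ma$point, c(2, 0, 0))
})

test_that("distances, depths and shifts are Euclidean and signed", {
  expect_equal(localization_error(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(localization_error(c(3, 4, 0), c(0, 0, 0)), 5)
  mon <- make_montage(16, 85, 150)
  expect_equal(source_depth(c(0, 0, 0), mon), 85, tolerance = 1e-9)
  p1 <- as.numeric(mon[1, 2:4])
  expect_equal(source_depth(p1, mon), 0)
  expect_equal(depth_shift(60, 40), 20)
  expect_equal(depth_shift(40, 60), -20)
  expect_equal(depth_shift(40, 40), 0)
})

test_that("local maxima are strict 1-ring maxima", {
  ico <- make_icosphere(2)
  m <- n_vertices(ico)
  expect_equal(count_local_maxima(ico, rep(1, m)), 0L)
  delta <- rep(0, m); delta[5] <- 1
  expect_equal(count_local_maxima(ico, delta), 1L)
  # two deltas more than 2 edges apart -> 2 maxima
  far <- which.max(rowSums(sweep(ico$vertices, 2,
                                 ico$vertices[5, ])^2))
  two <- rep(0, m); two[c(5, far)] <- 1
  expect_equal(count_local_maxima(ico, two), 2L)
  # monotone geodesic decay from one node has exactly one maximum
  for (mesh in list(ico, make_cortex_surface(300, seed = 5))) {
    g <- igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
    el <- sqrt(rowSums((mesh$vertices[mesh$edges[, 1], ] -
                          mesh$vertices[mesh$edges[, 2], ])^2))
    d <- as.numeric(igraph::distances(g, v = 1, weights = el))
    expect_equal(count_local_maxima(mesh, max(d) - d), 1L)
  }
  expect_error(count_local_maxima(ico, rep(1, 3)), "length")
})

test_that("compute_metrics assembles a consistent one-row table", {
  fx <- small_inverse_fixture()
  w <- build_weighting(omega = fx$omega, mode = "depth-only")
  op <- inverse_operator_tsvd(fx$L, w, 1e-8)
  ds <- simulate_datasets(fx$mesh, fx$montage, 1, seed = 2)[[1]]
  est <- estimate_sources(op, ds$data, L = fx$L)
  met <- compute_metrics(est, ds$data, est$bhat, fx$mesh, fx$montage,
                         ds$true_position,
                         reference_power = node_power(est))
  expect_equal(nrow(met), 1L)
  expect_equal(met$gof, 100 * (1 - met$rv))
  expect_equal(met$depth_shift_com, met$depth_sim - met$depth_est_com)
  expect_gte(met$localization_error_ma, 0)
  expect_equal(met$similarity_to_reference, 0)  # vs itself
})
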