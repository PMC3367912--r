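test_that("noise covariance estimation recovers a known white-noise variance", {
  set.seed(42)
  ns <- 8; m <- 1e5; sigma <- 1.7
  fake <- list(sensors = matrix(rnorm(ns * m, 0, sigma), ns, m), fs = 300)
  nc <- estimate_noise_covariance(fake, segment_selector = rep(TRUE, m),
                                  loading_fraction = 0)
  expect_lt(max(abs(diag(nc$entries) - sigma^2)) / sigma^2, 0.05)
  # determinism: identical data, identical matrices
  nc2 <- estimate_noise_covariance(fake, segment_selector = rep(TRUE, m),
                                   loading_fraction = 0)
  expect_identical(nc$entries, nc2$entries)
})

test_that("rank-deficient data without loading raises an estimation error", {
  ns <- 50
  fake <- list(sensors = matrix(rnorm(ns * 60), ns, 60), fs = 300)
  expect_error(estimate_noise_covariance(fake, segment_selector = rep(TRUE, 60),
                                         loading_fraction = 0),
               class = "oscmeg_estimation_error")
})

test_that("source covariance implements depth weighting and the loose constraint", {
  mesh <- fixture_mesh(64, 1)
  gain <- fixture_gain(64, 1)
  flat <- build_source_covariance(mesh, gain, depth_exponent = 0, loose_factor = 1)
  expect_equal(flat$diag, rep(1, 3 * mesh$n_vertices))
  sc <- build_source_covariance(mesh, gain, depth_exponent = 0.8, loose_factor = 0.6)
  nrm <- sc$diag[seq(1, length(sc$diag), 3)]
  tan1 <- sc$diag[seq(2, length(sc$diag), 3)]
  tan2 <- sc$diag[seq(3, length(sc$diag), 3)]
  expect_equal(tan1 / nrm, rep(0.6, mesh$n_vertices))
  expect_equal(tan2 / nrm, rep(0.6, mesh$n_vertices))
  expect_equal(mean(sc$diag), 1)
  # deeper (weaker-gain) vertices get larger prior weight: ordering matches
  # brute-force column norms
  cn <- sapply(seq_len(mesh$n_vertices), function(v)
    sqrt(sum(gain$entries[, (3 * v - 2):(3 * v)]^2)))
  expect_equal(order(nrm), order(cn^(-1.6)))
  weakest <- which.min(cn); strongest <- which.max(cn)
  expect_gt(nrm[weakest], nrm[strongest])
})

test_that("inverse operator approaches identity in the noiseless identity-gain limit", {
  n <- 12
  W <- make_inverse_operator(diag(n), diag(1e-12, n), rep(1, n), snr = Inf)
  expect_lt(max(abs(W$entries - diag(n))), 1e-6)
})

test_that("inverse operator equals the Tikhonov-equivalent algebraic form", {
  set.seed(7)
  ns <- 8; nc <- 12  # 8 sensors, 4 vertices x 3 orientations
  A <- matrix(rnorm(ns * nc), ns, nc)
  M0 <- matrix(rnorm(ns * ns), ns)
  C <- crossprod(M0) + diag(ns)
  r <- runif(nc, 0.5, 2)
  snr <- 3; lam2 <- 1 / snr^2
  W <- make_inverse_operator(A, C, r, snr = snr)$entries
  # oracle: R^(1/2) (R^(1/2) A^T C^-1 A R^(1/2) + lam2 I)^-1 R^(1/2) A^T C^-1
  R12 <- diag(sqrt(r))
  Ci <- solve(C)
  W2 <- R12 %*% solve(R12 %*% t(A) %*% Ci %*% A %*% R12 + lam2 * diag(nc)) %*%
    R12 %*% t(A) %*% Ci
  expect_lt(max(abs(W - W2)), 1e-8)
  # scaling C by 4 and lambda^2 by 1/4 leaves W unchanged
  W3 <- make_inverse_operator(A, 4 * C, r, snr = 2 * snr)$entries
  expect_equal(W, W3, tolerance = 1e-10)
})

test_that("source estimation is linear and dimension-checked", {
  mesh <- fixture_mesh(64, 1)
  gain <- fixture_gain(64, 1)
  sc <- build_source_covariance(mesh, gain)
  inv <- make_inverse_operator(gain, diag(gain$n_sensors), sc, snr = 3)
  expect_equal(apply_inverse(inv, numeric(gain$n_sensors)),
               matrix(0, 3 * mesh$n_vertices, 1))
  x1 <- rnorm(gain$n_sensors); x2 <- rnorm(gain$n_sensors)
  lhs <- apply_inverse(inv, x1 + x2)
  rhs <- apply_inverse(inv, x1) + apply_inverse(inv, x2)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  expect_error(apply_inverse(inv, numeric(gain$n_sensors + 1)),
               class = "oscmeg_data_error")
})

test_that("a point source localizes near its true vertex", {
  mesh <- fixture_mesh(64, 1)
  gain <- fixture_gain(64, 1)
  adj <- vertex_adjacency(mesh)
  sc <- build_source_covariance(mesh, gain)
  C <- diag(0.01, gain$n_sensors)
  inv <- make_inverse_operator(gain, C, sc, snr = 3)
  for (v in c(10L, 40L, 100L)) {
    x <- gain$entries[, (3 * v - 2):(3 * v)] %*% mesh$normals[v, ]
    est <- abs(apply_inverse(inv, x, component = "normal"))
    expect_lte(graph_distance(adj$neighbors, which.max(est), v), 2)
  }
})

test_that("results are invariant under joint sensor-space whitening", {
  mesh <- fixture_mesh(64, 1)
  gain <- fixture_gain(64, 1)
  ns <- gain$n_sensors
  sc <- build_source_covariance(mesh, gain)
  set.seed(11)
  M <- diag(ns) + 0.1 * matrix(rnorm(ns^2), ns)
  C <- diag(ns) * 0.5
  x <- rnorm(ns)
  inv1 <- make_inverse_operator(gain, C, sc, snr = 3)
  g2 <- gain; g2$entries <- M %*% gain$entries
  inv2 <- make_inverse_operator(g2, M %*% C %*% t(M), sc, snr = 3)
  s1 <- apply_inverse(inv1, x)
  s2 <- apply_inverse(inv2, as.vector(M %*% x))
  expect_lt(max(abs(s1 - s2)) / max(abs(s1)), 1e-8)
})

test_that("resolution matrix is more diagonally dominant than a shuffled control", {
  mesh <- fixture_mesh(64, 1)
  gain <- fixture_gain(64, 1)
  sc <- build_source_covariance(mesh, gain)
  inv <- make_inverse_operator(gain, diag(0.05, gain$n_sensors), sc, snr = 3)
  nv <- mesh$n_vertices
  RA <- inv$entries %*% oscmeg:::rotate_gain(gain$entries, sc$basis)
  # collapse 3x3 orientation blocks to a vertex-level magnitude
  Rv <- matrix(0, nv, nv)
  for (i in seq_len(nv)) for (j in seq_len(nv))
    Rv[i, j] <- sqrt(sum(RA[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]^2))
  dd_score <- function(Mt) mean(max.col(Mt) == seq_len(nrow(Mt)))
  set.seed(5)
  shuffled <- Rv[, sample(nv)]
  expect_gt(dd_score(Rv), dd_score(shuffled))
})

test_that("ROI time courses are sign-aligned against phase cancellation", {
  # two-vertex ROI with opposite normals and opposite waveforms averages to
  # the waveform, not zero
  w <- sin(seq(0, 4 * pi, length.out = 200))
  mesh2 <- list(normals = rbind(c(0, 0, 1), c(0, 0, -1)),
                roi = c("r", "r"), hemisphere = factor(c("left", "left")))
  series <- rbind(w, -w)
  expect_equal(roi_timecourse(series, mesh2, "r"), w, tolerance = 1e-12)
  # identical waveforms with aligned normals pass through unchanged
  mesh3 <- list(normals = rbind(c(0, 0, 1), c(0, 0, 1)),
                roi = c("r", "r"), hemisphere = factor(c("left", "left")))
  expect_equal(roi_timecourse(rbind(w, w), mesh3, "r"), w, tolerance = 1e-12)
  expect_error(roi_timecourse(series, mesh2, "missing"),
               class = "oscmeg_config_error")
})

test_that("ROI time course is invariant to joint (normal, waveform) negation", {
  set.seed(21)
  for (rep_ in 1:100) {
    k <- sample(3:8, 1)
    normals <- matrix(rnorm(3 * k), k)
    normals <- normals / sqrt(rowSums(normals^2))
    series <- matrix(rnorm(k * 50), k)
    mesh_k <- list(normals = normals, roi = rep("r", k),
                   hemisphere = factor(rep("left", k)))
    base <- roi_timecourse(series, mesh_k, "r")
    flip <- sample(k, 1)
    normals2 <- normals; normals2[flip, ] <- -normals2[flip, ]
    series2 <- series; series2[flip, ] <- -series2[flip, ]
    mesh_k2 <- mesh_k; mesh_k2$normals <- normals2
    expect_equal(roi_timecourse(series2, mesh_k2, "r"), base, tolerance = 1e-10)
  }
})
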