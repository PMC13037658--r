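test_that("sign vectors clamp size components and are seed-deterministic", {
  s <- make_sign_vector(123, K = 100)
  expect_equal(s$s[1:7], rep(0L, 7))
  expect_true(all(s$s[8:100] %in% c(-1L, 1L)))
  expect_identical(s$s, make_sign_vector(123, K = 100)$s)

  s0 <- make_sign_vector(0, K = 100)
  expect_equal(sum(s0$s != 0), 93)
  expect_true(all(abs(s0$s[s0$s != 0]) == 1))

  expect_error(make_sign_vector(1.5, K = 100), "integer")
  expect_error(make_sign_vector(1, K = 0), ">= 1")
})

test_that("trajectory steps follow the printed ladder formula", {
  s <- make_sign_vector(3, K = 100)
  tr <- make_trajectory(s, Z = 3, N = 17)
  expect_equal(tr$steps[9, ], rep(0, 100))
  expect_equal(max(abs(tr$steps[17, ])), 48 / 17)
  free <- which(s$s != 0)
  # magnitude identical across free components at each step
  for (j in c(1, 5, 13, 17)) {
    expect_equal(length(unique(abs(tr$steps[j, free]))), 1)
  }
  # antisymmetry of every (j, N+1-j) pair
  for (j in 1:17) expect_equal(tr$steps[j, ], -tr$steps[18 - j, ])
  # direct formula oracle at arbitrary (N, Z)
  tr2 <- make_trajectory(s, Z = 1.7, N = 9)
  for (j in 1:9) {
    expect_equal(tr2$steps[j, ], 2 * 1.7 * (j - 5) * s$s / 9)
  }
  expect_error(make_trajectory(s, N = 16), "odd")
  expect_error(make_trajectory(s, Z = -1), "positive")
})

test_that("synthetic basis is reproducible, orthonormal, and calibrated", {
  m <- icosphere(2, radius = 70)
  b1 <- synthesize_basis(m, K = 30, seed = 5)
  b2 <- synthesize_basis(m, K = 30, seed = 5)
  expect_identical(b1$fields, b2$fields)
  expect_identical(b1$global_scale, b2$global_scale)

  gram <- crossprod(b1$fields)
  expect_lt(max(abs(gram - diag(30))), 1e-8)

  # calibration: default-trajectory endpoint displaces by the target
  sv <- make_sign_vector(b1$seed, K = 30)
  tr <- make_trajectory(sv, Z = 3, N = 17)
  d <- mesh_distance(m, deform_mesh(m, b1, tr$steps[17, ]))
  expect_equal(d$mean_mm, 3.5, tolerance = 0.01)

  expect_error(synthesize_basis(m, K = 30, smoothness = -1), "positive")
  expect_error(synthesize_basis(m, K = 30, calibration_target_mm = 0),
               "positive")
})

test_that("random basis fields are smooth relative to mesh edges", {
  fx <- tiny_fixture()
  e <- megdistort:::mesh_edges(fx$mesh)
  for (k in c(10, 50, 100)) {
    f <- matrix(fx$basis$fields[, k], ncol = 3)
    edge_diff <- sqrt(rowSums((f[e[, 1], ] - f[e[, 2], ])^2))
    rms <- sqrt(mean(rowSums(f^2)))
    # white noise would give sqrt(2) * rms; smoothing must beat parity
    expect_lt(mean(edge_diff), 1.0 * rms)
  }
})

test_that("linear deformation is an exact identity at zero and adds linearly", {
  fx <- tiny_fixture()
  m <- fx$mesh; b <- fx$basis
  expect_identical(deform_mesh(m, b, rep(0, b$K))$vertices, m$vertices)

  set.seed(21)
  dz1 <- rnorm(b$K, sd = 0.5)
  dz2 <- rnorm(b$K, sd = 0.5)
  mp <- deform_mesh(m, b, dz1)
  mn <- deform_mesh(m, b, -dz1)
  expect_equal(mp$vertices - m$vertices, -(mn$vertices - m$vertices),
               tolerance = 1e-12)
  # two applications == one application of the sum (exact in a linear model)
  m12 <- deform_mesh(deform_mesh(m, b, dz1), b, dz2)
  msum <- deform_mesh(m, b, dz1 + dz2)
  expect_equal(m12$vertices, msum$vertices, tolerance = 1e-9)

  expect_error(deform_mesh(m, b, rep(0, 3)), "length")
  expect_error(deform_mesh(m, b, c(NA, rep(0, b$K - 1))), "non-finite")
})

test_that("trajectory geometry: midpoint identity, pair symmetry, monotonicity", {
  fx <- tiny_fixture()
  m <- fx$mesh; b <- fx$basis
  for (N in c(5, 9, 17)) {
    tr <- make_trajectory(make_sign_vector(2, K = b$K), Z = 3, N = N)
    mid <- (N + 1) / 2
    expect_identical(deform_mesh(m, b, tr$steps[mid, ])$vertices, m$vertices)
    dists <- vapply(seq_len(N), function(j) {
      mesh_distance(m, deform_mesh(m, b, tr$steps[j, ]))$mean_mm
    }, numeric(1))
    for (j in seq_len(N)) {
      expect_equal(dists[j], dists[N + 1 - j], tolerance = 1e-9)
    }
    # non-decreasing away from the midpoint
    expect_true(all(diff(dists[mid:N]) >= -1e-12))
    expect_true(all(diff(dists[mid:1]) >= -1e-12))
  }
})

test_that("different seeds explore near-orthogonal directions", {
  trajs <- lapply(1:8, function(s) {
    make_trajectory(make_sign_vector(s, K = 100), Z = 3, N = 17)
  })
  sim <- trajectory_similarity(trajs)
  expect_equal(sim$n_pairs, 28)
  expect_lt(sim$mean_r_squared, 0.1)

  # brute-force pairwise oracle over the 28 pairs
  dirs <- lapply(trajs, function(tr) tr$steps[17, ])
  r2 <- c()
  for (i in 1:7) for (j in (i + 1):8) {
    r2 <- c(r2, cor(dirs[[i]], dirs[[j]])^2)
  }
  expect_equal(sim$mean_r_squared, mean(r2))

  # self and sign-flip symmetry
  expect_equal(trajectory_similarity(trajs[[1]], trajs[[1]])$mean_r_squared, 1)
  flipped <- trajs[[1]]
  flipped$steps <- -flipped$steps
  expect_equal(trajectory_similarity(trajs[[1]], flipped)$mean_r_squared, 1)
})

test_that("clamped size components keep brain volume nearly constant", {
  fx <- tiny_fixture()
  m <- fx$mesh; b <- fx$basis
  v0 <- mesh_volume(m)
  tr <- make_trajectory(make_sign_vector(7, K = b$K), Z = 3, N = 17)
  for (j in c(1, 5, 13, 17)) {
    vj <- mesh_volume(deform_mesh(m, b, tr$steps[j, ]))
    expect_lt(abs(vj / v0 - 1), 0.02)
  }
})
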