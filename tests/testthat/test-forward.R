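test_that("sensor cap has the stated geometry and is reproducible", {
  s <- make_sensor_array(n = 120, radius = 120, seed = 3)
  expect_equal(length(s$labels), 120)
  expect_equal(max(abs(sqrt(rowSums(s$orientations^2)) - 1)), 0,
               tolerance = 1e-12)
  expect_lt(max(abs(sqrt(rowSums(s$positions^2)) - 120)), 1e-9)
  expect_identical(s$positions, make_sensor_array(120, 120, seed = 3)$positions)
  expect_error(make_sensor_array(n = 5), "at least 10")
})

test_that("sphere fit is the vertex centroid and translation-equivariant", {
  m <- icosphere(2, radius = 1, center = c(1, 2, 3))
  expect_equal(fit_sphere(m)$center, c(1, 2, 3), tolerance = 1e-9)

  mt <- mesh(sweep(m$vertices, 2, c(5, -2, 0), `+`), m$faces)
  expect_equal(fit_sphere(mt)$center, fit_sphere(m)$center + c(5, -2, 0))

  # brute-force average oracle
  expect_equal(fit_sphere(m)$center,
               apply(m$vertices, 2, mean), tolerance = 1e-14)
})

test_that("lead field matches an independent closed-form implementation", {
  fx <- tiny_fixture()
  L <- fx$L0
  set.seed(5)
  picks <- cbind(sample(nrow(fx$mesh$vertices), 10),
                 sample(length(fx$sensors$labels), 10))
  normals <- vertex_normals(fx$mesh, fx$sphere$center)
  for (k in 1:10) {
    v <- picks[k, 1]; c_i <- picks[k, 2]
    expected <- oracle_dipole_gain(
      fx$mesh$vertices[v, ], normals[v, ],
      fx$sensors$positions[c_i, ], fx$sensors$orientations[c_i, ],
      center = fx$sphere$center
    )
    expect_equal(L$matrix[c_i, v], expected, tolerance = 1e-10)
  }
})

test_that("radial dipoles are silent; gains are linear in the moment", {
  fx <- tiny_fixture()
  v <- fx$mesh$vertices[10, ]
  rad <- v - fx$sphere$center
  rad <- rad / sqrt(sum(rad^2))
  tang <- c(-rad[2], rad[1], 0)
  tang <- tang / sqrt(sum(tang^2))
  g_rad <- vapply(seq_len(120), function(i) {
    oracle_dipole_gain(v, rad, fx$sensors$positions[i, ],
                       fx$sensors$orientations[i, ], fx$sphere$center)
  }, numeric(1))
  g_tan <- vapply(seq_len(120), function(i) {
    oracle_dipole_gain(v, tang, fx$sensors$positions[i, ],
                       fx$sensors$orientations[i, ], fx$sphere$center)
  }, numeric(1))
  expect_lt(max(abs(g_rad)), 1e-10 * max(abs(g_tan)))

  # doubling the moment doubles every gain; two dipoles superpose
  mr <- mesh(fx$mesh$vertices, fx$mesh$faces)
  nn <- vertex_normals(mr, fx$sphere$center)
  L1 <- compute_leadfield(mr, fx$sphere, fx$sensors, normals = nn)
  g_two <- L1$matrix[, 10] + L1$matrix[, 20]
  both <- vapply(seq_len(120), function(i) {
    oracle_dipole_gain(fx$mesh$vertices[10, ], nn[10, ],
                       fx$sensors$positions[i, ],
                       fx$sensors$orientations[i, ], fx$sphere$center) +
      oracle_dipole_gain(fx$mesh$vertices[20, ], nn[20, ],
                         fx$sensors$positions[i, ],
                         fx$sensors$orientations[i, ], fx$sphere$center)
  }, numeric(1))
  expect_equal(g_two, both, tolerance = 1e-12)
})

test_that("gains are equivariant under joint rotation of the whole setup", {
  m <- icosphere(2, radius = 60)
  sph <- fit_sphere(m)
  sens <- make_sensor_array(n = 40, radius = 110)
  nn <- vertex_normals(m, sph$center)
  L <- compute_leadfield(m, sph, sens, normals = nn)

  set.seed(9)
  R <- random_rotation()
  m_r <- rotate_mesh(m, R)
  sens_r <- sens
  sens_r$positions <- sens$positions %*% t(R)
  sens_r$orientations <- sens$orientations %*% t(R)
  L_r <- compute_leadfield(m_r, fit_sphere(m_r), sens_r,
                           normals = nn %*% t(R))
  expect_equal(L_r$matrix, L$matrix, tolerance = 1e-9)
})

test_that("tangential gain decays as the source moves toward the centre", {
  sens <- make_sensor_array(n = 60, radius = 110)
  direction <- c(0.3, 0.2, 0.93)
  direction <- direction / sqrt(sum(direction^2))
  tang <- c(-direction[2], direction[1], 0)
  tang <- tang / sqrt(sum(tang^2))
  peaks <- vapply(seq(60, 5, by = -5), function(depth) {
    g <- vapply(seq_len(60), function(i) {
      oracle_dipole_gain(direction * depth, tang, sens$positions[i, ],
                         sens$orientations[i, ])
    }, numeric(1))
    max(abs(g))
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("row permutation preserves the gain multiset and is seeded", {
  fx <- tiny_fixture()
  Lp <- permute_leadfield_rows(fx$L0, seed = 11)
  expect_true(Lp$permuted)
  expect_equal(Lp$perm_seed, 11L)
  expect_equal(sort(Lp$matrix[, 5]), sort(fx$L0$matrix[, 5]))
  expect_identical(Lp$matrix, permute_leadfield_rows(fx$L0, 11)$matrix)
  expect_false(identical(Lp$matrix, permute_leadfield_rows(fx$L0, 12)$matrix))
})

test_that("leadfield rejects degenerate geometry", {
  m <- icosphere(1, radius = 50)
  sph <- fit_sphere(m)
  expect_error(
    compute_leadfield(m, sph, make_sensor_array(n = 20, radius = 40)),
    "outside"
  )
  m_centered <- mesh(rbind(m$vertices, c(0, 0, 0)),
                     rbind(m$faces, c(1, 2, nrow(m$vertices) + 1)))
  expect_error(
    compute_leadfield(m_centered, sph, make_sensor_array(n = 20, radius = 120)),
    "centre"
  )
})
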