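# One shared tiny fixture per test run: 642-vertex folded cortex, 120-channel
# cap, calibrated basis, high-SNR evoked single-dipole dataset. Built once
# and memoised; every test that needs realistic geometry reuses it.
tiny_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- generate_fixtures(master_seed = 42, preset = "tiny")
      sphere <- fit_sphere(fx$mesh)
      L0 <- compute_leadfield(fx$mesh, sphere, fx$sensors)
      ev <- simulate_evoked(
        fx$mesh, L0,
        sim_spec(vertex = fx$dataset_vertices[1], seed = 101)
      )
      cache <<- list(
        mesh = fx$mesh, basis = fx$basis, sensors = fx$sensors,
        sphere = sphere, L0 = L0, ev = ev,
        true_vertex = fx$dataset_vertices[1], fx = fx
      )
    }
    cache
  }
})

# small random PSD matrix
random_psd <- function(n) {
  a <- matrix(stats::rnorm(n * n), n, n)
  crossprod(a) / n + diag(n) * 0.01
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_mesh <- function(m, R) mesh(m$vertices %*% t(R), m$faces)
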