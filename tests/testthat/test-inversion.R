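test_that("data covariance equals the brute-force time-sample sum", {
  set.seed(1)
  Y <- matrix(rnorm(5 * 40), 5, 40)
  S <- data_covariance(Y)
  oracle <- matrix(0, 5, 5)
  for (t in 1:40) oracle <- oracle + tcrossprod(Y[, t])
  expect_equal(S, oracle / 40, tolerance = 1e-12)
  expect_equal(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > -1e-12))

  # constant channel row
  Yc <- rbind(rep(3, 10), rnorm(10))
  expect_equal(data_covariance(Yc)[1, 1], 9)
})

test_that("free energy evaluates exactly at the identity fixed point", {
  # Sigma = SigmaY = I, Nc = 2, Nt = 4; at lambda = v with a sharp
  # hyperprior the prior and Occam terms vanish and
  # F = -4 - 4 log(2 pi)
  r <- reml_optimize(diag(2), list(diag(2)), Nt = 4,
                     hyperpriors = list(v = 0, Pi = 1e10))
  expect_equal(r$F, -4 - 4 * log(2 * pi), tolerance = 1e-4)
  expect_equal(unname(r$F_terms["prior"]), 0, tolerance = 1e-8)
  expect_equal(unname(r$F_terms["occam"]), 0, tolerance = 1e-8)
})

test_that("single-component scale recovers the variance MLE", {
  r <- reml_optimize(2.5 * diag(10), list(diag(10)), Nt = 500)
  expect_equal(unname(r$scales), 2.5, tolerance = 0.05)
  expect_true(r$converged)
})

test_that("two-component scales are recovered across magnitudes", {
  set.seed(4)
  Q1 <- random_psd(12)
  Q2 <- diag(12)
  for (ab in list(c(0.1, 1), c(1, 0.1), c(10, 0.5), c(2, 5))) {
    Sigma_true <- ab[1] * Q1 + ab[2] * Q2
    # exact population covariance: isolates estimator bias from sampling
    r <- reml_optimize(Sigma_true, list(Q1, Q2), Nt = 500)
    expect_equal(unname(r$scales), ab, tolerance = 0.2)
  }
})

test_that("accuracy terms of F equal the Gaussian log-density sum", {
  set.seed(6)
  Y <- matrix(rnorm(8 * 60), 8, 60)
  SY <- tcrossprod(Y) / 60
  Q1 <- random_psd(8)
  r <- reml_optimize(SY, list(Q1, diag(8)), Nt = 60)
  # oracle: direct sum of multivariate normal log densities at the fitted
  # model covariance
  Sigma <- r$scales[1] * Q1 + r$scales[2] * diag(8)
  Si <- solve(Sigma)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  oracle <- sum(vapply(seq_len(60), function(t) {
    -0.5 * as.numeric(ld) - 0.5 * sum(Y[, t] * (Si %*% Y[, t])) -
      8 / 2 * log(2 * pi)
  }, numeric(1)))
  expect_equal(sum(r$F_terms[c("logdet", "trace", "const")]), oracle,
               tolerance = 1e-8)
})

test_that("posterior estimate matches the source-space (inversion-lemma) form", {
  expect_equal(compute_posterior(matrix(2, 1, 1), matrix(1, 1, 1), 1, 1)[1, 1], 1)

  set.seed(8)
  for (i in 1:100) {
    L <- matrix(rnorm(4 * 6), 4, 6)
    q <- runif(6, 0.5, 2)
    qe <- runif(1, 0.2, 1)
    Y <- matrix(rnorm(4 * 3), 4, 3)
    J <- compute_posterior(Y, L, q, diag(qe, 4))
    oracle <- solve(t(L) %*% L / qe + diag(1 / q)) %*% t(L) %*% Y / qe
    expect_equal(J, oracle, tolerance = 1e-10)
  }

  # prior shrinkage limit
  L <- matrix(rnorm(4 * 6), 4, 6)
  Y <- matrix(rnorm(4 * 3), 4, 3)
  J0 <- compute_posterior(Y, L, rep(1e-12, 6), diag(4))
  expect_lt(max(abs(J0)), 1e-10)
})

test_that("IID prior reproduces Tikhonov-regularized minimum norm", {
  set.seed(10)
  L <- matrix(rnorm(8 * 20), 8, 20)
  Y <- matrix(rnorm(8 * 5), 8, 5)
  q <- prior_iid(20)
  expect_equal(q$q, rep(1, 20))
  kappa <- 0.3
  J <- compute_posterior(Y, L, q$q, diag(kappa, 8))
  ridge <- solve(t(L) %*% L + kappa * diag(20)) %*% t(L) %*% Y
  expect_equal(J, ridge, tolerance = 1e-10)
})

test_that("EBB prior is uniform for white data and peaks at a strong source", {
  set.seed(12)
  L <- qr.Q(qr(matrix(rnorm(30 * 10), 30, 10)))  # orthonormal columns
  q <- prior_ebb(L, diag(30))
  expect_true(all(q$q > 0))
  expect_lt(diff(range(q$q)) / mean(q$q), 1e-8)
  expect_equal(sum(q$q), 1)

  fx <- tiny_fixture()
  qs <- prior_ebb(fx$L0, data_covariance(fx$ev))
  expect_equal(which.max(qs$q), fx$true_vertex)
})

test_that("patch profiles follow graph geodesic distance from their seeds", {
  m <- icosphere(1, radius = 30)
  pl <- make_patch_library(m, Np = 6, sigma_patch = 12, seed = 2)
  expect_equal(ncol(pl$profiles), 6)
  expect_equal(apply(pl$profiles, 2, which.max), pl$seeds)
  expect_equal(apply(pl$profiles, 2, max), rep(1, 6))

  # brute-force Dijkstra oracle on the edge graph
  e <- megdistort:::mesh_edges(m)
  w <- sqrt(rowSums((m$vertices[e[, 1], ] - m$vertices[e[, 2], ])^2))
  nv <- nrow(m$vertices)
  dijkstra <- function(src) {
    dist <- rep(Inf, nv); dist[src] <- 0
    visited <- rep(FALSE, nv)
    for (it in seq_len(nv)) {
      u <- which.min(ifelse(visited, Inf, dist))
      if (!is.finite(dist[u])) break
      visited[u] <- TRUE
      for (k in which(e[, 1] == u | e[, 2] == u)) {
        vtx <- if (e[k, 1] == u) e[k, 2] else e[k, 1]
        if (dist[u] + w[k] < dist[vtx]) dist[vtx] <- dist[u] + w[k]
      }
    }
    dist
  }
  for (j in c(1, 4)) {
    expect_equal(pl$profiles[, j], exp(-dijkstra(pl$seeds[j]) / 12),
                 tolerance = 1e-10)
  }
})

test_that("greedy search finds a generating patch and respects its stop rules", {
  fx <- tiny_fixture()
  pl <- make_patch_library(fx$mesh, Np = 12, sigma_patch = 10, seed = 1)
  set.seed(14)
  wav <- sin(2 * pi * 20 * (0:79) / 250)
  Jp <- outer(pl$profiles[, 7], wav) * 2
  sig <- fx$L0$matrix %*% Jp
  Y <- sig + matrix(rnorm(length(sig), sd = 0.05 * sd(sig)), nrow(sig))
  gs <- greedy_search_invert(Y, fx$L0, pl, config = list(max_patches = 4))
  expect_equal(gs$active_patches[1], 7)
  expect_equal(gs$method, "GS")

  # pure noise: no patch should beat the noise-only model decisively,
  # and free energy must not decrease over accepted greedy steps
  Yn <- matrix(rnorm(120 * 40), 120, 40)
  gs_n <- greedy_search_invert(Yn, fx$L0, pl,
                               config = list(max_patches = 3, tol_F = 5))
  expect_true(length(gs_n$active_patches) <= 3)
  expect_error(
    greedy_search_invert(Y, fx$L0,
                         structure(list(profiles = matrix(0, 642, 0),
                                        seeds = integer(0)),
                                   class = "patch_library")),
    "empty"
  )
})

test_that("beamformer weights satisfy unit gain and a constrained-QP oracle", {
  set.seed(16)
  L <- matrix(rnorm(3 * 4), 3, 4)
  S <- random_psd(3)
  W <- lcmv_weights(L, S, regularization = 0)
  expect_equal(colSums(W * L), rep(1, 4), tolerance = 1e-10)

  # quadratic-program oracle: minimize w' S w subject to w' l = 1
  # (closed-form Lagrange solution computed from first principles)
  for (i in 1:4) {
    l <- L[, i]
    w_qp <- solve(S, l) / as.numeric(t(l) %*% solve(S, l))
    expect_equal(W[, i], w_qp, tolerance = 1e-10)
    # verify optimality by random perturbation in the constraint plane
    base <- as.numeric(t(W[, i]) %*% S %*% W[, i])
    for (r in 1:5) {
      pert <- rnorm(3)
      pert <- pert - l * sum(pert * l) / sum(l * l)  # stay on w'l = 1
      wp <- W[, i] + 0.1 * pert
      expect_gte(as.numeric(t(wp) %*% S %*% wp), base - 1e-12)
    }
  }

  # white data: weights proportional to lead fields
  W_id <- lcmv_weights(L, diag(3), regularization = 0)
  for (i in 1:4) {
    expect_equal(W_id[, i], L[, i] / sum(L[, i]^2), tolerance = 1e-12)
  }
})

test_that("all three schemes invert the fixture and satisfy the model identity", {
  fx <- tiny_fixture()
  pl <- make_patch_library(fx$mesh, Np = 12, sigma_patch = 10, seed = 1)
  for (method in c("IID", "EBB", "GS")) {
    fit <- invert(fx$ev, fx$L0, method,
                  config = list(patches = pl, max_patches = 3))
    expect_s3_class(fit, "inversion_result")
    expect_true(is.finite(fit$F))
    # Sigma_a must equal L Qa L' + Qe by reconstruction
    recon <- megdistort:::model_covariance(fx$L0$matrix, fit$Qa,
                                           fit$Qe_scale)
    expect_equal(fit$Sigma_a, recon,
                 tolerance = 1e-8 * max(abs(fit$Sigma_a)))
    expect_equal(dim(fit$J), c(642, 100))
  }
})

test_that("noiseless data from the IID prior is explained almost perfectly", {
  fx <- tiny_fixture()
  set.seed(18)
  J_true <- matrix(rnorm(642 * 20), 642, 20)
  Y <- fx$L0$matrix %*% J_true
  fit <- invert(Y, fx$L0, "IID")
  expect_gt(variance_explained(Y, fit$Yhat), 0.999)
})

test_that("free energy ranks the generating component mixture above a reduced one", {
  set.seed(20)
  nc <- 16
  wins <- 0
  for (rep in 1:20) {
    Q1 <- random_psd(nc)
    Sigma_true <- 2 * Q1 + 0.5 * diag(nc)
    Y <- t(chol(Sigma_true)) %*% matrix(rnorm(nc * 200), nc, 200)
    SY <- tcrossprod(Y) / 200
    F_full <- reml_optimize(SY, list(Q1, diag(nc)), Nt = 200)$F
    F_reduced <- reml_optimize(SY, list(diag(nc)), Nt = 200)$F
    if (F_full >= F_reduced) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("permuting lead-field rows degrades the model evidence", {
  fx <- tiny_fixture()
  F_true <- invert(fx$ev, fx$L0, "EBB")$F
  wins <- 0
  for (s in 1:20) {
    F_null <- invert(fx$ev, permute_leadfield_rows(fx$L0, s), "EBB")$F
    if (F_true > F_null) wins <- wins + 1
  }
  expect_gte(wins, 19)
})
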