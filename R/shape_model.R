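#' Deterministic pseudo-random sign vector for a distortion trajectory
#'
#' A distortion trajectory is defined by a vector of signs s with one entry
#' per latent shape component: each free component is pushed either up
#' (+1) or down (-1) in z-score as the trajectory advances, with the
#' direction drawn once from a fair coin. The low-order "size" components
#' are clamped to zero so overall brain volume is preserved (sources must
#' not simply move closer to the sensors).
#'
#' @param seed integer; fully determines the vector.
#' @param K number of latent components (default 100).
#' @param size_components indices of the clamped size components
#'   (default `1:7`).
#' @return an object of class `sign_vector` with fields `s` (length K,
#'   entries in -1/0/+1), `seed`, `size_components`.
#' @export
make_sign_vector <- function(seed, K = 100L, size_components = 1:7) {
  if (length(seed) != 1L || !is.finite(seed) || seed != as.integer(seed)) {
    stop("seed must be a single integer")
  }
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (length(size_components) && (min(size_components) < 1 ||
                                  max(size_components) > K)) {
    stop("size_components must be a subset of 1..K")
  }
  s <- withr::with_seed(as.integer(seed), {
    2L * stats::rbinom(K, 1L, 0.5) - 1L
  })
  s[size_components] <- 0L
  structure(
    list(s = s, seed = as.integer(seed),
         size_components = as.integer(size_components)),
    class = "sign_vector"
  )
}

#' Distortion trajectory through latent shape space
#'
#' Builds the N-step ladder of latent offsets for one trajectory: step j
#' perturbs free component i by
#' \deqn{\delta z_{i,j} = 2 Z (j - (N+1)/2)\, s_i / N,}
#' so the midpoint step (N+1)/2 is exactly zero (the true anatomy) and the
#' ladder is antisymmetric about it. With the defaults N = 17, Z = 3 the
#' endpoints reach |dz| = Z (N-1)/N of about 2.82 z-scores.
#'
#' @param sign_vector a [make_sign_vector()] result.
#' @param Z maximum z-score magnitude (default 3).
#' @param N odd number of steps (default 17).
#' @return an object of class `trajectory` with fields `sign_vector`, `Z`,
#'   `N`, and `steps` (an `N x K` matrix of latent offsets).
#' @export
make_trajectory <- function(sign_vector, Z = 3, N = 17L) {
  stopifnot(inherits(sign_vector, "sign_vector"))
  N <- as.integer(N)
  if (N < 3L || N %% 2L == 0L) {
    stop("N must be odd and >= 3 (the midpoint step must be the identity)")
  }
  if (!is.finite(Z) || Z <= 0) stop("Z must be positive")
  j <- seq_len(N)
  scale <- 2 * Z * (j - (N + 1) / 2) / N
  steps <- outer(scale, as.numeric(sign_vector$s))
  structure(
    list(sign_vector = sign_vector, Z = Z, N = N, steps = steps),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> N=%d steps, Z=%g, K=%d components, seed=%d\n",
              x$N, x$Z, length(x$sign_vector$s), x$sign_vector$seed))
  invisible(x)
}

#' Synthetic latent shape basis over a mesh
#'
#' Constructs K per-vertex displacement fields that play the role of the
#' principal components of a population shape model: a latent z-score
#' vector maps linearly to a smooth deformation of the mesh. The first
#' seven components are global size/affine fields (three axis scalings,
#' three symmetric shears, and a translation toward the sensors) so that
#' clamping them (as the trajectory machinery does) structurally preserves
#' brain volume and source-to-sensor distance.
#' The remaining components are Gaussian random vertex displacement fields
#' smoothed by iterated neighbour averaging on the mesh graph. All K fields
#' are then orthonormalized (modified Gram-Schmidt, two passes) under the
#' vertex-displacement inner product.
#'
#' The basis carries a single calibration constant `global_scale`, fixed so
#' that the endpoint of a default trajectory (built from this basis's own
#' seed) displaces vertices by `calibration_target_mm` on average. This
#' anchors the distortion axis in millimetres.
#'
#' @param mesh the undistorted `mesh` the basis lives on.
#' @param K number of components (default 100).
#' @param smoothness length scale of the random fields in mm (default 15).
#' @param seed integer; makes the basis bit-reproducible.
#' @param calibration_target_mm mean vertex displacement at a default
#'   trajectory endpoint (default 3.5 mm).
#' @param n_size number of leading size/affine components (default 7).
#' @return an object of class `shape_basis`: `fields` is a `3 Nv x K`
#'   matrix (vertex-major flattening of K displacement fields, mm per unit
#'   z-score before `global_scale`), plus `K`, `size_components`,
#'   `global_scale`, `seed`, `smoothness`, `calibration`.
#' @export
synthesize_basis <- function(mesh, K = 100L, smoothness = 15, seed = 1L,
                             calibration_target_mm = 3.5, n_size = 7L) {
  stopifnot(inherits(mesh, "mesh"))
  K <- as.integer(K)
  nv <- n_vertices(mesh)
  if (K > 3L * nv) stop("K must be <= 3 x vertex count")
  if (smoothness <= 0) stop("smoothness must be positive")
  if (calibration_target_mm <= 0) stop("calibration target must be positive")
  if (K <= n_size) stop("K must exceed the number of size components")

  ctr <- colMeans(mesh$vertices)
  xc <- sweep(mesh$vertices, 2, ctr, `-`)
  zero <- numeric(nv)
  affine <- cbind(
    as.vector(cbind(xc[, 1], zero, zero)),     # scale x
    as.vector(cbind(zero, xc[, 2], zero)),     # scale y
    as.vector(cbind(zero, zero, xc[, 3])),     # scale z
    as.vector(cbind(xc[, 2], xc[, 1], zero)),  # shear xy
    as.vector(cbind(xc[, 3], zero, xc[, 1])),  # shear xz
    as.vector(cbind(zero, xc[, 3], xc[, 2])),  # shear yz
    as.vector(cbind(zero, zero, zero + 1))     # z-translation (toward cap)
  )[, seq_len(n_size), drop = FALSE]

  # neighbour structure for smoothing
  e <- mesh_edges(mesh)
  nbr_from <- c(e[, 1], e[, 2])
  nbr_to <- c(e[, 2], e[, 1])
  deg <- tabulate(nbr_from, nv)
  mean_edge <- mean(sqrt(rowSums(
    (mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2
  )))
  # variance of k averaging rounds spreads ~ k * h^2
  k_rounds <- max(1L, as.integer(round((smoothness / mean_edge)^2)))

  smooth_field <- function(m) {
    for (r in seq_len(k_rounds)) {
      for (d in 1:3) {
        s <- tabulate_weighted(nbr_from, m[nbr_to, d], nv)
        m[, d] <- 0.5 * m[, d] + 0.5 * s / deg
      }
    }
    m
  }

  rand <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(K - n_size), function(i) {
      as.vector(smooth_field(matrix(stats::rnorm(3 * nv), nv, 3)))
    }, numeric(3 * nv))
  })

  fields <- cbind(affine, rand)
  fields <- mgs_orthonormalize(fields)
  fields <- mgs_orthonormalize(fields)  # second pass for 1e-8 orthogonality

  basis <- structure(
    list(fields = fields, K = K, size_components = seq_len(n_size),
         global_scale = 1, seed = as.integer(seed),
         smoothness = smoothness,
         calibration = list(target_mm = calibration_target_mm,
                            Z = 3, N = 17L)),
    class = "shape_basis"
  )

  # calibrate: endpoint of the basis's own default trajectory must displace
  # vertices by calibration_target_mm on average
  sv <- make_sign_vector(basis$seed, K = K,
                         size_components = basis$size_components)
  traj <- make_trajectory(sv, Z = basis$calibration$Z,
                          N = basis$calibration$N)
  disp <- matrix(fields %*% traj$steps[traj$N, ], nv, 3)
  mean_disp <- mean(sqrt(rowSums(disp^2)))
  basis$global_scale <- calibration_target_mm / mean_disp
  basis
}

#' @export
print.shape_basis <- function(x, ...) {
  cat(sprintf(
    "<shape_basis> K=%d components (%d size), %d vertices, scale=%.4g, seed=%d\n",
    x$K, length(x$size_components), nrow(x$fields) / 3, x$global_scale,
    x$seed))
  invisible(x)
}

# modified Gram-Schmidt over columns
mgs_orthonormalize <- function(m) {
  for (i in seq_len(ncol(m))) {
    v <- m[, i]
    if (i > 1L) {
      prev <- m[, seq_len(i - 1L), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    nrm <- sqrt(sum(v^2))
    if (nrm < 1e-12) stop("degenerate field during orthonormalization")
    m[, i] <- v / nrm
  }
  m
}

#' Deform a mesh by a latent offset
#'
#' Applies the linear displacement model: each vertex moves by
#' `global_scale` times the latent-weighted sum of basis fields. The zero
#' offset is an exact identity, offsets add linearly, and topology and
#' vertex order are untouched.
#'
#' @param mesh the mesh the basis was built on.
#' @param basis a [synthesize_basis()] result.
#' @param dz numeric latent offset of length `basis$K` (z-scores).
#' @return the deformed `mesh`.
#' @export
deform_mesh <- function(mesh, basis, dz) {
  stopifnot(inherits(mesh, "mesh"), inherits(basis, "shape_basis"))
  dz <- as.numeric(dz)
  if (length(dz) != basis$K) {
    stop("dz has length ", length(dz), ", expected K = ", basis$K)
  }
  if (any(!is.finite(dz))) stop("non-finite entries in dz")
  nv <- n_vertices(mesh)
  if (nrow(basis$fields) != 3L * nv) {
    stop("basis was built on a mesh with a different vertex count")
  }
  if (all(dz == 0)) return(mesh)
  disp <- matrix(basis$fields %*% dz, nv, 3) * basis$global_scale
  mesh(mesh$vertices + disp, mesh$faces)
}

#' Similarity between distortion trajectories
#'
#' Squared Pearson correlation between the latent direction vectors of two
#' trajectories (their offsets at a matching nonzero step; direction is
#' step-invariant up to scale). For more than two trajectories, returns the
#' mean over all unordered pairs. Values near zero mean the surrogate
#' surfaces explore nearly orthogonal directions of shape space.
#'
#' @param ... two or more `trajectory` objects, or a single list of them.
#' @return a tibble with columns `n_trajectories`, `n_pairs`,
#'   `mean_r_squared`.
#' @export
trajectory_similarity <- function(...) {
  trajs <- list(...)
  if (length(trajs) == 1L && !inherits(trajs[[1]], "trajectory")) {
    trajs <- trajs[[1]]
  }
  stopifnot(length(trajs) >= 2L,
            all(vapply(trajs, inherits, logical(1), "trajectory")))
  K <- length(trajs[[1]]$sign_vector$s)
  dirs <- lapply(trajs, function(tr) {
    if (length(tr$sign_vector$s) != K) stop("trajectories differ in K")
    d <- tr$steps[tr$N, ]
    if (stats::sd(d) == 0) stop("zero-variance direction vector")
    d
  })
  pairs <- utils::combn(length(trajs), 2)
  r2 <- apply(pairs, 2, function(p) {
    stats::cor(dirs[[p[1]]], dirs[[p[2]]])^2
  })
  tibble::tibble(
    n_trajectories = length(trajs),
    n_pairs = ncol(pairs),
    mean_r_squared = mean(r2)
  )
}
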