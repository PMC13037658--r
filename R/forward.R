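#' Hemispheric cap sensor array
#'
#' Places n radial magnetometers near-uniformly (Fibonacci lattice) on a
#' spherical cap above the head, oriented along the outward radius. The
#' layout is fully deterministic; the seed is recorded for bookkeeping so
#' that serialized arrays can state their provenance.
#'
#' @param n number of sensors (>= 10).
#' @param radius sensor shell radius in mm; must clear the source mesh.
#' @param coverage polar half-angle of the cap in radians (default 2pi/3,
#'   a generous helmet covering down past the equator's midpoint).
#' @param seed integer, recorded in the result.
#' @param center 3-vector, sphere center the cap sits on (default origin).
#' @return an object of class `sensor_array` with `positions` (n x 3, mm),
#'   `orientations` (n x 3 unit vectors), `labels`, `radius`, `coverage`,
#'   `seed`.
#' @export
make_sensor_array <- function(n = 120L, radius = 120, coverage = 2 * pi / 3,
                              seed = 1L, center = c(0, 0, 0)) {
  n <- as.integer(n)
  if (n < 10L) stop("need at least 10 sensors")
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  # cos(theta) uniform on [cos(coverage), 1] gives area-uniform cap coverage
  z <- 1 - (i - 0.5) / n * (1 - cos(coverage))
  rho <- sqrt(pmax(0, 1 - z^2))
  az <- golden * i
  dirs <- cbind(rho * cos(az), rho * sin(az), z)
  structure(
    list(
      positions = sweep(dirs * radius, 2, center, `+`),
      orientations = dirs,
      labels = sprintf("MEG%03d", i),
      radius = radius, coverage = coverage, seed = as.integer(seed),
      center = center
    ),
    class = "sensor_array"
  )
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d radial magnetometers, radius %g mm\n",
              length(x$labels), x$radius))
  invisible(x)
}

#' Sensor array as a tibble
#'
#' @param x a `sensor_array`.
#' @param ... unused.
#' @return a tibble with position and orientation columns.
#' @method as_tibble sensor_array
#' @export
as_tibble.sensor_array <- function(x, ...) {
  pos <- x$positions
  ori <- x$orientations
  tibble::tibble(
    label = x$labels,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    ox = ori[, 1], oy = ori[, 2], oz = ori[, 3]
  )
}

#' Fit the spherical volume conductor to a mesh
#'
#' The single-sphere forward model needs only the volume centre; we take
#' the vertex centroid of the (undistorted) cortical mesh and hold it fixed
#' across a distortion trajectory, so that only the source geometry varies
#' between surrogate anatomies.
#'
#' @param mesh a `mesh`.
#' @return an object of class `sphere_model` with field `center` (mm).
#' @export
fit_sphere <- function(mesh) {
  stopifnot(inherits(mesh, "mesh"))
  structure(list(center = colMeans(mesh$vertices)), class = "sphere_model")
}

#' Single-sphere MEG lead field for surface-normal dipoles
#'
#' Computes the gain matrix mapping a unit current dipole at each mesh
#' vertex (oriented along the outward surface normal) to the radial
#' magnetometer signals, using the closed-form magnetic field of a current
#' dipole in a spherically symmetric conductor (the Sarvas formula). The
#' field outside such a conductor depends only on the sphere centre, not on
#' conductivity profile; radial dipoles are magnetically silent.
#'
#' Units: positions mm, dipole moment nAm, field fT, so gains are fT/nAm.
#'
#' @param mesh source `mesh`; vertices must lie strictly inside the sensor
#'   shell.
#' @param sphere a [fit_sphere()] result (volume centre).
#' @param sensors a [make_sensor_array()] result.
#' @param normals optional `Nv x 3` unit dipole orientations; default
#'   [vertex_normals()] of `mesh` oriented away from the sphere centre.
#' @return an object of class `leadfield` with `matrix` (`Nc x Nv`,
#'   fT/nAm), `channels`, `n_sources`, `units`, `sphere_center`,
#'   `permuted` flag, `perm_seed`.
#' @export
compute_leadfield <- function(mesh, sphere, sensors, normals = NULL) {
  stopifnot(inherits(mesh, "mesh"), inherits(sphere, "sphere_model"),
            inherits(sensors, "sensor_array"))
  if (is.null(normals)) normals <- vertex_normals(mesh, sphere$center)
  nv <- n_vertices(mesh)
  nc <- length(sensors$labels)
  # work in metres relative to the sphere centre
  r0 <- sweep(mesh$vertices, 2, sphere$center, `-`) * 1e-3
  rs <- sweep(sensors$positions, 2, sphere$center, `-`) * 1e-3
  src_rad <- sqrt(rowSums(r0^2))
  sen_rad <- sqrt(rowSums(rs^2))
  if (any(src_rad < 1e-9)) stop("dipole at the sphere centre")
  if (max(src_rad) >= min(sen_rad)) {
    stop("sensors must lie strictly outside the source extent")
  }
  G <- matrix(0, nc, nv)
  rnorm2 <- rowSums(rs^2)
  rn <- sqrt(rnorm2)
  for (i in seq_len(nv)) {
    G[, i] <- sarvas_gain(r0[i, ], normals[i, ], rs, rn, rnorm2,
                          sensors$orientations)
  }
  structure(
    list(matrix = G, channels = sensors$labels, n_sources = nv,
         units = "fT/nAm", sphere_center = sphere$center,
         permuted = FALSE, perm_seed = NULL),
    class = "leadfield"
  )
}

# Sarvas closed form: B(r) for dipole q at r0 in a spherical conductor
# centred at the origin. r0, q: 3-vectors (m; q direction, unit nAm);
# rs: Nc x 3 sensor positions (m); returns projections onto sensor
# orientations in fT per nAm.
sarvas_gain <- function(r0, q, rs, rn, rnorm2, orientations) {
  a_vec <- sweep(rs, 2, r0, `-`)
  an <- sqrt(rowSums(a_vec^2))
  r0_dot_r <- as.vector(rs %*% r0)
  a_dot_r <- rowSums(a_vec * rs)
  FF <- an * (rn * an + rnorm2 - r0_dot_r)
  c1 <- an^2 / rn + a_dot_r / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + a_dot_r / an
  gradF <- rs * c1 - matrix(r0, nrow(rs), 3, byrow = TRUE) * c2
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  qxr0_dot_r <- as.vector(rs %*% qxr0)
  B <- (matrix(qxr0, nrow(rs), 3, byrow = TRUE) * FF - gradF * qxr0_dot_r) *
    (1e-7 / FF^2)
  # B is tesla per A.m; convert to fT per nAm: 1e15 * 1e-9
  rowSums(B * orientations) * 1e6
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d channels x %d sources (%s)%s\n",
              nrow(x$matrix), x$n_sources, x$units,
              if (x$permuted) sprintf(", NULL (rows permuted, seed %d)",
                                      x$perm_seed) else ""))
  invisible(x)
}

#' Row-permuted null lead field
#'
#' Breaks the biophysical link between sensors and anatomy by randomly
#' interchanging the channel rows of the gain matrix while leaving the data
#' untouched. Reconstructions under the permuted lead field provide the
#' chance level against which anatomical selectivity is judged.
#'
#' @param leadfield a [compute_leadfield()] result.
#' @param seed integer seed for the uniform permutation.
#' @return a `leadfield` flagged `permuted = TRUE`.
#' @export
permute_leadfield_rows <- function(leadfield, seed) {
  stopifnot(inherits(leadfield, "leadfield"))
  nc <- nrow(leadfield$matrix)
  perm <- withr::with_seed(as.integer(seed), sample.int(nc))
  out <- leadfield
  out$matrix <- leadfield$matrix[perm, , drop = FALSE]
  out$permuted <- TRUE
  out$perm_seed <- as.integer(seed)
  out
}
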