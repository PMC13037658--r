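#' Triangular surface mesh
#'
#' A lightweight container for a triangulated surface with per-vertex
#' correspondence: vertices are 3D points in millimetres, faces index into
#' the vertex table (1-based). Deformations never add, remove, or reorder
#' vertices, so vertex index i always refers to the same anatomical location
#' across a family of distorted surfaces.
#'
#' @param vertices numeric matrix, `Nv x 3`, coordinates in mm.
#' @param faces integer matrix, `Nf x 3`, 1-based vertex indices.
#' @param normals optional numeric matrix, `Nv x 3`, unit per-vertex normals.
#' @return an object of class `mesh`.
#' @export
mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an Nv x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an Nf x 3 matrix")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(is.na(faces)) || any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range [1, Nv]")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!identical(dim(normals), dim(vertices))) {
      stop("normals must match vertices in shape")
    }
    nrm <- sqrt(rowSums(normals^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("normals must be unit length")
  }
  structure(
    list(vertices = vertices, faces = faces, normals = normals),
    class = "mesh"
  )
}

#' @export
print.mesh <- function(x, ...) {
  cat(sprintf(
    "<mesh> %d vertices, %d faces%s\n",
    nrow(x$vertices), nrow(x$faces),
    if (is.null(x$normals)) "" else ", with normals"
  ))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Unit icosphere mesh
#'
#' Builds a geodesic sphere by repeated midpoint subdivision of an
#' icosahedron, projecting new vertices back onto the unit sphere.
#' Subdivision levels 0..4 give 12, 42, 162, 642, 2562 vertices.
#'
#' @param subdivisions integer >= 0, number of subdivision rounds.
#' @param radius sphere radius (mm).
#' @param center 3-vector, sphere center (mm).
#' @return a `mesh`.
#' @export
icosphere <- function(subdivisions = 3L, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    mid_env <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      idx <- mid_env[[key]]
      if (is.null(idx)) {
        p <- (verts[a, ] + verts[b, ]) / 2
        p <- p / sqrt(sum(p^2))
        verts <<- rbind(verts, p)
        idx <- nrow(verts)
        mid_env[[key]] <- idx
      }
      idx
    }
    nf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(cc, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- nf
  }
  vv <- sweep(v * radius, 2, center, `+`)
  mesh(vv, f)
}

#' Toy folded cortex
#'
#' A deterministic "folded sphere": an icosphere whose radius is modulated
#' by a fixed sum of sinusoids in the angular coordinates, emulating gyral
#' and sulcal folding at a desk scale. The modulation is a fixed function of
#' position (no randomness), so the mesh is bit-reproducible.
#'
#' @param subdivisions icosphere subdivision level (3 gives 642 vertices,
#'   4 gives 2562).
#' @param radius base radius in mm (default 70, the scale of a hemisphere).
#' @param fold_amplitude_mm peak radial fold depth (mm).
#' @param fold_frequency angular frequency of the folding pattern.
#' @return a `mesh`.
#' @export
folded_cortex <- function(subdivisions = 3L, radius = 70,
                          fold_amplitude_mm = 5, fold_frequency = 6) {
  base <- icosphere(subdivisions, radius = 1)
  u <- base$vertices
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1])
  g <- sin(fold_frequency * theta) * cos(fold_frequency * phi) +
    0.5 * sin((fold_frequency + 1) * phi) * sin(2 * theta) +
    0.3 * cos(fold_frequency * theta + 2 * phi)
  r <- radius + fold_amplitude_mm * g / max(abs(g))
  mesh(u * r, base$faces)
}

#' Per-vertex outward surface normals
#'
#' Area-weighted average of incident face normals, normalized to unit
#' length. Orientation is made consistently outward: if the mean projection
#' of the normals onto the radial directions from `center` is negative the
#' whole field is flipped.
#'
#' @param mesh a `mesh`.
#' @param center 3-vector used to orient normals outward; defaults to the
#'   vertex centroid.
#' @return numeric `Nv x 3` matrix of unit vectors.
#' @export
vertex_normals <- function(mesh, center = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  if (is.null(center)) center <- colMeans(v)
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  # cross product rows; magnitude = 2 * face area, so summing raw cross
  # products is exactly area weighting
  fn <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  acc <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc[, d] <- acc[, d] + tabulate_weighted(f[, k], fn[, d], nrow(v))
    }
  }
  nrm <- sqrt(rowSums(acc^2))
  if (any(nrm == 0)) {
    stop("isolated vertex (no incident face) at index ",
         which(nrm == 0)[1])
  }
  nn <- acc / nrm
  radial <- sweep(v, 2, center, `-`)
  if (mean(rowSums(nn * radial)) < 0) nn <- -nn
  nn
}

# sum w over groups g in 1..n (base tabulate only counts)
tabulate_weighted <- function(g, w, n) {
  out <- numeric(n)
  s <- rowsum(w, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Vertex-correspondence distance statistics between two meshes
#'
#' Computes per-vertex Euclidean distances between corresponding vertices of
#' two meshes with identical vertex order and summarizes them. This is the
#' distortion measure used throughout: a deformed surrogate surface is
#' scored by the mean distance of each vertex to its counterpart on the
#' original surface.
#'
#' @param mesh_a,mesh_b two `mesh` objects with equal vertex count.
#' @return a one-row tibble with columns `mean_mm`, `sd_mm`, `p95_mm`.
#' @export
mesh_distance <- function(mesh_a, mesh_b) {
  if (n_vertices(mesh_a) != n_vertices(mesh_b)) {
    stop("vertex-count mismatch: ", n_vertices(mesh_a), " vs ",
         n_vertices(mesh_b))
  }
  d <- sqrt(rowSums((mesh_a$vertices - mesh_b$vertices)^2))
  tibble::tibble(
    mean_mm = mean(d),
    sd_mm = stats::sd(d),
    p95_mm = unname(stats::quantile(d, 0.95))
  )
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra against
#' the origin); absolute value returned. Exact for closed, consistently
#' oriented surfaces.
#'
#' @param mesh a `mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], ]; b <- v[f[, 2], ]; cc <- v[f[, 3], ]
  cr <- cbind(
    b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
    b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
    b[, 1] * cc[, 2] - b[, 2] * cc[, 1]
  )
  abs(sum(a * cr)) / 6
}

# unique undirected edges as a 2-column matrix
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# igraph over mesh edges, weighted by Euclidean edge length (mm)
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

# Euler characteristic V - E + F (2 for a closed genus-0 surface)
mesh_euler <- function(mesh) {
  n_vertices(mesh) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}
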