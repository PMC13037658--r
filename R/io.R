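#' Read a surface mesh from OFF or GIFTI
#'
#' Dispatches on file extension: `.off` (ASCII Object File Format) or
#' `.gii` (GIFTI surface, ASCII-encoded pointset + triangle arrays).
#' Writers and readers round-trip vertex order bit-exactly.
#'
#' @param path file path.
#' @return a `mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.off$", path, ignore.case = TRUE)) return(read_off(path))
  if (grepl("\\.gii$", path, ignore.case = TRUE)) return(read_gifti_surface(path))
  stop("unsupported mesh format (expected .off or .gii): ", path)
}

#' Write a surface mesh to OFF or GIFTI
#'
#' @param mesh a `mesh`.
#' @param path destination; format chosen by extension (`.off` or
#'   `.gii`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh"))
  if (grepl("\\.off$", path, ignore.case = TRUE)) return(write_off(mesh, path))
  if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    return(write_gifti_surface(mesh, path))
  }
  stop("unsupported mesh format (expected .off or .gii): ", path)
}

read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines) || toupper(lines[1]) != "OFF") {
    stop("OFF parse error: missing OFF header in ", path)
  }
  counts <- suppressWarnings(as.integer(strsplit(lines[2], "\\s+")[[1]]))
  if (length(counts) < 2L || any(is.na(counts[1:2]))) {
    stop("OFF parse error: bad count line in ", path)
  }
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2L + nv + nf) stop("OFF parse error: truncated file ", path)
  vl <- lines[3:(2 + nv)]
  verts <- matrix(scan(text = vl, quiet = TRUE), nv, 3, byrow = TRUE)
  fl <- lines[(3 + nv):(2 + nv + nf)]
  faces <- t(vapply(fl, function(ln) {
    xs <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(xs) < 4L || any(is.na(xs)) || xs[1] != 3) {
      stop("OFF parse error: malformed face line \"", ln, "\"")
    }
    as.integer(xs[2:4]) + 1L
  }, integer(3), USE.NAMES = FALSE))
  if (any(faces < 1L) || any(faces > nv)) {
    stop("OFF parse error: face index out of range in ", path)
  }
  mesh(verts, faces)
}

write_off <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  get_array <- function(intent) {
    a <- arrays[xml2::xml_attr(arrays, "Intent") == intent]
    if (!length(a)) stop("GIFTI parse error: missing ", intent, " in ", path)
    a <- a[[1]]
    if (xml2::xml_attr(a, "Encoding") != "ASCII") {
      stop("GIFTI parse error: only ASCII encoding supported")
    }
    dims <- c(as.integer(xml2::xml_attr(a, "Dim0")),
              as.integer(xml2::xml_attr(a, "Dim1")))
    txt <- xml2::xml_text(xml2::xml_find_first(a, ".//Data"))
    matrix(scan(text = txt, quiet = TRUE), dims[1], dims[2], byrow = TRUE)
  }
  verts <- get_array("NIFTI_INTENT_POINTSET")
  faces <- get_array("NIFTI_INTENT_TRIANGLE") + 1L
  mesh(verts, faces)
}

write_gifti_surface <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  fmt_rows <- function(m, fmt) {
    paste(apply(m, 1, function(r) paste(sprintf(fmt, r), collapse = " ")),
          collapse = "\n")
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    '<DataArray Intent="NIFTI_INTENT_POINTSET" DataType="NIFTI_TYPE_FLOAT64"',
    ' ArrayIndexingOrder="RowMajorOrder" Dimensionality="2"',
    sprintf(' Dim0="%d" Dim1="3" Encoding="ASCII" Endian="LittleEndian">\n',
            nrow(v)),
    "<Data>\n", fmt_rows(v, "%.17g"), "\n</Data>\n</DataArray>\n",
    '<DataArray Intent="NIFTI_INTENT_TRIANGLE" DataType="NIFTI_TYPE_INT32"',
    ' ArrayIndexingOrder="RowMajorOrder" Dimensionality="2"',
    sprintf(' Dim0="%d" Dim1="3" Encoding="ASCII" Endian="LittleEndian">\n',
            nrow(f)),
    "<Data>\n", fmt_rows(f, "%d"), "\n</Data>\n</DataArray>\n",
    "</GIFTI>\n"
  )
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Write a numeric matrix as delimited text with a JSON sidecar
#'
#' Tab-separated values at full double precision, plus `<path>.json`
#' holding the provided metadata (units, seeds, shapes, ...).
#'
#' @param m numeric matrix.
#' @param path destination `.tsv` path.
#' @param sidecar named list of metadata (may be empty).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, sidecar = list()) {
  m <- as.matrix(m)
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                         collapse = "\t"))
  writeLines(lines, path)
  sidecar$nrow <- nrow(m)
  sidecar$ncol <- ncol(m)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a delimited matrix written by [write_matrix_tsv()]
#'
#' @param path `.tsv` path.
#' @return the matrix, with the sidecar (if present) attached as attribute
#'   `"sidecar"`.
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    attr(m, "sidecar") <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  }
  m
}

config_defaults <- function() {
  list(
    master_seed = 42L,
    preset = "tiny",
    N = 17L,
    Z = 3,
    K = 100L,
    size_components = 1:7,
    trajectory_seeds = 1:8,
    smoothness = 15,
    calibration_target_mm = 3.5,
    n_sensors = 120L,
    sensor_radius = 120,
    sensor_coverage = 2 * pi / 3,
    n_datasets = 3L,
    n_trials = 336L,
    snr_db = -1.77,
    freq_hz = c(20, 15, 25),
    methods = c("EBB", "IID"),
    metrics = "free_energy",
    cv_runs = 10L,
    cv_frac = 0.1,
    gs_np = 64L,
    gs_sigma_patch = 10,
    n_null_seeds = 0L,
    null_method = "EBB",
    null_metric = "free_energy"
  )
}

#' Benchmark configuration with validated defaults
#'
#' Builds the full parameter set for the benchmark, applying overrides to
#' the defaults (N = 17 steps, Z = 3, K = 100 components with components
#' 1-7 clamped, 8 trajectory seeds, cross-validation of 10 runs at 10\% of
#' channels). Unknown keys are rejected.
#'
#' @param overrides named list of parameter overrides.
#' @return a validated list of class `megdistort_config`.
#' @export
default_config <- function(overrides = list()) {
  cfg <- config_defaults()
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  cfg$N <- as.integer(cfg$N)
  cfg$K <- as.integer(cfg$K)
  if (cfg$N < 3L || cfg$N %% 2L == 0L) {
    stop("config error: N must be odd and >= 3")
  }
  if (cfg$Z <= 0) stop("config error: Z must be positive")
  if (cfg$K <= max(cfg$size_components)) {
    stop("config error: K must exceed the clamped components")
  }
  if (!cfg$preset %in% c("tiny", "standard")) {
    stop("config error: preset must be 'tiny' or 'standard'")
  }
  if (cfg$cv_frac <= 0 || cfg$cv_frac >= 1) {
    stop("config error: cv_frac must be in (0, 1)")
  }
  if (!all(cfg$methods %in% c("EBB", "IID", "GS"))) {
    stop("config error: unknown method")
  }
  if (!all(cfg$metrics %in% c("free_energy", "r2", "cv_error",
                              "gamma_max"))) {
    stop("config error: unknown metric")
  }
  structure(cfg, class = "megdistort_config")
}

#' Load a benchmark configuration from JSON
#'
#' An empty file (or empty object) yields the full defaults; unknown keys
#' are rejected; validation errors name the offending field.
#'
#' @param path JSON file.
#' @return a `megdistort_config`.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  overrides <- if (!nzchar(trimws(txt))) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  default_config(as.list(overrides))
}

#' Write a configuration to JSON
#'
#' @param config a `megdistort_config` (or override list).
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "megdistort_config")) config <- default_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Generate the seeded fixture set
#'
#' Everything the benchmark needs, built offline from one master seed: a
#' toy folded-sphere cortex (deterministic sinusoidal gyral modulation of
#' an icosphere), a hemispheric cap of radial magnetometers, a calibrated
#' synthetic shape basis, and default simulation source vertices drawn
#' from the sensor-facing half of the cortex. Presets: `"tiny"` (642
#' vertices) and `"standard"` (2562 vertices).
#'
#' With `dir` set, the mesh (OFF and GIFTI), sensor table, basis matrix
#' (TSV + JSON sidecar), and configuration are also written to disk;
#' regeneration from the same master seed is byte-identical.
#'
#' @param master_seed integer master seed (default 42).
#' @param preset `"tiny"` or `"standard"`.
#' @param dir optional output directory.
#' @return an object of class `fixture_set`: `mesh`, `sensors`, `basis`,
#'   `dataset_vertices`, `master_seed`, `preset`, and `paths` when written.
#' @export
generate_fixtures <- function(master_seed = 42L, preset = c("tiny", "standard"),
                              dir = NULL) {
  preset <- match.arg(preset)
  subdiv <- if (preset == "tiny") 3L else 4L
  mesh0 <- folded_cortex(subdivisions = subdiv)
  sensors <- make_sensor_array(n = 120L, radius = 120,
                               coverage = 2 * pi / 3,
                               seed = as.integer(master_seed))
  basis <- synthesize_basis(mesh0, K = 100L, smoothness = 15,
                            seed = as.integer(master_seed),
                            calibration_target_mm = 3.5)
  # simulation sources: sensor-facing (upper) vertices, seeded draw
  upper <- which(mesh0$vertices[, 3] > 0.3 * max(mesh0$vertices[, 3]))
  dataset_vertices <- withr::with_seed(as.integer(master_seed), {
    unname(sample(upper, 3L))
  })
  fx <- structure(
    list(mesh = mesh0, sensors = sensors, basis = basis,
         dataset_vertices = dataset_vertices,
         master_seed = as.integer(master_seed), preset = preset,
         paths = NULL),
    class = "fixture_set"
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- list(
      mesh_off = file.path(dir, "cortex.off"),
      mesh_gii = file.path(dir, "cortex.surf.gii"),
      sensors = file.path(dir, "sensors.tsv"),
      basis = file.path(dir, "basis.tsv"),
      config = file.path(dir, "config.json")
    )
    write_mesh(mesh0, p$mesh_off)
    write_mesh(mesh0, p$mesh_gii)
    st <- as_tibble.sensor_array(sensors)
    write_matrix_tsv(as.matrix(st[, -1]), p$sensors,
                     sidecar = list(labels = st$label, units = "mm",
                                    columns = names(st)[-1],
                                    radius = sensors$radius,
                                    coverage = sensors$coverage,
                                    seed = sensors$seed))
    write_matrix_tsv(basis$fields, p$basis,
                     sidecar = list(K = basis$K,
                                    size_components = basis$size_components,
                                    global_scale = basis$global_scale,
                                    seed = basis$seed,
                                    smoothness = basis$smoothness,
                                    calibration = basis$calibration,
                                    units = "mm per z-score (before global_scale)"))
    write_config(list(master_seed = as.integer(master_seed),
                      preset = preset), p$config)
    fx$paths <- p
  }
  fx
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf("<fixture_set> preset '%s', seed %d: %d-vertex cortex, %d sensors, K=%d basis\n",
              x$preset, x$master_seed, n_vertices(x$mesh),
              length(x$sensors$labels), x$basis$K))
  invisible(x)
}
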