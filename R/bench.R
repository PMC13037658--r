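#' Single-dipole simulation specification
#'
#' Describes one simulated evoked dataset: a point dipole at a mesh vertex
#' with a windowed sinusoid time course, repeated over trials with white
#' sensor noise scaled to a target single-trial SNR at the peak channel.
#'
#' @param vertex source vertex index on the mesh.
#' @param moment_nAm dipole moment amplitude (default 10 nAm).
#' @param freq_hz sinusoid frequency (default 20 Hz, mid evoked band).
#' @param n_samples samples per trial (default 100).
#' @param sfreq sampling rate in Hz (default 250).
#' @param n_trials trials to average (default 336).
#' @param snr_db target single-trial SNR at the peak channel, in dB
#'   (default -1.77). Use `Inf` together with `allow_noise_free = TRUE`
#'   for a noise-free simulation.
#' @param seed noise seed.
#' @param allow_noise_free explicit opt-in for `snr_db = Inf`.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(vertex, moment_nAm = 10, freq_hz = 20,
                     n_samples = 100L, sfreq = 250, n_trials = 336L,
                     snr_db = -1.77, seed = 1L, allow_noise_free = FALSE) {
  if (is.infinite(snr_db) && !allow_noise_free) {
    stop("infinite SNR (noise-free) requires allow_noise_free = TRUE")
  }
  if (n_trials < 1L) stop("need at least one trial")
  structure(
    list(vertex = as.integer(vertex), moment_nAm = moment_nAm,
         freq_hz = freq_hz, n_samples = as.integer(n_samples),
         sfreq = sfreq, n_trials = as.integer(n_trials), snr_db = snr_db,
         seed = as.integer(seed), allow_noise_free = allow_noise_free),
    class = "sim_spec"
  )
}

#' Simulate a single-dipole evoked dataset
#'
#' The dipole time course is a Hann-windowed sinusoid; each trial is the
#' lead-field column of the source vertex times the time course plus white
#' sensor noise. Noise variance is set so the single-trial SNR at the
#' peak-amplitude channel (10 log10 of signal to noise variance over the
#' trial window) matches the requested target; trials are then averaged into the
#' returned evoked data. Realized peak- and median-channel SNRs are
#' recomputed from the generated trials and stored in the metadata.
#'
#' @param mesh source `mesh` (the true anatomy the dipole sits on).
#' @param leadfield `leadfield` computed on `mesh`.
#' @param spec a [sim_spec()].
#' @return an object of class `evoked`: `Y` (`Nc x Nt` averaged data,
#'   fT), `sfreq`, `n_trials`, `channels`, and `sim` metadata (true
#'   vertex, target and realized SNRs, noise sd, waveform parameters).
#' @export
simulate_evoked <- function(mesh, leadfield, spec) {
  stopifnot(inherits(spec, "sim_spec"), inherits(leadfield, "leadfield"))
  L <- leadfield$matrix
  if (spec$vertex < 1L || spec$vertex > ncol(L)) {
    stop("source vertex not on the mesh")
  }
  tt <- (seq_len(spec$n_samples) - 1) / spec$sfreq
  waveform <- hann_window(spec$n_samples) * sin(2 * pi * spec$freq_hz * tt)
  signal <- outer(L[, spec$vertex] * spec$moment_nAm, waveform)  # Nc x Nt
  chan_var <- rowMeans(signal^2)
  peak_chan <- which.max(chan_var)
  sigma2 <- if (is.infinite(spec$snr_db)) 0 else {
    chan_var[peak_chan] / 10^(spec$snr_db / 10)
  }
  nc <- nrow(L)
  nt <- spec$n_samples
  if (sigma2 > 0) {
    noise <- withr::with_seed(spec$seed, {
      matrix(stats::rnorm(nc * nt * spec$n_trials, sd = sqrt(sigma2)),
             nc * nt, spec$n_trials)
    })
    noise_avg <- matrix(rowMeans(noise), nc, nt)
    # realized single-trial noise power per channel, over trials and time
    noise_var_chan <- rowMeans(matrix(rowMeans(noise^2), nc, nt))
    snr_chan <- 10 * log10(chan_var / noise_var_chan)
  } else {
    noise_avg <- matrix(0, nc, nt)
    snr_chan <- rep(Inf, nc)
  }
  Y <- signal + noise_avg
  structure(
    list(Y = Y, sfreq = spec$sfreq, n_trials = spec$n_trials,
         channels = leadfield$channels,
         sim = list(spec = spec, true_vertex = spec$vertex,
                    peak_channel = peak_chan,
                    snr_peak_db = snr_chan[peak_chan],
                    snr_median_db = stats::median(snr_chan),
                    noise_sd = sqrt(sigma2), signal = signal,
                    waveform = waveform)),
    class = "evoked"
  )
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> %d channels x %d samples, %d trials averaged\n",
              nrow(x$Y), ncol(x$Y), x$n_trials))
  invisible(x)
}

#' Sweep an inversion across a distortion trajectory
#'
#' For each step of the trajectory: deform the true mesh, recompute surface
#' normals and the lead field (sphere centre held fixed at the true mesh's
#' centroid), invert the same evoked data on the surrogate anatomy, and
#' evaluate the requested fit metrics. Failures at individual steps are
#' recorded as `NA` and the sweep continues.
#'
#' @param data `evoked` data simulated or recorded on the true anatomy.
#' @param true_mesh the undistorted `mesh`.
#' @param basis `shape_basis` built on `true_mesh`.
#' @param trajectory a [make_trajectory()] result.
#' @param sensors `sensor_array`.
#' @param method inversion scheme.
#' @param metrics character subset of `c("free_energy", "r2", "cv_error",
#'   "gamma_max")`.
#' @param config passed to [invert()]; additionally `null_seed` (integer)
#'   row-permutes every lead field for the null pipeline, and `cv_runs`,
#'   `cv_frac`, `cv_seed` control the cross-validation metric.
#' @return a tibble with one row per step x metric: `step`,
#'   `distortion_mm`, `metric`, `value`, `method`, `trajectory_seed`,
#'   `is_null`.
#' @export
sweep_trajectory <- function(data, true_mesh, basis, trajectory, sensors,
                             method = "EBB", metrics = "free_energy",
                             config = list()) {
  stopifnot(inherits(trajectory, "trajectory"))
  known <- c("free_energy", "r2", "cv_error", "gamma_max")
  if (!all(metrics %in% known)) {
    stop("unknown metric(s): ", paste(setdiff(metrics, known), collapse = ", "))
  }
  sphere <- fit_sphere(true_mesh)
  is_null <- !is.null(config$null_seed)
  Y <- get_sensor_matrix(data)
  rows <- purrr::map(seq_len(trajectory$N), function(j) {
    res <- tryCatch({
      mesh_j <- deform_mesh(true_mesh, basis, trajectory$steps[j, ])
      dist_j <- mesh_distance(true_mesh, mesh_j)$mean_mm
      Lj <- compute_leadfield(mesh_j, sphere, sensors)
      if (is_null) Lj <- permute_leadfield_rows(Lj, config$null_seed)
      fit <- invert(data, Lj, method = method, config = config)
      vals <- vapply(metrics, function(m) {
        switch(m,
          free_energy = fit$F,
          r2 = variance_explained(Y, fit$Yhat),
          cv_error = cross_validation_error(
            data, Lj, method = method,
            n_runs = config$cv_runs %||% 10L,
            holdout_frac = config$cv_frac %||% 0.1,
            seed = config$cv_seed %||% 1L, config = config),
          gamma_max = normalized_projected_power(
            lcmv_weights(Lj, data_covariance(Y)),
            data_covariance(Y), fit$Qe_scale)$gamma_max
        )
      }, numeric(1))
      list(distortion = dist_j, values = vals)
    }, error = function(e) {
      list(distortion = NA_real_,
           values = stats::setNames(rep(NA_real_, length(metrics)), metrics))
    })
    tibble::tibble(
      step = j, distortion_mm = res$distortion, metric = metrics,
      value = unname(res$values), method = method,
      trajectory_seed = trajectory$sign_vector$seed, is_null = is_null
    )
  })
  dplyr::bind_rows(rows)
}

#' Distortion at the metric peak of a curve
#'
#' Finds the surface with the best metric value (maximum, or minimum for
#' `cv_error`, which is the only lower-is-better metric) and returns its
#' distortion in millimetres. Ties are broken toward smaller distortion.
#'
#' @param curve a tibble with columns `distortion_mm`, `value`, and
#'   optionally `metric` (a single metric).
#' @return peak distortion (mm, scalar).
#' @export
find_peak <- function(curve) {
  stopifnot(all(c("distortion_mm", "value") %in% names(curve)))
  metric <- if ("metric" %in% names(curve)) unique(curve$metric) else "free_energy"
  if (length(metric) != 1L) stop("find_peak expects a single-metric curve")
  v <- curve$value
  d <- curve$distortion_mm
  keep <- is.finite(v) & is.finite(d)
  if (!any(keep)) stop("no finite metric values in curve")
  v <- v[keep]; d <- d[keep]
  if (metric == "cv_error") v <- -v
  best <- v == max(v)
  min(d[best])
}

#' Distortion score over trajectory seeds
#'
#' Per-seed metric curves are reduced to their peak distortions; the score
#' for a method/metric pair is the arithmetic mean of those peaks. Zero is
#' perfect anatomical selectivity.
#'
#' @param curves a tibble of [sweep_trajectory()] rows over one or more
#'   trajectory seeds (one method, one metric).
#' @return a tibble with `method`, `metric`, `is_null`, `n_seeds`,
#'   `peaks` (list column of per-seed peak distortions), `score_mm`.
#' @export
distortion_score <- function(curves) {
  curves |>
    dplyr::group_by(.data$method, .data$metric, .data$is_null) |>
    dplyr::group_modify(function(df, key) {
      pk <- df |>
        dplyr::group_by(.data$trajectory_seed) |>
        dplyr::group_map(~ find_peak(.x)) |>
        unlist()
      tibble::tibble(n_seeds = length(pk), peaks = list(pk),
                     score_mm = mean(pk))
    }) |>
    dplyr::ungroup()
}

#' Permuted-lead-field null distortion scores
#'
#' Runs the identical sweep-and-score pipeline with every lead field
#' row-permuted (a fresh permutation seed per null run), yielding the
#' chance distribution of distortion scores for matched data.
#'
#' @param data `evoked` data.
#' @param true_mesh,basis,sensors as in [sweep_trajectory()].
#' @param trajectories list of `trajectory` objects (the seeds).
#' @param method,metric scheme and single metric.
#' @param n_null_seeds number of null runs (default 4).
#' @param config passed through.
#' @return a tibble of [distortion_score()] rows, one per null run, with
#'   `null_seed`.
#' @export
null_scores <- function(data, true_mesh, basis, trajectories,
                        method = "EBB", metric = "free_energy",
                        n_null_seeds = 4L, config = list()) {
  purrr::map_dfr(seq_len(n_null_seeds), function(k) {
    cfg <- config
    cfg$null_seed <- 1000L + k
    curves <- purrr::map_dfr(trajectories, function(tr) {
      sweep_trajectory(data, true_mesh, basis, tr, sensors = sensors_arg(
        true_mesh, config), method = method, metrics = metric, config = cfg)
    })
    distortion_score(curves) |>
      dplyr::mutate(null_seed = 1000L + k)
  })
}

# null_scores needs the sensor array; accept it through config to keep the
# exported signature close to the sweep's
sensors_arg <- function(true_mesh, config) {
  if (inherits(config$sensors, "sensor_array")) return(config$sensors)
  stop("pass the sensor array as config$sensors")
}

#' Paired one-tailed t-test between score sets
#'
#' Compares two matched sets of distortion scores (e.g. one per dataset)
#' with a paired t-test, `df = n - 1`. A zero-variance difference vector is
#' guarded: the statistic is returned as a large finite value with the
#' appropriate sign and a degenerate p-value.
#'
#' @param scores_a,scores_b numeric vectors of equal length (paired).
#' @param alternative "less" (default: A < B), "greater", or "two.sided".
#' @return a tibble with `t`, `df`, `p_value`, `mean_diff`.
#' @export
compare_scores <- function(scores_a, scores_b,
                           alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(scores_a) != length(scores_b)) stop("paired samples differ in length")
  d <- scores_a - scores_b
  n <- length(d)
  if (n < 2L) stop("need at least two pairs")
  sdd <- stats::sd(d)
  if (sdd == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * 1e12
  } else {
    t_stat <- mean(d) / (sdd / sqrt(n))
  }
  df <- n - 1
  p <- switch(alternative,
    less = stats::pt(t_stat, df),
    greater = stats::pt(t_stat, df, lower.tail = FALSE),
    two.sided = 2 * stats::pt(-abs(t_stat), df)
  )
  tibble::tibble(t = t_stat, df = df, p_value = p, mean_diff = mean(d))
}

#' Run the full distortion benchmark
#'
#' The factorial experiment: for each simulated dataset, each inversion
#' scheme, and each fit metric, sweep the evoked data across all
#' distortion trajectories, convert metric peaks to millimetres, and
#' (optionally) repeat with permuted-lead-field nulls for the chance
#' level. Everything is derived from one master seed, so a rerun is
#' bit-identical.
#'
#' @param config a benchmark configuration from [default_config()] /
#'   [load_config()], or a list of overrides to the defaults.
#' @return a list of class `benchmark_result`: `curves` (tidy per-step
#'   table), `scores` ([distortion_score()] rows per dataset x method x
#'   metric, veridical and null), `summary` (mean score per method x
#'   metric with chance level), `config`.
#' @export
run_benchmark <- function(config = list()) {
  cfg <- if (inherits(config, "megdistort_config")) config else
    default_config(config)
  fx <- generate_fixtures(master_seed = cfg$master_seed, preset = cfg$preset,
                          dir = NULL)
  mesh0 <- fx$mesh
  basis <- fx$basis
  sensors <- fx$sensors
  sphere <- fit_sphere(mesh0)
  L0 <- compute_leadfield(mesh0, sphere, sensors)
  trajs <- lapply(cfg$trajectory_seeds, function(s) {
    make_trajectory(make_sign_vector(s, K = cfg$K,
                                     size_components = cfg$size_components),
                    Z = cfg$Z, N = cfg$N)
  })
  datasets <- lapply(seq_len(cfg$n_datasets), function(d) {
    sp <- sim_spec(vertex = fx$dataset_vertices[d],
                   freq_hz = cfg$freq_hz[(d - 1) %% length(cfg$freq_hz) + 1],
                   n_trials = cfg$n_trials, snr_db = cfg$snr_db,
                   seed = cfg$master_seed * 100L + d)
    simulate_evoked(mesh0, L0, sp)
  })

  inv_cfg <- list(cv_runs = cfg$cv_runs, cv_frac = cfg$cv_frac,
                  mesh = mesh0, Np = cfg$gs_np,
                  sigma_patch = cfg$gs_sigma_patch)

  grid <- tidyr::expand_grid(dataset = seq_len(cfg$n_datasets),
                             method = cfg$methods)
  curves <- purrr::pmap_dfr(grid, function(dataset, method) {
    purrr::map_dfr(trajs, function(tr) {
      sweep_trajectory(datasets[[dataset]], mesh0, basis, tr, sensors,
                       method = method, metrics = cfg$metrics,
                       config = inv_cfg) |>
        dplyr::mutate(dataset = dataset)
    })
  })
  scores <- curves |>
    dplyr::group_by(.data$dataset) |>
    dplyr::group_modify(function(df, key) {
      df |>
        dplyr::group_split(.data$metric) |>
        purrr::map_dfr(distortion_score)
    }) |>
    dplyr::ungroup()

  null_rows <- NULL
  if (cfg$n_null_seeds > 0) {
    ncfg <- inv_cfg
    ncfg$sensors <- sensors
    null_rows <- purrr::map_dfr(seq_len(cfg$n_datasets), function(d) {
      null_scores(datasets[[d]], mesh0, basis, trajs,
                  method = cfg$null_method, metric = cfg$null_metric,
                  n_null_seeds = cfg$n_null_seeds, config = ncfg) |>
        dplyr::mutate(dataset = d)
    })
  }

  summary <- scores |>
    dplyr::group_by(.data$method, .data$metric) |>
    dplyr::summarise(mean_score_mm = mean(.data$score_mm),
                     se_score_mm = stats::sd(.data$score_mm) /
                       sqrt(dplyr::n()),
                     .groups = "drop")
  if (!is.null(null_rows)) {
    summary$chance_mm <- mean(null_rows$score_mm)
  }
  structure(
    list(curves = curves, scores = scores, null_scores = null_rows,
         summary = summary, config = cfg),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$summary)
  invisible(x)
}
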