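#' Variance explained by predicted sensor data
#'
#' Residual-based coefficient of determination between measured and
#' predicted sensor data:
#' \deqn{R^2 = (SST - SSR)/SST,\quad
#'   SSR = \|Y - \hat Y\|_F^2,\quad SST = \|Y\|_F^2.}
#' Reported as computed, so a prediction worse than zero gives a negative
#' value.
#'
#' @param Y measured data (`Nc x Nt` or `evoked`).
#' @param Yhat predicted data, same shape.
#' @return scalar R-squared (fraction).
#' @export
variance_explained <- function(Y, Yhat) {
  Y <- if (inherits(Y, "evoked")) Y$Y else as.matrix(Y)
  Yhat <- as.matrix(Yhat)
  if (any(!is.finite(Y)) || any(!is.finite(Yhat))) {
    stop("non-finite values in data or prediction")
  }
  if (!all(dim(Y) == dim(Yhat))) stop("Y and Yhat must have the same shape")
  sst <- sum(Y^2)
  if (sst == 0) stop("zero total sum of squares")
  ssr <- sum((Y - Yhat)^2)
  (sst - ssr) / sst
}

#' Channel-hold-out cross-validation error
#'
#' Repeatedly holds out a random fraction of MEG channels, re-runs the full
#' inversion (hyperparameter optimization included) on the remaining
#' channels, predicts the held-out channels through their lead-field rows
#' and the estimated currents, and reports the RMS prediction error in
#' femtotesla:
#' per run, \eqn{\mathrm{CV} = \frac{1}{N_c'} \sum_i
#' \sqrt{\frac{1}{N_t}\sum_t (y_{it} - \hat y_{it})^2}}, averaged over
#' runs. Channel draws are without replacement and independent across runs.
#'
#' @param data `evoked` or `Nc x Nt` matrix (fT).
#' @param leadfield `leadfield` or gain matrix.
#' @param method inversion scheme (see [invert()]).
#' @param n_runs number of hold-out repetitions (default 10).
#' @param holdout_frac fraction of channels held out per run (default
#'   0.1).
#' @param seed integer seed for the channel draws.
#' @param config passed to [invert()].
#' @return mean CV error in fT (scalar).
#' @export
cross_validation_error <- function(data, leadfield, method = "EBB",
                                   n_runs = 10L, holdout_frac = 0.1,
                                   seed = 1L, config = list()) {
  Y <- get_sensor_matrix(data)
  L <- get_gain_matrix(leadfield)
  nc <- nrow(L)
  n_out <- max(1L, floor(holdout_frac * nc))
  if (n_out >= nc) stop("holdout fraction leaves no training channels")
  draws <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_runs), function(i) sort(sample.int(nc, n_out)))
  })
  errs <- vapply(draws, function(ho) {
    keep <- setdiff(seq_len(nc), ho)
    fit <- invert(Y[keep, , drop = FALSE], L[keep, , drop = FALSE],
                  method = method, config = config)
    pred <- L[ho, , drop = FALSE] %*% fit$J
    cv_rms(Y[ho, , drop = FALSE], pred)
  }, numeric(1))
  mean(errs)
}

# per-channel RMS prediction error, averaged over channels (fT)
cv_rms <- function(Y, Yhat) {
  mean(sqrt(rowMeans((Y - Yhat)^2)))
}

#' Maximum normalized projected power
#'
#' For each source, the ratio of data power to noise power projected
#' through that source's spatial filter:
#' \deqn{\Gamma_\theta = \frac{w_\theta^T \Sigma_Y w_\theta}
#'   {w_\theta^T \Sigma_\epsilon w_\theta},}
#' maximized over sources. Correct source models concentrate data power in
#' few filters, so the maximum grows when the anatomy matches the data.
#'
#' @param W `Nc x Nv` weight matrix (e.g. [lcmv_weights()]).
#' @param SigmaY data covariance.
#' @param Sigma_eps sensor noise covariance (matrix or scalar times
#'   identity).
#' @return a list with `gamma_max`, `which_max` (source index, first index
#'   on ties), and `gamma` (per-source vector).
#' @export
normalized_projected_power <- function(W, SigmaY, Sigma_eps) {
  W <- as.matrix(W)
  SigmaY <- as.matrix(SigmaY)
  nc <- nrow(W)
  if (!is.matrix(Sigma_eps)) Sigma_eps <- diag(as.numeric(Sigma_eps), nc)
  num <- colSums(W * (SigmaY %*% W))
  den <- colSums(W * (Sigma_eps %*% W))
  if (any(den == 0)) stop("zero projected noise power for some source")
  gamma <- unname(num / den)
  i <- which.max(gamma)
  list(gamma_max = gamma[i], which_max = i, gamma = gamma)
}
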