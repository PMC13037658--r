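#' Sensor-level data covariance
#'
#' \eqn{\Sigma_Y = Y Y^T / N_t}: the second-moment matrix of the evoked
#' sensor data over time samples.
#'
#' @param data an `evoked` object or an `Nc x Nt` numeric matrix (fT).
#' @return `Nc x Nc` symmetric PSD matrix.
#' @export
data_covariance <- function(data) {
  Y <- get_sensor_matrix(data)
  tcrossprod(Y) / ncol(Y)
}

get_sensor_matrix <- function(data) {
  if (inherits(data, "evoked")) return(data$Y)
  Y <- as.matrix(data)
  if (!is.numeric(Y) || ncol(Y) < 2L) stop("need an Nc x Nt matrix, Nt >= 2")
  if (any(!is.finite(Y))) stop("non-finite sensor data")
  Y
}

#' Restricted-maximum-likelihood covariance component estimation
#'
#' Fits the scale hyperparameters of a linear covariance model
#' \eqn{\Sigma(\lambda) = \sum_k e^{\lambda_k} Q_k} to a sensor data
#' covariance by maximizing the negative variational free energy
#' \deqn{F = -\tfrac{N_t}{2}\log|\Sigma|
#'       - \tfrac{N_t}{2}\mathrm{tr}(\Sigma_Y \Sigma^{-1})
#'       - \tfrac{N_t N_c}{2}\log 2\pi
#'       - \tfrac12 (\hat\lambda - v)^T \Pi (\hat\lambda - v)
#'       - \tfrac12 \log|\Sigma_\lambda \Pi|,}
#' where the hyperparameters carry Gaussian prior
#' \eqn{N(v, \Pi^{-1})} and Gaussian posterior
#' \eqn{N(\hat\lambda, \Sigma_\lambda)}. The first three terms are exactly
#' the Gaussian log likelihood of the time samples under \eqn{\Sigma};
#' the last two are the hyperparameter complexity penalty and the Occam
#' (volume) term.
#'
#' Optimization is Fisher scoring on the log-scale hyperparameters with
#' Levenberg-Marquardt damping: steps that would decrease the objective are
#' rejected and retried with stronger damping. \eqn{\Sigma_\lambda} is the
#' inverse of the expected curvature plus prior precision at the optimum.
#'
#' @param SigmaY `Nc x Nc` data covariance.
#' @param components list of `Nc x Nc` PSD component matrices (at least one
#'   sensor noise component).
#' @param Nt number of time samples behind `SigmaY`.
#' @param hyperpriors list with `v` (prior mean, scalar or vector, default
#'   0) and `Pi` (prior precision, scalar or matrix, default 1/256).
#' @param max_iter maximum Fisher-scoring iterations (default 128).
#' @param tol_F convergence threshold on the change in objective
#'   (default 0.01).
#' @return an object of class `hyper_posterior`: `lambda` (log-scale
#'   estimates), `scales` (`exp(lambda)`), `Sigma_lambda`, `F`, `F_terms`
#'   (named breakdown: `logdet`, `trace`, `const`, `prior`, `occam`),
#'   `Sigma` (fitted model covariance), `converged`, `n_iter`.
#' @export
reml_optimize <- function(SigmaY, components, Nt, hyperpriors = NULL,
                          max_iter = 128L, tol_F = 0.01) {
  SigmaY <- as.matrix(SigmaY)
  nc <- nrow(SigmaY)
  nk <- length(components)
  if (nk < 1L) stop("need at least one covariance component")
  components <- lapply(components, function(q) {
    q <- as.matrix(q)
    if (!all(dim(q) == nc)) stop("component dimension mismatch")
    q
  })
  hp <- hyperpriors %||% list()
  v <- rep_len(hp$v %||% 0, nk)
  Pi <- hp$Pi %||% (1 / 256)
  if (is.null(dim(Pi))) Pi <- diag(rep_len(Pi, nk), nk)

  lam <- v
  damping <- 1e-8
  obj_prev <- -Inf
  converged <- FALSE
  iter_used <- 0L

  eval_state <- function(lam) {
    scl <- exp(pmin(pmax(lam, -32), 32))
    Sigma <- Reduce(`+`, Map(function(s, q) s * q, scl, components))
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    P <- chol2inv(ch)
    logdet <- 2 * sum(log(diag(ch)))
    ll <- -Nt / 2 * logdet - Nt / 2 * sum(P * SigmaY) -
      Nt * nc / 2 * log(2 * pi)
    prior <- -0.5 * as.numeric(crossprod(lam - v, Pi %*% (lam - v)))
    list(scl = scl, Sigma = Sigma, P = P, logdet = logdet,
         obj = ll + prior, ll = ll, prior = prior)
  }

  st <- eval_state(lam)
  if (is.null(st)) stop("initial covariance model is not positive definite")

  for (iter in seq_len(max_iter)) {
    iter_used <- iter
    # gradient and expected curvature at current lambda
    PQ <- lapply(seq_len(nk), function(k) st$P %*% (st$scl[k] * components[[k]]))
    A <- st$P %*% SigmaY %*% st$P
    g <- vapply(seq_len(nk), function(k) {
      -Nt / 2 * sum(diag(PQ[[k]])) +
        Nt / 2 * sum(A * t(st$scl[k] * components[[k]]))
    }, numeric(1)) - as.vector(Pi %*% (lam - v))
    H <- matrix(0, nk, nk)
    for (k in seq_len(nk)) {
      for (l in k:nk) {
        H[k, l] <- H[l, k] <- Nt / 2 * sum(PQ[[k]] * t(PQ[[l]]))
      }
    }
    H <- H + Pi

    accepted <- FALSE
    for (try in 1:16) {
      Hd <- H + damping * diag(pmax(diag(H), 1e-8), nk)
      step <- tryCatch(solve(Hd, g), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- eval_state(lam + step)
        if (!is.null(cand) && cand$obj >= st$obj - 1e-12) {
          lam <- lam + step
          st <- cand
          damping <- max(damping / 4, 1e-10)
          accepted <- TRUE
          break
        }
      }
      damping <- damping * 8
    }
    if (!accepted) break
    if (abs(st$obj - obj_prev) < tol_F) {
      converged <- TRUE
      obj_prev <- st$obj
      break
    }
    obj_prev <- st$obj
  }

  # posterior covariance of hyperparameters at the optimum
  PQ <- lapply(seq_len(nk), function(k) st$P %*% (st$scl[k] * components[[k]]))
  H <- matrix(0, nk, nk)
  for (k in seq_len(nk)) {
    for (l in k:nk) {
      H[k, l] <- H[l, k] <- Nt / 2 * sum(PQ[[k]] * t(PQ[[l]]))
    }
  }
  H <- H + Pi
  Sigma_lambda <- tryCatch(solve(H), error = function(e) {
    solve(H + 1e-8 * diag(nk))
  })

  occam <- -0.5 * as.numeric(determinant(Sigma_lambda %*% Pi,
                                         logarithm = TRUE)$modulus)
  F_terms <- c(
    logdet = -Nt / 2 * st$logdet,
    trace = -Nt / 2 * sum(st$P * SigmaY),
    const = -Nt * nc / 2 * log(2 * pi),
    prior = st$prior,
    occam = occam
  )
  structure(
    list(lambda = lam, scales = st$scl, Sigma_lambda = Sigma_lambda,
         F = sum(F_terms), F_terms = F_terms, Sigma = st$Sigma,
         converged = converged, n_iter = iter_used,
         warning_flag = !converged),
    class = "hyper_posterior"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior mean current estimate
#'
#' The conditional expectation of the source currents under the linear
#' Gaussian model with source covariance `Qa` and sensor noise covariance
#' `Qe`:
#' \deqn{\hat J = Q_a L^T (L Q_a L^T + Q_e)^{-1} Y,}
#' computed with a symmetric linear solve (no explicit inverse).
#'
#' @param Y `Nc x Nt` sensor data (or `evoked`).
#' @param L `Nc x Nv` lead-field matrix (or `leadfield`).
#' @param Qa source covariance: a length-`Nv` vector (diagonal), an
#'   `Nv x Nv` matrix, or a low-rank `list(P, h)` meaning
#'   `P diag(h) t(P)`.
#' @param Qe sensor noise covariance: scalar (times identity) or matrix.
#' @return `Nv x Nt` matrix of current estimates (nAm).
#' @export
compute_posterior <- function(Y, L, Qa, Qe) {
  Y <- if (inherits(Y, "evoked")) Y$Y else as.matrix(Y)
  L <- get_gain_matrix(L)
  nc <- nrow(L)
  Sigma <- model_covariance(L, Qa, Qe)
  x <- tryCatch(
    solve(Sigma, Y),
    error = function(e) {
      stop("model sensor covariance is singular (rank deficient): ",
           conditionMessage(e))
    }
  )
  qa_lt_x(L, Qa, x)
}

get_gain_matrix <- function(L) {
  if (inherits(L, "leadfield")) return(L$matrix)
  as.matrix(L)
}

model_covariance <- function(L, Qa, Qe) {
  nc <- nrow(L)
  S <- if (is.list(Qa)) {
    M <- L %*% Qa$P
    M %*% (Qa$h * t(M))
  } else if (is.matrix(Qa)) {
    L %*% Qa %*% t(L)
  } else {
    sweep(L, 2, as.numeric(Qa), `*`) %*% t(L)
  }
  if (is.matrix(Qe)) S + Qe else S + diag(as.numeric(Qe), nc)
}

qa_lt_x <- function(L, Qa, x) {
  if (is.list(Qa)) {
    M <- L %*% Qa$P
    Qa$P %*% (Qa$h * crossprod(M, x))
  } else if (is.matrix(Qa)) {
    Qa %*% crossprod(L, x)
  } else {
    as.numeric(Qa) * crossprod(L, x)
  }
}

#' IID (minimum norm) source prior
#'
#' A single diagonal source variance component with identical weight at
#' every source: no location is favoured, and the free-energy optimization
#' of its scale against the sensor noise component plays the role of
#' Tikhonov regularization in the classical minimum-norm solution.
#'
#' @param Nv number of sources.
#' @return a `covariance_component` (diagonal, unit weights).
#' @export
prior_iid <- function(Nv) {
  new_source_component(rep(1, Nv), "IID")
}

new_source_component <- function(q, label) {
  structure(list(domain = "source", type = "diag", q = as.numeric(q),
                 label = label),
            class = "covariance_component")
}

#' Empirical Bayes beamformer source prior
#'
#' Diagonal source variances from beamformer power estimates under
#' unit-gain, uncorrelated-source assumptions:
#' \eqn{q_i = (\tilde l_i^T \Sigma_Y^{-1} \tilde l_i)^{-1}} with
#' column-normalized lead fields \eqn{\tilde l_i = l_i / \|l_i\|}. A small
#' ridge (fraction of the mean diagonal) stabilizes the covariance inverse,
#' and the component is rescaled to unit trace so that its overall scale is
#' left to the free-energy optimization.
#'
#' @param L lead field (`leadfield` or matrix).
#' @param SigmaY data covariance.
#' @param ridge ridge fraction of the mean diagonal (default 1e-6).
#' @return a `covariance_component` (diagonal).
#' @export
prior_ebb <- function(L, SigmaY, ridge = 1e-6) {
  L <- get_gain_matrix(L)
  SigmaY <- as.matrix(SigmaY)
  nc <- nrow(SigmaY)
  Sr <- SigmaY + diag(ridge * mean(diag(SigmaY)), nc)
  ch <- tryCatch(chol(Sr), error = function(e) {
    stop("data covariance is rank deficient even after ridge")
  })
  Sinv <- chol2inv(ch)
  cn <- sqrt(colSums(L^2))
  if (any(cn == 0)) stop("zero lead-field column")
  Lt <- sweep(L, 2, cn, `/`)
  q <- 1 / colSums(Lt * (Sinv %*% Lt))
  new_source_component(q / sum(q), "EBB")
}

#' Cortical patch prior library for greedy search
#'
#' `Np` patch seed vertices are chosen quasi-uniformly over the mesh by
#' farthest-point sampling on graph geodesic distance (first seed drawn by
#' the given seed, the rest deterministic). Each patch profile decays
#' exponentially with geodesic distance from its seed with length scale
#' `sigma_patch`, giving a rank-1 source covariance per patch.
#'
#' @param mesh source `mesh`.
#' @param Np number of patches (default 64).
#' @param sigma_patch geodesic decay length in mm (default 10).
#' @param seed integer seed for the initial sample.
#' @return an object of class `patch_library`: `seeds` (vertex indices),
#'   `profiles` (`Nv x Np`, each column max 1 at its seed), `sigma_patch`.
#' @export
make_patch_library <- function(mesh, Np = 64L, sigma_patch = 10, seed = 1L) {
  stopifnot(inherits(mesh, "mesh"))
  Np <- as.integer(Np)
  nv <- n_vertices(mesh)
  if (Np < 1L || Np > nv) stop("Np must be in 1..Nv")
  g <- mesh_graph(mesh)
  first <- withr::with_seed(as.integer(seed), sample.int(nv, 1))
  seeds <- integer(Np)
  seeds[1] <- first
  if (Np > 1L) {
    dmin <- as.vector(igraph::distances(g, v = first))
    for (k in 2:Np) {
      nxt <- which.max(dmin)  # ties: first index wins
      seeds[k] <- nxt
      dmin <- pmin(dmin, as.vector(igraph::distances(g, v = nxt)))
    }
  }
  d <- t(igraph::distances(g, v = seeds))  # Nv x Np
  profiles <- exp(-d / sigma_patch)
  structure(
    list(seeds = seeds, profiles = profiles, sigma_patch = sigma_patch,
         seed = as.integer(seed)),
    class = "patch_library"
  )
}

#' LCMV beamformer weights
#'
#' Unit-gain spatial filters \eqn{w_i = \Sigma_Y^{-1} l_i
#' (l_i^T \Sigma_Y^{-1} l_i)^{-1}}: each column minimizes projected output
#' variance subject to passing a unit source at its own location. A ridge
#' (fraction of the mean diagonal) regularizes the covariance inverse.
#'
#' @param L lead field (`leadfield` or matrix).
#' @param SigmaY data covariance.
#' @param regularization ridge fraction of the mean diagonal (default
#'   0.05).
#' @return `Nc x Nv` weight matrix (column i maps sensor data to source
#'   i).
#' @export
lcmv_weights <- function(L, SigmaY, regularization = 0.05) {
  L <- get_gain_matrix(L)
  SigmaY <- as.matrix(SigmaY)
  nc <- nrow(SigmaY)
  Sr <- SigmaY + diag(regularization * mean(diag(SigmaY)), nc)
  Sinv <- chol2inv(chol(Sr))
  SL <- Sinv %*% L
  denom <- colSums(L * SL)
  if (any(denom <= 0)) stop("non-positive beamformer denominator")
  sweep(SL, 2, denom, `/`)
}
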