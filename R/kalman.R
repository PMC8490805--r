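# Continuous-discrete Kalman filter: continuous mean/covariance propagation
# between irregularly spaced observations, discrete measurement updates at
# the observation instants.

symmetrize <- function(S) (S + t(S)) / 2

#' Observation model
#'
#' Linear observation \eqn{z(t_n) = H x(t_n) + v(t_n)} with
#' \eqn{v \sim N(0, R_{obs})}, sampled at discrete, not necessarily equally
#' spaced, instants.
#'
#' @param H p x n selection/weighting matrix.
#' @param R_obs p x p symmetric positive-definite observation-noise
#'   covariance; a scalar or vector is expanded to a diagonal.
#' @return An `observation_model`.
#' @export
observation_model <- function(H, R_obs) {
  H <- as.matrix(H)
  if (!is.matrix(R_obs)) R_obs <- diag(rep_len(as.numeric(R_obs), nrow(H)),
                                       nrow(H))
  if (nrow(R_obs) != nrow(H)) stop("R_obs dimension must match rows of H")
  if (max(abs(R_obs - t(R_obs))) > 1e-10) stop("R_obs must be symmetric")
  if (min(eigen(symmetrize(R_obs), symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("R_obs must be positive definite")
  structure(list(H = H, R_obs = symmetrize(R_obs)), class = "observation_model")
}

#' Filter state (estimate and covariance at a time point)
#'
#' @param time Time stamp (minutes).
#' @param xhat State estimate vector.
#' @param Sigma Symmetric PSD covariance matrix; a scalar or vector is
#'   expanded to a diagonal.
#' @return A `filter_state`.
#' @export
filter_state <- function(time, xhat, Sigma) {
  xhat <- as.numeric(xhat)
  n <- length(xhat)
  if (!is.matrix(Sigma)) Sigma <- diag(rep_len(as.numeric(Sigma), n), n)
  if (nrow(Sigma) != n) stop("Sigma dimension must match xhat")
  Sigma <- symmetrize(as.matrix(Sigma))
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("Sigma must be positive semi-definite")
  structure(list(time = as.numeric(time), xhat = xhat, Sigma = Sigma),
            class = "filter_state")
}

# Van Loan discretization of (A, G Q G') over dt: returns the transition
# matrix Phi = exp(A dt) and the discrete process-noise covariance Qd.
van_loan <- function(A, GQGt, dt) {
  n <- nrow(A)
  M <- rbind(cbind(-A, GQGt), cbind(matrix(0, n, n), t(A))) * dt
  E <- mexp(M, 1)
  Phi <- t(E[n + seq_len(n), n + seq_len(n), drop = FALSE])
  Qd <- Phi %*% E[seq_len(n), n + seq_len(n), drop = FALSE]
  list(Phi = Phi, Qd = symmetrize(Qd))
}

# Cached discretization of dynamics over one step with constant input value.
discretize_dynamics <- function(dyn, uval, dt, cache = NULL) {
  b <- if (ncol(dyn$B) > 0L) as.numeric(dyn$B %*% uval) else numeric(nrow(dyn$A))
  key <- paste0(signif(dt, 15), "|", paste(signif(b, 15), collapse = ","))
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  st <- lti_step(dyn$A, b, dt)
  vl <- van_loan(dyn$A, dyn$G %*% dyn$Q %*% t(dyn$G), dt)
  out <- list(Phi = st$Phi, d = st$d, Qd = vl$Qd)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Propagate a filter state forward in time (no measurements)
#'
#' Between observations the conditional mean follows
#' \eqn{d\hat x/dt = A\hat x + Bu} and the covariance
#' \eqn{d\Sigma/dt = A\Sigma + \Sigma A^T + GQG^T}; both are advanced exactly
#' for piecewise-constant `u` via Van Loan discretization.
#'
#' @param fs A [filter_state()].
#' @param dyn A [linear_dynamics()].
#' @param u Input signal (`NULL`, constant vector, or `function(t)`), held at
#'   its value at `fs$time` over the step.
#' @param tau Target time, `tau >= fs$time`.
#' @return The propagated `filter_state` at `tau`.
#' @export
time_update <- function(fs, dyn, u, tau) {
  stopifnot(inherits(fs, "filter_state"), inherits(dyn, "linear_dynamics"))
  if (tau < fs$time) stop("tau must be >= current filter time")
  dt <- tau - fs$time
  if (dt == 0) return(fs)
  uf <- input_fun(u, ncol(dyn$B))
  dd <- discretize_dynamics(dyn, uf(fs$time), dt)
  xh <- as.numeric(dd$Phi %*% fs$xhat) + dd$d
  Sg <- symmetrize(dd$Phi %*% fs$Sigma %*% t(dd$Phi) + dd$Qd)
  filter_state(tau, xh, Sg)
}

#' Assimilate one observation into a filter state
#'
#' Standard Kalman measurement update with gain
#' \eqn{K = \Sigma H^T (H\Sigma H^T + R)^{-1}}, mean
#' \eqn{\hat x^+ = \hat x + K(z - H\hat x)} and Joseph-form covariance
#' \eqn{\Sigma^+ = (I-KH)\Sigma(I-KH)^T + KRK^T} (algebraically equal to
#' \eqn{(I-KH)\Sigma}, but PSD-safe).
#'
#' @param fs A `filter_state` whose time equals the observation time.
#' @param om An [observation_model()].
#' @param z Observation vector.
#' @return List with fields `state` (updated `filter_state`), `innovation`
#'   (`z - H xhat` under the prior) and `gain`.
#' @export
measurement_update <- function(fs, om, z) {
  stopifnot(inherits(fs, "filter_state"), inherits(om, "observation_model"))
  H <- om$H
  if (ncol(H) != length(fs$xhat)) stop("H dimension does not match state")
  z <- as.numeric(z)
  if (length(z) != nrow(H)) stop("observation dimension does not match H")
  S <- symmetrize(H %*% fs$Sigma %*% t(H) + om$R_obs)
  rc <- rcond(S)
  if (!is.finite(rc) || rc < 1e-14) stop("singular innovation covariance")
  K <- fs$Sigma %*% t(H) %*% solve(S)
  innov <- z - as.numeric(H %*% fs$xhat)
  xh <- fs$xhat + as.numeric(K %*% innov)
  IKH <- diag(1, length(fs$xhat)) - K %*% H
  Sg <- symmetrize(IKH %*% fs$Sigma %*% t(IKH) + K %*% om$R_obs %*% t(K))
  list(state = filter_state(fs$time, xh, Sg), innovation = innov, gain = K)
}

#' Run the continuous-discrete Kalman filter over an observation series
#'
#' Alternates [time_update()] to each observation instant with
#' [measurement_update()] there; spacing may be irregular.  If the initial
#' time coincides with the first observation, that observation is
#' assimilated directly.
#'
#' @param dyn A [linear_dynamics()].
#' @param om An [observation_model()].
#' @param series An [observation_series()] (fields `times`, `values`).
#' @param init Initial `filter_state` with `init$time <= series$times[1]`
#'   (any initial time is allowed when the series is empty).
#' @param u Input signal.
#' @return A `filtered_trajectory`: fields `times`, `xhat` (T x n posterior
#'   means), `Sigma` (n x n x T), `innovations` (T x p), `gains` (list),
#'   `loglik` (Gaussian innovation log-likelihood).
#' @export
run_filter <- function(dyn, om, series, init, u = NULL) {
  stopifnot(inherits(series, "observation_series"))
  Tn <- length(series$times)
  n <- length(init$xhat)
  if (Tn > 0 && init$time > series$times[1] + 1e-12)
    stop("init time must not exceed the first observation time")
  xhat <- matrix(NA_real_, Tn, n)
  Sig <- array(NA_real_, dim = c(n, n, Tn))
  innov <- matrix(NA_real_, Tn, nrow(om$H))
  gains <- vector("list", Tn)
  loglik <- 0
  fs <- init
  for (i in seq_len(Tn)) {
    fs <- time_update(fs, dyn, u, series$times[i])
    S <- symmetrize(om$H %*% fs$Sigma %*% t(om$H) + om$R_obs)
    up <- measurement_update(fs, om, series$values[i, ])
    loglik <- loglik - 0.5 * (length(up$innovation) * log(2 * pi) +
      determinant(S, logarithm = TRUE)$modulus[1] +
      sum(up$innovation * solve(S, up$innovation)))
    fs <- up$state
    xhat[i, ] <- fs$xhat
    Sig[, , i] <- fs$Sigma
    innov[i, ] <- up$innovation
    gains[[i]] <- up$gain
  }
  structure(list(times = series$times, xhat = xhat, Sigma = Sig,
                 innovations = innov, gains = gains, loglik = loglik,
                 final = fs), class = "filtered_trajectory")
}

#' Forecast the flow state over a horizon
#'
#' Repeated [time_update()] steps with no measurement updates; the covariance
#' is reported at every step, quantifying forecast uncertainty growth.
#'
#' @param fs Starting `filter_state`.
#' @param dyn A `linear_dynamics`.
#' @param u Input signal.
#' @param horizon Nonnegative horizon (minutes).
#' @param by Step size (minutes), default 1.
#' @return List of `filter_state` at times `fs$time + seq(0, horizon, by)`
#'   (including the start).
#' @export
forecast_flow <- function(fs, dyn, u = NULL, horizon, by = 1) {
  if (horizon < 0) stop("horizon must be >= 0")
  steps <- seq(0, horizon, by = by)
  if (steps[length(steps)] < horizon) steps <- c(steps, horizon)
  out <- vector("list", length(steps))
  out[[1]] <- fs
  for (i in seq_along(steps)[-1]) {
    fs <- time_update(fs, dyn, u, out[[1]]$time + steps[i])
    out[[i]] <- fs
  }
  out
}
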