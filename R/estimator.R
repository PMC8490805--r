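# Second estimation stage: recursive least squares on the rate-parameter
# perturbation, with exponential forgetting and Fisher-information dynamics.
#
# Continuous-time target dynamics (Psi is the N x r sensitivity matrix, y the
# state residual):
#   d(dk)/dt = P Psi' (y - Psi dk)
#   dP/dt    = a P - P Psi' Psi P
#   dR/dt    = -a R + Psi' Psi          (Fisher information, R = P^{-1})
# Discretization: exponential decay exp(-a dt) applied exactly, and the
# information increment Psi'Psi integrated by the trapezoidal rule split into
# two rank updates (previous regressor before the decay, current one after).
# The P-recursion and the Fisher recursion share the same increment, so
# P(t) R(t) = I holds exactly under matched initialization.

#' Estimator state for the rate-perturbation stage
#'
#' @param r Number of rate parameters.
#' @param a Forgetting rate (per minute, >= 0); past residuals are weighted
#'   by `exp(-a * age)`.
#' @param p0 Initial gain scale: `P(0) = p0 * I`.  The defining Fisher
#'   integral gives `R(0) = 0`, which leaves `P(0)` undefined; a large `p0`
#'   (default 1e4) encodes an almost-uninformative start.
#' @param fisher0 Initial Fisher matrix (default `diag(1/p0, r)`, matched to
#'   `P(0)` so that the P-R duality holds along the trajectory).
#' @param time Start time.
#' @return An `estimator_state` with fields `time`, `dk_hat`, `P`, `fisher`,
#'   `a`, `y`, `psi_prev`.
#' @export
estimator_state <- function(r, a = 0.1, p0 = 1e4, fisher0 = NULL, time = 0) {
  stopifnot(r >= 1L, a >= 0, p0 > 0)
  if (is.null(fisher0)) fisher0 <- diag(1 / p0, r)
  structure(list(time = time, dk_hat = numeric(r), P = diag(p0, r),
                 b = numeric(r), fisher = as.matrix(fisher0), a = a, y = NULL,
                 psi_prev = NULL, y_prev = NULL),
            class = "estimator_state")
}

#' Residual between filtered and simulated nominal state
#'
#' The discrepancy \eqn{y(t) = \hat\eta(t) - \eta_{model}(t)} between the
#' filter's state estimate and the nominal-parameter simulation, which the
#' perturbation model explains as \eqn{y \approx \Psi(t)\,\Delta k}.
#'
#' @param eta_hat Filtered state estimate at `t`.
#' @param eta_model Simulated nominal state at the same `t`.
#' @return Numeric residual vector.
#' @export
residual_signal <- function(eta_hat, eta_model) {
  eta_hat <- as.numeric(eta_hat); eta_model <- as.numeric(eta_model)
  if (length(eta_hat) != length(eta_model)) stop("dimension mismatch")
  eta_hat - eta_model
}

# Rank update adding weight w * Psi'Psi to the information matrix, applied to
# P by the Woodbury identity (keeps P symmetric PD).
info_update_P <- function(P, Psi, w) {
  if (w == 0 || all(Psi == 0)) return(P)
  Nn <- nrow(Psi)
  Sm <- diag(1 / w, Nn) + Psi %*% P %*% t(Psi)
  P2 <- P - P %*% t(Psi) %*% solve(Sm, Psi %*% P)
  symmetrize(P2)
}

est_core <- function(es, Psi, y, dt, do_rls = TRUE, do_fisher = TRUE) {
  stopifnot(inherits(es, "estimator_state"), dt > 0)
  Psi <- as.matrix(Psi)
  r <- length(es$dk_hat)
  if (ncol(Psi) != r) stop("Psi must have r columns")
  lam <- exp(-es$a * dt)
  Pp <- es$psi_prev
  if (is.null(Pp)) Pp <- matrix(0, nrow(Psi), r)
  if (!all(dim(Pp) == dim(Psi))) stop("regressor dimension changed mid-run")
  yp <- es$y_prev
  if (is.null(yp)) yp <- numeric(nrow(Psi))

  if (do_rls) {
    P <- es$P
    P <- info_update_P(P, Pp, dt / 2)
    P <- P / lam
    P <- info_update_P(P, Psi, dt / 2)
    ev <- eigen(P, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(abs(ev$values)))
      stop("gain matrix lost positive definiteness (degenerate regressors)")
    if (min(ev$values) <= 0)  # repair roundoff-level indefiniteness
      P <- symmetrize(ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors)))
    if (!is.null(y)) {
      y <- as.numeric(y)
      if (length(y) != nrow(Psi)) stop("residual dimension does not match Psi")
      # information vector accumulated with the same decay and trapezoid
      # weights as P^-1, so dk = P b minimizes the forgetting-weighted
      # least-squares criterion exactly at every step
      es$b <- lam * (es$b + (dt / 2) * as.numeric(crossprod(Pp, yp))) +
        (dt / 2) * as.numeric(crossprod(Psi, y))
      es$dk_hat <- as.numeric(P %*% es$b)
      es$y <- y
      es$y_prev <- y
    }
    es$P <- P
  }
  if (do_fisher) {
    es$fisher <- symmetrize(lam * (es$fisher + (dt / 2) * crossprod(Pp)) +
                              (dt / 2) * crossprod(Psi))
  }
  es$psi_prev <- Psi
  es$time <- es$time + dt
  es
}

#' One recursive-least-squares step with forgetting
#'
#' Advances the perturbation estimate and gain matrix by one step of the
#' forgetting-factor RLS dynamics (discrete forgetting factor
#' `lambda = exp(-a dt)`); converges to the continuous gradient-flow
#' equations as `dt -> 0`.
#'
#' @param es An [estimator_state()].
#' @param Psi N x r sensitivity matrix at the new time (columns are the
#'   per-parameter state sensitivities).
#' @param y Residual signal at the new time (see [residual_signal()]).
#' @param dt Positive time step (minutes).
#' @return Updated `estimator_state` (does not touch the Fisher matrix; see
#'   [estimator_step()] for the combined update).
#' @export
rls_step <- function(es, Psi, y, dt) est_core(es, Psi, y, dt, TRUE, FALSE)

#' One Fisher-information step
#'
#' Advances the Fisher matrix by \eqn{dR/dt = -aR + \Psi^T\Psi}: exact
#' exponential decay of the old information plus a trapezoidal increment of
#' the regressor outer product.
#'
#' @inheritParams rls_step
#' @return Updated `estimator_state` (Fisher field only).
#' @export
fisher_step <- function(es, Psi, dt) est_core(es, Psi, NULL, dt, FALSE, TRUE)

#' Combined RLS + Fisher update
#'
#' Applies [rls_step()] and [fisher_step()] as one consistent update sharing
#' a single information increment, which preserves the duality
#' `P(t) %*% fisher(t) = I` under matched initialization.
#'
#' @inheritParams rls_step
#' @return Updated `estimator_state`.
#' @export
estimator_step <- function(es, Psi, y, dt) est_core(es, Psi, y, dt, TRUE, TRUE)

#' Configuration for the two-stage estimator
#'
#' @param a Forgetting rate per minute (default 0.1).
#' @param p0 Initial RLS gain scale (default 1e4).
#' @param sigma0 Initial filter standard deviation per state (default 10).
#' @param refresh Refresh the nominal rates with the current perturbation
#'   estimate during the run (default `TRUE`).
#' @param burn_in_epochs Observation epochs before the first refresh and
#'   before identifiability is judged (default 60).
#' @param cadence Refresh every `cadence` epochs after burn-in (default 30).
#' @param eta0 Known initial state; if `NULL`, lifted from the first
#'   observation by pseudo-inverse of `H`.
#' @param q_process Process-noise intensity (diagonal of `Q`, default 1e-2).
#' @param u Input signal passed through to the integrators.
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(a = 0.1, p0 = 1e4, sigma0 = 10, refresh = TRUE,
                             burn_in_epochs = 60, cadence = 30, eta0 = NULL,
                             q_process = 1e-2, u = NULL) {
  structure(list(a = a, p0 = p0, sigma0 = sigma0, refresh = refresh,
                 burn_in_epochs = burn_in_epochs, cadence = cadence,
                 eta0 = eta0, q_process = q_process, u = u),
            class = "estimator_config")
}

#' Two-stage joint state and rate-parameter estimation
#'
#' Implements the recursive two-stage scheme.  Per observation epoch:
#' stage 1 advances the nominal-model state and its parameter sensitivities
#' exactly and runs the continuous-discrete Kalman filter to obtain the state
#' estimate; stage 2 forms the residual between the filtered and the
#' simulated state and feeds it, with the sensitivity matrix as regressor, to
#' the forgetting-factor RLS and the Fisher recursion.  With `refresh = TRUE`
#' the accumulated perturbation is folded into the nominal rates every
#' `cadence` epochs after burn-in (rates projected onto `k >= 0`), the model
#' state is rebased onto the filtered estimate and the sensitivities restart
#' from zero, so later epochs re-linearize about the improved rates.
#'
#' @param net A `flow_network`.
#' @param k_nominal Nominal rate parameters (the \eqn{\bar k} the
#'   perturbation is measured from).
#' @param series An [observation_series()] of node counts.
#' @param om An [observation_model()] over the network species.
#' @param cfg An [estimator_config()].
#' @return List with `k_hat` (data.frame: time plus one column per rate),
#'   `dk_hat` (matrix of perturbation estimates), `filter` (posterior means),
#'   `estimator` (final `estimator_state`), and `diagnostics`
#'   (`trace_P`, `fisher_rank`, `identifiable`, `innovations`).
#' @export
two_stage_estimate <- function(net, k_nominal, series, om, cfg = estimator_config()) {
  stopifnot(inherits(net, "flow_network"), inherits(series, "observation_series"),
            inherits(om, "observation_model"))
  kbar <- as_rate_values(k_nominal, net)
  r <- length(kbar)
  N <- length(net$species)
  Tn <- length(series$times)
  if (Tn < 2L) stop("need at least two observation epochs")
  if (ncol(om$H) != N) stop("observation model does not match the network")

  eta0 <- cfg$eta0
  if (is.null(eta0)) eta0 <- as.numeric(MASS::ginv(om$H) %*% series$values[1, ])

  k_cur <- kbar
  es <- estimator_state(r, a = cfg$a, p0 = cfg$p0, time = series$times[1])
  fs <- filter_state(series$times[1], eta0, diag(cfg$sigma0^2, N))
  up <- measurement_update(fs, om, series$values[1, ])
  fs <- up$state

  ss <- sensitivity_system(net, k_cur)
  dyn <- build_system_matrices(net, k_cur, Q = diag(cfg$q_process, N))
  uf <- input_fun(cfg$u, length(net$input_channels), series$times)

  xm <- c(numeric(N * r), eta0)   # joint [vec(Psi); eta_model]
  step_cache <- new.env(parent = emptyenv())
  filt_cache <- new.env(parent = emptyenv())

  k_hat <- matrix(NA_real_, Tn, r, dimnames = list(NULL, net$rate_names))
  dk_hat <- matrix(NA_real_, Tn, r, dimnames = list(NULL, net$rate_names))
  xhat <- matrix(NA_real_, Tn, N, dimnames = list(NULL, net$species))
  innov <- matrix(NA_real_, Tn, nrow(om$H))
  trace_P <- numeric(Tn)
  k_hat[1, ] <- k_cur; dk_hat[1, ] <- 0
  xhat[1, ] <- fs$xhat
  innov[1, ] <- up$innovation
  trace_P[1] <- sum(diag(es$P))

  for (n in 2:Tn) {
    dt <- series$times[n] - series$times[n - 1L]
    uval <- uf(series$times[n - 1L])

    # stage 1: nominal model + sensitivities (one exact joint step)
    b <- if (ss$m > 0L) as.numeric(ss$B %*% uval) else numeric(nrow(ss$M))
    key <- paste0(signif(dt, 15), "|", paste(signif(b, 15), collapse = ","))
    st <- step_cache[[key]]
    if (is.null(st)) { st <- lti_step(ss$M, b, dt); step_cache[[key]] <- st }
    xm <- as.numeric(st$Phi %*% xm) + st$d
    Psi <- matrix(xm[seq_len(N * r)], N, r)
    eta_model <- xm[N * r + seq_len(N)]

    # stage 1: filter
    bf <- if (ncol(dyn$B) > 0L) as.numeric(dyn$B %*% uval) else numeric(N)
    fkey <- paste0(signif(dt, 15), "|", paste(signif(bf, 15), collapse = ","))
    fst <- filt_cache[[fkey]]
    if (is.null(fst)) {
      fst <- c(lti_step(dyn$A, bf, dt),
               van_loan(dyn$A, dyn$G %*% dyn$Q %*% t(dyn$G), dt)["Qd"])
      filt_cache[[fkey]] <- fst
    }
    fs <- filter_state(series$times[n],
                       as.numeric(fst$Phi %*% fs$xhat) + fst$d,
                       symmetrize(fst$Phi %*% fs$Sigma %*% t(fst$Phi) + fst$Qd))
    up <- measurement_update(fs, om, series$values[n, ])
    fs <- up$state

    # stage 2
    y <- residual_signal(fs$xhat, eta_model)
    es <- estimator_step(es, Psi, y, dt)

    refreshed <- FALSE
    if (isTRUE(cfg$refresh) && n > cfg$burn_in_epochs &&
        ((n - cfg$burn_in_epochs) %% cfg$cadence == 0L)) {
      k_cur <- pmax(0, k_cur + es$dk_hat)
      es$dk_hat <- numeric(r)
      es$b <- numeric(r)
      es$psi_prev <- NULL
      es$y_prev <- NULL
      xm <- c(numeric(N * r), fs$xhat)
      ss <- sensitivity_system(net, k_cur)
      dyn <- build_system_matrices(net, k_cur, Q = diag(cfg$q_process, N))
      step_cache <- new.env(parent = emptyenv())
      filt_cache <- new.env(parent = emptyenv())
      refreshed <- TRUE
    }

    k_hat[n, ] <- pmax(0, k_cur + es$dk_hat)
    dk_hat[n, ] <- es$dk_hat
    xhat[n, ] <- fs$xhat
    innov[n, ] <- up$innovation
    trace_P[n] <- sum(diag(es$P))
  }

  fev <- eigen(es$fisher, symmetric = TRUE, only.values = TRUE)$values
  fr <- sum(fev > 1e-8 * max(fev, 0))
  structure(list(
    k_hat = data.frame(time = series$times, k_hat, check.names = FALSE),
    dk_hat = dk_hat,
    filter = list(times = series$times, xhat = xhat, final = fs),
    estimator = es,
    diagnostics = list(trace_P = trace_P, fisher_rank = fr,
                       identifiable = fr == r, innovations = innov)
  ), class = "two_stage_fit")
}

#' @export
print.two_stage_fit <- function(x, ...) {
  Tn <- nrow(x$k_hat)
  cat(sprintf("two-stage fit: %d epochs, %d rate parameters\n", Tn, ncol(x$dk_hat)))
  cat("final rate estimates:\n")
  print(unlist(x$k_hat[Tn, -1, drop = FALSE]))
  if (!x$diagnostics$identifiable)
    cat(sprintf("warning: Fisher information rank %d < %d (non-identifiable configuration)\n",
                x$diagnostics$fisher_rank, ncol(x$dk_hat)))
  invisible(x)
}
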