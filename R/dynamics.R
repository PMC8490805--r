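# Deterministic integration of the compartmental state ODE and its
# parameter-sensitivity ODEs.  All stepping is exact for piecewise-constant
# inputs: the state map uses the matrix exponential of an augmented
# [[A, Bu], [0, 0]] block, covariances (in the filter) use Van Loan's method.

# exp(M * dt) for a base matrix.
mexp <- function(M, dt = 1) {
  if (nrow(M) == 1L) return(matrix(exp(M[1, 1] * dt), 1, 1))
  unname(as.matrix(Matrix::expm(M * dt)))
}

# One exact step of dx/dt = A x + b (b constant): returns Phi and the
# displacement d with x(t+dt) = Phi x(t) + d.
lti_step <- function(A, b, dt) {
  n <- nrow(A)
  if (all(b == 0)) return(list(Phi = mexp(A, dt), d = numeric(n)))
  M <- rbind(cbind(A, b), 0)
  E <- mexp(M, dt)
  list(Phi = E[seq_len(n), seq_len(n), drop = FALSE], d = E[seq_len(n), n + 1L])
}

# Resolve a user-supplied input signal to a function(t) -> m-vector.
# Accepted forms: NULL (no input), a constant numeric vector, a function,
# or a matrix with one row per grid point (row i held on [t_i, t_{i+1})).
input_fun <- function(u, m, times = NULL) {
  if (m == 0L) return(function(t) numeric(0))
  if (is.null(u)) return(function(t) numeric(m))
  if (is.function(u)) return(u)
  if (is.matrix(u)) {
    stopifnot(!is.null(times), nrow(u) == length(times), ncol(u) == m)
    return(function(t) {
      i <- findInterval(t, times, rightmost.closed = FALSE)
      i <- min(max(i, 1L), nrow(u))
      as.numeric(u[i, ])
    })
  }
  uu <- rep_len(as.numeric(u), m)
  function(t) uu
}

check_grid <- function(times) {
  stopifnot(is.numeric(times), length(times) >= 1L)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  as.numeric(times)
}

#' Integrate the flow-state ODE on a time grid
#'
#' Solves \eqn{d\eta/dt = A\eta + Bu(t)} exactly per step for
#' piecewise-constant `u` (held at the left grid point), using the matrix
#' exponential of the augmented system.
#'
#' @param dyn A [linear_dynamics()] object.
#' @param eta0 Initial state vector.
#' @param u Input signal: `NULL`, a constant vector, a `function(t)`, or a
#'   matrix with one row per grid point.
#' @param times Strictly increasing numeric grid (minutes).
#' @return A `state_trajectory` with fields `times` and `states`
#'   (length(times) x N matrix).
#' @examples
#' net <- parse_rule_file("WAIT -> TRANSIT @ k1")
#' dyn <- build_system_matrices(net, c(k1 = 1))
#' tr <- integrate_state(dyn, c(1, 0), NULL, 0:5)
#' tr$states[2, 1]  # exp(-1)
#' @export
integrate_state <- function(dyn, eta0, u, times) {
  stopifnot(inherits(dyn, "linear_dynamics"))
  times <- check_grid(times)
  N <- nrow(dyn$A)
  if (length(eta0) != N) stop("eta0 has wrong dimension")
  uf <- input_fun(u, ncol(dyn$B), times)
  states <- matrix(NA_real_, length(times), N,
                   dimnames = list(NULL, dyn$state_labels))
  x <- as.numeric(eta0)
  states[1, ] <- x
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(length(times) - 1L)) {
    dt <- times[i + 1L] - times[i]
    b <- if (ncol(dyn$B) > 0L) as.numeric(dyn$B %*% uf(times[i])) else numeric(N)
    key <- paste0(signif(dt, 15), "|", paste(signif(b, 15), collapse = ","))
    st <- cache[[key]]
    if (is.null(st)) {
      st <- lti_step(dyn$A, b, dt)
      cache[[key]] <- st
    }
    x <- as.numeric(st$Phi %*% x) + st$d
    if (any(!is.finite(x))) stop("nonfinite state during integration")
    states[i + 1L, ] <- x
  }
  structure(list(times = times, states = states), class = "state_trajectory")
}

# Joint (r+1)N system matrix for state + all sensitivities:
# d/dt [vec(Psi); eta] with blocks I_r (x) A on the Psi rows, couplings
# dA_j eta, and A on the eta rows; input rows stack dB_j over B.
sensitivity_system <- function(net, kbar) {
  dyn <- build_system_matrices(net, kbar)
  jac <- rate_jacobians(net, kbar)
  N <- nrow(dyn$A); r <- length(jac); m <- ncol(dyn$B)
  M <- matrix(0, (r + 1L) * N, (r + 1L) * N)
  Bbig <- matrix(0, (r + 1L) * N, m)
  for (j in seq_len(r)) {
    rows <- (j - 1L) * N + seq_len(N)
    M[rows, rows] <- dyn$A
    M[rows, r * N + seq_len(N)] <- jac[[j]]$dA
    if (m > 0L) Bbig[rows, ] <- jac[[j]]$dB
  }
  erows <- r * N + seq_len(N)
  M[erows, erows] <- dyn$A
  if (m > 0L) Bbig[erows, ] <- dyn$B
  list(M = M, B = Bbig, N = N, r = r, m = m, dyn = dyn)
}

#' Integrate the parameter-sensitivity ODEs
#'
#' Computes \eqn{\psi_j(t) = \partial\eta(t,k)/\partial k_j} for all rates
#' jointly, from \eqn{d\psi_j/dt = A\psi_j + (\partial A/\partial k_j)\eta +
#' (\partial B/\partial k_j)u}, with \eqn{\psi_j(0) = 0}.  The state and all
#' sensitivities are advanced as one exact linear step, so the returned
#' sensitivities are consistent with [integrate_state()] at `kbar`.
#'
#' @param net A `flow_network`.
#' @param kbar Nominal rate parameters.
#' @param eta Optional `state_trajectory` computed at `kbar` on `times`;
#'   its first row provides the initial state.  Alternatively pass `eta0`.
#' @param u Input signal (see [integrate_state()]).
#' @param times Strictly increasing grid; must match `eta$times` if given.
#' @param eta0 Initial state, used when `eta` is `NULL`.
#' @return A `sensitivity_trajectory` with fields `times` and `psi`
#'   (N x r x length(times) array).
#' @export
integrate_sensitivities <- function(net, kbar, eta = NULL, u = NULL, times, eta0 = NULL) {
  times <- check_grid(times)
  if (!is.null(eta)) {
    stopifnot(inherits(eta, "state_trajectory"))
    if (length(eta$times) != length(times) || max(abs(eta$times - times)) > 1e-9)
      stop("grid mismatch between eta and times")
    eta0 <- eta$states[1, ]
  }
  if (is.null(eta0)) stop("either eta or eta0 must be supplied")
  ss <- sensitivity_system(net, kbar)
  N <- ss$N; r <- ss$r
  uf <- input_fun(u, ss$m, times)
  x <- c(numeric(N * r), as.numeric(eta0))
  psi <- array(0, dim = c(N, r, length(times)),
               dimnames = list(net$species, net$rate_names, NULL))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(length(times) - 1L)) {
    dt <- times[i + 1L] - times[i]
    b <- if (ss$m > 0L) as.numeric(ss$B %*% uf(times[i])) else numeric(nrow(ss$M))
    key <- paste0(signif(dt, 15), "|", paste(signif(b, 15), collapse = ","))
    st <- cache[[key]]
    if (is.null(st)) {
      st <- lti_step(ss$M, b, dt)
      cache[[key]] <- st
    }
    x <- as.numeric(st$Phi %*% x) + st$d
    psi[, , i + 1L] <- matrix(x[seq_len(N * r)], N, r)
  }
  structure(list(times = times, psi = psi), class = "sensitivity_trajectory")
}

#' Sensitivity-augmented dynamics for one rate parameter
#'
#' Stacks the sensitivity \eqn{\psi_j} over the state \eqn{\eta} into the 2N
#' system \eqn{dx = A_{aug} x\,dt + B_{aug} u\,dt + G\,dw} with the block
#' upper-triangular matrix `A_aug = [[A, dA_j], [0, A]]` and
#' `B_aug = [dB_j; B]`, suitable for joint filtering of state and
#' sensitivity.
#'
#' @param net A `flow_network`.
#' @param kbar Nominal rate parameters.
#' @param j Parameter index, `1 <= j <= r`.
#' @param G Noise-injection matrix for the augmented system (default: identity
#'   on the \eqn{\eta} rows, zero on the \eqn{\psi} rows).
#' @param Q Noise-intensity matrix (default `diag(q_default, ncol(G))`).
#' @param q_default Diagonal default for `Q`.
#' @return A `linear_dynamics` of dimension 2N; state labels are
#'   `psi.<species>` followed by the species.
#' @export
build_augmented_system <- function(net, kbar, j, G = NULL, Q = NULL, q_default = 1e-2) {
  stopifnot(inherits(net, "flow_network"))
  r <- length(net$rate_names)
  if (!(j >= 1L && j <= r)) stop("parameter index out of range")
  dyn <- build_system_matrices(net, kbar)
  jac <- rate_jacobians(net, kbar)[[j]]
  N <- nrow(dyn$A)
  Aaug <- rbind(cbind(dyn$A, jac$dA), cbind(matrix(0, N, N), dyn$A))
  Baug <- rbind(jac$dB, dyn$B)
  if (is.null(G)) G <- rbind(matrix(0, N, N), diag(1, N))
  if (is.null(Q)) Q <- diag(q_default, ncol(G))
  labels <- c(paste0("psi.", net$species), net$species)
  linear_dynamics(Aaug, Baug, G, Q, state_labels = labels,
                  input_labels = net$input_channels)
}
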