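#' One step of the modulated network dynamics
#'
#' Advances the latent population activity by the discrete update
#' \deqn{x_{t+1} = x_t + (W \odot \Gamma_i)\,\tanh(S \circ x_t + V) - D \circ x_t + C + \epsilon_t,}
#' where \eqn{\Gamma_i} is the modulation matrix of the active regime,
#' \eqn{S} is applied elementwise (excitatory slope on excitatory entries,
#' inhibitory slope on inhibitory entries) and \eqn{D} holds positive leak
#' magnitudes (see [mindy_params()] for the sign convention).
#'
#' @param x state vector of length n (finite).
#' @param params a [mindy_params()] bundle.
#' @param regime active regime index in \code{1..m}.
#' @param eps process noise vector (length n) or 0.
#' @return the next state vector.
#' @export
model_step <- function(x, params, regime = 1L, eps = 0) {
  x <- as.numeric(x)
  n <- n_populations(params)
  if (length(x) != n) stop("state length must equal n")
  if (!all(is.finite(x))) stop("state must be finite")
  regime <- as.integer(regime)
  if (regime < 1L || regime > length(params$gammas))
    stop("regime index out of range: ", regime)
  M <- effective_weights(params, regime)
  phi <- tanh(slope_vector(params) * x + params$V)
  x + as.numeric(M %*% phi) - params$D * x + params$C + eps
}

# W elementwise-scaled by the active regime's modulation
effective_weights <- function(params, regime) {
  g <- params$gammas[[regime]]
  assemble_W(params$W) * outer(g$u, g$v)
}

#' Jacobian of the state update at a linearization point
#'
#' Returns \eqn{\partial x_{t+1} / \partial x_t = I + (W \odot \Gamma_i)
#' \,\mathrm{diag}(s (1 - \tanh^2(s x + V))) - \mathrm{diag}(D)}, used by the
#' extended Kalman filter and by backpropagation through the rollout.
#'
#' @inheritParams model_step
#' @return n x n Jacobian matrix.
#' @export
dynamics_jacobian <- function(x, params, regime = 1L) {
  M <- effective_weights(params, regime)
  s <- slope_vector(params)
  phi <- tanh(s * as.numeric(x) + params$V)
  diag(nrow(M)) + M %*% diag(s * (1 - phi^2), nrow(M)) - diag(params$D)
}

#' Map latent activity to sensor observations
#'
#' Applies the lead field: \eqn{y_t = H x_t + \nu_t}. Because the lead-field
#' columns over inhibitory populations are zero, the observation is invariant
#' to any change confined to inhibitory state entries.
#'
#' @param x state vector of length n.
#' @param params a [mindy_params()] bundle.
#' @param nu measurement noise vector (length channels) or 0.
#' @return channel observation vector.
#' @export
model_observe <- function(x, params, nu = 0) {
  x <- as.numeric(x)
  if (length(x) != ncol(params$H))
    stop("state length must match the lead-field columns")
  as.numeric(params$H %*% x) + nu
}

#' Forward-simulate the modulated network
#'
#' Iterates [model_step()] and [model_observe()] along a given regime-label
#' sequence, drawing Gaussian process noise \eqn{\epsilon_t \sim N(0, Q)} and
#' measurement noise \eqn{\nu_t \sim N(0, R)} from a seeded generator. With
#' both covariances zero the trajectory is deterministic and identical across
#' seeds. The regime label at time \code{t} selects the modulation used for
#' the transition from \code{t} to \code{t+1}.
#'
#' @param params a [mindy_params()] bundle.
#' @param labels length-T integer regime sequence.
#' @param x0 initial state (default zeros).
#' @param seed integer seed for the noise draws (ignored when both
#'   covariances are zero); \code{NULL} leaves the RNG state alone.
#' @return list with \code{states} (n x T) and \code{y} (channels x T);
#'   \code{states[, t]} is the state at time t (\code{states[, 1] ==
#'   step(x0)}), and \code{y[, t] = H states[, t] + nu_t}.
#' @export
simulate_mindy <- function(params, labels, x0 = NULL, seed = NULL) {
  labels <- as.integer(labels)
  m <- length(params$gammas)
  if (any(labels < 1L | labels > m)) stop("regime labels out of range 1..m")
  n <- n_populations(params)
  nc <- nrow(params$H)
  T_len <- length(labels)
  if (is.null(x0)) x0 <- numeric(n)
  check_psd(params$Q, "Q"); check_psd(params$R, "R")

  if (!is.null(seed)) set.seed(seed)
  Lq <- psd_factor(params$Q)
  Lr <- psd_factor(params$R)
  eps <- if (is.null(Lq)) matrix(0, n, T_len) else
    Lq %*% matrix(stats::rnorm(n * T_len), n, T_len)
  nu <- if (is.null(Lr)) matrix(0, nc, T_len) else
    Lr %*% matrix(stats::rnorm(nc * T_len), nc, T_len)

  states <- matrix(0, n, T_len)
  y <- matrix(0, nc, T_len)
  x <- as.numeric(x0)
  for (t in seq_len(T_len)) {
    x <- model_step(x, params, labels[t], eps[, t])
    states[, t] <- x
    y[, t] <- model_observe(x, params, nu[, t])
  }
  list(states = states, y = y)
}

# lower-triangular-ish factor L with L %*% t(L) == M; NULL for the zero matrix
psd_factor <- function(M) {
  if (all(M == 0)) return(NULL)
  e <- eigen(M, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(ev), length(ev))
}
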