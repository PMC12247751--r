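#' Configuration of the dual-estimation fit
#'
#' Each iteration draws one random window of data, runs an extended Kalman
#' filter over \code{kalman_window_len} samples, forecasts the following
#' \code{free_sim_horizon} samples by noiseless free simulation, and
#' backpropagates the summed innovation and forecast errors into all
#' learnable parameters, followed by a NADAM step and projection onto the
#' structural constraints. Iteration stops when an exponentially smoothed
#' combined error changes by less than \code{convergence_tol} (relative,
#' checked every \code{check_every} iterations) or at \code{max_iterations}.
#'
#' @param kalman_window_len filter window length in timesteps.
#' @param free_sim_horizon forecast horizon in timesteps.
#' @param n_windows_per_epoch windows drawn per epoch (bookkeeping only; the
#'   total number of windows is \code{max_iterations}).
#' @param learning_rate NADAM step size.
#' @param lr_min_frac floor of the cosine learning-rate decay, as a fraction
#'   of \code{learning_rate} (the step size anneals from
#'   \code{learning_rate} to \code{learning_rate * lr_min_frac} over
#'   \code{max_iterations}).
#' @param average_tail fraction of the final iterations whose parameter
#'   iterates are averaged into the returned estimate (tail averaging damps
#'   the stochastic-window bounce; 0 disables).
#' @param scalar_lr_frac learning-rate fraction applied to the
#'   physiological scalars (leaks \code{D}, biases \code{C}, slopes
#'   \code{S}, offsets \code{V}). These start at standard values and move
#'   slowly; fast adaptation lets unobserved populations re-parameterize
#'   into equivalent but structurally scrambled circuits.
#' @param beta1,beta2,adam_eps NADAM moment decays and stabilizer.
#' @param max_iterations maximum number of windows.
#' @param convergence_tol relative tolerance on the smoothed combined error.
#' @param check_every convergence check cadence (iterations).
#' @param smooth_halflife half-life (iterations) of the error smoothing.
#' @param min_iterations do not stop before this many iterations.
#' @param seed integer seed for window draws and random initialization.
#' @param pin_gamma1 hold regime 1's modulation at the exact all-ones matrix.
#' @param learn_H update the lead field (off by default; H is usually known).
#' @param learn_noise update the diagonal noise covariances.
#' @param fs_weight multiplier on the free-simulation (forecast) error in
#'   the combined objective; the innovation error has weight 1.
#' @param whiten_innovations score the filter by the whitened innovation
#'   criterion (Mahalanobis norm plus log-determinant of the innovation
#'   covariance, the Gaussian filtering likelihood) instead of the raw
#'   squared innovation norm. Weighs weakly excited directions properly.
#' @param gauge_normalize fix the rank-1 diagonal gauge freedom of the
#'   \code{W * Gamma_i} factorization by rescaling the modulation factors to
#'   unit mean across regimes (the compensating scale moves into \code{W};
#'   the model function is unchanged). Applied only when no regime is
#'   pinned — a pinned baseline already fixes the gauge.
#' @return list of class \code{fit_config}.
#' @export
fit_config <- function(kalman_window_len = 200, free_sim_horizon = 8,
                       n_windows_per_epoch = 1,
                       learning_rate = 0.01, lr_min_frac = 0.05,
                       average_tail = 0.3, scalar_lr_frac = 0.1,
                       beta1 = 0.9, beta2 = 0.999,
                       adam_eps = 1e-8,
                       max_iterations = 8000, convergence_tol = 1e-4,
                       check_every = 50, smooth_halflife = 50,
                       min_iterations = 300,
                       seed = 1L, pin_gamma1 = FALSE,
                       learn_H = FALSE, learn_noise = TRUE,
                       fs_weight = 0.1, whiten_innovations = TRUE,
                       gauge_normalize = TRUE) {
  if (kalman_window_len < 1 || free_sim_horizon < 1)
    stop("window lengths must be at least 1")
  if (convergence_tol <= 0) stop("convergence_tol must be positive")
  structure(as.list(environment()), class = "fit_config")
}

# flat learnable representation of a mindy_params bundle
params_to_primitives <- function(params) {
  m <- length(params$gammas)
  n <- n_populations(params)
  U <- vapply(params$gammas, function(g) g$u, numeric(n))
  Vf <- vapply(params$gammas, function(g) g$v, numeric(n))
  list(W = assemble_W(params$W),
       U = matrix(U, n, m), Vf = matrix(Vf, n, m),
       D = params$D, C = params$C,
       S = params$S, Voff = params$V,
       H = params$H,
       qdiag = diag(params$Q), rdiag = diag(params$R),
       n_exc = params$W$n_exc, n_inh = params$W$n_inh,
       mask = params$W$sparsity_mask,
       pinned1 = isTRUE(params$gammas[[1]]$pinned))
}

primitives_to_params <- function(pr, validate = TRUE) {
  ne <- pr$n_exc; ni <- pr$n_inh; n <- ne + ni
  W <- structured_connectivity(
    Wee = pr$W[1:ne, 1:ne, drop = FALSE],
    Wie = pr$W[1:ne, (ne + 1):n, drop = FALSE],
    Wei = pr$W[(ne + 1):n, 1:ne, drop = FALSE],
    Wii = pr$W[(ne + 1):n, (ne + 1):n, drop = FALSE],
    mask = pr$mask, validate = validate)
  gammas <- lapply(seq_len(ncol(pr$U)), function(i) {
    modulation_matrix(pr$U[, i], pr$Vf[, i], regime_index = i,
                      pinned = (i == 1L && pr$pinned1))
  })
  mindy_params(W = W, gammas = gammas, D = pr$D, S = pr$S, V = pr$Voff,
               C = pr$C, H = pr$H, Q = diag(pr$qdiag, n),
               R = diag(pr$rdiag, length(pr$rdiag)), validate = validate)
}

slope_vec_from <- function(S, ne, ni) c(rep(S[[1]], ne), rep(S[[2]], ni))

#' Extended Kalman filter over one window of observations
#'
#' Runs the predict/linearize/correct recursion of the extended Kalman filter
#' for the modulated nonlinear dynamics: the prediction uses the active
#' regime's modulation at every timestep, the Jacobian is evaluated at the
#' current filtered estimate, and the correction uses the lead field and the
#' measurement covariance. Near-singular innovation covariances are
#' regularized by a small jitter with a warning.
#'
#' @param params a [mindy_params()] bundle.
#' @param y_window channels x L observation matrix.
#' @param labels_window length-L regime labels (label at position t selects
#'   the modulation for the transition into sample t).
#' @param x0 initial state mean (default: lead-field pseudo-inverse applied
#'   to the first observation).
#' @param P0 initial state covariance (default identity).
#' @return list with \code{means} (n x L filtered means), \code{covariances}
#'   (n x n x L array), \code{innovations} (channels x L),
#'   \code{innovation_sse} (summed squared innovations).
#' @export
kalman_filter_window <- function(params, y_window, labels_window,
                                 x0 = NULL, P0 = NULL) {
  y_window <- as.matrix(y_window)
  L <- ncol(y_window)
  labels_window <- as.integer(labels_window)
  if (length(labels_window) != L) stop("labels must match the window length")
  m <- length(params$gammas)
  if (any(labels_window < 1L | labels_window > m))
    stop("regime labels out of range 1..m")
  n <- n_populations(params)
  H <- params$H
  if (is.null(x0)) x0 <- as.numeric(pseudo_inverse(H) %*% y_window[, 1])
  if (is.null(P0)) P0 <- diag(n)
  Q <- params$Q
  R <- params$R
  check_psd(Q, "Q"); check_psd(R, "R")

  x <- as.numeric(x0)
  P <- P0
  means <- matrix(0, n, L)
  covs <- array(0, c(n, n, L))
  innov <- matrix(0, nrow(H), L)
  sse <- 0
  warned <- FALSE
  for (t in seq_len(L)) {
    g <- labels_window[t]
    xp <- model_step(x, params, g)
    F_t <- dynamics_jacobian(x, params, g)
    Pp <- F_t %*% P %*% t(F_t) + Q
    S_t <- H %*% Pp %*% t(H) + R
    S_t <- (S_t + t(S_t)) / 2
    if (rcond(S_t) < 1e-12) {
      if (!warned) {
        warning("near-singular innovation covariance; adding jitter",
                call. = FALSE)
        warned <- TRUE
      }
      diag(S_t) <- diag(S_t) + 1e-6 * (1 + max(diag(S_t)))
    }
    e <- y_window[, t] - as.numeric(H %*% xp)
    K <- Pp %*% t(H) %*% solve(S_t)
    x <- xp + as.numeric(K %*% e)
    if (!all(is.finite(x))) stop("Kalman filter diverged (non-finite state)")
    P <- Pp - K %*% H %*% Pp
    P <- (P + t(P)) / 2
    means[, t] <- x
    covs[, , t] <- P
    innov[, t] <- e
    sse <- sse + sum(e^2)
  }
  list(means = means, covariances = covs, innovations = innov,
       innovation_sse = sse)
}

pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Free-simulation forecast from an estimated state
#'
#' Rolls the model forward without noise from a filtered state estimate,
#' using the labeled regime at each future step, and scores the prediction
#' against held-out observations.
#'
#' @param params a [mindy_params()] bundle.
#' @param x_hat state estimate to start from.
#' @param labels_future regime labels of the forecast steps (length horizon).
#' @param y_future optional channels x horizon observations to score against.
#' @param horizon number of steps (default \code{length(labels_future)}).
#' @return list with \code{y_pred} (channels x horizon),
#'   \code{states} (n x horizon) and \code{prediction_sse} (\code{NA} when
#'   \code{y_future} is missing).
#' @export
free_sim_predict <- function(params, x_hat, labels_future, y_future = NULL,
                             horizon = length(labels_future)) {
  if (horizon < 1) stop("horizon must be at least 1")
  labels_future <- as.integer(labels_future)[seq_len(horizon)]
  z <- as.numeric(x_hat)
  n <- n_populations(params)
  states <- matrix(0, n, horizon)
  y_pred <- matrix(0, nrow(params$H), horizon)
  for (t in seq_len(horizon)) {
    z <- model_step(z, params, labels_future[t])
    if (!all(is.finite(z)))
      stop("free simulation diverged (non-finite state) at step ", t)
    states[, t] <- z
    y_pred[, t] <- model_observe(z, params)
  }
  sse <- NA_real_
  if (!is.null(y_future)) {
    y_future <- as.matrix(y_future)
    sse <- sum((y_future[, seq_len(horizon), drop = FALSE] - y_pred)^2)
  }
  list(y_pred = y_pred, states = states, prediction_sse = sse)
}

# elementwise projection of the learnable primitives onto the feasible set
project_primitives <- function(pr, pin_gamma1 = pr$pinned1) {
  ne <- pr$n_exc; ni <- pr$n_inh; n <- ne + ni
  ee <- 1:ne; ii <- (ne + 1):n
  W <- pr$W
  W[ee, ee] <- pmax(W[ee, ee], 0) * pr$mask$ee
  W[ii, ee] <- pmax(W[ii, ee], 0) * pr$mask$ei
  Bie <- pmin(W[ee, ii, drop = FALSE], 0)
  W[ee, ii] <- diag_rect(Bie[cbind(seq_len(min(ne, ni)), seq_len(min(ne, ni)))],
                         ne, ni)
  Bii <- pmin(W[ii, ii, drop = FALSE], 0)
  W[ii, ii] <- diag_rect(diag(Bii), ni, ni)
  pr$W <- W
  pr$U <- pmax(pr$U, 0)
  pr$Vf <- pmax(pr$Vf, 0)
  if (pin_gamma1) {
    pr$U[, 1] <- 1
    pr$Vf[, 1] <- 1
  }
  pr$D <- pmin(pmax(pr$D, 0), 2)
  pr$S <- pmax(pr$S, 1e-6)
  pr$qdiag <- pmax(pr$qdiag, 1e-6)
  pr$rdiag <- pmax(pr$rdiag, 1e-6)
  pr$H[, ii] <- 0
  pr
}

#' Project a parameter bundle onto the structural constraints
#'
#' Elementwise projection: clamps \code{Wee}/\code{Wei} at >= 0 and
#' \code{Wie}/\code{Wii} at <= 0, zeroes the inhibitory-source off-diagonals,
#' re-applies the sparsity mask, clamps the modulation factors at >= 0,
#' resets a pinned regime-1 modulation to the exact all-ones matrix, zeroes
#' the inhibitory lead-field columns, and floors the eigenvalues of \code{Q}
#' and \code{R} at \code{eig_floor}. Idempotent; feasible parameters are
#' returned unchanged.
#'
#' @param params a [mindy_params()] bundle (possibly infeasible; it is not
#'   validated on input).
#' @param eig_floor eigenvalue floor for the noise covariances.
#' @return a feasible [mindy_params()] bundle.
#' @export
apply_constraints <- function(params, eig_floor = 1e-6) {
  pr <- params_to_primitives_raw(params)
  pr <- project_primitives(pr)
  out <- primitives_to_params_keepQR(pr, params, eig_floor)
  out
}

# like params_to_primitives but tolerant of infeasible input
params_to_primitives_raw <- function(params) {
  m <- length(params$gammas)
  n <- params$W$n_exc + params$W$n_inh
  U <- vapply(params$gammas, function(g) as.numeric(g$u), numeric(n))
  Vf <- vapply(params$gammas, function(g) as.numeric(g$v), numeric(n))
  list(W = assemble_W(params$W),
       U = matrix(U, n, m), Vf = matrix(Vf, n, m),
       D = params$D, C = params$C, S = params$S, Voff = params$V,
       H = params$H,
       qdiag = diag(params$Q), rdiag = diag(params$R),
       n_exc = params$W$n_exc, n_inh = params$W$n_inh,
       mask = params$W$sparsity_mask,
       pinned1 = isTRUE(params$gammas[[1]]$pinned))
}

primitives_to_params_keepQR <- function(pr, orig, eig_floor) {
  p <- primitives_to_params(pr, validate = FALSE)
  p$Q <- psd_project(orig$Q, eig_floor)
  p$R <- psd_project(orig$R, eig_floor)
  validate_params(p)
  p
}

psd_project <- function(M, floor = 1e-6) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= floor) return(M)  # already feasible: exact idempotence
  e$vectors %*% diag(pmax(e$values, floor), nrow(M)) %*% t(e$vectors)
}

#' Random initialization of the learnable parameters
#'
#' Connectivity blocks start at small correctly signed uniforms (masked),
#' modulation factors near 1, leaks and slopes at their standard
#' excitatory/inhibitory defaults, offsets and biases at zero.
#'
#' @param n_exc,n_inh population counts.
#' @param m number of regimes.
#' @param H lead field (channels x n); required.
#' @param Q,R noise covariances used to initialize the filter.
#' @param mask sparsity mask (list \code{ee}, \code{ei}); drawn at random if
#'   \code{NULL}.
#' @param pin_gamma1 pin regime 1's modulation to the all-ones matrix.
#' @param w_scale magnitude of the initial connectivity draws.
#' @param gamma_sd spread of the initial modulation factors around 1.
#' @return a feasible [mindy_params()] bundle.
#' @export
random_init_params <- function(n_exc, n_inh = n_exc, m, H, Q, R,
                               mask = NULL, pin_gamma1 = FALSE,
                               w_scale = 0.1, gamma_sd = 0.05,
                               inh_init = c(0.3, 0.7)) {
  if (is.null(mask)) mask <- random_sparsity_mask(n_exc, n_inh)
  Wee <- matrix(stats::runif(n_exc * n_exc, 0, w_scale), n_exc, n_exc) * mask$ee
  Wei <- matrix(stats::runif(n_inh * n_exc, 0, w_scale), n_inh, n_exc) * mask$ei
  # inhibitory couplings start at model-class scale: a population whose
  # I -> E route starts near zero carries almost no gradient and can stay
  # pruned for the whole fit
  Wie <- -stats::runif(min(n_exc, n_inh), inh_init[1], inh_init[2])
  Wii <- -stats::runif(n_inh, 0, w_scale)
  W <- structured_connectivity(Wee, diag_rect(Wie, n_exc, n_inh), Wei,
                               diag_rect(Wii, n_inh, n_inh), mask = mask)
  n <- n_exc + n_inh
  gammas <- lapply(seq_len(m), function(i) {
    if (i == 1L && pin_gamma1)
      modulation_matrix(rep(1, n), regime_index = 1L, pinned = TRUE)
    else
      modulation_matrix(pmax(stats::rnorm(n, 1, gamma_sd), 0),
                        pmax(stats::rnorm(n, 1, gamma_sd), 0),
                        regime_index = i)
  })
  mindy_params(W = W, gammas = gammas,
               D = c(rep(0.65, n_exc), rep(0.8, n_inh)),
               S = c(exc = 2.5, inh = 1), V = 0, C = 0,
               H = H, Q = Q, R = R)
}

# fix the rank-1 diagonal gauge of W o (u v^T): rescale the modulation
# factors to unit occupancy-weighted mean across regimes and absorb the
# scale into W. Exact reparameterization; the modeled dynamics are
# unchanged. Occupancy weighting keeps a rarely visited regime's weakly
# constrained factors from polluting the shared connectivity.
gauge_normalize_primitives <- function(pr, weights = NULL, eps = 1e-6) {
  if (is.null(weights)) weights <- rep(1 / ncol(pr$U), ncol(pr$U))
  a <- pmax(as.numeric(pr$U %*% weights), eps)
  b <- pmax(as.numeric(pr$Vf %*% weights), eps)
  pr$U <- pr$U / a
  pr$Vf <- pr$Vf / b
  pr$W <- pr$W * outer(a, b)
  pr
}

# one NADAM update; st holds m, v, t
nadam_update <- function(theta, g, st, lr, b1, b2, eps) {
  st$t <- st$t + 1
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^st$t)
  vhat <- st$v / (1 - b2^st$t)
  step <- lr * (b1 * mhat + (1 - b1) * g / (1 - b1^st$t)) / (sqrt(vhat) + eps)
  list(theta = theta - step, st = st)
}

new_nadam_state <- function(x) list(m = x * 0, v = x * 0, t = 0)

#' Fit the modulated network model to a regime-labeled recording
#'
#' Dual estimation by stochastic windows: each iteration draws a uniformly
#' random window, filters it with the extended Kalman filter, forecasts the
#' following segment by free simulation, backpropagates the combined
#' innovation + forecast error into all learnable parameters (and, when
#' enabled, the diagonal noise covariances), applies a NADAM update, and
#' projects the parameters back onto the structural constraint set. Only the
#' modulation matrix matching each timestep's label receives gradient from
#' that timestep. Iteration stops on convergence of the smoothed combined
#' error or at \code{max_iterations}.
#'
#' @param recording a [labeled_recording()].
#' @param config a [fit_config()].
#' @param init a feasible [mindy_params()] starting point, or the string
#'   \code{"random"} (then \code{H}, \code{Q}, \code{R} must be supplied and
#'   \code{mask}/\code{m} control the architecture).
#' @param H,Q,R lead field and noise covariances for random initialization.
#' @param mask sparsity mask for random initialization (random if
#'   \code{NULL}).
#' @param m number of regimes for random initialization (default: largest
#'   label in the recording).
#' @return An object of class \code{mindy_fit}: list with \code{params}
#'   (constrained [mindy_params()]), \code{loss_trace} (data frame with
#'   per-iteration Kalman, free-simulation, combined and smoothed errors),
#'   \code{window_log} (window start indices), \code{converged},
#'   \code{config}.
#' @export
fit_mindy <- function(recording, config = fit_config(), init = "random",
                      H = NULL, Q = NULL, R = NULL, mask = NULL, m = NULL) {
  stopifnot(inherits(recording, "labeled_recording"))
  stopifnot(inherits(config, "fit_config"))
  y <- recording$y
  labels <- recording$labels
  T_len <- ncol(y)
  L <- config$kalman_window_len
  hz <- config$free_sim_horizon
  if (T_len < L + hz + 1) stop("recording shorter than one window + horizon")

  if (!is.null(config$seed)) set.seed(config$seed)

  if (identical(init, "random")) {
    if (is.null(H) || is.null(Q) || is.null(R))
      stop("random initialization requires H, Q and R")
    if (is.null(m)) m <- max(labels)
    n <- ncol(H)
    if (n %% 2 != 0 && is.null(mask))
      stop("cannot infer n_exc/n_inh from H; supply a mask or init")
    ne <- if (!is.null(mask)) ncol(mask$ee) else n %/% 2
    ni <- n - ne
    init <- random_init_params(ne, ni, m = m, H = H, Q = Q, R = R,
                               mask = mask, pin_gamma1 = config$pin_gamma1)
  }
  stopifnot(inherits(init, "mindy_params"))
  m <- length(init$gammas)
  if (max(labels) > m)
    stop("recording labels exceed the number of regimes m = ", m)

  pr <- params_to_primitives(init)
  pr$pinned1 <- pr$pinned1 || config$pin_gamma1
  pr <- project_primitives(pr)
  ne <- pr$n_exc; ni <- pr$n_inh
  Hplus <- pseudo_inverse(pr$H)
  P0 <- diag(ne + ni)

  # valid window starts: x0 anchored at s, data s+1 .. s+L+hz
  starts <- seq_len(T_len - L - hz)
  if (!is.null(recording$session_bounds)) {
    b <- recording$session_bounds
    bad <- vapply(starts, function(s) any(b >= s & b < s + L + hz), logical(1))
    starts <- starts[!bad]
    if (length(starts) == 0) stop("no window fits within a single session")
  }

  learn <- c("W", "U", "Vf", "D", "C", "S", "Voff")
  if (config$learn_H) learn <- c(learn, "H")
  opt <- list()
  for (nm in learn) opt[[nm]] <- new_nadam_state(pr[[nm]])
  log_q <- log(pr$qdiag); log_r <- log(pr$rdiag)
  if (config$learn_noise) {
    opt$log_q <- new_nadam_state(log_q)
    opt$log_r <- new_nadam_state(log_r)
  }

  alpha <- 1 - 2^(-1 / config$smooth_halflife)
  smoothed <- NA_real_
  last_check <- NA_real_
  converged <- FALSE
  n_iter <- 0L
  bad_streak <- 0L
  trace_kf <- trace_fs <- trace_sm <- numeric(config$max_iterations)
  window_log <- integer(config$max_iterations)
  last_stable <- pr

  avg_from <- if (config$average_tail > 0)
    floor(config$max_iterations * (1 - config$average_tail)) + 1L
  else config$max_iterations + 1L
  avg_fields <- c("W", "U", "Vf", "D", "C", "S", "Voff", "H",
                  "qdiag", "rdiag")
  regime_w <- tabulate(labels, m)
  regime_w <- regime_w / sum(regime_w)
  avg_acc <- NULL
  avg_n <- 0L

  for (it in seq_len(config$max_iterations)) {
    lr_t <- config$learning_rate *
      (config$lr_min_frac + (1 - config$lr_min_frac) *
         0.5 * (1 + cos(pi * (it - 1) / config$max_iterations)))
    s <- starts[sample.int(length(starts), 1)]
    idx <- (s + 1):(s + L + hz)
    x0 <- as.numeric(Hplus %*% y[, s])
    svec <- slope_vec_from(pr$S, ne, ni)
    res <- cpp_window_grad(y[, idx, drop = FALSE], labels[idx], L, hz,
                           x0, P0, pr$W, pr$U, pr$Vf, pr$D, pr$C,
                           svec, pr$Voff, pr$H, pr$qdiag, pr$rdiag,
                           isTRUE(config$whiten_innovations),
                           config$fs_weight)
    loss <- res$loss_kf + res$loss_fs
    if (!isTRUE(res$ok) || !is.finite(loss)) {
      bad_streak <- bad_streak + 1L
      if (bad_streak > 50L) {
        warning("persistent divergence; returning last stable parameters",
                call. = FALSE)
        pr <- last_stable
        break
      }
      next
    }
    bad_streak <- 0L
    last_stable <- pr
    n_iter <- n_iter + 1L
    window_log[n_iter] <- s
    trace_kf[n_iter] <- res$loss_kf
    trace_fs[n_iter] <- res$loss_fs

    gsv <- as.numeric(res$grad_svec)
    gS <- c(sum(gsv[1:ne]), sum(gsv[(ne + 1):(ne + ni)]))
    grads <- list(W = res$grad_W, U = res$grad_U, Vf = res$grad_Vf,
                  D = as.numeric(res$grad_D), C = as.numeric(res$grad_C),
                  S = gS, Voff = as.numeric(res$grad_Voff), H = res$grad_H)
    if (pr$pinned1) {
      grads$U[, 1] <- 0
      grads$Vf[, 1] <- 0
    }
    for (nm in learn) {
      lr_nm <- if (nm %in% c("D", "C", "S", "Voff"))
        lr_t * config$scalar_lr_frac else lr_t
      up <- nadam_update(pr[[nm]], grads[[nm]], opt[[nm]],
                         lr_nm, config$beta1, config$beta2,
                         config$adam_eps)
      pr[[nm]] <- up$theta
      opt[[nm]] <- up$st
    }
    if (config$learn_noise) {
      upq <- nadam_update(log_q, as.numeric(res$grad_qdiag) * pr$qdiag, opt$log_q,
                          lr_t, config$beta1, config$beta2,
                          config$adam_eps)
      log_q <- upq$theta; opt$log_q <- upq$st
      upr <- nadam_update(log_r, as.numeric(res$grad_rdiag) * pr$rdiag, opt$log_r,
                          lr_t, config$beta1, config$beta2,
                          config$adam_eps)
      log_r <- upr$theta; opt$log_r <- upr$st
      pr$qdiag <- exp(pmin(log_q, 10))
      pr$rdiag <- exp(pmin(log_r, 10))
    }
    pr <- project_primitives(pr)
    if (isTRUE(config$gauge_normalize) && !pr$pinned1)
      pr <- gauge_normalize_primitives(pr, regime_w)
    if (it >= avg_from) {
      if (is.null(avg_acc)) avg_acc <- pr[avg_fields]
      else for (nm in avg_fields) avg_acc[[nm]] <- avg_acc[[nm]] + pr[[nm]]
      avg_n <- avg_n + 1L
    }

    smoothed <- if (is.na(smoothed)) loss else alpha * loss + (1 - alpha) * smoothed
    trace_sm[n_iter] <- smoothed
    if (n_iter %% config$check_every == 0L) {
      if (!is.na(last_check) && n_iter >= config$min_iterations &&
          abs(smoothed - last_check) / max(last_check, 1e-12) <
            config$convergence_tol) {
        converged <- TRUE
        break
      }
      last_check <- smoothed
    }
  }

  if (!is.null(avg_acc) && avg_n > 0L) {
    for (nm in avg_fields) pr[[nm]] <- avg_acc[[nm]] / avg_n
    pr <- project_primitives(pr)
    if (isTRUE(config$gauge_normalize) && !pr$pinned1)
      pr <- gauge_normalize_primitives(pr, regime_w)
  }

  keep <- seq_len(n_iter)
  structure(list(
    params = primitives_to_params(pr),
    loss_trace = data.frame(iteration = keep,
                            kalman = trace_kf[keep],
                            free_sim = trace_fs[keep],
                            combined = trace_kf[keep] + trace_fs[keep],
                            smoothed = trace_sm[keep]),
    window_log = window_log[keep],
    converged = converged,
    config = config), class = "mindy_fit")
}

#' @export
print.mindy_fit <- function(x, ...) {
  nt <- nrow(x$loss_trace)
  cat(sprintf(
    "<mindy_fit> %d iterations, %s (final combined error %.4g)\n", nt,
    if (x$converged) "converged" else "stopped at max_iterations",
    if (nt > 0) x$loss_trace$combined[nt] else NA_real_))
  invisible(x)
}
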