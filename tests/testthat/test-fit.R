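test_that("EKF equals the textbook linear Kalman filter on linear dynamics", {
  # with W = 0 the update x' = (1 - D) x + C is exactly linear, so the
  # extended filter's linearization is exact and must match a from-scratch
  # linear KF implementation
  set.seed(18)
  ne <- 2; ni <- 2; n <- 4; nc <- 2
  W <- structured_connectivity(matrix(0, 2, 2), diag(0, 2),
                               matrix(0, 2, 2), diag(0, 2))
  H <- matrix(rnorm(nc * n), nc, n); H[, 3:4] <- 0
  Q <- diag(0.3, n); R <- diag(0.2, nc)
  D <- c(0.5, 0.6, 0.7, 0.8); C <- c(0.1, -0.2, 0.05, 0)
  p <- mindy_params(W = W, gammas = list(modulation_matrix(rep(1, n))),
                    D = D, S = c(exc = 1, inh = 1), V = 0, C = C,
                    H = H, Q = Q, R = R)
  y <- matrix(rnorm(nc * 40), nc, 40)
  x0 <- rnorm(n); P0 <- diag(n)
  kf <- kalman_filter_window(p, y, rep(1L, 40), x0 = x0, P0 = P0)
  oracle <- oracle_linear_kf(y, diag(1 - D), C, H, Q, R, x0, P0)
  expect_lt(max(abs(kf$means - oracle)), 1e-10)
})

test_that("noiseless observable system drives innovations to zero", {
  # square full-rank excitatory lead field, zero measurement noise: the
  # filter locks onto the exact state and innovations vanish
  cfg <- synth_config(n_exc = 3, n_inh = 3, m = 1, T_len = 300,
                      n_channels = 3, q_diag = 0, r_base = 0, r_jitter = 0,
                      require_all_regimes = FALSE)
  b <- generate_dataset(cfg, seed = 31)
  p <- b$params
  p$H <- cbind(diag(3), matrix(0, 3, 3))
  x0 <- rnorm(6, sd = 2)
  sim <- simulate_mindy(p, rep(1L, 300), x0 = x0)
  p$Q <- diag(1e-8, 6); p$R <- diag(1e-8, 3)
  kf <- suppressWarnings(
    kalman_filter_window(p, sim$y, rep(1L, 300)))
  late <- abs(kf$innovations[, 250:300])
  expect_lt(max(late), 1e-3)
  # filtered excitatory states match the observations they generated
  expect_lt(max(abs(kf$means[1:3, 250:300] - sim$y[, 250:300])), 1e-3)
})

test_that("switching between two all-ones modulations changes nothing", {
  p <- small_params(ne = 3, ni = 3, m = 2, nc = 3, seed = 41)
  p$gammas[[1]] <- modulation_matrix(rep(1, 6), regime_index = 1L)
  p$gammas[[2]] <- modulation_matrix(rep(1, 6), regime_index = 2L)
  y <- matrix(rnorm(3 * 30), 3, 30)
  labs_switch <- rep(c(1L, 2L), 15)
  kf1 <- kalman_filter_window(p, y, labs_switch)
  kf2 <- kalman_filter_window(p, y, rep(1L, 30))
  expect_equal(kf1$means, kf2$means, tolerance = 1e-12)
  expect_equal(kf1$innovation_sse, kf2$innovation_sse, tolerance = 1e-12)
})

test_that("free simulation matches chained oracle steps and simulate()", {
  p <- toy_params(S = c(exc = 1, inh = 1), D = 0.5)
  x <- c(0.1, -0.2)
  fs <- free_sim_predict(p, x, rep(1L, 3))
  xo <- x
  for (t in 1:3) {
    xo <- oracle_step(xo, p, 1L)
    expect_equal(fs$states[, t], xo, tolerance = 1e-12)
  }
  p2 <- small_params(seed = 8)
  x2 <- rnorm(6)
  labs <- c(1L, 2L, 1L, 2L)
  fs2 <- free_sim_predict(p2, x2, labs)
  # simulate with zero covariances equals the rollout
  p2z <- p2; p2z$Q <- diag(0, 6); p2z$R <- diag(0, nrow(p2$H))
  simz <- simulate_mindy(p2z, labs, x0 = x2)
  expect_equal(fs2$states, simz$states, tolerance = 1e-12)
  # horizon-1 forecast with perfect state and parameters on noiseless data
  expect_equal(free_sim_predict(p2z, x2, 1L,
                                y_future = simz$y[, 1, drop = FALSE])$prediction_sse,
               0, tolerance = 1e-20)
})

test_that("constraint projection is an idempotent elementwise clamp", {
  p <- small_params(ne = 3, ni = 3, m = 2, seed = 51)
  expect_equal(apply_constraints(p), apply_constraints(apply_constraints(p)))
  # already-feasible parameters pass through unchanged
  pc <- apply_constraints(p)
  expect_equal(pc$W$Wee, p$W$Wee)
  expect_equal(pc$D, p$D)

  # single violation: exactly that entry is clamped, everything else intact
  bad <- p
  bad$W$Wee[2, 1] <- -0.5
  fixed <- apply_constraints(bad)
  expect_identical(fixed$W$Wee[2, 1], 0)
  others <- which(!(row(p$W$Wee) == 2 & col(p$W$Wee) == 1))
  expect_equal(fixed$W$Wee[others], bad$W$Wee[others])

  # random infeasible parameters: result equals the brute-force clamp oracle
  set.seed(6)
  mess <- p
  mess$W$Wee <- matrix(rnorm(9), 3, 3)
  mess$W$Wei <- matrix(rnorm(9), 3, 3)
  mess$W$Wie <- matrix(rnorm(9), 3, 3)
  mess$W$Wii <- matrix(rnorm(9), 3, 3)
  mess$gammas[[1]] <- structure(
    list(regime_index = 1L, u = rnorm(6, 1, 1), v = rnorm(6, 1, 1),
         pinned = FALSE), class = "modulation_matrix")
  out <- apply_constraints(mess)
  mask <- p$W$sparsity_mask
  expect_equal(out$W$Wee, pmax(mess$W$Wee, 0) * mask$ee)
  expect_equal(out$W$Wei, pmax(mess$W$Wei, 0) * mask$ei)
  expect_equal(out$W$Wie, diag(pmin(diag(mess$W$Wie), 0), 3))
  expect_equal(out$W$Wii, diag(pmin(diag(mess$W$Wii), 0), 3))
  expect_equal(out$gammas[[1]]$u, pmax(mess$gammas[[1]]$u, 0))
  expect_valid_params(out)
})

test_that("pinned baseline modulation is restored exactly by projection", {
  p <- small_params(ne = 3, ni = 3, m = 2, seed = 52)
  p$gammas[[1]] <- structure(
    list(regime_index = 1L, u = runif(6, 0.5, 2), v = runif(6, 0.5, 2),
         pinned = TRUE), class = "modulation_matrix")
  out <- apply_constraints(p)
  expect_identical(out$gammas[[1]]$u, rep(1, 6))
  expect_identical(gamma_dense(out$gammas[[1]]), matrix(1, 6, 6))
})

test_that("compiled window gradients equal the plain-R reference", {
  cfg <- synth_config(n_exc = 3, n_inh = 3, m = 2, T_len = 80,
                      n_channels = 3, require_all_regimes = FALSE)
  b <- generate_dataset(cfg, seed = 7)
  pr <- modmindy:::params_to_primitives(b$params)
  sv <- modmindy:::slope_vec_from(pr$S, 3, 3)
  y <- b$recording$y[, 2:31]
  lab <- b$labels[2:31]
  x0 <- as.numeric(modmindy:::pseudo_inverse(pr$H) %*% b$recording$y[, 1])
  for (whiten in c(FALSE, TRUE)) {
    cpp <- modmindy:::cpp_window_grad(y, lab, 25L, 5L, x0, diag(6), pr$W,
                                      pr$U, pr$Vf, pr$D, pr$C, sv, pr$Voff,
                                      pr$H, pr$qdiag, pr$rdiag, whiten)
    ref <- modmindy:::window_grad_r(y, lab, 25L, 5L, x0, diag(6), pr$W,
                                    pr$U, pr$Vf, pr$D, pr$C, sv, pr$Voff,
                                    pr$H, pr$qdiag, pr$rdiag, whiten)
    for (nm in c("loss_kf", "loss_fs", "grad_W", "grad_U", "grad_Vf",
                 "grad_D", "grad_C", "grad_svec", "grad_Voff", "grad_H",
                 "grad_qdiag", "grad_rdiag")) {
      expect_lt(max(abs(cpp[[nm]] - ref[[nm]])), 1e-9)
    }
  }
})

test_that("window gradients match central finite differences", {
  cfg <- synth_config(n_exc = 2, n_inh = 2, m = 2, T_len = 40,
                      n_channels = 2, require_all_regimes = FALSE)
  b <- generate_dataset(cfg, seed = 19)
  pr <- modmindy:::params_to_primitives(b$params)
  y <- b$recording$y[, 2:25]
  lab <- b$labels[2:25]
  x0 <- as.numeric(modmindy:::pseudo_inverse(pr$H) %*% b$recording$y[, 1])
  loss_fn <- function(pr2) {
    sv <- modmindy:::slope_vec_from(pr2$S, 2, 2)
    r <- modmindy:::cpp_window_grad(y, lab, 18L, 6L, x0, diag(4), pr2$W,
                                    pr2$U, pr2$Vf, pr2$D, pr2$C, sv,
                                    pr2$Voff, pr2$H, pr2$qdiag, pr2$rdiag,
                                    FALSE)
    r$loss_kf + r$loss_fs
  }
  sv <- modmindy:::slope_vec_from(pr$S, 2, 2)
  g <- modmindy:::cpp_window_grad(y, lab, 18L, 6L, x0, diag(4), pr$W, pr$U,
                                  pr$Vf, pr$D, pr$C, sv, pr$Voff, pr$H,
                                  pr$qdiag, pr$rdiag, FALSE)
  eps <- 1e-6
  for (field in c("W", "U", "D", "qdiag", "rdiag")) {
    arr <- pr[[field]]
    gan <- switch(field, W = g$grad_W, U = g$grad_U, D = g$grad_D,
                  qdiag = g$grad_qdiag, rdiag = g$grad_rdiag)
    for (i in seq_along(arr)) {
      p1 <- pr; p1[[field]][i] <- arr[i] + eps
      p2 <- pr; p2[[field]][i] <- arr[i] - eps
      gnum <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      expect_lt(abs(gnum - as.numeric(gan)[i]) / max(abs(gnum), 1e-3), 1e-4)
    }
  }
})

test_that("fitting is deterministic under a fixed seed", {
  cfg <- synth_config(n_exc = 2, n_inh = 2, m = 2, T_len = 600,
                      n_channels = 2)
  b <- generate_dataset(cfg, seed = 3)
  fc <- fit_config(max_iterations = 120, min_iterations = 121, seed = 10)
  f1 <- fit_mindy(b$recording, fc, init = "random", H = b$params$H,
                  Q = b$params$Q, R = b$params$R,
                  mask = b$params$W$sparsity_mask)
  f2 <- fit_mindy(b$recording, fc, init = "random", H = b$params$H,
                  Q = b$params$Q, R = b$params$R,
                  mask = b$params$W$sparsity_mask)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$window_log, f2$window_log)
})

test_that("structural invariants survive 1000 optimizer steps", {
  cfg <- synth_config(n_exc = 3, n_inh = 3, m = 2, T_len = 1200,
                      n_channels = 3)
  b <- generate_dataset(cfg, seed = 23)
  fc <- fit_config(max_iterations = 1000, min_iterations = 1001, seed = 2,
                   pin_gamma1 = TRUE, learn_noise = TRUE)
  fit <- fit_mindy(b$recording, fc, init = "random", H = b$params$H,
                   Q = b$params$Q, R = b$params$R,
                   mask = b$params$W$sparsity_mask)
  p <- fit$params
  expect_valid_params(p)
  expect_true(all(p$W$Wee >= 0) && all(p$W$Wei >= 0))
  expect_true(all(p$W$Wee[b$params$W$sparsity_mask$ee == 0] == 0))
  expect_identical(gamma_dense(p$gammas[[1]]), matrix(1, 6, 6))
  for (g in p$gammas) expect_true(all(g$u >= 0) && all(g$v >= 0))
  expect_true(all(eigen(p$Q, only.values = TRUE)$values >= 1e-6 - 1e-12))
})

test_that("smoothed fitting error decreases substantially from its start", {
  cfg <- synth_config(n_exc = 3, n_inh = 3, m = 2, T_len = 1500,
                      n_channels = 3, q_diag = 1e-4, r_base = 1e-4,
                      r_jitter = 0)
  b <- generate_dataset(cfg, seed = 29)
  fc <- fit_config(max_iterations = 1500, min_iterations = 1501, seed = 4,
                   learn_noise = FALSE, whiten_innovations = FALSE)
  fit <- fit_mindy(b$recording, fc, init = "random", H = b$params$H,
                   Q = diag(1e-4, 6), R = diag(1e-4, 3),
                   mask = b$params$W$sparsity_mask)
  lt <- fit$loss_trace
  expect_gt(lt$smoothed[1] / lt$smoothed[nrow(lt)], 10)
})

test_that("tiny-model recovery exceeds r = 0.9 on the full connectivity", {
  cfg <- synth_config(n_exc = 4, n_inh = 4, m = 2, T_len = 2000,
                      n_channels = 4)
  b <- generate_dataset(cfg, seed = 12)
  fc <- fit_config(max_iterations = 4000, min_iterations = 4001, seed = 24,
                   learn_noise = FALSE)
  fit <- fit_mindy(b$recording, fc, init = "random", H = b$params$H,
                   Q = b$params$Q, R = b$params$R,
                   mask = b$params$W$sparsity_mask)
  rep <- masked_correlation(b$params, fit$params)
  expect_gt(rep$r_full_W, 0.9)
  expect_gt(rep$r_Wee, 0.85)
})

test_that("labels beyond the declared number of regimes are rejected", {
  cfg <- synth_config(n_exc = 2, n_inh = 2, m = 2, T_len = 500,
                      n_channels = 2)
  b <- generate_dataset(cfg, seed = 33)
  rec <- b$recording
  rec$labels[5] <- 7L
  fc <- fit_config(max_iterations = 10, seed = 1)
  expect_error(fit_mindy(rec, fc, init = b$params), "exceed")
})
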