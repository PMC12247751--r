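# small fixtures shared across test files; everything is built in code

# 2-population toy (1 E, 1 I) with hand-chosen weights
toy_params <- function(S = c(exc = 1, inh = 1), D = 0.5, gamma = NULL,
                       Q = diag(0, 2), R = diag(0, 1)) {
  W <- structured_connectivity(Wee = matrix(0.6, 1, 1),
                               Wie = matrix(-0.4, 1, 1),
                               Wei = matrix(0.7, 1, 1),
                               Wii = matrix(-0.3, 1, 1))
  if (is.null(gamma)) gamma <- modulation_matrix(rep(1, 2), pinned = TRUE)
  mindy_params(W = W, gammas = list(gamma), D = D, S = S, V = 0, C = 0,
               H = matrix(c(1, 0), 1, 2), Q = Q, R = R)
}

# small random-but-valid parameter bundle
small_params <- function(ne = 3, ni = 3, m = 2, nc = 3, seed = 1) {
  cfg <- synth_config(n_exc = ne, n_inh = ni, m = m, T_len = 10,
                      n_channels = nc, require_all_regimes = FALSE)
  generate_dataset(cfg, seed = seed)$params
}

# independent brute-force evaluation of one dynamics step (double loop)
oracle_step <- function(x, params, regime, eps = 0) {
  n <- length(x)
  W <- assemble_W(params$W)
  G <- gamma_dense(params$gammas[[regime]])
  s <- c(rep(params$S[["exc"]], params$W$n_exc),
         rep(params$S[["inh"]], params$W$n_inh))
  out <- numeric(n)
  for (j in seq_len(n)) {
    acc <- 0
    for (k in seq_len(n)) {
      acc <- acc + W[j, k] * G[j, k] * tanh(s[k] * x[k] + params$V[k])
    }
    out[j] <- x[j] + acc - params$D[j] * x[j] + params$C[j] +
      (if (length(eps) == 1) eps else eps[j])
  }
  out
}

# textbook linear Kalman filter for x' = F x + c + w, y = H x + v
oracle_linear_kf <- function(y, F_m, cvec, H, Q, R, x0, P0) {
  n <- nrow(F_m)
  L <- ncol(y)
  x <- x0; P <- P0
  means <- matrix(0, n, L)
  for (t in seq_len(L)) {
    xp <- as.numeric(F_m %*% x) + cvec
    Pp <- F_m %*% P %*% t(F_m) + Q
    S_t <- H %*% Pp %*% t(H) + R
    K <- Pp %*% t(H) %*% solve(S_t)
    e <- y[, t] - as.numeric(H %*% xp)
    x <- xp + as.numeric(K %*% e)
    P <- Pp - K %*% H %*% Pp
    means[, t] <- x
  }
  means
}

# from-definition Pearson correlation (covariance ratio)
oracle_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

expect_valid_params <- function(p) {
  expect_silent(modmindy:::validate_params(p))
}
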