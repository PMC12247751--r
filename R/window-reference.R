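# Plain-R mirror of cpp_window_grad: same filter, same exact reverse-mode
# backward pass through the mean, covariance and gain recursions. Kept as the
# reference the compiled core is tested against (equality of losses and
# gradients, finite-difference checks). Internal; not exported.
window_grad_r <- function(y, labels, L, h, x0, P0, W, U, Vf, D, C,
                          svec, Voff, H, qdiag, rdiag, whiten = FALSE,
                          fs_weight = 1) {
  n <- nrow(W); ch <- nrow(H); m <- ncol(U)
  Ttot <- L + h
  stopifnot(ncol(y) >= Ttot, length(labels) >= Ttot)
  M <- lapply(seq_len(m), function(g) W * outer(U[, g], Vf[, g]))

  Xsrc <- matrix(0, n, Ttot); Phi <- matrix(0, n, Ttot)
  Xp <- matrix(0, n, L); Es <- matrix(0, ch, L)
  Ks <- array(0, c(n, ch, L)); Fs <- array(0, c(n, n, L))
  Pprev <- array(0, c(n, n, L)); Pps <- array(0, c(n, n, L))
  Sinvs <- array(0, c(ch, ch, L))
  Dsim <- matrix(0, ch, h)
  gH <- matrix(0, ch, n)
  loss_kf <- 0; loss_fs <- 0

  x <- as.numeric(x0); P <- P0
  for (t in seq_len(L)) {
    g <- labels[t]
    phi <- tanh(svec * x + Voff)
    Xsrc[, t] <- x; Phi[, t] <- phi
    xp <- x + as.numeric(M[[g]] %*% phi) - D * x + C
    w <- svec * (1 - phi^2)
    F_t <- diag(n) + M[[g]] %*% diag(w, n) - diag(D, n)
    Pprev[, , t] <- P
    Pp <- F_t %*% P %*% t(F_t) + diag(qdiag, n)
    S_t <- H %*% Pp %*% t(H)
    diag(S_t) <- diag(S_t) + rdiag
    S_t <- (S_t + t(S_t)) / 2
    diag(S_t) <- diag(S_t) + 1e-10
    Sinv <- solve(S_t)
    e <- y[, t] - as.numeric(H %*% xp)
    K <- Pp %*% t(H) %*% Sinv
    x <- xp + as.numeric(K %*% e)
    P <- Pp - K %*% H %*% Pp
    P <- (P + t(P)) / 2
    Fs[, , t] <- F_t; Pps[, , t] <- Pp; Sinvs[, , t] <- Sinv
    Ks[, , t] <- K; Es[, t] <- e; Xp[, t] <- xp
    loss_kf <- loss_kf + if (whiten)
      sum(e * (Sinv %*% e)) + determinant(S_t)$modulus else sum(e^2)
  }
  z <- x
  for (t in (L + 1):Ttot) {
    g <- labels[t]
    phi <- tanh(svec * z + Voff)
    Xsrc[, t] <- z; Phi[, t] <- phi
    z <- z + as.numeric(M[[g]] %*% phi) - D * z + C
    d <- y[, t] - as.numeric(H %*% z)
    Dsim[, t - L] <- d
    loss_fs <- loss_fs + fs_weight * sum(d^2)
    gH <- gH - 2 * fs_weight * outer(d, z)
  }

  gM <- lapply(seq_len(m), function(g) matrix(0, n, n))
  gD <- numeric(n); gC <- numeric(n); gs <- numeric(n); gV <- numeric(n)
  gq <- numeric(n); gr <- numeric(ch)

  stepback <- function(xbar_p, wbar, t) {
    g <- labels[t]
    xsrc <- Xsrc[, t]; phi <- Phi[, t]
    dphi <- 1 - phi^2
    gM[[g]] <<- gM[[g]] + outer(xbar_p, phi)
    gD <<- gD - xbar_p * xsrc
    gC <<- gC + xbar_p
    phibar <- as.numeric(t(M[[g]]) %*% xbar_p)
    gs <<- gs + dphi * wbar
    phibar <- phibar - 2 * (svec * phi) * wbar
    abar <- dphi * phibar
    gV <<- gV + abar
    gs <<- gs + xsrc * abar
    xbar_p - D * xbar_p + svec * abar
  }

  xbar <- numeric(n)
  for (t in Ttot:(L + 1)) {
    xbar <- xbar - 2 * fs_weight * as.numeric(t(H) %*% Dsim[, t - L])
    xbar <- stepback(xbar, numeric(n), t)
  }
  Pbar <- matrix(0, n, n)
  for (t in L:1) {
    Pbar <- (Pbar + t(Pbar)) / 2
    K <- matrix(Ks[, , t], n, ch)
    F_t <- matrix(Fs[, , t], n, n)
    Pp <- matrix(Pps[, , t], n, n)
    Sinv <- matrix(Sinvs[, , t], ch, ch)
    Pm <- matrix(Pprev[, , t], n, n)
    e <- Es[, t]; xp <- Xp[, t]

    Kbar <- outer(xbar, e) - Pbar %*% Pp %*% t(H)
    se <- as.numeric(Sinv %*% e)
    ebar <- as.numeric(t(K) %*% xbar) + if (whiten) 2 * se else 2 * e
    Ppbar <- Pbar - t(H) %*% t(K) %*% Pbar
    gH <- gH - t(K) %*% Pbar %*% Pp
    xpbar <- xbar - as.numeric(t(H) %*% ebar)
    gH <- gH - outer(ebar, xp)
    Ppbar <- Ppbar + Kbar %*% Sinv %*% H
    Sinvbar <- H %*% Pp %*% Kbar
    if (whiten) Sinvbar <- Sinvbar + outer(e, e)
    Sbar <- -Sinv %*% Sinvbar %*% Sinv
    if (whiten) Sbar <- Sbar + Sinv
    Sbar <- (Sbar + t(Sbar)) / 2
    gH <- gH + Sinv %*% t(Kbar) %*% Pp
    gr <- gr + diag(Sbar)
    Ppbar <- Ppbar + t(H) %*% Sbar %*% H
    gH <- gH + 2 * Sbar %*% H %*% Pp
    gq <- gq + diag(Ppbar)
    Fbar <- (Ppbar + t(Ppbar)) %*% F_t %*% Pm
    Pbar <- t(F_t) %*% Ppbar %*% F_t
    g <- labels[t]
    w <- svec * (1 - Phi[, t]^2)
    gM[[g]] <- gM[[g]] + Fbar %*% diag(w, n)
    wbar <- diag(t(M[[g]]) %*% Fbar)
    gD <- gD - diag(Fbar)
    xbar <- stepback(xpbar, wbar, t)
  }

  gW <- matrix(0, n, n)
  gU <- matrix(0, n, m); gVf <- matrix(0, n, m)
  for (g in seq_len(m)) {
    gW <- gW + gM[[g]] * outer(U[, g], Vf[, g])
    gMW <- gM[[g]] * W
    gU[, g] <- as.numeric(gMW %*% Vf[, g])
    gVf[, g] <- as.numeric(t(gMW) %*% U[, g])
  }
  list(ok = TRUE, loss_kf = loss_kf, loss_fs = loss_fs,
       grad_W = gW, grad_U = gU, grad_Vf = gVf, grad_D = gD, grad_C = gC,
       grad_svec = gs, grad_Voff = gV, grad_H = gH,
       grad_qdiag = gq, grad_rdiag = gr)
}
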