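// Inner loop of the dual-estimation fit: one randomly drawn data window is
// processed by an extended Kalman filter (predict with the modulated
// nonlinear update, linearize, correct with the lead field), followed by a
// noiseless free-simulation forecast over the next `h` samples. The summed
// innovation SSE plus forecast SSE is backpropagated analytically through
// the full filter recursion — mean, covariance and gain — and through the
// rollout, yielding exact reverse-mode gradients for every parameter
// including the diagonal noise covariances. The only non-differentiated
// pieces are the constant 1e-10 jitter and the rare fallback
// regularization of a numerically singular innovation covariance.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List cpp_window_grad(const arma::mat& y,        // c x (L + h)
                           const arma::ivec& labels,  // length L + h, 1-based
                           const int L, const int h,
                           const arma::vec& x0, const arma::mat& P0,
                           const arma::mat& W,
                           const arma::mat& U, const arma::mat& Vf,
                           const arma::vec& D, const arma::vec& C,
                           const arma::vec& svec, const arma::vec& Voff,
                           const arma::mat& H,
                           const arma::vec& qdiag, const arma::vec& rdiag,
                           const bool whiten = false,
                           const double fs_weight = 1.0,
                           const bool want_states = false) {
  const int n = W.n_rows;
  const int c = H.n_rows;
  const int m = U.n_cols;
  const int Ttot = L + h;
  if ((int)y.n_cols < Ttot || (int)labels.n_elem < Ttot)
    Rcpp::stop("window shorter than kalman length + horizon");

  // effective per-regime weights M_g = W o (u_g v_g^T)
  cube M(n, n, m);
  for (int g = 0; g < m; ++g)
    M.slice(g) = W % (U.col(g) * Vf.col(g).t());

  mat Xsrc(n, Ttot, fill::zeros);   // state each step started from
  mat Phi(n, Ttot, fill::zeros);    // tanh activation at the source state
  mat Xp(n, L, fill::zeros);        // predicted means
  mat Es(c, L, fill::zeros);        // innovations
  mat Dsim(c, h, fill::zeros);      // forecast residuals
  mat Xfilt(n, L, fill::zeros);
  cube Ks(n, c, L), Fs(n, n, L), Pprev(n, n, L), Pps(n, n, L);
  cube Sinvs(c, c, L);

  double loss_kf = 0.0, loss_fs = 0.0;
  bool ok = true;

  // ---- forward: extended Kalman filter over the first L samples ----
  vec x = x0;
  mat P = P0;
  const mat In = eye(n, n);
  for (int t = 0; t < L && ok; ++t) {
    const int g = labels(t) - 1;
    if (g < 0 || g >= m) Rcpp::stop("regime label out of range");
    vec phi = tanh(svec % x + Voff);
    Xsrc.col(t) = x;
    Phi.col(t) = phi;
    vec xp = x + M.slice(g) * phi - D % x + C;
    vec w = svec % (1.0 - phi % phi);
    mat F = In + M.slice(g) * diagmat(w);
    F.diag() -= D;
    Pprev.slice(t) = P;
    mat Pp = F * P * F.t();
    Pp.diag() += qdiag;
    mat S = H * Pp * H.t();
    S.diag() += rdiag;
    S = 0.5 * (S + S.t());
    S.diag() += 1e-10;
    mat Sinv;
    if (!inv_sympd(Sinv, S)) {
      S.diag() += 1e-6 * (1.0 + S.diag().max());
      if (!inv_sympd(Sinv, S)) { ok = false; break; }
    }
    vec e = y.col(t) - H * xp;
    mat K = Pp * H.t() * Sinv;
    x = xp + K * e;
    P = Pp - K * H * Pp;
    P = 0.5 * (P + P.t());
    if (!x.is_finite()) { ok = false; break; }
    Fs.slice(t) = F;
    Pps.slice(t) = Pp;
    Sinvs.slice(t) = Sinv;
    Ks.slice(t) = K;
    Es.col(t) = e;
    Xp.col(t) = xp;
    Xfilt.col(t) = x;
    if (whiten) {
      double ld, sgn;
      log_det(ld, sgn, S);
      loss_kf += dot(e, Sinv * e) + ld;
    } else {
      loss_kf += dot(e, e);
    }
  }

  // ---- forward: noiseless free simulation over the next h samples ----
  vec zfin(n, fill::zeros);
  if (ok) {
    vec z = x;
    for (int t = L; t < Ttot && ok; ++t) {
      const int g = labels(t) - 1;
      if (g < 0 || g >= m) Rcpp::stop("regime label out of range");
      vec phi = tanh(svec % z + Voff);
      Xsrc.col(t) = z;
      Phi.col(t) = phi;
      z = z + M.slice(g) * phi - D % z + C;
      if (!z.is_finite()) { ok = false; break; }
      Dsim.col(t - L) = y.col(t) - H * z;
      loss_fs += fs_weight * dot(Dsim.col(t - L), Dsim.col(t - L));
    }
    zfin = z;
  }

  cube gM(n, n, m, fill::zeros);
  vec gD(n, fill::zeros), gC(n, fill::zeros);
  vec gs(n, fill::zeros), gV(n, fill::zeros);
  vec gq(n, fill::zeros), gr(c, fill::zeros);
  mat gH(c, n, fill::zeros);

  if (ok) {
    // shared tail of one dynamics step: given the adjoint `xbar_p` of the
    // step output and the adjoint `wbar` of the Jacobian's activation-slope
    // vector (zero in free simulation), accumulate parameter gradients and
    // return the adjoint of the source state.
    auto stepback = [&](const vec& xbar_p, const vec& wbar, int t) -> vec {
      const int g = labels(t) - 1;
      const vec xsrc = Xsrc.col(t);
      const vec phi = Phi.col(t);
      const vec dphi = 1.0 - phi % phi;
      gM.slice(g) += xbar_p * phi.t();
      gD += -xbar_p % xsrc;
      gC += xbar_p;
      vec phibar = M.slice(g).t() * xbar_p;
      // w = svec o (1 - phi^2)
      gs += dphi % wbar;
      phibar += -2.0 * (svec % phi) % wbar;
      vec abar = dphi % phibar;          // a = svec o x + Voff
      gV += abar;
      gs += xsrc % abar;
      return xbar_p - D % xbar_p + svec % abar;
    };

    // backward through the free simulation (the forecast state z_t is the
    // source of step t+1, or the final z; gH needs d * z^T)
    vec xbar(n, fill::zeros);
    const vec zero_n = zeros<vec>(n);
    for (int t = Ttot - 1; t >= L; --t) {
      vec z_t = (t + 1 < Ttot) ? vec(Xsrc.col(t + 1)) : zfin;
      xbar += -2.0 * fs_weight * H.t() * Dsim.col(t - L);
      gH += -2.0 * fs_weight * Dsim.col(t - L) * z_t.t();
      xbar = stepback(xbar, zero_n, t);
    }
    // backward through the filter: adjoints of the filtered mean and
    // covariance flow together
    mat Pbar(n, n, fill::zeros);
    for (int t = L - 1; t >= 0; --t) {
      Pbar = 0.5 * (Pbar + Pbar.t());
      const mat& K = Ks.slice(t);
      const mat& F = Fs.slice(t);
      const mat& Pp = Pps.slice(t);
      const mat& Sinv = Sinvs.slice(t);
      const mat& Pm = Pprev.slice(t);
      const vec e = Es.col(t);
      const vec xp = Xp.col(t);

      // x_t = xp + K e ; P_t = Pp - K H Pp
      mat Kbar = xbar * e.t() - Pbar * Pp * H.t();
      vec se = Sinv * e;
      vec ebar = K.t() * xbar + (whiten ? 2.0 * se : 2.0 * e);
      mat Ppbar = Pbar - H.t() * K.t() * Pbar;
      gH += -K.t() * Pbar * Pp;
      // e = y - H xp
      vec xpbar = xbar - H.t() * ebar;
      gH += -ebar * xp.t();
      // K = Pp H^T Sinv; whitened loss adds e^T Sinv e + log det S
      Ppbar += Kbar * Sinv * H;          // Sinv, Pp symmetric
      mat Sinvbar = H * Pp * Kbar;
      if (whiten) Sinvbar += e * e.t();
      mat Sbar = -Sinv * Sinvbar * Sinv;
      if (whiten) Sbar += Sinv;          // d(log det S)/dS
      Sbar = 0.5 * (Sbar + Sbar.t());
      gH += Sinv * Kbar.t() * Pp;
      // S = H Pp H^T + diag(r)
      gr += Sbar.diag();
      Ppbar += H.t() * Sbar * H;
      gH += 2.0 * Sbar * H * Pp;
      // Pp = F P F^T + diag(q)
      gq += Ppbar.diag();
      mat Fbar = (Ppbar + Ppbar.t()) * F * Pm;
      Pbar = F.t() * Ppbar * F;
      // F = I + M diag(w) - diag(D)
      const int g = labels(t) - 1;
      gM.slice(g) += Fbar * diagmat(svec % (1.0 - square(Phi.col(t))));
      vec wbar = diagvec(M.slice(g).t() * Fbar);
      gD += -Fbar.diag();
      xbar = stepback(xpbar, wbar, t);
    }
  }

  mat gW(n, n, fill::zeros);
  mat gU(n, m, fill::zeros), gVf(n, m, fill::zeros);
  for (int g = 0; g < m; ++g) {
    gW += gM.slice(g) % (U.col(g) * Vf.col(g).t());
    mat gMW = gM.slice(g) % W;
    gU.col(g) = gMW * Vf.col(g);
    gVf.col(g) = gMW.t() * U.col(g);
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("ok") = ok,
    Rcpp::Named("loss_kf") = loss_kf,
    Rcpp::Named("loss_fs") = loss_fs,
    Rcpp::Named("grad_W") = gW,
    Rcpp::Named("grad_U") = gU,
    Rcpp::Named("grad_Vf") = gVf,
    Rcpp::Named("grad_D") = gD,
    Rcpp::Named("grad_C") = gC,
    Rcpp::Named("grad_svec") = gs,
    Rcpp::Named("grad_Voff") = gV,
    Rcpp::Named("grad_H") = gH,
    Rcpp::Named("grad_qdiag") = gq,
    Rcpp::Named("grad_rdiag") = gr);
  if (want_states) out["x_filt"] = Xfilt;
  return out;
}
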