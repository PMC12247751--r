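#' Hidden-Markov regime-switching specification
#'
#' @param A m x m transition probability matrix. Rows that do not sum to 1
#'   are renormalized with a warning when \code{renormalize = TRUE} (the
#'   default), otherwise rejected.
#' @param pi initial state probability vector (renormalized the same way).
#' @param renormalize renormalize rows of A and pi to sum to 1.
#' @return An object of class \code{hmm_spec}.
#' @export
hmm_spec <- function(A, pi = rep(1 / nrow(A), nrow(A)), renormalize = TRUE) {
  A <- as.matrix(A)
  pi <- as.numeric(pi)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (length(pi) != nrow(A)) stop("pi length must match A")
  if (any(A < 0) || any(pi < 0)) stop("probabilities must be nonnegative")
  rs <- rowSums(A)
  if (any(abs(rs - 1) > 1e-12)) {
    if (!renormalize) stop("rows of A must sum to 1")
    warning("rows of A do not sum to 1; renormalizing", call. = FALSE)
    A <- A / rs
  }
  if (abs(sum(pi) - 1) > 1e-12) {
    if (!renormalize) stop("pi must sum to 1")
    pi <- pi / sum(pi)
  }
  structure(list(A = A, pi = pi), class = "hmm_spec")
}

#' Default sticky regime chain
#'
#' The default transition structure \code{0.999 I + (0.001/m) (11' - I)}
#' (self-stick probability near 0.999, uniform escape) does not have unit row
#' sums as written; rows are renormalized, preserving the near-diagonal
#' structure.
#'
#' @param m number of regimes.
#' @return An [hmm_spec()].
#' @export
default_hmm <- function(m) {
  A <- 0.999 * diag(m) + (0.001 / m) * (matrix(1, m, m) - diag(m))
  suppressWarnings(hmm_spec(A, rep(1 / m, m)))
}

#' Configuration of the synthetic ground-truth generator
#'
#' Defaults reproduce the generator's study conditions: 20 excitatory and 20
#' paired inhibitory populations observed through a 20-channel random lead
#' field at 250 Hz for 20,000 timesteps (80 s), with 3 regimes switched by a
#' sticky hidden-Markov chain. Connectivity blocks combine a sparse part
#' (cubed uniforms scaled by 16/20), a low-rank part (factors of cubed
#' uniforms plus 0.2-scaled uniforms, rank n/4) and a uniform diagonal; 75\%
#' of off-diagonal excitatory-source entries are then masked to zero.
#' Modulation vectors are drawn around 1 (regime mean mu ~ N(1, 0.1); spread
#' sigma from a uniform- or normal-family branch chosen by a fair coin) so the
#' modulations rescale connections only moderately.
#'
#' @param n_exc,n_inh numbers of excitatory/inhibitory populations.
#' @param m number of regimes.
#' @param T_len number of simulated timesteps.
#' @param fs nominal sampling rate (Hz).
#' @param n_channels number of observation channels (default \code{n_exc}).
#' @param ws_scale prefactor of the sparse connectivity part.
#' @param lowrank_mix weight of the uniform term in the low-rank factors.
#' @param sparsity_frac fraction of off-diagonal Wee/Wei entries masked to 0.
#' @param S_exc,S_inh group sigmoid slopes.
#' @param D_exc_base,D_inh_base,D_jitter leak magnitudes: D = base +
#'   jitter * U(0,1) per population.
#' @param wie_min,wie_max magnitude range of the diagonal I-to-E couplings
#'   (drawn as \code{-U(wie_min, wie_max)}). The lower bound is kept away
#'   from zero: an inhibitory population whose only route to the observed
#'   excitatory populations vanishes is unidentifiable in principle, which
#'   would make ground-truth recovery ill-posed rather than merely hard.
#' @param q_diag process noise variance (diagonal of Q).
#' @param r_base,r_jitter measurement noise variances: diag(R) = r_base +
#'   r_jitter * U(0,1) per channel.
#' @param mu_mean,mu_sd distribution of each regime's modulation mean.
#' @param sigma_unif_mean,sigma_unif_sd spread distribution, uniform branch.
#' @param sigma_norm_mean,sigma_norm_sd spread distribution, normal branch.
#' @param pin_first_gamma fix regime 1's modulation at the all-ones matrix
#'   (the unmodulated baseline; with \code{m = 1} this generates stationary
#'   single-regime data).
#' @param require_all_regimes resample the regime sequence until every regime
#'   appears at least \code{min_regime_samples} times (a recovery study
#'   cannot probe a modulation that is never active); the sticky chain makes
#'   missing regimes possible at short T.
#' @param min_regime_samples minimum samples per regime when
#'   \code{require_all_regimes} is set.
#' @return list of class \code{synth_config}.
#' @export
synth_config <- function(n_exc = 20, n_inh = n_exc, m = 3, T_len = 20000,
                         fs = 250, n_channels = n_exc,
                         ws_scale = 16 / 20, lowrank_mix = 0.2,
                         sparsity_frac = 0.75,
                         wie_min = 0.3, wie_max = 1,
                         S_exc = 2.5, S_inh = 1,
                         D_exc_base = 0.65, D_inh_base = 0.8, D_jitter = 0.02,
                         q_diag = 0.25, r_base = 0.2, r_jitter = 0.1,
                         mu_mean = 1, mu_sd = 0.1,
                         sigma_unif_mean = 0.4, sigma_unif_sd = 0.1,
                         sigma_norm_mean = 0.05, sigma_norm_sd = 0.01,
                         pin_first_gamma = FALSE,
                         require_all_regimes = TRUE,
                         min_regime_samples = 100) {
  cfg <- as.list(environment())
  if (cfg$n_exc < 2) stop("n_exc must be at least 2")
  if (cfg$m < 1) stop("m must be at least 1")
  if (cfg$T_len < 1) stop("T_len must be positive")
  structure(cfg, class = "synth_config")
}

# sparse-plus-low-rank nonnegative block per the generator's recipe
synth_exc_block <- function(nr, nc, ws_scale, lowrank_mix) {
  Ws <- ws_scale * matrix(stats::runif(nr * nc)^3, nr, nc)
  r <- max(1L, floor(nc / 4))
  Wl1 <- matrix(stats::runif(nr * r)^3 + lowrank_mix * stats::runif(nr * r), nr, r)
  Wl2 <- matrix(stats::runif(nc * r)^3 + lowrank_mix * stats::runif(nc * r), nc, r)
  Wd <- stats::runif(min(nr, nc))
  B <- Ws + Wl1 %*% t(Wl2)
  k <- min(nr, nc)
  B[cbind(seq_len(k), seq_len(k))] <- B[cbind(seq_len(k), seq_len(k))] + Wd
  B
}

#' Draw a random structured connectivity matrix
#'
#' Excitatory-source blocks are built as sparse part + low-rank part +
#' diagonal (see [synth_config()]), then masked so that exactly
#' \code{ceiling(sparsity_frac * n_offdiag)} off-diagonal entries of each
#' block are zero. Inhibitory-source blocks are diagonal with entries drawn
#' as \code{-U(0, 1)}.
#'
#' @param n_exc,n_inh block dimensions (\code{n_exc >= 2}).
#' @param seed optional integer seed.
#' @param config a [synth_config()] supplying the distribution parameters.
#' @return A [structured_connectivity()].
#' @export
generate_connectivity <- function(n_exc = 20, n_inh = n_exc, seed = NULL,
                                  config = synth_config(n_exc = n_exc,
                                                        n_inh = n_inh)) {
  if (n_exc < 2) stop("n_exc must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  Wee <- synth_exc_block(n_exc, n_exc, config$ws_scale, config$lowrank_mix)
  Wei <- synth_exc_block(n_inh, n_exc, config$ws_scale, config$lowrank_mix)
  mask <- random_sparsity_mask(n_exc, n_inh, frac = config$sparsity_frac)
  Wee <- Wee * mask$ee
  Wei <- Wei * mask$ei
  Wie <- -stats::runif(min(n_exc, n_inh), config$wie_min, config$wie_max)
  Wii <- -stats::runif(n_inh)
  structured_connectivity(Wee = Wee,
                          Wie = diag_rect(Wie, n_exc, n_inh),
                          Wei = Wei,
                          Wii = diag_rect(Wii, n_inh, n_inh),
                          mask = mask)
}

#' Draw regime modulation matrices
#'
#' For each regime: draw the regime mean \code{mu ~ N(1, 0.1)}; flip a fair
#' coin between a uniform and a normal family; draw the spread
#' \code{sigma ~ N(0.4, 0.1)} (uniform branch) or \code{N(0.05, 0.01)}
#' (normal branch); draw the factor vector from
#' \code{U(mu - sigma/2, mu + sigma/2)} or \code{N(mu, sigma)}; clip negatives
#' to 0 and form the symmetric rank-1 matrix \code{g \%o\% g}.
#'
#' @param m number of regimes.
#' @param n number of populations.
#' @param seed optional integer seed.
#' @param config a [synth_config()] supplying the branch distributions.
#' @param pin_first if \code{TRUE}, regime 1 is the exact all-ones baseline.
#' @return list of \code{m} [modulation_matrix()] objects.
#' @export
generate_modulations <- function(m, n, seed = NULL,
                                 config = synth_config(),
                                 pin_first = config$pin_first_gamma) {
  if (m < 1) stop("m must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    if (i == 1L && pin_first) {
      out[[i]] <- modulation_matrix(rep(1, n), regime_index = 1L, pinned = TRUE)
      next
    }
    mu <- stats::rnorm(1, config$mu_mean, config$mu_sd)
    use_unif <- stats::runif(1) < 0.5
    if (use_unif) {
      sigma <- stats::rnorm(1, config$sigma_unif_mean, config$sigma_unif_sd)
      g <- stats::runif(n, mu - sigma / 2, mu + sigma / 2)
    } else {
      sigma <- stats::rnorm(1, config$sigma_norm_mean, config$sigma_norm_sd)
      g <- stats::rnorm(n, mu, abs(sigma))
    }
    g <- pmax(g, 0)
    out[[i]] <- modulation_matrix(g, regime_index = as.integer(i))
  }
  out
}

#' Sample a regime-label sequence from the hidden-Markov chain
#'
#' @param hmm an [hmm_spec()].
#' @param T_len sequence length.
#' @param seed optional integer seed.
#' @return integer vector of length \code{T_len} with values in \code{1..m}.
#' @export
generate_regimes <- function(hmm, T_len, seed = NULL) {
  stopifnot(inherits(hmm, "hmm_spec"))
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(hmm$A)
  labels <- integer(T_len)
  labels[1] <- sample.int(m, 1, prob = hmm$pi)
  for (t in seq_len(T_len - 1L)) {
    labels[t + 1L] <- sample.int(m, 1, prob = hmm$A[labels[t], ])
  }
  labels
}

#' Generate a full ground-truth bundle for parameter-recovery studies
#'
#' Draws a complete parameter set (connectivity, modulations, leaks, lead
#' field with standard-normal excitatory entries and zero inhibitory columns,
#' diagonal noise covariances), samples a regime sequence from the sticky
#' hidden-Markov chain, forward-simulates the network, and packages the truth
#' together with the observed recording.
#'
#' @param config a [synth_config()].
#' @param seed integer seed controlling every draw.
#' @return An object of class \code{ground_truth_bundle}: list with
#'   \code{params} ([mindy_params()]), \code{labels}, \code{states} (n x T),
#'   \code{recording} ([labeled_recording()]), \code{generator_seed},
#'   \code{config}.
#' @export
generate_dataset <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  ne <- config$n_exc; ni <- config$n_inh
  n <- ne + ni
  nc <- config$n_channels
  if (nc < 1) stop("n_channels must be positive")

  W <- generate_connectivity(ne, ni, seed = NULL, config = config)
  gammas <- generate_modulations(config$m, n, seed = NULL, config = config)
  D <- c(config$D_exc_base + config$D_jitter * stats::runif(ne),
         config$D_inh_base + config$D_jitter * stats::runif(ni))
  Hexc <- matrix(stats::rnorm(nc * ne), nc, ne)
  H <- cbind(Hexc, matrix(0, nc, ni))
  Q <- config$q_diag * diag(n)
  R <- diag(config$r_base + config$r_jitter * stats::runif(nc), nc)
  params <- mindy_params(W = W, gammas = gammas, D = D,
                         S = c(exc = config$S_exc, inh = config$S_inh),
                         V = 0, C = 0, H = H, Q = Q, R = R)

  hmm <- default_hmm(config$m)
  labels <- generate_regimes(hmm, config$T_len)
  if (isTRUE(config$require_all_regimes) && config$m > 1) {
    tries <- 0
    while (min(tabulate(labels, config$m)) < config$min_regime_samples) {
      labels <- generate_regimes(hmm, config$T_len)
      tries <- tries + 1
      if (tries > 1000)
        stop("could not draw a regime sequence covering all regimes; ",
             "increase T_len or lower min_regime_samples")
    }
  }
  sim <- simulate_mindy(params, labels, x0 = numeric(n), seed = NULL)
  rec <- labeled_recording(sim$y, fs = config$fs, labels = labels)
  structure(list(params = params, labels = labels, states = sim$states,
                 recording = rec, generator_seed = seed, config = config),
            class = "ground_truth_bundle")
}

#' @export
print.ground_truth_bundle <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_bundle> seed %d: n = %d, m = %d, T = %d, %d channels\n",
    x$generator_seed, n_populations(x$params), length(x$params$gammas),
    ncol(x$recording$y), nrow(x$recording$y)))
  invisible(x)
}
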