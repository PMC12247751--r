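#' Structured excitatory/inhibitory connectivity
#'
#' Builds the signed, block-structured connectivity matrix used by the model.
#' The state vector stacks excitatory populations first and inhibitory
#' populations second, and the assembled weight matrix has block layout
#' \deqn{W = \begin{pmatrix} W_{ee} & W_{ie} \\ W_{ei} & W_{ii} \end{pmatrix}}
#' where the excitatory-source blocks \code{Wee} (E to E) and \code{Wei}
#' (E to I) are nonnegative and dense up to a fixed sparsity mask, and the
#' inhibitory-source blocks \code{Wie} (I to E) and \code{Wii} (I to I) are
#' nonpositive and diagonal (inhibitory populations project only locally).
#'
#' A fixed binary mask zeroes 75\% (by default) of the off-diagonal entries of
#' \code{Wee} and \code{Wei}; the mask is part of the object and is held fixed
#' over a fit.
#'
#' @param Wee n_exc x n_exc nonnegative matrix (excitatory to excitatory).
#' @param Wie n_exc x n_inh nonpositive diagonal matrix (inhibitory to
#'   excitatory); a vector of diagonal values is also accepted.
#' @param Wei n_inh x n_exc nonnegative matrix (excitatory to inhibitory).
#' @param Wii n_inh x n_inh nonpositive diagonal matrix; a vector of diagonal
#'   values is also accepted.
#' @param mask list with binary (0/1) matrices \code{ee} (n_exc x n_exc) and
#'   \code{ei} (n_inh x n_exc); 1 marks an entry that is allowed to be
#'   nonzero. Diagonal entries must be 1. If \code{NULL}, a fully dense mask
#'   is used.
#' @param validate check all structural invariants (signs, diagonality, mask
#'   consistency); set \code{FALSE} only for internal intermediate objects.
#' @return An object of class \code{structured_connectivity}.
#' @seealso [generate_connectivity()], [random_sparsity_mask()], [assemble_W()]
#' @export
structured_connectivity <- function(Wee, Wie, Wei, Wii, mask = NULL,
                                    validate = TRUE) {
  Wee <- as.matrix(Wee)
  Wei <- as.matrix(Wei)
  n_exc <- nrow(Wee)
  n_inh <- nrow(Wei)
  if (is.vector(Wie) && !is.matrix(Wie)) Wie <- diag_rect(Wie, n_exc, n_inh)
  if (is.vector(Wii) && !is.matrix(Wii)) Wii <- diag_rect(Wii, n_inh, n_inh)
  Wie <- as.matrix(Wie)
  Wii <- as.matrix(Wii)
  if (is.null(mask)) {
    mask <- list(ee = matrix(1, n_exc, n_exc), ei = matrix(1, n_inh, n_exc))
  }
  obj <- structure(
    list(n_exc = n_exc, n_inh = n_inh,
         Wee = Wee, Wie = Wie, Wei = Wei, Wii = Wii,
         sparsity_mask = mask),
    class = "structured_connectivity")
  if (validate) validate_connectivity(obj)
  obj
}

#' @export
print.structured_connectivity <- function(x, ...) {
  nz <- sum(x$sparsity_mask$ee) + sum(x$sparsity_mask$ei)
  tot <- length(x$sparsity_mask$ee) + length(x$sparsity_mask$ei)
  cat(sprintf(
    "<structured_connectivity> %d excitatory + %d inhibitory populations\n",
    x$n_exc, x$n_inh))
  cat(sprintf("  mask keeps %d / %d entries of Wee & Wei (%.1f%% zeroed)\n",
              nz, tot, 100 * (1 - nz / tot)))
  invisible(x)
}

# rectangular "diagonal" matrix with values d on entries [j, j]
diag_rect <- function(d, nr, nc) {
  M <- matrix(0, nr, nc)
  k <- min(nr, nc, length(d))
  M[cbind(seq_len(k), seq_len(k))] <- d[seq_len(k)]
  M
}

validate_connectivity <- function(w) {
  stopifnot(inherits(w, "structured_connectivity"))
  ne <- w$n_exc; ni <- w$n_inh
  if (!all(dim(w$Wee) == c(ne, ne))) stop("Wee must be n_exc x n_exc")
  if (!all(dim(w$Wie) == c(ne, ni))) stop("Wie must be n_exc x n_inh")
  if (!all(dim(w$Wei) == c(ni, ne))) stop("Wei must be n_inh x n_exc")
  if (!all(dim(w$Wii) == c(ni, ni))) stop("Wii must be n_inh x n_inh")
  if (any(w$Wee < 0) || any(w$Wei < 0))
    stop("excitatory-source blocks Wee, Wei must be nonnegative")
  if (any(w$Wie > 0) || any(w$Wii > 0))
    stop("inhibitory-source blocks Wie, Wii must be nonpositive")
  if (any(off_diagonal(w$Wie) != 0) || any(off_diagonal(w$Wii) != 0))
    stop("Wie and Wii must be diagonal")
  m <- w$sparsity_mask
  if (!all(dim(m$ee) == c(ne, ne)) || !all(dim(m$ei) == c(ni, ne)))
    stop("sparsity mask dimensions do not match blocks")
  if (!all(m$ee %in% c(0, 1)) || !all(m$ei %in% c(0, 1)))
    stop("sparsity mask must be binary")
  if (any(diag(m$ee) != 1)) stop("mask must keep the Wee diagonal")
  k <- min(ne, ni)
  if (any(m$ei[cbind(seq_len(k), seq_len(k))] != 1))
    stop("mask must keep the Wei diagonal")
  if (any(w$Wee[m$ee == 0] != 0) || any(w$Wei[m$ei == 0] != 0))
    stop("masked entries of Wee/Wei must be exactly zero")
  invisible(w)
}

off_diagonal <- function(M) {
  k <- min(dim(M))
  M[cbind(seq_len(k), seq_len(k))] <- 0
  M
}

#' Assemble the full connectivity matrix from its blocks
#'
#' @param w a [structured_connectivity()] object.
#' @return The (n_exc + n_inh) square matrix \code{rbind(cbind(Wee, Wie),
#'   cbind(Wei, Wii))}.
#' @export
assemble_W <- function(w) {
  rbind(cbind(w$Wee, w$Wie), cbind(w$Wei, w$Wii))
}

#' Draw a random sparsity mask for the excitatory-source blocks
#'
#' Selects, uniformly at random, a fixed fraction of the off-diagonal entries
#' of each excitatory-source block (\code{Wee}, \code{Wei}) and marks them as
#' structurally zero. Exactly \code{ceiling(frac * n_offdiag)} entries are
#' zeroed per block; diagonals are always kept.
#'
#' @param n_exc,n_inh block dimensions.
#' @param frac fraction of off-diagonal entries to zero (default 0.75).
#' @return list with binary matrices \code{ee} and \code{ei} (1 = keep).
#' @export
random_sparsity_mask <- function(n_exc, n_inh = n_exc, frac = 0.75) {
  one_block <- function(nr, nc) {
    m <- matrix(1, nr, nc)
    k <- min(nr, nc)
    # off-diagonal = everything except the paired [j, j] entries
    off <- setdiff(seq_along(m), cbind_index(seq_len(k), seq_len(k), nr))
    nzero <- ceiling(frac * length(off))
    m[sample(off, nzero)] <- 0
    m
  }
  list(ee = one_block(n_exc, n_exc), ei = one_block(n_inh, n_exc))
}

cbind_index <- function(i, j, nr) (j - 1L) * nr + i

#' Rank-1 nonnegative modulation matrix for one regime
#'
#' A modulation matrix \eqn{\Gamma_i = u v^\top} scales the baseline
#' connectivity element-wise (\eqn{W \odot \Gamma_i}) in regime \eqn{i}. The
#' rank-1 structure encodes spatially diffuse neuromodulation; nonnegativity
#' preserves the sign structure of \eqn{W}. The factors are stored; the dense
#' matrix is materialized on demand with [gamma_dense()].
#'
#' @param u,v nonnegative n-vectors; \code{v} defaults to \code{u}
#'   (symmetric modulation, as in the synthetic generator).
#' @param regime_index integer regime label in \code{1..m}.
#' @param pinned if \code{TRUE} the matrix is the exact all-ones baseline
#'   (\code{u}, \code{v} are forced to 1), so \eqn{W \odot \Gamma = W}.
#' @return An object of class \code{modulation_matrix}.
#' @export
modulation_matrix <- function(u, v = u, regime_index = 1L, pinned = FALSE) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (pinned) {
    u <- rep(1, length(u)); v <- rep(1, length(v))
  }
  if (any(u < 0) || any(v < 0))
    stop("modulation factors must be nonnegative")
  structure(list(regime_index = as.integer(regime_index),
                 u = u, v = v, pinned = isTRUE(pinned)),
            class = "modulation_matrix")
}

#' Materialize the dense modulation matrix
#' @param g a [modulation_matrix()].
#' @return the n x n matrix \code{u \%o\% v}.
#' @export
gamma_dense <- function(g) outer(g$u, g$v)

#' @export
print.modulation_matrix <- function(x, ...) {
  cat(sprintf("<modulation_matrix> regime %d, n = %d%s\n", x$regime_index,
              length(x$u), if (x$pinned) " (pinned to all-ones)" else ""))
  invisible(x)
}

#' Full parameter bundle of the modulated network model
#'
#' Collects everything the generative model and the fitting engine need:
#' the structured connectivity \code{W}, one rank-1 modulation matrix per
#' regime, the decay, activation and bias parameters, the lead field, and the
#' two noise covariances.
#'
#' Sign convention of the decay: \code{D} stores positive leak magnitudes and
#' the state update applies it as \code{- D * x} (activity decays toward
#' baseline at rate \code{D}); see the package vignette for the rationale.
#'
#' @param W a [structured_connectivity()].
#' @param gammas list of \code{m} [modulation_matrix()] objects, ordered by
#'   regime index 1..m.
#' @param D positive leak magnitudes, length n = n_exc + n_inh (recycled).
#' @param S sigmoid slope, either a named vector \code{c(exc=, inh=)} or a
#'   length-2 vector (excitatory, inhibitory group slopes).
#' @param V sigmoid offset, length n (recycled).
#' @param C baseline bias, length n (recycled).
#' @param H lead field, channels x n; columns over inhibitory populations
#'   must be zero (inhibitory activity is invisible to the sensors).
#' @param Q process noise covariance (n x n, symmetric PSD) of the state
#'   update noise.
#' @param R measurement noise covariance (channels x channels, symmetric PSD).
#' @param validate check invariants.
#' @return An object of class \code{mindy_params}.
#' @export
mindy_params <- function(W, gammas, D, S, V = 0, C = 0, H, Q, R,
                         validate = TRUE) {
  stopifnot(inherits(W, "structured_connectivity"))
  n <- W$n_exc + W$n_inh
  S <- as.numeric(S)
  if (length(S) != 2) stop("S must give one slope per group (exc, inh)")
  names(S) <- c("exc", "inh")
  p <- structure(list(
    W = W,
    gammas = gammas,
    D = rep_len(as.numeric(D), n),
    S = S,
    V = rep_len(as.numeric(V), n),
    C = rep_len(as.numeric(C), n),
    H = as.matrix(H),
    Q = as.matrix(Q),
    R = as.matrix(R)), class = "mindy_params")
  if (validate) validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "mindy_params"))
  validate_connectivity(p$W)
  n <- p$W$n_exc + p$W$n_inh
  m <- length(p$gammas)
  if (m < 1) stop("at least one regime (modulation matrix) is required")
  for (i in seq_len(m)) {
    g <- p$gammas[[i]]
    if (!inherits(g, "modulation_matrix")) stop("gammas must be modulation_matrix objects")
    if (length(g$u) != n) stop("modulation factor length must equal n")
    if (any(g$u < 0) || any(g$v < 0)) stop("modulation factors must be nonnegative")
  }
  if (ncol(p$H) != n) stop("H must have n columns")
  inh_cols <- (p$W$n_exc + 1):n
  if (any(p$H[, inh_cols] != 0))
    stop("lead-field columns over inhibitory populations must be zero")
  check_psd(p$Q, "Q"); check_psd(p$R, "R")
  if (nrow(p$Q) != n) stop("Q must be n x n")
  if (nrow(p$R) != nrow(p$H)) stop("R must be channels x channels")
  invisible(p)
}

check_psd <- function(M, name, tol = 1e-8) {
  if (!isSymmetric(unname(M), tol = 1e-8))
    stop(name, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1))
    stop(name, " must be positive semidefinite")
  invisible(TRUE)
}

#' @export
print.mindy_params <- function(x, ...) {
  cat(sprintf(
    "<mindy_params> n = %d (%d E + %d I), %d regime(s), %d channel(s)\n",
    x$W$n_exc + x$W$n_inh, x$W$n_exc, x$W$n_inh, length(x$gammas),
    nrow(x$H)))
  invisible(x)
}

# per-population slope vector (E slope on excitatory entries, I slope on
# inhibitory entries)
slope_vector <- function(p) {
  c(rep(p$S[["exc"]], p$W$n_exc), rep(p$S[["inh"]], p$W$n_inh))
}

n_populations <- function(p) p$W$n_exc + p$W$n_inh

#' Regime-labeled multichannel recording
#'
#' @param y channels x T numeric observation matrix.
#' @param fs sampling rate in Hz.
#' @param labels length-T integer regime labels in \code{1..m}.
#' @param channel_names optional character vector of channel names.
#' @param session_bounds optional integer vector of last-sample indices of
#'   each concatenated session (used to keep fitting windows within sessions).
#' @return An object of class \code{labeled_recording}.
#' @export
labeled_recording <- function(y, fs, labels, channel_names = NULL,
                              session_bounds = NULL) {
  y <- as.matrix(y)
  labels <- as.integer(labels)
  if (length(labels) != ncol(y))
    stop("labels length must equal the number of timepoints")
  if (any(labels < 1L)) stop("regime labels must be positive integers")
  if (!is.null(channel_names) && length(channel_names) != nrow(y))
    stop("channel_names length must equal the number of channels")
  structure(list(y = y, fs = as.numeric(fs), labels = labels,
                 channel_names = channel_names,
                 session_bounds = session_bounds),
            class = "labeled_recording")
}

#' @export
print.labeled_recording <- function(x, ...) {
  cat(sprintf(
    "<labeled_recording> %d channels x %d samples @ %g Hz, %d regime(s) (%.1f s)\n",
    nrow(x$y), ncol(x$y), x$fs, length(unique(x$labels)), ncol(x$y) / x$fs))
  invisible(x)
}
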