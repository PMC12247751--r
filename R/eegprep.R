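#' EEG preprocessing configuration
#'
#' @param band bandpass edges in Hz, \code{c(low, high)} with
#'   \code{0 < low < high < fs/2}.
#' @param channel_subset optional character vector of channel names to keep
#'   (order defines the output channel order).
#' @param filter_order order of the Butterworth bandpass prototype (applied
#'   forward-backward, so the effective attenuation is doubled).
#' @return list of class \code{preprocess_config}.
#' @export
preprocess_config <- function(band = c(0.5, 15), channel_subset = NULL,
                              filter_order = 4) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stop("band must be c(low, high) with 0 < low < high")
  structure(list(band = band, channel_subset = channel_subset,
                 filter_order = filter_order), class = "preprocess_config")
}

#' Preprocess raw multichannel recordings into a labeled recording
#'
#' Each session is bandpass-filtered per channel with a zero-phase
#' Butterworth filter, median-centered, and scaled by its mean absolute
#' deviation around the median (constant channels are left unscaled with a
#' warning); sessions are then concatenated in order and every sample is
#' labeled with its session's regime index 1..m. Session boundaries are
#' recorded so that fitting windows can avoid straddling concatenation seams.
#'
#' @param raw a channels x time numeric matrix (single session) or a list of
#'   such matrices (one per regime, in regime order). Row names, or
#'   \code{channel_names}, identify channels.
#' @param fs sampling rate in Hz; must exceed twice the upper band edge.
#' @param config a [preprocess_config()].
#' @param channel_names optional channel names (used when \code{raw} has no
#'   row names).
#' @return A [labeled_recording()] with per-session boundaries.
#' @export
preprocess <- function(raw, fs, config = preprocess_config(),
                       channel_names = NULL) {
  if (is.matrix(raw)) raw <- list(raw)
  if (!length(raw)) stop("no sessions supplied")
  raw <- lapply(raw, as.matrix)
  if (fs <= 2 * config$band[2])
    stop("sampling rate too low for the requested band (need fs > 2*high)")
  nm <- channel_names
  if (is.null(nm)) nm <- rownames(raw[[1]])
  if (!is.null(config$channel_subset)) {
    if (is.null(nm)) stop("channel subset requested but channels are unnamed")
    missing <- setdiff(config$channel_subset, nm)
    if (length(missing))
      stop("missing channel(s): ", paste(missing, collapse = ", "))
    keep <- match(config$channel_subset, nm)
    raw <- lapply(raw, function(x) x[keep, , drop = FALSE])
    nm <- config$channel_subset
  }

  bf <- signal::butter(config$filter_order,
                       config$band / (fs / 2), type = "pass")
  one_session <- function(x) {
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_len(nrow(x))) {
      if (diff(range(x[i, ])) == 0) {
        # a constant channel carries no signal; filtering it would only
        # inject edge transients, and its mean absolute deviation is zero
        warning("constant channel: centered to zero, scale left at 1",
                call. = FALSE)
        out[i, ] <- 0
        next
      }
      ch <- signal::filtfilt(bf, x[i, ])
      ch <- ch - stats::median(ch)
      s <- mean(abs(ch))
      if (s == 0) {
        warning("zero mean absolute deviation; leaving scale at 1",
                call. = FALSE)
        s <- 1
      }
      out[i, ] <- ch / s
    }
    out
  }
  proc <- lapply(raw, one_session)
  lens <- vapply(proc, ncol, integer(1))
  labels <- rep(seq_along(proc), lens)
  labeled_recording(do.call(cbind, proc), fs = fs, labels = labels,
                    channel_names = nm,
                    session_bounds = cumsum(lens))
}

#' Lead field with uniform common-reference coupling
#'
#' The standard lead field used for channel-resolved fits: each channel sees
#' its own excitatory population minus a small uniform contribution from all
#' excitatory populations, \eqn{H_{exc} = I - 0.05\,11^\top}, and nothing
#' from inhibitory populations.
#'
#' @param n_channels number of channels (= number of excitatory populations).
#' @return the \code{n_channels x 2*n_channels} matrix
#'   \code{[I - 0.05*11' | 0]}.
#' @export
build_lead_field <- function(n_channels) {
  if (n_channels < 1) stop("n_channels must be positive")
  Hexc <- diag(n_channels) - 0.05 * matrix(1, n_channels, n_channels)
  cbind(Hexc, matrix(0, n_channels, n_channels))
}

#' Fixed noise covariances for real-data fits
#'
#' Diagonal initializations used when fitting recorded EEG: process noise
#' \code{Q = 0.25 I} over the latent states and measurement noise
#' \code{R = 1.2 I} over the channels.
#'
#' @param n_channels number of observation channels.
#' @param n_states latent state dimension (default \code{2 * n_channels}:
#'   one excitatory and one inhibitory population per channel).
#' @return list with matrices \code{Q} (n_states square) and \code{R}
#'   (n_channels square).
#' @export
build_fixed_noise <- function(n_channels, n_states = 2 * n_channels) {
  list(Q = 0.25 * diag(n_states), R = 1.2 * diag(n_channels))
}
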