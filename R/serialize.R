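#' Save a parameter bundle, recording, or ground-truth bundle to JSON
#'
#' A single JSON container holds every matrix/vector at full precision
#' (exact binary round-trip for doubles) plus the architecture attributes
#' (population counts, number of regimes, pinned-baseline flag). Recordings
#' may also be exported as CSV with [write_recording_csv()].
#'
#' @param x a [mindy_params()], [labeled_recording()], or
#'   \code{ground_truth_bundle}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_mindy_json <- function(x, path) {
  payload <- encode_obj(x)
  # I(17) = 17 significant digits: exact binary round-trip for doubles
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

encode_obj <- function(x) {
  if (inherits(x, "mindy_params")) {
    list(type = "mindy_params",
         n_exc = x$W$n_exc, n_inh = x$W$n_inh, m = length(x$gammas),
         Wee = x$W$Wee, Wie = x$W$Wie, Wei = x$W$Wei, Wii = x$W$Wii,
         mask_ee = x$W$sparsity_mask$ee, mask_ei = x$W$sparsity_mask$ei,
         gamma_u = lapply(x$gammas, `[[`, "u"),
         gamma_v = lapply(x$gammas, `[[`, "v"),
         gamma_pinned = vapply(x$gammas, `[[`, logical(1), "pinned"),
         D = x$D, S = unname(x$S), V = x$V, C = x$C,
         H = x$H, Q = x$Q, R = x$R)
  } else if (inherits(x, "labeled_recording")) {
    list(type = "labeled_recording",
         y = x$y, fs = x$fs, labels = x$labels,
         channel_names = x$channel_names,
         session_bounds = x$session_bounds)
  } else if (inherits(x, "ground_truth_bundle")) {
    cfg <- unclass(x$config)
    list(type = "ground_truth_bundle",
         params = encode_obj(x$params),
         labels = x$labels,
         states = x$states,
         recording = encode_obj(x$recording),
         generator_seed = x$generator_seed,
         config = cfg)
  } else stop("unsupported object type for serialization")
}

#' Load an object written by [write_mindy_json()]
#'
#' @param path JSON file path.
#' @return the reconstructed object (class depends on the stored type).
#' @export
read_mindy_json <- function(path) {
  decode_obj(jsonlite::read_json(path, simplifyVector = TRUE))
}

decode_obj <- function(j) {
  switch(j$type,
    mindy_params = {
      mask <- list(ee = as.matrix(j$mask_ee) + 0, ei = as.matrix(j$mask_ei) + 0)
      W <- structured_connectivity(as.matrix(j$Wee), as.matrix(j$Wie),
                                   as.matrix(j$Wei), as.matrix(j$Wii),
                                   mask = mask)
      gammas <- lapply(seq_len(j$m), function(i) {
        u <- as.numeric(if (is.list(j$gamma_u)) j$gamma_u[[i]] else j$gamma_u[i, ])
        v <- as.numeric(if (is.list(j$gamma_v)) j$gamma_v[[i]] else j$gamma_v[i, ])
        modulation_matrix(u, v, regime_index = i, pinned = j$gamma_pinned[i])
      })
      mindy_params(W = W, gammas = gammas, D = j$D, S = j$S, V = j$V,
                   C = j$C, H = as.matrix(j$H), Q = as.matrix(j$Q),
                   R = as.matrix(j$R))
    },
    labeled_recording = labeled_recording(
      as.matrix(j$y), fs = j$fs, labels = j$labels,
      channel_names = if (length(j$channel_names)) j$channel_names else NULL,
      session_bounds = if (length(j$session_bounds)) j$session_bounds else NULL),
    ground_truth_bundle = {
      cfg <- do.call(synth_config, j$config)
      structure(list(params = decode_obj(j$params),
                     labels = as.integer(j$labels),
                     states = as.matrix(j$states),
                     recording = decode_obj(j$recording),
                     generator_seed = j$generator_seed,
                     config = cfg),
                class = "ground_truth_bundle")
    },
    stop("unknown serialized type: ", j$type))
}

#' Export a labeled recording as CSV
#'
#' One row per sample: \code{time_s}, \code{label}, then one column per
#' channel.
#'
#' @param rec a [labeled_recording()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "labeled_recording"))
  nm <- rec$channel_names
  if (is.null(nm)) nm <- paste0("ch", seq_len(nrow(rec$y)))
  df <- data.frame(time_s = (seq_len(ncol(rec$y)) - 1) / rec$fs,
                   label = rec$labels)
  df <- cbind(df, as.data.frame(t(rec$y), col.names = nm))
  names(df) <- c("time_s", "label", nm)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export per-iteration fit errors as CSV
#'
#' @param fit a [fit_mindy()] result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_loss_csv <- function(fit, path) {
  stopifnot(inherits(fit, "mindy_fit"))
  utils::write.csv(fit$loss_trace, path, row.names = FALSE)
  invisible(path)
}
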