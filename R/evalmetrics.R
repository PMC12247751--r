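#' Masked ground-truth recovery correlations
#'
#' Pearson correlations between true and fitted parameters, computed over the
#' entries that survive the true sparsity mask (structurally zero entries are
#' identical in both matrices and would inflate the correlation; they are
#' excluded by default). The full-W correlation additionally includes the
#' inhibitory-source diagonals. Modulation matrices are compared over their
#' effective excitatory sub-blocks (the masking of \code{W} propagates
#' through the Hadamard product). Pearson correlation is scale-invariant, so
#' recovery is assessed up to the overall scaling left free by the
#' \eqn{W \odot \Gamma} factorization.
#'
#' @param true_params,fitted_params [mindy_params()] bundles of matching
#'   architecture; the mask is taken from \code{true_params}.
#' @param use_mask restrict to mask-surviving entries (default). With
#'   \code{FALSE} all entries of each block are used.
#' @return An object of class \code{recovery_report}: list with
#'   \code{r_full_W}, \code{r_Wee}, \code{r_Wei}, per-regime vectors
#'   \code{r_gamma_EE} and \code{r_gamma_EI}, and \code{mask_used}.
#' @export
masked_correlation <- function(true_params, fitted_params, use_mask = TRUE) {
  wt <- true_params$W; wf <- fitted_params$W
  if (wt$n_exc != wf$n_exc || wt$n_inh != wf$n_inh)
    stop("parameter bundles have mismatched architecture")
  ne <- wt$n_exc; ni <- wt$n_inh
  mask <- wt$sparsity_mask
  if (!use_mask) {
    mask <- list(ee = matrix(1, ne, ne), ei = matrix(1, ni, ne))
  }
  ee_idx <- which(mask$ee == 1)
  ei_idx <- which(mask$ei == 1)

  pearson <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("correlation undefined: zero-variance vector")
    stats::cor(a, b)
  }

  k <- min(ne, ni)
  pair_idx <- cbind(seq_len(k), seq_len(k))
  full_vec <- function(w) {
    c(w$Wee[ee_idx], w$Wei[ei_idx], w$Wie[pair_idx], diag(w$Wii))
  }

  m <- min(length(true_params$gammas), length(fitted_params$gammas))
  r_gee <- r_gei <- numeric(m)
  for (i in seq_len(m)) {
    if (isTRUE(true_params$gammas[[i]]$pinned) &&
        isTRUE(fitted_params$gammas[[i]]$pinned)) {
      # both sides are the exact all-ones baseline: recovery is trivially
      # exact and the correlation is undefined (zero variance)
      r_gee[i] <- NA_real_
      r_gei[i] <- NA_real_
      next
    }
    Gt <- gamma_dense(true_params$gammas[[i]])
    Gf <- gamma_dense(fitted_params$gammas[[i]])
    ee_t <- Gt[1:ne, 1:ne][ee_idx]; ee_f <- Gf[1:ne, 1:ne][ee_idx]
    ei_t <- Gt[(ne + 1):(ne + ni), 1:ne][ei_idx]
    ei_f <- Gf[(ne + 1):(ne + ni), 1:ne][ei_idx]
    r_gee[i] <- pearson(ee_t, ee_f)
    r_gei[i] <- pearson(ei_t, ei_f)
  }

  structure(list(
    r_full_W = pearson(full_vec(wt), full_vec(wf)),
    r_Wee = pearson(wt$Wee[ee_idx], wf$Wee[ee_idx]),
    r_Wei = pearson(wt$Wei[ei_idx], wf$Wei[ei_idx]),
    r_gamma_EE = r_gee,
    r_gamma_EI = r_gei,
    mask_used = mask), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> r(W) = %.4f, r(Wee) = %.4f, r(Wei) = %.4f\n",
              x$r_full_W, x$r_Wee, x$r_Wei))
  if (length(x$r_gamma_EE))
    cat("  r(Gamma EE):", sprintf("%.4f", x$r_gamma_EE), "\n",
        " r(Gamma EI):", sprintf("%.4f", x$r_gamma_EI), "\n")
  invisible(x)
}

# masked full-W vector of one parameter bundle (shared helper)
masked_W_vector <- function(params) {
  w <- params$W
  ne <- w$n_exc; ni <- w$n_inh
  k <- min(ne, ni)
  pair_idx <- cbind(seq_len(k), seq_len(k))
  c(w$Wee[w$sparsity_mask$ee == 1], w$Wei[w$sparsity_mask$ei == 1],
    w$Wie[pair_idx], diag(w$Wii))
}

block_vector <- function(params, block = c("W", "Wee", "Wei")) {
  block <- match.arg(block)
  w <- params$W
  switch(block,
         W = masked_W_vector(params),
         Wee = w$Wee[w$sparsity_mask$ee == 1],
         Wei = w$Wei[w$sparsity_mask$ei == 1])
}

#' Split-half test-retest reliability of fitted connectivity
#'
#' Each subject's data is fitted twice on temporally split halves.
#' Within-subject reliability is the correlation of a subject's two half-fit
#' connectivities; across-subject values are the correlations of half-fits
#' between different subjects (all four half pairings of each subject pair).
#' Individualization shows as within-subject correlations exceeding
#' across-subject ones; the two distributions are compared with a two-sample
#' Wilcoxon rank-sum test.
#'
#' All fits must share one sparsity mask (as when a single random mask is
#' applied to every subject); correlations are computed over the
#' mask-surviving entries.
#'
#' @param fits_by_subject list with one element per subject, each a list of
#'   exactly two half fits ([mindy_fit()] results or [mindy_params()]).
#' @param blocks which connectivity blocks to report.
#' @return list with \code{within} and \code{across} data frames of
#'   correlations, \code{p_value} (named per block), and \code{medians}.
#' @export
split_half_reliability <- function(fits_by_subject,
                                   blocks = c("W", "Wee", "Wei")) {
  ns <- length(fits_by_subject)
  if (ns < 2) stop("at least 2 subjects are required")
  get_params <- function(f) {
    if (inherits(f, "mindy_fit")) f$params
    else if (inherits(f, "mindy_params")) f
    else stop("fits must be mindy_fit or mindy_params objects")
  }
  halves <- lapply(fits_by_subject, function(s) {
    if (length(s) != 2) stop("each subject needs exactly 2 half fits")
    lapply(s, get_params)
  })
  mask0 <- halves[[1]][[1]]$W$sparsity_mask
  for (s in halves) for (p in s) {
    if (!identical(p$W$sparsity_mask$ee, mask0$ee) ||
        !identical(p$W$sparsity_mask$ei, mask0$ei))
      stop("all fits must share one sparsity mask")
  }

  corr <- function(a, b, blk) stats::cor(block_vector(a, blk),
                                         block_vector(b, blk))
  within <- do.call(rbind, lapply(seq_len(ns), function(i) {
    row <- lapply(blocks, function(b) corr(halves[[i]][[1]],
                                           halves[[i]][[2]], b))
    names(row) <- paste0("r_", blocks)
    cbind(data.frame(subject = i), as.data.frame(row))
  }))
  pairs <- utils::combn(ns, 2)
  across <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    do.call(rbind, lapply(1:2, function(hi) {
      do.call(rbind, lapply(1:2, function(hj) {
        row <- lapply(blocks, function(b) corr(halves[[i]][[hi]],
                                               halves[[j]][[hj]], b))
        names(row) <- paste0("r_", blocks)
        cbind(data.frame(subject_a = i, half_a = hi,
                         subject_b = j, half_b = hj),
              as.data.frame(row))
      }))
    }))
  }))
  p_value <- vapply(blocks, function(b) {
    stats::wilcox.test(within[[paste0("r_", b)]],
                       across[[paste0("r_", b)]],
                       alternative = "greater", exact = FALSE)$p.value
  }, numeric(1))
  medians <- vapply(blocks, function(b) c(
    within = stats::median(within[[paste0("r_", b)]]),
    across = stats::median(across[[paste0("r_", b)]])), numeric(2))
  list(within = within, across = across, p_value = p_value,
       medians = medians)
}

#' Modulation impact between two regimes
#'
#' The signed change in effective connection strength when moving from
#' regime a to regime b: \eqn{W \odot (\Gamma_b - \Gamma_a)}. Positive
#' entries are strengthened connections, negative entries weakened ones; the
#' measure is exactly antisymmetric in its regime arguments.
#'
#' @param W a [structured_connectivity()] or plain numeric matrix.
#' @param gamma_a,gamma_b [modulation_matrix()] objects or dense matrices.
#' @return An object of class \code{impact_matrix}: list with \code{value}
#'   (n x n), \code{postsynaptic} (row means: average impact on each target
#'   population), \code{from_regime}, \code{to_regime}.
#' @export
modulation_impact <- function(W, gamma_a, gamma_b) {
  Wm <- if (inherits(W, "structured_connectivity")) assemble_W(W) else as.matrix(W)
  ga <- if (inherits(gamma_a, "modulation_matrix")) gamma_dense(gamma_a) else as.matrix(gamma_a)
  gb <- if (inherits(gamma_b, "modulation_matrix")) gamma_dense(gamma_b) else as.matrix(gamma_b)
  if (!all(dim(Wm) == dim(ga)) || !all(dim(Wm) == dim(gb)))
    stop("W and the modulation matrices must have matching shapes")
  val <- Wm * (gb - ga)
  structure(list(
    value = val,
    postsynaptic = rowMeans(val),
    from_regime = if (inherits(gamma_a, "modulation_matrix")) gamma_a$regime_index else NA_integer_,
    to_regime = if (inherits(gamma_b, "modulation_matrix")) gamma_b$regime_index else NA_integer_),
    class = "impact_matrix")
}

#' @export
print.impact_matrix <- function(x, ...) {
  cat(sprintf("<impact_matrix> regime %s -> %s, mean impact %.4g\n",
              x$from_regime, x$to_regime, mean(x$value)))
  invisible(x)
}

#' Distribution summary of modulation values
#'
#' Summarizes, per regime, the modulation entries over the effective entry
#' set: with a connectivity argument, the mask-surviving excitatory-source
#' entries plus the inhibitory-source diagonals (the only positions where the
#' modulation can act); otherwise all entries. Entries exactly equal to 1
#' count as not greater than 1 (strict inequality).
#'
#' @param gammas list of [modulation_matrix()] objects (or dense matrices).
#' @param W optional [structured_connectivity()] defining the effective
#'   entries.
#' @return data frame with one row per regime: \code{regime},
#'   \code{n_entries}, \code{frac_below_1} (entries in \code{[0, 1)}),
#'   \code{frac_gt_1} (entries \code{> 1}), and quartiles \code{q25},
#'   \code{median}, \code{q75}.
#' @export
gamma_value_summary <- function(gammas, W = NULL) {
  idx <- NULL
  if (!is.null(W)) {
    stopifnot(inherits(W, "structured_connectivity"))
    ne <- W$n_exc; ni <- W$n_inh; n <- ne + ni
    eff <- matrix(FALSE, n, n)
    eff[1:ne, 1:ne][W$sparsity_mask$ee == 1] <- TRUE
    eff[(ne + 1):n, 1:ne][W$sparsity_mask$ei == 1] <- TRUE
    k <- min(ne, ni)
    eff[cbind(seq_len(k), ne + seq_len(k))] <- TRUE
    eff[cbind(ne + seq_len(ni), ne + seq_len(ni))] <- TRUE
    idx <- which(eff)
  }
  rows <- lapply(seq_along(gammas), function(i) {
    g <- gammas[[i]]
    G <- if (inherits(g, "modulation_matrix")) gamma_dense(g) else as.matrix(g)
    vals <- if (is.null(idx)) as.numeric(G) else G[idx]
    q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(regime = i, n_entries = length(vals),
               frac_below_1 = mean(vals >= 0 & vals < 1),
               frac_gt_1 = mean(vals > 1),
               q25 = q[1], median = q[2], q75 = q[3])
  })
  do.call(rbind, rows)
}
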