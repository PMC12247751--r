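test_that("masked correlation is exact for self- and scaled comparison", {
  p <- small_params(ne = 4, ni = 4, m = 2, nc = 4, seed = 61)
  rep_self <- masked_correlation(p, p)
  expect_equal(rep_self$r_full_W, 1, tolerance = 1e-12)
  expect_equal(rep_self$r_Wee, 1, tolerance = 1e-12)
  expect_equal(rep_self$r_gamma_EE, rep(1, 2), tolerance = 1e-12)

  # uniform scaling leaves every correlation at 1 (recovery is assessed up
  # to a scale factor)
  p2 <- p
  p2$W$Wee <- 2 * p$W$Wee
  p2$W$Wei <- 2 * p$W$Wei
  p2$W$Wie <- 2 * p$W$Wie
  p2$W$Wii <- 2 * p$W$Wii
  rep_scaled <- masked_correlation(p, p2)
  expect_equal(rep_scaled$r_full_W, 1, tolerance = 1e-12)
  expect_equal(rep_scaled$r_Wei, 1, tolerance = 1e-12)
})

test_that("masked correlation matches the from-definition Pearson oracle", {
  pa <- small_params(ne = 3, ni = 3, m = 2, seed = 62)
  pb <- small_params(ne = 3, ni = 3, m = 2, seed = 63)
  pb$W$sparsity_mask <- pa$W$sparsity_mask
  pb$W$Wee <- pb$W$Wee * pa$W$sparsity_mask$ee
  pb$W$Wei <- pb$W$Wei * pa$W$sparsity_mask$ei
  rep <- masked_correlation(pa, pb)
  m <- pa$W$sparsity_mask
  expect_equal(rep$r_Wee,
               oracle_pearson(pa$W$Wee[m$ee == 1], pb$W$Wee[m$ee == 1]),
               tolerance = 1e-12)
  full_a <- c(pa$W$Wee[m$ee == 1], pa$W$Wei[m$ei == 1],
              diag(pa$W$Wie), diag(pa$W$Wii))
  full_b <- c(pb$W$Wee[m$ee == 1], pb$W$Wei[m$ei == 1],
              diag(pb$W$Wie), diag(pb$W$Wii))
  expect_equal(rep$r_full_W, oracle_pearson(full_a, full_b),
               tolerance = 1e-12)
  # symmetry in the arguments
  rep_rev <- masked_correlation(pb, pa)
  expect_equal(rep$r_full_W, rep_rev$r_full_W, tolerance = 1e-12)
})

test_that("masked correlation rejects degenerate zero-variance input", {
  p <- small_params(ne = 3, ni = 3, m = 1, seed = 64)
  pz <- p
  pz$W$Wee[] <- 0.5 * p$W$sparsity_mask$ee  # constant over surviving entries
  pz$W$Wee <- pz$W$Wee
  expect_error(masked_correlation(p, pz), "zero-variance")
})

test_that("split-half reliability enumerates every half pairing once", {
  set.seed(71)
  mask <- random_sparsity_mask(4, 4)
  mk <- function() {
    p <- small_params(ne = 4, ni = 4, m = 1, nc = 4, seed = sample.int(1e6, 1))
    p$W$sparsity_mask <- mask
    p$W$Wee <- (p$W$Wee + 0.01) * mask$ee
    p$W$Wei <- (p$W$Wei + 0.01) * mask$ei
    p
  }
  ns <- 3
  subs <- lapply(1:ns, function(i) list(mk(), mk()))
  rel <- split_half_reliability(subs)
  expect_equal(nrow(rel$within), ns)
  expect_equal(nrow(rel$across), 4 * choose(ns, 2))
  # brute-force enumeration oracle over all cross-subject half pairs
  vecW <- function(p) c(p$W$Wee[mask$ee == 1], p$W$Wei[mask$ei == 1],
                        diag(p$W$Wie), diag(p$W$Wii))
  oracle <- c()
  for (i in 1:(ns - 1)) for (j in (i + 1):ns)
    for (hi in 1:2) for (hj in 1:2)
      oracle <- c(oracle, cor(vecW(subs[[i]][[hi]]), vecW(subs[[j]][[hj]])))
  expect_equal(sort(rel$across$r_W), sort(oracle), tolerance = 1e-12)
})

test_that("identical halves give perfect within-subject reliability", {
  set.seed(72)
  mask <- random_sparsity_mask(4, 4)
  subs <- lapply(1:3, function(i) {
    p <- small_params(ne = 4, ni = 4, m = 1, nc = 4, seed = 100 + i)
    p$W$sparsity_mask <- mask
    p$W$Wee <- p$W$Wee * mask$ee
    p$W$Wei <- p$W$Wei * mask$ei
    list(p, p)
  })
  rel <- split_half_reliability(subs)
  expect_equal(rel$within$r_W, rep(1, 3), tolerance = 1e-12)
  expect_lt(rel$p_value[["W"]], 0.05)
})

test_that("independent subjects give across-subject correlations near zero", {
  # iid entries within the block, so independence alone sets the expectation;
  # heterogeneous-block full-W vectors share a deterministic sign pattern and
  # are not a clean independence probe
  set.seed(73)
  mk <- function() {
    W <- structured_connectivity(matrix(runif(36), 6, 6), diag(-1, 6),
                                 matrix(runif(36), 6, 6), diag(-1, 6))
    mindy_params(W = W, gammas = list(modulation_matrix(rep(1, 6 * 2))),
                 D = 0.5, S = c(exc = 1, inh = 1),
                 H = cbind(diag(6), matrix(0, 6, 6)),
                 Q = diag(12), R = diag(6))
  }
  rs <- replicate(40, {
    subs <- list(list(mk(), mk()), list(mk(), mk()))
    median(split_half_reliability(subs)$across$r_Wee)
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("modulation impact is the Hadamard difference with antisymmetry", {
  W <- matrix(c(1, -2, 0, 3, 4, -1, 2, 0, 1), 3, 3)
  ga <- matrix(runif(9), 3, 3)
  gb <- matrix(runif(9), 3, 3)
  imp <- modulation_impact(W, ga, gb)
  # elementwise oracle
  for (j in 1:3) for (k in 1:3)
    expect_equal(imp$value[j, k], W[j, k] * (gb[j, k] - ga[j, k]),
                 tolerance = 1e-12)
  rev <- modulation_impact(W, gb, ga)
  expect_equal(imp$value + rev$value, matrix(0, 3, 3), tolerance = 1e-15)
  expect_equal(modulation_impact(W, ga, ga)$value, matrix(0, 3, 3))
  expect_equal(imp$postsynaptic, rowMeans(imp$value), tolerance = 1e-15)
})

test_that("impact accepts structured connectivity and modulation objects", {
  p <- small_params(ne = 3, ni = 3, m = 2, seed = 75)
  imp <- modulation_impact(p$W, p$gammas[[1]], p$gammas[[2]])
  expect_equal(imp$from_regime, 1L)
  expect_equal(imp$value,
               assemble_W(p$W) * (gamma_dense(p$gammas[[2]]) -
                                    gamma_dense(p$gammas[[1]])),
               tolerance = 1e-14)
})

test_that("gamma value summary counts the boundary strictly", {
  ones <- modulation_matrix(rep(1, 4))
  half <- modulation_matrix(rep(sqrt(0.5), 4))
  s <- gamma_value_summary(list(ones, half))
  expect_equal(s$frac_gt_1, c(0, 0))      # exactly 1 is not greater than 1
  expect_equal(s$frac_below_1, c(0, 1))
  g <- modulation_matrix(runif(5, 0.5, 1.5))
  G <- gamma_dense(g)
  s2 <- gamma_value_summary(list(g))
  expect_equal(s2$frac_gt_1, mean(as.numeric(G) > 1), tolerance = 1e-15)
  expect_equal(s2$median, median(as.numeric(G)), tolerance = 1e-12)
})

test_that("gamma value summary restricts to mask-surviving entries", {
  p <- small_params(ne = 3, ni = 3, m = 1, seed = 76)
  g <- p$gammas[[1]]
  s <- gamma_value_summary(list(g), W = p$W)
  n_eff <- sum(p$W$sparsity_mask$ee) + sum(p$W$sparsity_mask$ei) + 3 + 3
  expect_equal(s$n_entries, n_eff)
})
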