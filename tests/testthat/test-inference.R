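test_that("nuisance adjustment is an exact identity", {
  set.seed(32)
  Is <- 40; Iv <- 6
  sol <- make_toy_solution(matrix(rnorm(Is)), matrix(rnorm(Iv)),
                           matrix(1, Iv, 1), impulse_basis(),
                           N = matrix(rnorm(Is * 2), Is),
                           P = matrix(rnorm(Iv * 2), Iv))
  Y <- matrix(rnorm(Is * Iv), Is)
  expect_equal(adjust_fmri(Y, sol) + tcrossprod(sol$N, sol$P), Y,
               tolerance = 1e-12)
  # Q = 0 leaves the data untouched; Y = N P' maps to zero
  sol0 <- make_toy_solution(sol$S, sol$V, sol$B, impulse_basis())
  expect_identical(adjust_fmri(Y, sol0), Y)
  expect_lt(max(abs(adjust_fmri(tcrossprod(sol$N, sol$P), sol))), 1e-12)
})

test_that("wavelet transform is orthonormal with exact reconstruction", {
  dw <- scmtf:::dwt_matrix(64, 3)
  expect_equal(dw$W %*% t(dw$W), diag(64), tolerance = 1e-12)
  x <- rnorm(64)
  expect_equal(as.numeric(crossprod(dw$W, dw$W %*% x)), x, tolerance = 1e-12)
  expect_equal(sort(unlist(dw$blocks)), 1:64)
})

test_that("surrogates preserve variance and autocorrelation structure", {
  set.seed(33)
  lag1 <- function(x) cor(x[-1], x[-length(x)])
  # white noise column
  Yw <- matrix(rnorm(270), ncol = 1)
  sw <- wavelet_resample(Yw, L = 100, seed = 1)
  vr <- apply(sw$surrogates[, 1, ], 2, var)
  expect_lt(max(abs(vr / var(Yw[, 1]) - 1)), 0.10)
  a1 <- mean(apply(sw$surrogates[, 1, ], 2, lag1))
  expect_lt(abs(a1 - lag1(Yw[, 1])), 0.1)
  # strongly autocorrelated AR(1) column
  Ya <- matrix(as.numeric(arima.sim(list(ar = 0.8), 270)), ncol = 1)
  sa <- wavelet_resample(Ya, L = 100, seed = 2)
  aa <- mean(apply(sa$surrogates[, 1, ], 2, lag1))
  expect_lt(abs(aa - lag1(Ya[, 1])), 0.15)
  # bit-reproducible under the same seed
  s1 <- wavelet_resample(Ya, L = 5, seed = 99)
  s2 <- wavelet_resample(Ya, L = 5, seed = 99)
  expect_identical(s1$surrogates, s2$surrogates)
  # shared permutation preserves cross-column correlation
  z <- rnorm(270)
  Y2 <- cbind(z + 0.2 * rnorm(270), z + 0.2 * rnorm(270))
  sh <- wavelet_resample(Y2, L = 30, seed = 3)
  cc <- mean(apply(sh$surrogates, 3, function(m) cor(m[, 1], m[, 2])))
  expect_gt(cc, 0.8)
  expect_warning(wavelet_resample(matrix(rnorm(20), ncol = 1), L = 2,
                                  seed = 1), "32")
})

test_that("pseudo-t equals textbook OLS on a hand-sized example", {
  s <- c(0.4, -1.2, 0.7, 2.1, -0.3, 0.9)
  y <- c(0.2, -1.0, 1.1, 1.8, 0.1, 0.6)
  sol <- make_toy_solution(matrix(s), matrix(1, 3, 1), matrix(1, 3, 1),
                           impulse_basis())
  tt <- pseudo_t(sol, y, roi = 1)
  ref <- summary(lm(y ~ 0 + s))$coefficients[1, "t value"]
  expect_equal(tt, ref, tolerance = 1e-10)
  # scale invariance of the t statistic
  expect_equal(pseudo_t(sol, 10 * y, roi = 1), tt, tolerance = 1e-10)
  # perfect fit hits the finite sentinel
  expect_message(tcap <- pseudo_t(sol, s, roi = 1), "capped")
  expect_equal(abs(tcap), 1e6)
  expect_error(pseudo_t(sol, y[1], roi = 1), "more time points")
})

test_that("null pseudo-t rejection rate matches the t reference", {
  set.seed(34)
  Is <- 40
  sol <- make_toy_solution(matrix(rnorm(Is)), matrix(1, 1, 1),
                           matrix(1, 1, 1), impulse_basis())
  designs <- scmtf:::snpm_designs(sol, Is)
  Y <- matrix(rnorm(Is * 2000), Is)
  tt <- scmtf:::t_from_design(designs[[1]], Y)$t
  crit <- qt(0.975, df = Is - 1)
  rate <- mean(abs(tt) > crit)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("familywise thresholds follow the max-statistic rule", {
  # all null statistics identical: both thresholds equal that constant
  null_t <- array(3.3, c(50, 10, 2))
  thr <- fwe_thresholds(null_t, alpha = 0.05)
  expect_equal(thr$T_hi, c(3.3, 3.3))
  expect_equal(thr$T_lo, c(3.3, 3.3))
  expect_warning(fwe_thresholds(array(rnorm(10 * 4), c(10, 4, 1))),
                 "unstable")
  # "each" convention is more liberal than the two-sided default
  set.seed(35)
  nt <- array(rnorm(200 * 20), c(200, 20, 1))
  t2 <- fwe_thresholds(nt, 0.05, tail = "two.sided")
  te <- fwe_thresholds(nt, 0.05, tail = "each")
  expect_gt(t2$T_hi, te$T_hi)
  expect_lt(t2$T_lo, te$T_lo)
})

test_that("planted activation is detected and masks obey the thresholds", {
  set.seed(36)
  Is <- 200; Iv <- 15
  s <- as.numeric(arima.sim(list(ar = 0.5), Is))
  s <- (s - mean(s)) / sd(s)
  grid <- lag_grid(0, 6.6, 2.2)
  basis <- hrf_basis(list(c(3, 1, 6, 1, 1 / 6)), grid)
  hs <- toeplitz_apply(toeplitz_op(basis$waveforms[1, ], 0, Is), s)
  hits <- 0
  for (i in 1:10) {
    set.seed(400 + i)
    Y <- matrix(rnorm(Is * Iv), Is, Iv)
    Y[, 4] <- Y[, 4] + hs * sqrt(10) / sd(hs)     # ~10 dB planted coupling
    sol <- make_toy_solution(matrix(s), matrix(rnorm(Iv)), matrix(1, Iv, 1),
                             basis)
    sn <- build_snpm(sol, Y, L = 100, seed = 500 + i)
    hits <- hits + sn$act_mask[1, 4]
    # invariant: masks are exactly the thresholded statistics
    expect_identical(sn$act_mask, sn$t > sn$thresh_hi)
    expect_identical(sn$deact_mask, sn$t < sn$thresh_lo)
  }
  expect_gte(hits, 9)
})

test_that("top-k restriction and beta statistic are honoured", {
  set.seed(37)
  Is <- 100; Iv <- 8
  sol <- make_toy_solution(matrix(rnorm(Is)), matrix(rnorm(Iv)),
                           matrix(1, Iv, 1), impulse_basis())
  Y <- matrix(rnorm(Is * Iv), Is)
  sn <- build_snpm(sol, Y, L = 50, seed = 1, top_k = 3)
  expect_lte(sum(sn$act_mask | sn$deact_mask), 3)
  snb <- build_snpm(sol, Y, L = 50, seed = 1, statistic = "beta")
  expect_equal(snb$statistic, "beta")
  df <- tidy(snb)
  expect_equal(nrow(df), Iv)
})
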