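toy_full_solution <- function(Is, Ig, Im, Iv, R, K, Q, grid, seed = 1) {
  set.seed(seed)
  theta <- default_hrf_params(K, grid$n_pre * grid$dt)
  theta <- lapply(theta, function(th) th * (1 + 0.05 * rnorm(5)))
  scmtf:::new_scmtf_solution(
    S = matrix(rnorm(Is * R), Is), G = matrix(rnorm(Ig * R), Ig),
    M = matrix(rnorm(Im * R), Im), V = matrix(rnorm(Iv * R), Iv),
    B = matrix(rnorm(Iv * K), Iv), basis = hrf_basis(theta, grid),
    N = matrix(rnorm(Is * Q), Is, Q), P = matrix(rnorm(Iv * Q), Iv, Q),
    lambda_x = rep(1, R), lambda_y = rep(1, R), cost = NA_real_,
    converged = TRUE, config = scmtf_config(R = R, K = K, Q = Q))
}

test_that("analytic gradient matches central differences", {
  set.seed(21)
  Is <- 20; Ig <- 5; Im <- 4; Iv <- 6; R <- 2; K <- 2; Q <- 1
  lay <- scmtf:::scmtf_layout(Is, Ig, Im, Iv, R, K, Q)
  grid <- lag_grid(6.6, 8.8, 2.2)
  Xv <- array(rnorm(Is * Ig * Im), c(Is, Ig, Im))
  Yv <- matrix(rnorm(Is * Iv), Is, Iv)
  w <- list(beta_x = 0.7, beta_y = 1.3, gamma_x = 0.05, gamma_y = 0.04)
  theta <- list(c(16, 1, 26, 1, 1 / 6), c(6, 1.2, 16, 1, 0.3))
  par0 <- scmtf:::pack_params(
    matrix(rnorm(Is * R), Is), matrix(rnorm(Ig * R), Ig),
    matrix(rnorm(Im * R), Im), matrix(rnorm(Iv * R), Iv),
    matrix(rnorm(Iv * K), Iv), theta,
    matrix(rnorm(Is * Q), Is), matrix(rnorm(Iv * Q), Iv))
  X1 <- scmtf:::unfold1(Xv)
  f <- function(p) as.numeric(scmtf:::scmtf_objective(p, lay, X1, dim(Xv),
                                                      Yv, grid, w))
  g <- scmtf:::scmtf_gradient(par0, lay, X1, dim(Xv), Yv, grid, w)
  idx <- sort(c(sample(lay$total, 30), lay$offs[["theta"]] + 1:10))
  num <- vapply(idx, function(i) {
    h <- 1e-6 * max(abs(par0[i]), 1)
    pp <- par0; pp[i] <- pp[i] + h
    pm <- par0; pm[i] <- pm[i] - h
    (f(pp) - f(pm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - g[idx]) / pmax(abs(num), 1)), 1e-5)
})

test_that("coupled prediction reduces to s v' + N P' for an impulse HRF", {
  set.seed(22)
  Is <- 12; Iv <- 5
  s <- rnorm(Is); v <- rnorm(Iv)
  N <- matrix(rnorm(Is), Is, 1); P <- matrix(rnorm(Iv), Iv, 1)
  sol <- make_toy_solution(matrix(s), matrix(v), matrix(1, Iv, 1),
                           impulse_basis(), N, P)
  pred <- model_predict(sol)
  expect_equal(pred$Yhat, outer(s, v) + tcrossprod(N, P), tolerance = 1e-12)
})

test_that("fMRI model matches the termwise brute-force expansion", {
  set.seed(23)
  grid <- lag_grid(6.6, 8.8, 2.2)
  sol <- toy_full_solution(30, 4, 3, 8, 2, 2, 1, grid, seed = 23)
  pred <- model_predict(sol)
  Yb <- brute_coupled(sol$S, sol$V, sol$B, sol$basis$waveforms, grid$n_pre,
                      sol$N, sol$P)
  expect_equal(pred$Yhat, Yb, tolerance = 1e-12)
  # shared-HRF structure: (R + K) * Iv coupled spatial parameters
  expect_equal(length(sol$V) + length(sol$B),
               (ncol(sol$S) + ncol(sol$B)) * nrow(sol$V))
})

test_that("cost equals an independently coded evaluation", {
  grid <- lag_grid(0, 2.2, 2.2)
  # perfect fit with zero l1 weights gives J = 0
  set.seed(24)
  sol <- toy_full_solution(10, 3, 2, 4, 1, 1, 0, grid, seed = 24)
  pred <- model_predict(sol)
  cfg0 <- scmtf_config(R = 1, K = 1, Q = 0, beta_x = 1, beta_y = 1,
                       gamma_x = 0, gamma_y = 0)
  expect_equal(scmtf_cost(sol, pred$Xhat, pred$Yhat, cfg0), 0,
               tolerance = 1e-20)

  # hand-style elementwise computation on a tiny 2x2x2 / 2x2 instance
  sol2 <- toy_full_solution(2, 2, 2, 2, 1, 1, 0, grid, seed = 25)
  X <- array(rnorm(8), c(2, 2, 2)); Y <- matrix(rnorm(4), 2, 2)
  cfg <- scmtf_config(R = 1, K = 1, Q = 0, beta_x = 0.3, beta_y = 0.6,
                      gamma_x = 0.11, gamma_y = 0.07)
  J <- scmtf_cost(sol2, X, Y, cfg)
  # independent evaluation: explicit sums
  Xhat <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    Xhat[i, j, k] <- sol2$S[i, 1] * sol2$G[j, 1] * sol2$M[k, 1]
  }
  hs <- brute_conv(sol2$basis$waveforms[1, ], grid$n_pre, sol2$S[, 1])
  Yhat <- matrix(0, 2, 2)
  for (i in 1:2) for (iv in 1:2) {
    Yhat[i, iv] <- hs[i] * sol2$B[iv, 1] * sol2$V[iv, 1]
  }
  lam_x <- sqrt(sum(sol2$S^2)) * sqrt(sum(sol2$G^2)) * sqrt(sum(sol2$M^2))
  lam_y <- sqrt(sum((sol2$B[, 1] * sol2$V[, 1])^2))
  J_hand <- 0.3 * sum((X - Xhat)^2) + 0.6 * sum((Y - Yhat)^2) +
    0.11 * lam_x + 0.07 * lam_y
  expect_equal(J, J_hand, tolerance = 1e-12)
})

test_that("counter-scaling factors leaves the fit but not the penalty", {
  grid <- lag_grid(0, 2.2, 2.2)
  sol <- toy_full_solution(10, 3, 2, 4, 1, 1, 0, grid, seed = 26)
  X <- model_predict(sol)$Xhat
  Y <- model_predict(sol)$Yhat
  cfg <- scmtf_config(R = 1, K = 1, Q = 0, beta_x = 1, beta_y = 0,
                      gamma_x = 0.5, gamma_y = 0)
  sol2 <- sol
  sol2$S <- 3 * sol$S; sol2$G <- sol$G / 3
  expect_equal(model_predict(sol2)$Xhat, X, tolerance = 1e-12)
  expect_equal(scmtf_cost(sol, X, Y, cfg), scmtf_cost(sol2, X, Y, cfg),
               tolerance = 1e-12)  # lambda_x = ||s|| ||g|| ||m|| is invariant
  sol3 <- sol
  sol3$S <- 3 * sol$S                       # unbalanced scaling
  expect_gt(scmtf_cost(sol3, X, Y, cfg) -
              sum((X - model_predict(sol3)$Xhat)^2),
            scmtf_cost(sol, X, Y, cfg) - 0)
})

test_that("calibration removes ambiguities without changing the model", {
  set.seed(27)
  grid <- lag_grid(6.6, 8.8, 2.2)
  sol <- toy_full_solution(25, 5, 4, 7, 2, 2, 1, grid, seed = 27)
  cal <- calibrate(sol)
  # unit norms and nonnegative amplitudes
  expect_equal(colSums(cal$S^2), rep(1, 2), tolerance = 1e-12)
  expect_equal(colSums(cal$G^2), rep(1, 2), tolerance = 1e-12)
  expect_equal(colSums(cal$M^2), rep(1, 2), tolerance = 1e-12)
  expect_true(all(cal$lambda_x >= 0))
  # model invariance
  p0 <- model_predict(sol); p1 <- model_predict(cal)
  expect_equal(p0$Xhat, p1$Xhat, tolerance = 1e-10)
  expect_equal(p0$Yhat, p1$Yhat, tolerance = 1e-10)
  # idempotence
  cal2 <- calibrate(cal)
  expect_equal(cal2$S, cal$S, tolerance = 1e-12)
  expect_equal(cal2$V, cal$V, tolerance = 1e-12)
  expect_equal(cal2$B, cal$B, tolerance = 1e-12)
  # joint sign flip of (s_r, g_r) is undone
  flip <- sol
  flip$S[, 1] <- -flip$S[, 1]; flip$G[, 1] <- -flip$G[, 1]
  calf <- calibrate(flip)
  expect_equal(calf$S, cal$S, tolerance = 1e-12)
  expect_equal(calf$G, cal$G, tolerance = 1e-12)
  # calibrated HRF main lobes are positive
  H <- roi_hrfs(cal)
  lobes <- apply(H, 1, function(wv) wv[which.max(abs(wv))])
  expect_true(all(lobes > 0))
})

test_that("the IED component is the one tracking the envelope", {
  set.seed(28)
  S <- matrix(rnorm(50 * 3), 50)
  sol <- make_toy_solution(S, matrix(rnorm(4 * 3), 4), matrix(1, 4, 1),
                           impulse_basis())
  expect_equal(select_ied_component(sol, S[, 1])$index, 1L)
  expect_equal(select_ied_component(sol, S[, 1])$correlation, 1)
  s3 <- S[, 3] + 0.05 * rnorm(50)
  expect_equal(select_ied_component(sol, s3)$index, 3L)
  # tie broken by lowest index
  sol$S[, 2] <- sol$S[, 1]
  expect_message(res <- select_ied_component(sol, S[, 1]), "tie")
  expect_equal(res$index, 1L)
  expect_error(select_ied_component(sol, rep(1, 50)), "constant")
})

test_that("with the fMRI terms off the fit reduces to the EEG CPD", {
  set.seed(29)
  S <- matrix(rnorm(40 * 2), 40); G <- matrix(rnorm(10 * 2), 10)
  M <- matrix(rnorm(6 * 2), 6)
  X <- scmtf:::cpd_compose(S, G, M)
  Y <- matrix(rnorm(40 * 5), 40, 5)
  cfg <- scmtf_config(R = 2, K = 1, Q = 0, beta_y = 0, gamma_x = 0,
                      gamma_y = 0, n_inits = 1, max_iter = 200, seed = 1)
  fit <- fit_scmtf(X, Y, cfg, tr = 2.2)
  sol <- best_solution(fit)
  expect_gt(factor_congruence(list(S, G, M),
                              list(sol$S, sol$G, sol$M))$score, 0.99)
})

test_that("cost decreases from initialization and restarts are ranked", {
  ds <- generate_dataset(Is = 80, Iv = 12, Ig = 8, Im = 6, seed = 30)
  cfg <- scmtf_config(R = 2, K = 2, Q = 1, n_inits = 2, max_iter = 60,
                      seed = 30)
  fit <- fit_scmtf(ds$X, ds$Y, cfg)
  costs <- vapply(fit$solutions, `[[`, numeric(1), "cost")
  expect_true(!is.unsorted(costs))
  # the optimizer's solution beats the raw initialization cost
  init_cost <- scmtf_cost(best_solution(fit), ds$X, ds$Y)
  expect_lte(best_solution(fit)$cost, init_cost + 1e-8)
})

test_that("model selection prefers the true rank on synthetic data", {
  ds <- generate_dataset(Is = 150, Iv = 20, Ig = 12, Im = 8, seed = 31)
  s_ref <- enhance_eeg(ds$eeg)$envelope[1:150]
  fits <- lapply(1:3, function(r) {
    fit_scmtf(ds$X, ds$Y, scmtf_config(R = r, K = 2, Q = 1, n_inits = 2,
                                       max_iter = 150, seed = 31 + r))
  })
  sel <- select_model(fits, s_ref)
  expect_equal(sel$R, 2L)
  expect_equal(nrow(sel$scores), 3L)
  expect_named(sel$scores, c("R", "stability", "relevance", "eeg_relerr",
                             "gain_next", "eligible", "selected"))
  # single candidate returned trivially
  sel1 <- select_model(fits[1], s_ref)
  expect_equal(sel1$R, 1L)
})
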