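#' Configuration for the structured coupled matrix-tensor factorization
#'
#' @param R number of shared sources.
#' @param K number of HRF basis functions (default 3).
#' @param Q rank of the fMRI-only (uncoupled) nuisance term (default 2).
#' @param beta_x,beta_y data-fit weights; defaults `1/||X||_F^2` and
#'   `1/||Y||_F^2` (computed at fit time), which equalizes the influence of
#'   the two modalities.
#' @param gamma_x,gamma_y l1 weights on the source amplitude vectors;
#'   default `0.01 * (beta_x ||X||^2 + beta_y ||Y||^2) / R`.
#' @param n_inits number of independent initializations (default 50).
#' @param max_iter maximum L-BFGS iterations per initialization.
#' @param tol relative cost-change tolerance (default 1e-8).
#' @param seed integer seed.
#' @param t_pre,t_post HRF lag-grid support in seconds (see [lag_grid()]).
#' @param theta_init optional list of K initial HRF parameter sets
#'   (default [default_hrf_params()]).
#' @param perturb relative standard deviation of the per-restart
#'   perturbation of V, B, N, P and theta (default 0.1).
#' @return object of class `scmtf_config`.
#' @export
scmtf_config <- function(R = 2, K = 3, Q = 2, beta_x = NULL, beta_y = NULL,
                         gamma_x = NULL, gamma_y = NULL, n_inits = 50,
                         max_iter = 500, tol = 1e-8, seed = NULL,
                         t_pre = 10, t_post = 22, theta_init = NULL,
                         perturb = 0.1) {
  stopifnot(R >= 1, K >= 1, Q >= 0, n_inits >= 1, max_iter >= 1, tol > 0)
  structure(list(R = as.integer(R), K = as.integer(K), Q = as.integer(Q),
                 beta_x = beta_x, beta_y = beta_y, gamma_x = gamma_x,
                 gamma_y = gamma_y, n_inits = as.integer(n_inits),
                 max_iter = as.integer(max_iter), tol = tol, seed = seed,
                 t_pre = t_pre, t_post = t_post, theta_init = theta_init,
                 perturb = perturb),
            class = "scmtf_config")
}

new_scmtf_solution <- function(S, G, M, V, B, basis, N, P, lambda_x, lambda_y,
                               cost, converged, config, relerr_x = NA_real_,
                               relerr_y = NA_real_, calibrated = FALSE,
                               degenerate = FALSE, amp_x = NULL) {
  if (is.null(amp_x)) amp_x <- rep(1, ncol(S))
  structure(list(S = S, G = G, M = M, V = V, B = B, basis = basis, N = N,
                 P = P, lambda_x = lambda_x, lambda_y = lambda_y, cost = cost,
                 converged = converged, config = config, relerr_x = relerr_x,
                 relerr_y = relerr_y, calibrated = calibrated,
                 degenerate = degenerate, amp_x = amp_x),
            class = "scmtf_solution")
}

# EEG-mode amplitudes: 1 for raw solutions; after calibration the factor
# norms live here (columns of S, G, M are unit norm)
solution_amp <- function(sol) {
  if (is.null(sol$amp_x)) rep(1, ncol(sol$S)) else sol$amp_x
}

basis_ops <- function(basis, Is) {
  lapply(seq_len(nrow(basis$waveforms)), function(k) {
    toeplitz_op(basis$waveforms[k, ], basis$grid$n_pre, Is)
  })
}

coupled_predict <- function(S, V, B, ops) {
  Is <- nrow(S); Iv <- nrow(V)
  Yc <- matrix(0, Is, Iv)
  CkS <- vector("list", length(ops))
  for (k in seq_along(ops)) {
    Ck <- toeplitz_apply(ops[[k]], S)
    CkS[[k]] <- Ck
    Yc <- Yc + Ck %*% t(V * B[, k])
  }
  attr(Yc, "CkS") <- CkS
  Yc
}

#' Reconstruct EEG tensor and fMRI matrix from an sCMTF solution
#'
#' The EEG reconstruction is the polyadic model `sum_r s_r o g_r o m_r`;
#' the fMRI reconstruction is
#' `sum_r sum_k (H_k s_r) o (b_k * v_r) + N P'`, where `H_k` is the
#' Toeplitz convolution operator of the k-th HRF basis function and
#' `b_k * v_r` the elementwise (Khatri-Rao-constrained) spatial loading, so
#' the coupled part carries `(R + K) * Iv` spatial parameters rather than
#' `R * K * Iv`.
#'
#' @param sol an `scmtf_solution`.
#' @return list with `Xhat` (Is x Ig x Im array) and `Yhat` (Is x Iv).
#' @export
model_predict <- function(sol) {
  amp <- solution_amp(sol)
  Xhat <- cpd_compose(sweep(sol$S, 2, amp, "*"), sol$G, sol$M)
  ops <- basis_ops(sol$basis, nrow(sol$S))
  Yhat <- coupled_predict(sol$S, sol$V, sol$B, ops)
  attr(Yhat, "CkS") <- NULL
  if (ncol(sol$N) > 0L) Yhat <- Yhat + tcrossprod(sol$N, sol$P)
  list(Xhat = Xhat, Yhat = Yhat)
}

lambda_x_of <- function(S, G, M) {
  vapply(seq_len(ncol(S)), function(r) {
    norm2(S[, r]) * norm2(G[, r]) * norm2(M[, r])
  }, numeric(1))
}

lambda_y_of <- function(V, B) {
  vapply(seq_len(ncol(V)), function(r) {
    sum(vapply(seq_len(ncol(B)), function(k) norm2(B[, k] * V[, r]),
               numeric(1)))
  }, numeric(1))
}

#' Regularized sCMTF cost
#'
#' `J = beta_x ||X - Xhat||_F^2 + beta_y ||Y - Yhat||_F^2 +
#'  gamma_x ||lambda_x||_1 + gamma_y ||lambda_y||_1`, with
#' `lambda_x[r] = ||s_r|| ||g_r|| ||m_r||` and
#' `lambda_y[r] = sum_k ||b_k * v_r||` recomputed from the current factors
#' at every evaluation.
#'
#' @param sol an `scmtf_solution`.
#' @param X data tensor (array or `spectrogram_tensor`).
#' @param Y data matrix (matrix or `bold_matrix`).
#' @param config an [scmtf_config()] supplying the weights (NULL entries are
#'   resolved from the data as documented there).
#' @return scalar cost `J`.
#' @export
scmtf_cost <- function(sol, X, Y, config = sol$config) {
  Xv <- if (inherits(X, "spectrogram_tensor")) X$values else X
  Yv <- if (inherits(Y, "bold_matrix")) Y$values else Y
  w <- resolve_weights(config, Xv, Yv)
  pred <- model_predict(sol)
  w$beta_x * sum((Xv - pred$Xhat)^2) + w$beta_y * sum((Yv - pred$Yhat)^2) +
    w$gamma_x * sum(solution_amp(sol) * lambda_x_of(sol$S, sol$G, sol$M)) +
    w$gamma_y * sum(lambda_y_of(sol$V, sol$B))
}

resolve_weights <- function(config, Xv, Yv) {
  bx <- config$beta_x; by <- config$beta_y
  if (is.null(bx)) bx <- 1 / sum(Xv^2)
  if (is.null(by)) by <- 1 / sum(Yv^2)
  gx <- config$gamma_x; gy <- config$gamma_y
  if (is.null(gx)) gx <- 0.01 * (bx * sum(Xv^2) + by * sum(Yv^2)) / config$R
  if (is.null(gy)) gy <- gx
  list(beta_x = bx, beta_y = by, gamma_x = gx, gamma_y = gy)
}

# ---- parameter packing ------------------------------------------------------

scmtf_layout <- function(Is, Ig, Im, Iv, R, K, Q) {
  sizes <- c(S = Is * R, G = Ig * R, M = Im * R, V = Iv * R, B = Iv * K,
             theta = 5L * K, N = Is * Q, P = Iv * Q)
  offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
  names(offs) <- names(sizes)
  list(Is = Is, Ig = Ig, Im = Im, Iv = Iv, R = R, K = K, Q = Q,
       sizes = sizes, offs = offs, total = sum(sizes))
}

pack_params <- function(S, G, M, V, B, theta, N, P) {
  c(as.numeric(S), as.numeric(G), as.numeric(M), as.numeric(V),
    as.numeric(B), unlist(theta), as.numeric(N), as.numeric(P))
}

unpack_params <- function(par, lay) {
  take <- function(name, nr, nc) {
    if (nr * nc == 0L) return(matrix(0, nr, nc))
    i0 <- lay$offs[[name]]
    matrix(par[i0 + seq_len(nr * nc)], nr, nc)
  }
  theta_flat <- par[(lay$offs[["theta"]] + 1L):(lay$offs[["theta"]] + 5L * lay$K)]
  list(S = take("S", lay$Is, lay$R), G = take("G", lay$Ig, lay$R),
       M = take("M", lay$Im, lay$R), V = take("V", lay$Iv, lay$R),
       B = take("B", lay$Iv, lay$K),
       theta = split(theta_flat, rep(seq_len(lay$K), each = 5L)),
       N = take("N", lay$Is, max(lay$Q, 0L)),
       P = take("P", lay$Iv, max(lay$Q, 0L)))
}

# waveform Jacobian wrt theta by central finite differences (relative step)
hrf_jacobian <- function(theta, grid, rel_step = 1e-4) {
  J <- matrix(0, grid$n_lags, 5L)
  for (i in seq_len(5L)) {
    h <- rel_step * max(abs(theta[i]), 1e-2)
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- max(tm[i] - h, if (i == 5L) 0 else 1e-8)
    J[, i] <- (hrf_from_params(tp, grid) - hrf_from_params(tm, grid)) /
      (tp[i] - tm[i])
  }
  J
}

# cost and gradient of the full objective at a packed parameter vector
scmtf_objective <- function(par, lay, X1, Xdim, Yv, grid, w) {
  p <- unpack_params(par, lay)
  basisW <- t(vapply(p$theta, hrf_from_params, numeric(grid$n_lags),
                     grid = grid))
  ops <- lapply(seq_len(lay$K), function(k) {
    toeplitz_op(basisW[k, ], grid$n_pre, lay$Is)
  })
  KRmg <- khatri_rao(p$M, p$G)
  Ex1 <- p$S %*% t(KRmg) - X1
  Yc <- coupled_predict(p$S, p$V, p$B, ops)
  CkS <- attr(Yc, "CkS")
  Ey <- Yc - Yv
  if (lay$Q > 0L) Ey <- Ey + tcrossprod(p$N, p$P)
  lam_x <- lambda_x_of(p$S, p$G, p$M)
  lam_y <- lambda_y_of(p$V, p$B)
  J <- w$beta_x * sum(Ex1^2) + w$beta_y * sum(Ey^2) +
    w$gamma_x * sum(lam_x) + w$gamma_y * sum(lam_y)
  attr(J, "state") <- list(p = p, Ex1 = Ex1, Ey = Ey, CkS = CkS, ops = ops,
                           KRmg = KRmg, basisW = basisW)
  J
}

scmtf_gradient <- function(par, lay, X1, Xdim, Yv, grid, w,
                           state = NULL) {
  if (is.null(state)) {
    J <- scmtf_objective(par, lay, X1, Xdim, Yv, grid, w)
    state <- attr(J, "state")
  }
  p <- state$p; Ex1 <- state$Ex1; Ey <- state$Ey
  CkS <- state$CkS; ops <- state$ops
  Ex <- array(Ex1, Xdim)
  Ex2 <- unfold2(Ex); Ex3 <- unfold3(Ex)

  dS <- 2 * w$beta_x * Ex1 %*% state$KRmg
  dG <- 2 * w$beta_x * Ex2 %*% khatri_rao(p$M, p$S)
  dM <- 2 * w$beta_x * Ex3 %*% khatri_rao(p$G, p$S)
  dV <- matrix(0, lay$Iv, lay$R)
  dB <- matrix(0, lay$Iv, lay$K)
  dtheta <- vector("list", lay$K)
  for (k in seq_len(lay$K)) {
    EtC <- crossprod(Ey, CkS[[k]])                       # Iv x R
    dV <- dV + 2 * w$beta_y * EtC * p$B[, k]
    dB[, k] <- 2 * w$beta_y * rowSums(EtC * p$V)
    Wk <- p$V * p$B[, k]
    A <- Ey %*% Wk                                        # Is x R
    dS <- dS + 2 * w$beta_y * toeplitz_apply_t(ops[[k]], A)
    # gradient wrt the kernel samples: cross-correlation of A with S
    m <- grid$n_lags
    gh <- numeric(m)
    for (j in seq_len(m)) {
      sh <- j - 1L - grid$n_pre
      o_lo <- max(1L, 1L + sh); o_hi <- min(lay$Is, lay$Is + sh)
      if (o_lo > o_hi) next
      gh[j] <- 2 * w$beta_y *
        sum(A[o_lo:o_hi, , drop = FALSE] *
              p$S[(o_lo - sh):(o_hi - sh), , drop = FALSE])
    }
    dtheta[[k]] <- as.numeric(crossprod(hrf_jacobian(p$theta[[k]], grid), gh))
  }
  if (lay$Q > 0L) {
    dN <- 2 * w$beta_y * Ey %*% p$P
    dP <- 2 * w$beta_y * crossprod(Ey, p$N)
  } else {
    dN <- matrix(0, lay$Is, 0L); dP <- matrix(0, lay$Iv, 0L)
  }
  # l1 amplitude penalties
  for (r in seq_len(lay$R)) {
    ns <- norm2(p$S[, r]); ng <- norm2(p$G[, r]); nm <- norm2(p$M[, r])
    if (ns > 0) dS[, r] <- dS[, r] + w$gamma_x * ng * nm * p$S[, r] / ns
    if (ng > 0) dG[, r] <- dG[, r] + w$gamma_x * ns * nm * p$G[, r] / ng
    if (nm > 0) dM[, r] <- dM[, r] + w$gamma_x * ns * ng * p$M[, r] / nm
    for (k in seq_len(lay$K)) {
      bv <- p$B[, k] * p$V[, r]
      nbv <- norm2(bv)
      if (nbv > 0) {
        dV[, r] <- dV[, r] + w$gamma_y * p$B[, k]^2 * p$V[, r] / nbv
        dB[, k] <- dB[, k] + w$gamma_y * p$V[, r]^2 * p$B[, k] / nbv
      }
    }
  }
  pack_params(dS, dG, dM, dV, dB, dtheta, dN, dP)
}

# ---- fitting ----------------------------------------------------------------

#' Fit the structured coupled matrix-tensor factorization
#'
#' Jointly decomposes the EEG spectrogram tensor `X` and the fMRI ROI
#' matrix `Y` into R shared sources with region-specific HRFs, by
#' minimizing the regularized cost (see [scmtf_cost()]) over all free
#' variables (S, G, M, V, B, HRF parameters theta, and the uncoupled
#' nuisance factors N, P) with L-BFGS. Initialization: a CPD of the EEG
#' tensor provides (S, G, M) (shared across restarts); V and B are obtained
#' by least squares given S and the initial HRF basis, with the
#' Khatri-Rao (shared-HRF) structure imposed via a rank-1 truncation per
#' ROI; N and P come from a truncated SVD of the residual. Each restart
#' perturbs V, B, N, P and theta with relative Gaussian noise.
#'
#' @param X `spectrogram_tensor` or Is x Ig x Im array.
#' @param Y `bold_matrix` or Is x Iv matrix (columns z-scored).
#' @param config an [scmtf_config()].
#' @param tr repetition time in seconds (taken from `X`/`Y` when they carry
#'   one).
#' @return object of class `scmtf_fit`: list with `solutions` (one
#'   calibrated `scmtf_solution` per successful restart, sorted by cost),
#'   `config`, `cpd` (the shared EEG-only initialization).
#' @export
fit_scmtf <- function(X, Y, config = scmtf_config(), tr = NULL) {
  Xv <- if (inherits(X, "spectrogram_tensor")) X$values else X
  Yv <- if (inherits(Y, "bold_matrix")) Y$values else as.matrix(Y)
  if (is.null(tr)) {
    tr <- if (inherits(X, "spectrogram_tensor") && !is.null(X$tr)) X$tr
    else if (inherits(Y, "bold_matrix")) Y$tr else 2.2
  }
  d <- dim(Xv)
  if (d[1L] != nrow(Yv)) {
    stop("time axes disagree: EEG tensor has ", d[1L],
         " volumes but fMRI matrix has ", nrow(Yv))
  }
  lay <- scmtf_layout(d[1L], d[2L], d[3L], ncol(Yv), config$R, config$K,
                      config$Q)
  grid <- lag_grid(config$t_pre, config$t_post, tr)
  w <- resolve_weights(config, Xv, Yv)
  if (!is.null(config$seed)) set.seed(config$seed)

  # stationarity to 1e-8 suffices here: the CPD is only the initialization,
  # and ALS converges slowly when the tensor is overfactored
  cpd <- suppressWarnings(
    cpd_eeg(Xv, config$R, n_inits = 3, max_iter = 300, tol = 1e-8))
  theta0 <- config$theta_init
  if (is.null(theta0)) theta0 <- default_hrf_params(config$K, config$t_pre)
  stopifnot(length(theta0) == config$K)

  init_VB <- function(S, theta) {
    basis <- hrf_basis(theta, grid)
    ops <- basis_ops(basis, lay$Is)
    Z <- do.call(cbind, lapply(ops, function(op) toeplitz_apply(op, S)))
    Cf <- pinv_sym(crossprod(Z)) %*% crossprod(Z, Yv)       # (K*R) x Iv
    V <- matrix(0, lay$Iv, lay$R); B <- matrix(0, lay$Iv, lay$K)
    for (iv in seq_len(lay$Iv)) {
      Civ <- matrix(Cf[, iv], lay$R, lay$K)                 # r fast, k slow
      sv <- svd(Civ, nu = 1, nv = 1)
      s1 <- sqrt(sv$d[1L])
      V[iv, ] <- sv$u[, 1L] * s1
      B[iv, ] <- sv$v[, 1L] * s1
    }
    list(V = V, B = B)
  }

  X1 <- unfold1(Xv)
  nrmX <- norm2(X1); nrmY <- norm2(Yv)
  lower <- rep(-Inf, lay$total); upper <- rep(Inf, lay$total)
  th_idx <- lay$offs[["theta"]] + seq_len(5L * lay$K)
  lower[th_idx] <- rep(c(1.05, 0.05, 1.05, 0.05, 0), lay$K)
  upper[th_idx] <- rep(c(300, 20, 300, 20, 20), lay$K)

  vb0 <- init_VB(cpd$S, theta0)
  resid0 <- Yv - coupled_predict(cpd$S, vb0$V, vb0$B,
                                 basis_ops(hrf_basis(theta0, grid), lay$Is))
  if (config$Q > 0L) {
    sv <- svd(resid0, nu = config$Q, nv = config$Q)
    N0 <- sv$u %*% diag(sqrt(sv$d[seq_len(config$Q)]), config$Q)
    P0 <- sv$v %*% diag(sqrt(sv$d[seq_len(config$Q)]), config$Q)
  } else {
    N0 <- matrix(0, lay$Is, 0L); P0 <- matrix(0, lay$Iv, 0L)
  }

  perturb_mat <- function(A, rel) {
    if (length(A) == 0L) return(A)
    A + stats::rnorm(length(A), sd = rel * max(stats::sd(A), 1e-8))
  }

  solutions <- list()
  for (i in seq_len(config$n_inits)) {
    if (i == 1L) {
      Vi <- vb0$V; Bi <- vb0$B; Ni <- N0; Pi <- P0; thi <- theta0
    } else {
      Vi <- perturb_mat(vb0$V, config$perturb)
      Bi <- perturb_mat(vb0$B, config$perturb)
      Ni <- perturb_mat(N0, config$perturb)
      Pi <- perturb_mat(P0, config$perturb)
      thi <- lapply(theta0, function(th) {
        pmax(th * (1 + stats::rnorm(5L, sd = config$perturb)),
             c(1.05, 0.05, 1.05, 0.05, 0))
      })
    }
    par0 <- pack_params(cpd$S, cpd$G, cpd$M, Vi, Bi, thi, Ni, Pi)
    fit <- tryCatch(
      stats::optim(par0,
                   fn = function(par) as.numeric(
                     scmtf_objective(par, lay, X1, d, Yv, grid, w)),
                   gr = function(par)
                     scmtf_gradient(par, lay, X1, d, Yv, grid, w),
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = config$max_iter,
                                  factr = config$tol / .Machine$double.eps)),
      error = function(e) e)
    if (inherits(fit, "error") || !is.finite(fit$value)) {
      message("restart ", i, " discarded: ",
              if (inherits(fit, "error")) conditionMessage(fit)
              else "non-finite cost")
      next
    }
    p <- unpack_params(fit$par, lay)
    basis <- hrf_basis(p$theta, grid)
    sol <- new_scmtf_solution(
      S = p$S, G = p$G, M = p$M, V = p$V, B = p$B, basis = basis,
      N = p$N, P = p$P,
      lambda_x = lambda_x_of(p$S, p$G, p$M),
      lambda_y = lambda_y_of(p$V, p$B),
      cost = fit$value, converged = fit$convergence == 0L, config = config)
    pred <- model_predict(sol)
    sol$relerr_x <- norm2(unfold1(pred$Xhat) - X1) / nrmX
    sol$relerr_y <- norm2(pred$Yhat - Yv) / nrmY
    lam <- sol$lambda_x
    sol$degenerate <- any(lam < 1e-6 * max(lam))
    solutions[[length(solutions) + 1L]] <- calibrate(sol)
  }
  if (!length(solutions)) stop("all restarts failed")
  solutions <- solutions[order(vapply(solutions, `[[`, numeric(1), "cost"))]
  structure(list(solutions = solutions, config = config, cpd = cpd,
                 grid = grid),
            class = "scmtf_fit")
}

#' Best (lowest-cost) solution of an sCMTF fit
#' @param fit an `scmtf_fit`.
#' @export
best_solution <- function(fit) fit$solutions[[1L]]

#' Calibrate an sCMTF solution
#'
#' Removes the scaling and sign ambiguities left by the factorization:
#' columns of S, G, M are scaled to unit norm with the amplitudes absorbed
#' into `lambda_x`; `g_r` and `m_r` are flipped so their largest-magnitude
#' entries are positive, with compensating flips/scales pushed into `s_r`
#' and then into `v_r` so the reconstruction is unchanged; each ROI's HRF
#' polarity is chosen so its main lobe (largest-magnitude extremum) is
#' positive, compensated in the corresponding rows of V; basis waveforms
#' are scaled to unit norm with the scales absorbed into B. Idempotent, and
#' invariant under [model_predict()] (both checked in the tests).
#'
#' @param sol an `scmtf_solution`.
#' @return calibrated `scmtf_solution`.
#' @export
calibrate <- function(sol) {
  S <- sol$S; G <- sol$G; M <- sol$M; V <- sol$V; B <- sol$B
  basis <- sol$basis
  amp <- solution_amp(sol)
  R <- ncol(S)
  for (r in seq_len(R)) {
    sg <- sign(G[which.max(abs(G[, r])), r]); if (sg == 0) sg <- 1
    sm <- sign(M[which.max(abs(M[, r])), r]); if (sm == 0) sm <- 1
    G[, r] <- sg * G[, r]; M[, r] <- sm * M[, r]
    ns <- norm2(S[, r]); ng <- norm2(G[, r]); nm <- norm2(M[, r])
    if (ng > 0) G[, r] <- G[, r] / ng
    if (nm > 0) M[, r] <- M[, r] / nm
    if (ns > 0) S[, r] <- (sg * sm) * S[, r] / ns
    # amplitudes move to amp (EEG mode); the temporal rescaling/flip is
    # compensated in the fMRI spatial signature
    amp[r] <- amp[r] * max(ns, .Machine$double.eps) * ng * nm
    V[, r] <- V[, r] * ns * (sg * sm)
  }
  # unit-norm basis waveforms, scales into B
  nrm <- sqrt(rowSums(basis$waveforms^2))
  nrm[nrm < .Machine$double.eps] <- 1
  basis$waveforms <- basis$waveforms / nrm
  basis$scale <- basis$scale * nrm
  B <- sweep(B, 2, nrm, "*")
  # per-ROI HRF polarity: main lobe positive, compensated in V rows
  hrfs <- B %*% basis$waveforms                    # Iv x n_lags
  for (iv in seq_len(nrow(B))) {
    pk <- hrfs[iv, which.max(abs(hrfs[iv, ]))]
    if (pk < 0) {
      B[iv, ] <- -B[iv, ]
      V[iv, ] <- -V[iv, ]
    }
  }
  out <- sol
  out$S <- S; out$G <- G; out$M <- M; out$V <- V; out$B <- B
  out$basis <- basis
  out$amp_x <- amp
  out$lambda_x <- amp * lambda_x_of(S, G, M)   # = amp: factors are unit norm
  out$lambda_y <- lambda_y_of(V, B)
  out$calibrated <- TRUE
  out
}

#' ROI HRF waveforms of a solution
#'
#' @param sol an `scmtf_solution`.
#' @return Iv x n_lags matrix of per-ROI HRF waveforms.
#' @export
roi_hrfs <- function(sol) {
  sol$B %*% sol$basis$waveforms
}

#' Identify the IED-related component
#'
#' Picks the source whose temporal signature has the highest Pearson
#' correlation with the broadband power envelope of the enhanced EEG.
#' Ties are broken by the lowest index (with a message).
#'
#' @param sol an `scmtf_solution`.
#' @param s_ref per-TR reference envelope (length Is).
#' @return list with `index` and `correlation`.
#' @export
select_ied_component <- function(sol, s_ref) {
  stopifnot(length(s_ref) == nrow(sol$S))
  if (stats::sd(s_ref) < .Machine$double.eps) {
    stop("constant reference envelope: correlation undefined")
  }
  cors <- apply(sol$S, 2, function(s) {
    if (stats::sd(s) < .Machine$double.eps) return(-Inf)
    stats::cor(s, s_ref)
  })
  top <- max(cors)
  idx <- which(cors >= top - 1e-12)
  if (length(idx) > 1L) {
    message("tie between components ", paste(idx, collapse = ", "),
            "; picking the lowest index")
  }
  list(index = idx[1L], correlation = cors[idx[1L]], correlations = cors)
}

#' Select the model order (rank) across candidate fits
#'
#' Scores every candidate rank on (a) stability: the mean pairwise factor
#' congruence of the up-to-five lowest-cost restarts; (b) relevance: the
#' IED-envelope correlation of the best restart's best-matching component;
#' (c) parsimony: whether the EEG fit curve has plateaued, i.e. the
#' relative fit gain of the next-larger rank falls below
#' `plateau` (for the largest candidate the gain is taken as zero). The
#' chosen rank is the smallest one with stability >= `stability_min`,
#' relevance >= `relevance_min` and a plateaued successor; if no candidate
#' qualifies, the rank with maximal relevance is returned. The full score
#' table is returned for audit.
#'
#' @param fits named list of `scmtf_fit` objects, one per candidate rank
#'   (names or configs supply R).
#' @param s_ref per-TR reference envelope.
#' @param stability_min,relevance_min,plateau selection thresholds.
#' @return list with `R` (chosen rank), `solution` (best solution at that
#'   rank), `ied` (component index + correlation), `scores` (tibble).
#' @export
select_model <- function(fits, s_ref, stability_min = 0.9,
                         relevance_min = 0.3, plateau = 0.03) {
  Rs <- vapply(fits, function(f) f$config$R, integer(1))
  ord <- order(Rs)
  fits <- fits[ord]; Rs <- Rs[ord]
  stab <- rel <- fitx <- numeric(length(fits))
  for (i in seq_along(fits)) {
    sols <- fits[[i]]$solutions
    top <- sols[seq_len(min(5L, length(sols)))]
    if (length(top) < 2L) {
      stab[i] <- 1
    } else {
      prs <- utils::combn(length(top), 2L)
      stab[i] <- mean(apply(prs, 2, function(pr) {
        factor_congruence(
          list(top[[pr[1L]]]$S, top[[pr[1L]]]$G, top[[pr[1L]]]$M),
          list(top[[pr[2L]]]$S, top[[pr[2L]]]$G, top[[pr[2L]]]$M))$score
      }))
    }
    best <- sols[[1L]]
    rel[i] <- select_ied_component(best, s_ref)$correlation
    fitx[i] <- best$relerr_x
  }
  gain_next <- c(if (length(fits) > 1L) fitx[-length(fitx)] - fitx[-1L], 0)
  eligible <- stab >= stability_min & rel >= relevance_min &
    gain_next < plateau
  chosen <- if (any(eligible)) which(eligible)[1L] else which.max(rel)
  best <- fits[[chosen]]$solutions[[1L]]
  scores <- tibble::tibble(R = Rs, stability = stab, relevance = rel,
                           eeg_relerr = fitx, gain_next = gain_next,
                           eligible = eligible, selected = seq_along(Rs) == chosen)
  list(R = Rs[chosen], solution = best,
       ied = select_ied_component(best, s_ref), scores = scores)
}
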