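#' Canonical polyadic decomposition (CPD) of the EEG spectrogram tensor
#'
#' Fits a rank-R trilinear model `X ~ sum_r s_r o g_r o m_r` by alternating
#' least squares, from a leading-singular-vector initialization plus
#' `n_inits - 1` random restarts, keeping the best-fitting solution. The
#' factors are returned unnormalized; downstream calibration resolves the
#' scaling/sign ambiguities.
#'
#' @param X a `spectrogram_tensor` or plain Is x Ig x Im array.
#' @param R rank (number of sources).
#' @param seed integer seed for the random restarts.
#' @param n_inits number of initializations (default 3).
#' @param max_iter maximum ALS sweeps per initialization (default 500).
#' @param tol relative change in fit below which iteration stops.
#' @return list with factor matrices `S` (Is x R), `G` (Ig x R),
#'   `M` (Im x R), `relerr` (relative Frobenius error), `converged`,
#'   `iterations`.
#' @export
cpd_eeg <- function(X, R, seed = NULL, n_inits = 3, max_iter = 500,
                    tol = 1e-10) {
  V <- if (inherits(X, "spectrogram_tensor")) X$values else X
  stopifnot(length(dim(V)) == 3L, R >= 1)
  d <- dim(V)
  if (R > min(d)) {
    warning("rank R = ", R, " exceeds the smallest tensor dimension (",
            min(d), "); the decomposition is not unique")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  X1 <- unfold1(V); X2 <- unfold2(V); X3 <- unfold3(V)
  nrmX <- norm2(X1)

  nvecs <- function(Xn, R) {
    ei <- eigen(tcrossprod(Xn), symmetric = TRUE)
    U <- ei$vectors[, seq_len(min(R, ncol(ei$vectors))), drop = FALSE]
    if (ncol(U) < R) U <- cbind(U, matrix(stats::rnorm(nrow(U) * (R - ncol(U))),
                                          nrow(U)))
    U
  }

  run_als <- function(G, M) {
    relerr <- Inf
    S <- NULL
    for (it in seq_len(max_iter)) {
      GG <- crossprod(G); MM <- crossprod(M)
      S <- X1 %*% khatri_rao(M, G) %*% pinv_sym(MM * GG)
      SS <- crossprod(S)
      G <- X2 %*% khatri_rao(M, S) %*% pinv_sym(MM * SS)
      GG <- crossprod(G)
      M <- X3 %*% khatri_rao(G, S) %*% pinv_sym(GG * SS)
      MM <- crossprod(M)
      # column rebalancing for numerical stability
      for (r in seq_len(R)) {
        sc <- c(norm2(S[, r]), norm2(G[, r]), norm2(M[, r]))
        if (any(sc == 0)) next
        tot <- prod(sc)^(1 / 3)
        S[, r] <- S[, r] / sc[1] * tot
        G[, r] <- G[, r] / sc[2] * tot
        M[, r] <- M[, r] / sc[3] * tot
      }
      err <- norm2(X1 - S %*% t(khatri_rao(M, G))) / nrmX
      if (is.finite(relerr) && abs(relerr - err) < tol * max(1, relerr)) {
        return(list(S = S, G = G, M = M, relerr = err, converged = TRUE,
                    iterations = it))
      }
      relerr <- err
    }
    list(S = S, G = G, M = M, relerr = relerr, converged = FALSE,
         iterations = max_iter)
  }

  best <- NULL
  for (i in seq_len(max(1L, n_inits))) {
    if (i == 1L) {
      G0 <- nvecs(X2, R); M0 <- nvecs(X3, R)
    } else {
      G0 <- matrix(stats::rnorm(d[2L] * R), d[2L], R)
      M0 <- matrix(stats::rnorm(d[3L] * R), d[3L], R)
    }
    sol <- run_als(G0, M0)
    if (is.null(best) || (is.finite(sol$relerr) && sol$relerr < best$relerr)) {
      best <- sol
    }
  }
  if (!best$converged) {
    warning("CPD did not reach the stationarity tolerance within ", max_iter,
            " sweeps; returning the best iterate")
  }
  best
}

# pseudo-inverse of a small symmetric (Gram) matrix
pinv_sym <- function(A, tol = 1e-12) {
  ei <- eigen((A + t(A)) / 2, symmetric = TRUE)
  pos <- ei$values > tol * max(abs(ei$values), .Machine$double.eps)
  if (!any(pos)) return(matrix(0, nrow(A), ncol(A)))
  V <- ei$vectors[, pos, drop = FALSE]
  V %*% (t(V) / ei$values[pos])
}
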