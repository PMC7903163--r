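#' Remove the uncoupled nuisance term from the fMRI data
#'
#' Returns `Y - N P'`: the fMRI matrix with the structured fMRI-only
#' variation (as captured by the rank-Q uncoupled term of the
#' factorization) removed. Only this adjusted matrix is resampled when
#' building surrogate data.
#'
#' @param Y `bold_matrix` or time x ROI matrix.
#' @param sol an `scmtf_solution`.
#' @return time x ROI matrix.
#' @export
adjust_fmri <- function(Y, sol) {
  Yv <- if (inherits(Y, "bold_matrix")) Y$values else as.matrix(Y)
  if (ncol(sol$N) == 0L) return(Yv)
  Yv - tcrossprod(sol$N, sol$P)
}

# ---- periodized Daubechies-4 DWT -------------------------------------------

daub4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4L], -h[3L], h[2L], -h[1L])
  list(h = h, g = g)
}

# one analysis level on a coefficient vector of even length (periodized)
dwt_step <- function(c0) {
  f <- daub4_filters()
  n <- length(c0)
  half <- n %/% 2L
  idx <- function(n_off) ((2L * (seq_len(half) - 1L) + n_off) %% n) + 1L
  a <- d <- numeric(half)
  for (j in 0:3) {
    a <- a + f$h[j + 1L] * c0[idx(j)]
    d <- d + f$g[j + 1L] * c0[idx(j)]
  }
  c(a, d)
}

#' Orthonormal wavelet analysis matrix (Daubechies-4, periodized)
#'
#' Builds the `n x n` matrix whose rows are the depth-level wavelet
#' analysis functionals; rows are ordered `[approx_depth, detail_depth,
#' detail_{depth-1}, ..., detail_1]`. The matrix is orthonormal, so the
#' synthesis transform is its transpose. `n` must be a power of two and
#' `n / 2^depth >= 1`.
#'
#' @param n series length (power of two).
#' @param depth number of decomposition levels.
#' @return list with `W` (n x n), `blocks` (row index list per scale).
#' @keywords internal
dwt_matrix <- function(n, depth) {
  stopifnot(n >= 2, bitwAnd(n, n - 1L) == 0L, depth >= 1, 2^depth <= n)
  W <- diag(n)
  m <- n
  for (l in seq_len(depth)) {
    W[seq_len(m), ] <- apply(W[seq_len(m), , drop = FALSE], 2, dwt_step)
    m <- m %/% 2L
  }
  blocks <- list(seq_len(m))                       # coarsest approximation
  lo <- m
  for (l in depth:1) {
    blocks[[length(blocks) + 1L]] <- (lo + 1L):(2L * lo)
    lo <- 2L * lo
  }
  list(W = W, blocks = blocks)
}

.dwt_cache <- new.env(parent = emptyenv())
dwt_cached <- function(n, depth) {
  key <- paste(n, depth, sep = "_")
  if (is.null(.dwt_cache[[key]])) .dwt_cache[[key]] <- dwt_matrix(n, depth)
  .dwt_cache[[key]]
}

#' Wavelet-based resampling of fMRI time series
#'
#' Generates surrogate datasets that are exchangeable under the null
#' hypothesis of no EEG-coupled BOLD effect while preserving the
#' spatiotemporal correlation structure: each column is transformed with a
#' periodized Daubechies-4 discrete wavelet transform (after reflection
#' padding to the next power of two), the coefficients are permuted within
#' each scale -- by default with one permutation per scale shared across
#' all columns, which preserves the cross-ROI covariance -- and the
#' transform is inverted. The decomposition depth is the largest with at
#' least 8 coefficients in the coarsest retained scale.
#'
#' @param Y_adj time x ROI matrix (nuisance-adjusted, see [adjust_fmri()]).
#' @param L number of surrogates (default 250).
#' @param seed integer seed; the same seed reproduces the surrogate set
#'   bit for bit.
#' @param shared_perm share each scale's permutation across columns
#'   (default `TRUE`); `FALSE` permutes every column independently.
#' @return object of class `surrogate_set` with `surrogates`
#'   (Is x Iv x L array), `wavelet_name`, `seed`, `depth`.
#' @export
wavelet_resample <- function(Y_adj, L = 250, seed = NULL, shared_perm = TRUE) {
  Y_adj <- as.matrix(Y_adj)
  Is <- nrow(Y_adj); Iv <- ncol(Y_adj)
  stopifnot(L >= 1)
  if (Is < 32L) warning("fewer than 32 time points; surrogate quality is poor")
  npad <- 2L^ceiling(log2(max(Is, 8L)))
  depth <- max(1L, floor(log2(npad / 8)))
  if (npad / 2^depth < 8L) {
    depth <- max(1L, floor(log2(npad / 8)))
    warning("decomposition depth reduced to ", depth,
            " to keep >= 8 coefficients per scale")
  }
  dw <- dwt_cached(npad, depth)
  if (npad > Is) {
    n_extra <- npad - Is
    refl <- Y_adj[Is - seq_len(n_extra) + 1L, , drop = FALSE]
    Ypad <- rbind(Y_adj, refl)
  } else {
    Ypad <- Y_adj
  }
  C <- dw$W %*% Ypad
  if (!is.null(seed)) set.seed(seed)
  mu0 <- colMeans(Y_adj)
  sd0 <- apply(Y_adj, 2, stats::sd)
  sur <- array(0, c(Is, Iv, L))
  for (l in seq_len(L)) {
    Cp <- C
    for (blk in dw$blocks) {
      if (shared_perm) {
        Cp[blk, ] <- C[blk[sample.int(length(blk))], , drop = FALSE]
      } else {
        for (j in seq_len(Iv)) {
          Cp[blk, j] <- C[blk[sample.int(length(blk))], j]
        }
      }
    }
    Ys <- crossprod(dw$W, Cp)[seq_len(Is), , drop = FALSE]
    # amplitude adjustment: the transform is orthonormal on the padded
    # series, but truncating back to Is samples perturbs the per-column
    # variance; restore the original first two moments exactly (the
    # pseudo-t statistic is location/scale free, so inference is unchanged)
    sds <- apply(Ys, 2, stats::sd)
    sds[sds < .Machine$double.eps] <- 1
    Ys <- sweep(Ys, 2, colMeans(Ys), "-")
    Ys <- sweep(sweep(Ys, 2, sds, "/"), 2, sd0, "*")
    sur[, , l] <- sweep(Ys, 2, mu0, "+")
  }
  structure(list(surrogates = sur, wavelet_name = "db4", seed = seed,
                 depth = depth),
            class = "surrogate_set")
}

# ---- pseudo-t statistics ----------------------------------------------------

# per-ROI local design matrices D_iv = [z_iv(1) ... z_iv(R)] and the OLS
# quantities needed for t statistics
snpm_designs <- function(sol, Is) {
  R <- ncol(sol$S)
  ops <- basis_ops(sol$basis, Is)
  CkS <- lapply(ops, function(op) toeplitz_apply(op, sol$S))   # Is x R each
  Iv <- nrow(sol$B)
  lapply(seq_len(Iv), function(iv) {
    D <- matrix(0, Is, R)
    for (k in seq_along(CkS)) D <- D + sol$B[iv, k] * CkS[[k]]
    DtD <- crossprod(D)
    DtDi <- pinv_sym(DtD)
    if (qr(D)$rank < R) {
      warning("rank-deficient local design in ROI ", iv,
              "; using the pseudo-inverse")
    }
    list(D = D, proj = DtDi %*% t(D), dinv = diag(DtDi), df = Is - R)
  })
}

T_SENTINEL <- 1e6

# t statistics for one ROI given its design quantities and columns of data
t_from_design <- function(dz, Ys) {
  betas <- dz$proj %*% Ys                        # R x L
  fitted <- dz$D %*% betas
  rss <- colSums((Ys - fitted)^2)
  se <- sqrt(outer(dz$dinv, rss / max(dz$df, 1L)))
  tt <- betas / se
  bad <- !is.finite(tt) | abs(tt) > T_SENTINEL
  if (any(bad)) {
    tt[bad] <- sign(betas[bad]) * T_SENTINEL
    tt[!is.finite(tt)] <- 0
  }
  list(t = tt, betas = betas)
}

#' Pseudo-t statistics of one ROI's BOLD series against all sources
#'
#' Builds the ROI's local design matrix from the fitted temporal signatures
#' convolved with the ROI's HRF, solves for the betas by (pseudo-inverse)
#' least squares, and converts them to t statistics using the standard OLS
#' standard error with `Is - R` degrees of freedom. Perfect fits are capped
#' at a finite sentinel (1e6) with a message.
#'
#' @param sol an `scmtf_solution`.
#' @param y numeric BOLD series (length Is) for the ROI.
#' @param roi ROI index (selects the ROI-specific HRF coefficients).
#' @return numeric R-vector of t statistics.
#' @export
pseudo_t <- function(sol, y, roi) {
  Is <- length(y)
  if (Is <= ncol(sol$S)) stop("need more time points than sources")
  dz <- snpm_designs(sol, Is)[[roi]]
  res <- t_from_design(dz, matrix(y, ncol = 1L))
  if (any(abs(res$t) >= T_SENTINEL)) {
    message("perfect fit in ROI ", roi, ": |t| capped at ", T_SENTINEL)
  }
  as.numeric(res$t)
}

# observed / surrogate statistic maps: returns R x Iv matrix (t or betas)
stat_map <- function(designs, Y, statistic = "pseudo_t") {
  R <- nrow(designs[[1L]]$proj)
  Iv <- length(designs)
  out <- matrix(0, R, Iv)
  for (iv in seq_len(Iv)) {
    res <- t_from_design(designs[[iv]], Y[, iv, drop = FALSE])
    out[, iv] <- if (statistic == "pseudo_t") res$t else res$betas
  }
  out
}

#' Maximum-statistic familywise-error thresholds
#'
#' For every source, forms the empirical distribution of the maximal (and
#' minimal) statistic over all ROIs across surrogates and returns the
#' activation threshold `T_hi` and deactivation threshold `T_lo`. With
#' `tail = "two.sided"` (default) the nominal level is split across the two
#' tails so that the familywise error over both directions is controlled
#' jointly at `alpha`; `tail = "each"` tests each direction at the full
#' `alpha` (the convention of thresholding the max at the
#' `1 - alpha` percentile and the min at the `alpha` percentile).
#'
#' @param null_t L x Iv x R array of surrogate statistics.
#' @param alpha familywise error level (default 0.05).
#' @param tail `"two.sided"` or `"each"` (see above).
#' @return list with `T_hi`, `T_lo` (R-vectors).
#' @export
fwe_thresholds <- function(null_t, alpha = 0.05, tail = c("two.sided", "each")) {
  tail <- match.arg(tail)
  stopifnot(length(dim(null_t)) == 3L, alpha > 0, alpha < 1)
  L <- dim(null_t)[1L]; R <- dim(null_t)[3L]
  if (L < 20L) warning("only ", L, " surrogates: percentile estimates are unstable")
  a_tail <- if (tail == "two.sided") alpha / 2 else alpha
  m <- floor(a_tail * L)
  T_hi <- T_lo <- numeric(R)
  for (r in seq_len(R)) {
    maxs <- apply(null_t[, , r, drop = FALSE], 1, max)
    mins <- apply(null_t[, , r, drop = FALSE], 1, min)
    sx_hi <- sort(maxs); sx_lo <- sort(mins)
    T_hi[r] <- if (m >= 1L) sx_hi[L - m + 1L] else sx_hi[L]
    T_lo[r] <- if (m >= 1L) sx_lo[m] else sx_lo[1L]
  }
  list(T_hi = T_hi, T_lo = T_lo)
}

#' Statistical nonparametric map of the fMRI spatial signatures
#'
#' Runs the full resampling inference for a fitted solution: removes the
#' uncoupled nuisance term, generates L wavelet-resampled surrogates,
#' computes the per-ROI, per-source statistic (pseudo-t by default, or the
#' raw OLS betas with `statistic = "beta"`) on each surrogate, derives
#' maximum-statistic familywise thresholds per source, and applies them to
#' the statistics of the unshuffled data.
#'
#' @param sol an `scmtf_solution`.
#' @param Y `bold_matrix` or time x ROI matrix the solution was fitted on.
#' @param L number of surrogates (default 250).
#' @param alpha familywise error level (default 0.05).
#' @param seed integer seed for the surrogate generator.
#' @param tail threshold convention, see [fwe_thresholds()].
#' @param statistic `"pseudo_t"` (default) or `"beta"`.
#' @param top_k optional: additionally restrict each mask to the `top_k`
#'   ROIs with the largest observed statistic magnitude per source.
#' @param shared_perm see [wavelet_resample()].
#' @return object of class `snpm_result` with fields `t` (R x Iv observed
#'   statistics), `v` (fitted spatial signatures), `thresh_hi`, `thresh_lo`,
#'   `act_mask`, `deact_mask` (R x Iv logical), `alpha`, `statistic`.
#' @export
build_snpm <- function(sol, Y, L = 250, alpha = 0.05, seed = NULL,
                       tail = c("two.sided", "each"),
                       statistic = c("pseudo_t", "beta"), top_k = NULL,
                       shared_perm = TRUE) {
  tail <- match.arg(tail)
  statistic <- match.arg(statistic)
  Y_adj <- adjust_fmri(Y, sol)
  Is <- nrow(Y_adj); Iv <- ncol(Y_adj); R <- ncol(sol$S)
  if (Is <= R) stop("need more time points than sources")
  designs <- snpm_designs(sol, Is)
  t_obs <- stat_map(designs, Y_adj, statistic)
  sur <- wavelet_resample(Y_adj, L = L, seed = seed,
                          shared_perm = shared_perm)
  null_t <- array(0, c(L, Iv, R))
  for (iv in seq_len(Iv)) {
    res <- t_from_design(designs[[iv]], sur$surrogates[, iv, ])
    stat <- if (statistic == "pseudo_t") res$t else res$betas
    for (r in seq_len(R)) null_t[, iv, r] <- stat[r, ]
  }
  thr <- fwe_thresholds(null_t, alpha = alpha, tail = tail)
  act <- t_obs > thr$T_hi
  deact <- t_obs < thr$T_lo
  if (!is.null(top_k)) {
    for (r in seq_len(R)) {
      keep <- top_k_indices(abs(t_obs[r, ]), min(top_k, Iv))
      mask <- rep(FALSE, Iv); mask[keep] <- TRUE
      act[r, ] <- act[r, ] & mask
      deact[r, ] <- deact[r, ] & mask
    }
  }
  structure(list(t = t_obs, v = t(sol$V), thresh_hi = thr$T_hi,
                 thresh_lo = thr$T_lo, act_mask = act, deact_mask = deact,
                 alpha = alpha, statistic = statistic, tail = tail,
                 n_surrogates = L),
            class = "snpm_result")
}
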