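#' EEG recording container
#'
#' Bundles a channels x samples signal array with its sampling rate, channel
#' labels, an annotation mask marking interictal epileptic discharge (IED)
#' segments, and the fMRI repetition time used downstream for
#' synchronization. Channels are standardized to unit standard deviation
#' unless `standardize = FALSE`.
#'
#' @param signals channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param ied_mask logical per-sample vector, `TRUE` inside annotated IED
#'   segments. Defaults to all-`FALSE`.
#' @param channel_labels optional character vector.
#' @param tr fMRI repetition time in seconds.
#' @param standardize divide each channel by its standard deviation.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, fs, ied_mask = NULL, channel_labels = NULL,
                          tr = 2.2, standardize = TRUE) {
  signals <- as.matrix(signals)
  if (is.null(ied_mask)) ied_mask <- rep(FALSE, ncol(signals))
  stopifnot(fs > 0, tr > 0, length(ied_mask) == ncol(signals))
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(signals)))
  }
  if (standardize) {
    s <- apply(signals, 1, stats::sd)
    s[s < .Machine$double.eps] <- 1
    signals <- signals / s
  }
  structure(list(signals = signals, fs = fs, ied_mask = as.logical(ied_mask),
                 channel_labels = channel_labels, tr = tr),
            class = "eeg_recording")
}

#' Convert annotation intervals (seconds) to a per-sample mask
#'
#' @param onsets,offsets numeric vectors of interval starts/ends in seconds.
#' @param n_samples,fs recording length and sampling rate.
#' @return logical vector of length `n_samples`.
#' @export
annotations_to_mask <- function(onsets, offsets, n_samples, fs) {
  stopifnot(length(onsets) == length(offsets), all(offsets >= onsets))
  mask <- rep(FALSE, n_samples)
  for (i in seq_along(onsets)) {
    lo <- max(1L, floor(onsets[i] * fs) + 1L)
    hi <- min(n_samples, ceiling(offsets[i] * fs))
    if (lo <= hi) mask[lo:hi] <- TRUE
  }
  mask
}

#' Time-delay embedding of multichannel EEG
#'
#' Stacks lagged copies `x[t - tau], ..., x[t], ..., x[t + tau]` of the
#' channels x samples signal into a `(2*Im*tau + Im)` x samples array, so
#' that a spatial filter on the embedded signal is a spatiotemporal (FIR)
#' filter on the original channels. Boundary columns where any lag runs off
#' the recording are flagged (`valid`) and excluded from covariance
#' estimation.
#'
#' @param rec an [eeg_recording()] (or plain channels x samples matrix).
#' @param tau nonnegative integer lag count.
#' @return object of class `embedded_eeg` with `signals`
#'   (`Im*(2*tau+1)` x samples), `tau`, `im`, `valid` (logical per sample),
#'   and the original `ied_mask`/`fs`/`tr` when available.
#' @export
delay_embed <- function(rec, tau) {
  X <- if (inherits(rec, "eeg_recording")) rec$signals else as.matrix(rec)
  stopifnot(tau >= 0, tau == round(tau), nrow(X) >= 1, ncol(X) >= 1)
  tau <- as.integer(tau)
  n <- ncol(X); im <- nrow(X)
  if (n - 2L * tau < 1L) {
    stop("invalid parameter: tau = ", tau,
         " leaves no valid interior samples for a recording of ", n,
         " samples")
  }
  nrow_out <- im * (2L * tau + 1L)
  E <- matrix(0, nrow_out, n)
  for (l in -tau:tau) {
    rows <- (l + tau) * im + seq_len(im)
    src_lo <- max(1L, 1L + l); src_hi <- min(n, n + l)
    dst_lo <- src_lo - l; dst_hi <- src_hi - l
    E[rows, dst_lo:dst_hi] <- X[, src_lo:src_hi, drop = FALSE]
  }
  valid <- rep(TRUE, n)
  if (tau > 0L) {
    valid[seq_len(tau)] <- FALSE
    valid[(n - tau + 1L):n] <- FALSE
  }
  structure(list(
    signals = E, tau = tau, im = im, valid = valid,
    ied_mask = if (inherits(rec, "eeg_recording")) rec$ied_mask else NULL,
    fs = if (inherits(rec, "eeg_recording")) rec$fs else NULL,
    tr = if (inherits(rec, "eeg_recording")) rec$tr else NULL
  ), class = "embedded_eeg")
}

#' Estimate a multi-channel Wiener filter from IED annotations
#'
#' Computes the covariance `Rxx` of the embedded EEG during annotated IED
#' segments and `Rnn` outside them, then forms the SNR-maximizing filter
#' `W = Rxx^{-1} (Rxx - Rnn)` through the generalized eigenvalue
#' decomposition (GEVD) of the pencil `(Rxx, Rnn)`: with generalized
#' eigenvectors `Z` (normalized so `Z' Rnn Z = I`) and eigenvalues `lambda`,
#' `W = Z diag(1 - 1/lambda) Z' Rnn`, truncated to the directions with
#' `lambda > 1`. The truncation enforces positive semidefiniteness of
#' `Rxx - Rnn` in the whitened domain, which is the standard rank selection
#' for this filter.
#'
#' @param emb an [embedded_eeg()].
#' @param ied_mask logical per-sample mask (defaults to the one carried by
#'   `emb`).
#' @param shrinkage diagonal shrinkage added to both covariances, as a
#'   fraction of `trace/dim` (default `1e-6`), for numerical stability.
#' @return object of class `wiener_filter` with `weights` (square,
#'   embedded-dim), `tau`, `gevd_rank`, `eigenvalues`.
#' @export
estimate_mwf <- function(emb, ied_mask = NULL, shrinkage = 1e-6) {
  stopifnot(inherits(emb, "embedded_eeg"), shrinkage >= 0, shrinkage <= 1)
  if (is.null(ied_mask)) ied_mask <- emb$ied_mask
  if (is.null(ied_mask)) stop("invalid input: no IED mask available")
  stopifnot(length(ied_mask) == ncol(emb$signals))
  use <- emb$valid
  d <- nrow(emb$signals)
  idx_x <- which(ied_mask & use)
  idx_n <- which(!ied_mask & use)
  if (length(idx_x) < 2L || length(idx_n) < 2L) {
    stop("invalid input: IED mask must contain both annotated and ",
         "background samples")
  }
  Rxx <- tcrossprod(emb$signals[, idx_x, drop = FALSE]) / length(idx_x)
  Rnn <- tcrossprod(emb$signals[, idx_n, drop = FALSE]) / length(idx_n)
  ridge_x <- shrinkage * sum(diag(Rxx)) / d
  ridge_n <- shrinkage * sum(diag(Rnn)) / d
  Rxx <- Rxx + diag(ridge_x, d)
  Rnn <- Rnn + diag(ridge_n, d)
  L <- tryCatch(chol(Rnn), error = function(e) {
    stop("numerical error: background covariance is singular; increase ",
         "`shrinkage` or provide more background samples (", e$message, ")")
  })
  # whitened pencil: A = L^{-T} Rxx L^{-1} (L upper triangular, Rnn = L'L)
  Linv <- backsolve(L, diag(d))
  A <- crossprod(Linv, Rxx) %*% Linv
  A <- (A + t(A)) / 2
  ei <- eigen(A, symmetric = TRUE)
  keep <- ei$values > 1
  rank <- sum(keep)
  W <- matrix(0, d, d)
  Z <- matrix(0, d, 0L)
  if (rank > 0L) {
    Z <- Linv %*% ei$vectors[, keep, drop = FALSE]   # Z' Rnn Z = I
    W <- Z %*% ((1 - 1 / ei$values[keep]) * t(Z)) %*% Rnn
  }
  structure(list(weights = W, tau = emb$tau, gevd_rank = rank,
                 eigenvalues = ei$values, gevd_vectors = Z),
            class = "wiener_filter")
}

#' Apply a multi-channel Wiener filter to embedded EEG
#'
#' Returns `t(W) %*% x_tilde`: a set of spatiotemporally filtered output
#' signals in which IED-like waveforms are preserved and background EEG is
#' suppressed.
#'
#' @param filter a [wiener_filter()] (or plain weight matrix).
#' @param emb an [embedded_eeg()] (or plain embedded signal matrix).
#' @return filtered signal matrix, `n_out` x samples.
#' @export
apply_mwf <- function(filter, emb) {
  W <- if (inherits(filter, "wiener_filter")) filter$weights else
    as.matrix(filter)
  E <- if (inherits(emb, "embedded_eeg")) emb$signals else as.matrix(emb)
  if (nrow(W) != nrow(E)) {
    stop("dimension mismatch: filter has ", nrow(W),
         " input rows but embedded signal has ", nrow(E))
  }
  crossprod(W, E)
}

#' Broadband power envelope per fMRI volume
#'
#' Sums the mean squared amplitude of all (filtered) channels within each
#' nonoverlapping window of one repetition time, yielding the per-TR
#' reference vector used to identify the IED-related component of the
#' factorization. All filtered output channels contribute (summed in
#' quadrature); windows are aligned to the start of the recording, i.e. to
#' the first fMRI volume's acquisition start.
#'
#' @param x channels x samples signal matrix (filtered EEG).
#' @param fs sampling rate in Hz.
#' @param tr window length in seconds (the fMRI TR).
#' @return numeric vector of length `floor(samples / (fs * tr))`.
#' @export
broadband_envelope <- function(x, fs, tr) {
  x <- as.matrix(x)
  spw <- round(fs * tr)
  n_win <- floor(ncol(x) / spw)
  if (n_win < 1L) stop("recording shorter than one TR window")
  vapply(seq_len(n_win), function(i) {
    seg <- x[, ((i - 1L) * spw + 1L):(i * spw), drop = FALSE]
    sum(rowMeans(seg^2))
  }, numeric(1))
}

#' Full EEG enhancement step
#'
#' Convenience wrapper: delay-embed, estimate the Wiener filter on the
#' annotation mask, filter, and compute the broadband envelope.
#'
#' @param rec an [eeg_recording()] with a nontrivial `ied_mask`.
#' @param tau embedding lag count (default 4).
#' @param shrinkage covariance shrinkage, see [estimate_mwf()].
#' @return list with `filtered` (n_out x samples), `filter`, `envelope`
#'   (per-TR reference vector), `emb`.
#' @export
enhance_eeg <- function(rec, tau = 4, shrinkage = 1e-6) {
  emb <- delay_embed(rec, tau)
  filt <- estimate_mwf(emb, shrinkage = shrinkage)
  out <- apply_mwf(filt, emb)
  env <- broadband_envelope(out, rec$fs, rec$tr)
  list(filtered = out, filter = filt, envelope = env, emb = emb)
}
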