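#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the DPSS sequences; the `k` tapers with the largest
#' eigenvalues are returned, each normalized to unit energy.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (at most `2*nw - 1` is sensible).
#' @return n x k matrix of tapers.
#' @keywords internal
dpss_tapers <- function(n, nw = 3.5, k = 6) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  w <- nw / n
  t0 <- seq_len(n) - 1
  d <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  e <- (t0 * (n - t0) / 2)[-1]
  Tm <- diag(d)
  Tm[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- e
  Tm[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- e
  ei <- eigen(Tm, symmetric = TRUE)
  V <- ei$vectors[, seq_len(k), drop = FALSE]
  # conventional polarity: each taper's mean (odd) / first lobe positive
  for (j in seq_len(k)) if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  sweep(V, 2, sqrt(colSums(V^2)), "/")
}

# small cache so repeated TR segments reuse the eigendecomposition
.dpss_cache <- new.env(parent = emptyenv())
dpss_cached <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (is.null(.dpss_cache[[key]])) .dpss_cache[[key]] <- dpss_tapers(n, nw, k)
  .dpss_cache[[key]]
}

#' Multitaper spectrogram tensor of multichannel EEG
#'
#' Thomson multitaper power estimates on nonoverlapping segments of one
#' repetition time, with squared Fourier magnitudes averaged into 1-Hz bins
#' from `fmin` to `fmax` Hz, yielding the time points x frequencies x
#' channels tensor that is synchronized 1:1 with the fMRI volumes.
#'
#' @param x channels x samples numeric matrix (enhanced EEG).
#' @param fs sampling rate (Hz).
#' @param tr segment length in seconds (the fMRI TR).
#' @param fmin,fmax frequency band edges in Hz (default 1 to 40; bin `g`
#'   collects frequencies in `[g - 0.5, g + 0.5)`).
#' @param nw multitaper time-bandwidth product (default 3.5).
#' @param k number of tapers (default 6).
#' @param n_volumes optional cap on the number of segments (to match a
#'   known fMRI volume count).
#' @return object of class `spectrogram_tensor` with `values`
#'   (Is x Ig x Im), `freqs`, `tr`, `channel_labels`.
#' @export
multitaper_spectrogram <- function(x, fs, tr, fmin = 1, fmax = 40, nw = 3.5,
                                   k = 6, n_volumes = NULL) {
  x <- as.matrix(x)
  if (fs / 2 <= fmax) {
    stop("invalid parameter: fmax = ", fmax,
         " Hz requires a sampling rate above ", 2 * fmax, " Hz")
  }
  spw <- round(fs * tr)
  if (fs / spw > 1 + 1e-9) {
    warning("segment length resolves only ", signif(fs / spw, 3),
            " Hz; 1 Hz bins will be coarse")
  }
  Is <- floor(ncol(x) / spw)
  if (!is.null(n_volumes)) Is <- min(Is, n_volumes)
  stopifnot(Is >= 1)
  im <- nrow(x)
  freqs <- seq(fmin, fmax)
  fgrid <- (seq_len(spw) - 1) * fs / spw
  bin_of <- findInterval(fgrid, freqs - 0.5)
  bin_of[fgrid >= fmax + 0.5 | fgrid < fmin - 0.5] <- 0L
  tapers <- dpss_cached(spw, nw, min(k, spw))
  X <- array(0, c(Is, length(freqs), im))
  for (m in seq_len(im)) {
    seg <- matrix(x[m, seq_len(Is * spw)], spw, Is)
    psd <- matrix(0, spw, Is)
    for (j in seq_len(ncol(tapers))) {
      psd <- psd + abs(stats::mvfft(seg * tapers[, j]))^2
    }
    psd <- psd / ncol(tapers)
    for (g in seq_along(freqs)) {
      sel <- which(bin_of == g)
      if (length(sel)) X[, g, m] <- colMeans(psd[sel, , drop = FALSE])
    }
  }
  structure(list(values = X, freqs = freqs, tr = tr,
                 channel_labels = rownames(x)),
            class = "spectrogram_tensor")
}

#' Normalize a spectrogram tensor
#'
#' Equalizes the influence of each channel and each frequency and focuses
#' the decomposition on relative power increases/decreases: each
#' (frequency, channel) fiber is log-transformed (only when all its values
#' are positive, i.e. raw power; already-normalized input is left on its
#' scale, which makes the operation idempotent) and z-scored along time.
#' Constant fibers are set to zero with a warning.
#'
#' @param x a `spectrogram_tensor` (or plain Is x Ig x Im array).
#' @param log apply the log transform to positive power values
#'   (default `TRUE`); set `FALSE` for plain fiber z-scoring.
#' @return normalized object of the same class.
#' @export
normalize_spectrogram <- function(x, log = TRUE) {
  obj <- if (inherits(x, "spectrogram_tensor")) x else
    structure(list(values = x, freqs = NULL, tr = NULL,
                   channel_labels = NULL), class = "spectrogram_tensor")
  V <- obj$values
  d <- dim(V)
  if (log && all(V > 0)) V <- base::log(V)
  Vm <- matrix(V, d[1L], d[2L] * d[3L])
  mu <- colMeans(Vm)
  sdv <- apply(Vm, 2, stats::sd)
  const <- sdv < 1e-12
  if (any(const)) {
    warning(sum(const), " constant (frequency, channel) fiber(s) set to zero")
    sdv[const] <- 1
  }
  Vm <- sweep(sweep(Vm, 2, mu, "-"), 2, sdv, "/")
  Vm[, const] <- 0
  obj$values <- array(Vm, d)
  obj
}

#' Regress confounds out of BOLD time series
#'
#' Removes motion parameters (plus their squares and first derivatives),
#' boxcar scrubbing regressors at volumes with scan-to-scan translation
#' above `scrub_threshold` mm, and the leading principal components of
#' noise-region (CSF/white-matter) time series, via least-squares
#' projection. Collinear design columns are dropped with a warning.
#'
#' @param series time x variables numeric matrix (or vector).
#' @param motion optional time x 6 motion parameter matrix (first three
#'   columns treated as translations in mm for scrubbing).
#' @param noise_series optional time x voxels matrix of CSF/WM signals from
#'   which `n_compcor` principal components are extracted.
#' @param confounds optional extra regressors (time x q matrix).
#' @param scrub_threshold scan-to-scan displacement threshold in mm
#'   (default 1).
#' @param n_compcor number of noise principal components (default 5).
#' @return residual series (same shape as `series`), mean-centered; the
#'   design matrix is attached as attribute `"design"`.
#' @export
regress_confounds <- function(series, motion = NULL, noise_series = NULL,
                              confounds = NULL, scrub_threshold = 1,
                              n_compcor = 5) {
  y <- as.matrix(series)
  n <- nrow(y)
  D <- matrix(1, n, 1)
  colnames(D) <- "intercept"
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n)
    dmotion <- rbind(0, diff(motion))
    blk <- cbind(motion, motion^2, dmotion)
    colnames(blk) <- c(paste0("mot", seq_len(ncol(motion))),
                       paste0("mot", seq_len(ncol(motion)), "_sq"),
                       paste0("mot", seq_len(ncol(motion)), "_d"))
    D <- cbind(D, blk)
    ntr <- min(3L, ncol(motion))
    fd <- rowSums(abs(rbind(0, diff(motion[, seq_len(ntr), drop = FALSE]))))
    flag <- which(fd > scrub_threshold)
    if (length(flag)) {
      scrub <- matrix(0, n, length(flag))
      scrub[cbind(flag, seq_along(flag))] <- 1
      colnames(scrub) <- paste0("scrub", flag)
      D <- cbind(D, scrub)
    }
  }
  if (!is.null(noise_series) && n_compcor > 0) {
    ns <- scale(as.matrix(noise_series), scale = FALSE)
    stopifnot(nrow(ns) == n)
    p <- min(n_compcor, ncol(ns), n - 1L)
    pcs <- stats::prcomp(ns, center = FALSE)$x[, seq_len(p), drop = FALSE]
    colnames(pcs) <- paste0("compcor", seq_len(p))
    D <- cbind(D, pcs)
  }
  if (!is.null(confounds)) {
    cf <- as.matrix(confounds)
    stopifnot(nrow(cf) == n)
    if (is.null(colnames(cf))) colnames(cf) <- paste0("conf", seq_len(ncol(cf)))
    D <- cbind(D, cf)
  }
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_idx <- qrD$pivot[(qrD$rank + 1L):ncol(D)]
    warning("dropping ", length(drop_idx), " collinear confound column(s): ",
            paste(colnames(D)[drop_idx], collapse = ", "))
    D <- D[, -drop_idx, drop = FALSE]
    qrD <- qr(D)
  }
  res <- y - D %*% qr.coef(qrD, y)
  if (!is.matrix(series)) res <- res[, 1L]
  attr(res, "design") <- D
  res
}

#' Zero-phase band-pass filtering of BOLD time series
#'
#' Fourth-order Butterworth band-pass, applied forward and backward
#' (zero phase) to each column.
#'
#' @param series time x variables matrix (or vector).
#' @param tr sampling interval in seconds.
#' @param low,high band edges in Hz (defaults 0.008 and 0.20).
#' @param order filter order (default 4).
#' @return filtered series with the same shape.
#' @export
bandpass_bold <- function(series, tr, low = 0.008, high = 0.20, order = 4) {
  nyq <- 1 / (2 * tr)
  if (!(low > 0 && low < high && high < nyq)) {
    stop("invalid parameter: need 0 < low < high < Nyquist = ",
         signif(nyq, 4), " Hz")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  y <- as.matrix(series)
  # demean first: the DC component is outside the band anyway, and removing
  # it before filtering avoids slow edge transients of the zero-phase pass
  y <- sweep(y, 2, colMeans(y), "-")
  out <- apply(y, 2, function(col) signal::filtfilt(bf, col))
  if (!is.matrix(series)) out <- out[, 1L]
  out
}

#' Parcellate 4-D BOLD data into an ROI time-series matrix
#'
#' Averages the time series of all voxels sharing an atlas label, then
#' z-scores each ROI column (mean 0, unit standard deviation). Labels with
#' no voxels are dropped with a warning; the retained-label index map is
#' kept so maps can later be re-expanded to the full atlas.
#'
#' @param bold 4-D array (x, y, z, time) or a voxels x time matrix.
#' @param atlas integer labeling: 3-D array matching the BOLD grid, or a
#'   per-voxel label vector when `bold` is a matrix. Label 0 = background.
#' @param tr repetition time in seconds.
#' @param labels optional label set to extract (default: all positive
#'   labels present in `atlas`).
#' @return object of class `bold_matrix` with `values` (time x ROI,
#'   z-scored), `roi_ids`, `dropped`, `tr`.
#' @export
parcellate <- function(bold, atlas, tr = 2.2, labels = NULL) {
  if (is.array(bold) && length(dim(bold)) == 4L) {
    d <- dim(bold)
    stopifnot(all(dim(atlas) == d[1:3]))
    bold <- matrix(bold, prod(d[1:3]), d[4L])
    atlas <- as.integer(atlas)
  } else {
    bold <- as.matrix(bold)
    atlas <- as.integer(atlas)
    stopifnot(length(atlas) == nrow(bold))
  }
  if (is.null(labels)) labels <- sort(unique(atlas[atlas > 0]))
  if (!length(labels)) stop("invalid input: no atlas labels overlap the data")
  counts <- vapply(labels, function(l) sum(atlas == l), integer(1))
  dropped <- labels[counts == 0L]
  if (length(dropped)) {
    warning("dropping ", length(dropped), " empty parcel(s): ",
            paste(dropped, collapse = ", "))
  }
  keep <- labels[counts > 0L]
  if (!length(keep)) stop("invalid input: no atlas labels overlap the data")
  Y <- vapply(keep, function(l) {
    colMeans(bold[atlas == l, , drop = FALSE])
  }, numeric(ncol(bold)))
  structure(list(values = zscore_cols(Y), roi_ids = keep, dropped = dropped,
                 tr = tr),
            class = "bold_matrix")
}

#' Wrap a precomputed time x ROI matrix as a `bold_matrix`
#'
#' @param values time x ROI numeric matrix (z-scored per column unless
#'   `zscore = FALSE` is already satisfied; z-scoring is always applied).
#' @param tr repetition time in seconds.
#' @param roi_ids optional parcel identifiers.
#' @export
bold_matrix <- function(values, tr = 2.2, roi_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(roi_ids)) roi_ids <- seq_len(ncol(values))
  structure(list(values = zscore_cols(values), roi_ids = roi_ids,
                 dropped = integer(0), tr = tr),
            class = "bold_matrix")
}
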