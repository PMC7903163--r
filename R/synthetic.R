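#' Generate a synthetic EEG-fMRI dataset with known ground truth
#'
#' Builds a dataset that follows the generative model of the structured
#' coupled factorization exactly before noise: a rank-R spectrogram tensor
#' `X = [[S0, G0, M0]] + noise`, a BOLD matrix
#' `Y = sum_{r,k} (H_k s_r) o (b_k * v_r) + N P' + noise`, plus a raw
#' multichannel EEG realization with template spikes at the interictal
#' discharge times for end-to-end testing of the Wiener-filter enhancement.
#'
#' One source (the first) is an "IED" source: its temporal signature is a
#' smoothed Poisson spike train, its spectral signature is dominated by low
#' frequencies and its EEG topography is focal. A configurable fraction of
#' ROIs forms the epileptogenic "zone": these regions load strongly on the
#' IED source and receive a deviant HRF (by default an acausal one whose
#' main peak precedes the EEG correlate by about 5 s), while background
#' regions get a canonical causal HRF.
#'
#' @param Is,Iv,Ig,Im sizes: time points, ROIs, frequency bins, channels
#'   (defaults 270, 50, 20, 16: a ten-minute session at TR 2.2 s).
#' @param R,K,Q numbers of sources, HRF basis functions and nuisance
#'   components (defaults 2, 2, 1).
#' @param snr_eeg,snr_fmri additive-noise SNR in dB for tensor and matrix
#'   (defaults 10 and 10).
#' @param tr repetition time in seconds (default 2.2).
#' @param fs raw-EEG sampling rate in Hz (default 200).
#' @param spike_rate IED rate per minute (default 2).
#' @param spike_duration template spike duration in seconds (default 0.3).
#' @param spike_amplitude template amplitude relative to the unit-variance
#'   EEG background (default 4: annotated interictal discharges are
#'   prominent transients, clearly visible above the ongoing EEG).
#' @param zone_fraction fraction of ROIs in the epileptogenic zone
#'   (default 0.1).
#' @param deviant_theta five-parameter set of the deviant (zone) HRF basis
#'   function; the default peaks at lag -5 s (acausal).
#' @param nuisance_scale Frobenius norm of `N P'` relative to the coupled
#'   signal (default 0.5).
#' @param t_pre,t_post HRF lag-grid support in seconds.
#' @param seed integer seed; the same seed reproduces the dataset bit for
#'   bit.
#' @return list of class `scmtf_synth` with `X` (`spectrogram_tensor`),
#'   `Y` (`bold_matrix`, columns near unit variance, not re-z-scored so the
#'   generative identity holds exactly), `eeg` (an [eeg_recording()] with
#'   IED annotations), and `truth` (factors `S0, G0, M0, V0, B0`, basis
#'   parameters `theta0`, `N0, P0`, `spike_train`, `zone_mask`, `grid`,
#'   SNRs, seed).
#' @export
generate_dataset <- function(Is = 270, Iv = 50, Ig = 20, Im = 16, R = 2,
                             K = 2, Q = 1, snr_eeg = 10, snr_fmri = 10,
                             tr = 2.2, fs = 200, spike_rate = 2,
                             spike_duration = 0.3, spike_amplitude = 4,
                             zone_fraction = 0.1,
                             deviant_theta = c(6, 1, 16, 1, 0.2),
                             nuisance_scale = 0.5, t_pre = 10, t_post = 22,
                             seed = 1) {
  stopifnot(Is >= 8, Iv >= 4, Ig >= 2, Im >= 2, R >= 1, K >= 1, Q >= 0)
  set.seed(seed)
  grid <- lag_grid(t_pre, t_post, tr)

  # --- temporal signatures ---------------------------------------------------
  rate_per_tr <- spike_rate / 60 * tr
  spike_train <- stats::rpois(Is, rate_per_tr)
  smooth3 <- function(x) {
    v <- as.numeric(stats::filter(x, c(0.25, 0.5, 0.25), sides = 2L))
    v[is.na(v)] <- x[is.na(v)]
    v
  }
  s_ied <- smooth3(spike_train)
  s_ied <- (s_ied - mean(s_ied)) / max(stats::sd(s_ied), 1e-12)
  S0 <- matrix(0, Is, R)
  S0[, 1L] <- s_ied
  if (R > 1L) {
    for (r in 2:R) {
      ar <- as.numeric(stats::arima.sim(list(ar = 0.7), Is))
      S0[, r] <- (ar - mean(ar)) / stats::sd(ar)
    }
  }

  # --- spectral signatures ---------------------------------------------------
  f <- seq_len(Ig)
  G0 <- matrix(0, Ig, R)
  G0[, 1L] <- exp(-0.35 * f)                     # low-frequency dominant
  if (R > 1L) {
    for (r in 2:R) {
      ctr <- stats::runif(1, 0.4 * Ig, 0.8 * Ig) # e.g. alpha-band bump
      G0[, r] <- exp(-(f - ctr)^2 / (2 * (0.12 * Ig)^2)) + 0.05
    }
  }
  G0 <- sweep(G0, 2, sqrt(colSums(G0^2)), "/")

  # --- EEG topographies ------------------------------------------------------
  M0 <- matrix(0, Im, R)
  focal <- stats::rgeom(1, 0.5) %% Im + 1L
  M0[, 1L] <- exp(-abs(seq_len(Im) - focal) / 1.5)   # focal
  if (R > 1L) {
    for (r in 2:R) {
      raw <- stats::rnorm(Im)
      M0[, r] <- abs(as.numeric(stats::filter(raw, rep(1 / 3, 3),
                                              sides = 2L, circular = TRUE))) + 0.3
    }
  }
  M0 <- sweep(M0, 2, sqrt(colSums(M0^2)), "/")

  # --- zone, HRFs and fMRI spatial loadings ---------------------------------
  n_zone <- max(1L, round(zone_fraction * Iv))
  zone_idx <- sample.int(Iv, n_zone)
  zone_mask <- seq_len(Iv) %in% zone_idx
  theta_canonical <- default_hrf_params(1L, t_pre)[[1L]]
  theta0 <- c(list(theta_canonical),
              rep(list(deviant_theta), max(K - 1L, 0L)))[seq_len(K)]
  basis0 <- hrf_basis(theta0, grid)
  B0 <- matrix(0, Iv, K)
  B0[, 1L] <- 1 + 0.05 * stats::rnorm(Iv)
  if (K > 1L) {
    B0[zone_idx, 1L] <- 0.05 * stats::rnorm(n_zone)
    B0[zone_idx, 2L] <- 1 + 0.05 * stats::rnorm(n_zone)
  }
  V0 <- matrix(0.4 * stats::rnorm(Iv * R), Iv, R)
  V0[zone_idx, 1L] <- 2 + 0.3 * abs(stats::rnorm(n_zone))

  # --- assemble modalities ---------------------------------------------------
  X_clean <- cpd_compose(S0, G0, M0)
  sig_x <- sqrt(mean(X_clean^2))
  noise_x <- array(stats::rnorm(length(X_clean)), dim(X_clean)) *
    sig_x / 10^(snr_eeg / 20)
  X <- structure(list(values = X_clean + noise_x, freqs = f, tr = tr,
                      channel_labels = paste0("ch", seq_len(Im))),
                 class = "spectrogram_tensor")

  ops <- basis_ops(basis0, Is)
  Y_coupled <- coupled_predict(S0, V0, B0, ops)
  attr(Y_coupled, "CkS") <- NULL
  if (Q > 0L) {
    N0 <- matrix(0, Is, Q); P0 <- matrix(stats::rnorm(Iv * Q), Iv, Q)
    for (q in seq_len(Q)) {
      ar <- as.numeric(stats::arima.sim(list(ar = 0.9), Is))
      N0[, q] <- (ar - mean(ar)) / stats::sd(ar)
    }
    NP <- tcrossprod(N0, P0)
    NP <- NP * nuisance_scale * norm2(Y_coupled) / max(norm2(NP), 1e-12)
    # fold the rescaling into P0 so truth reproduces the data exactly
    P0 <- P0 * nuisance_scale * norm2(Y_coupled) /
      max(norm2(tcrossprod(N0, P0)), 1e-12)
  } else {
    N0 <- matrix(0, Is, 0L); P0 <- matrix(0, Iv, 0L)
  }
  sig_y <- sqrt(mean(Y_coupled^2))
  noise_y <- matrix(stats::rnorm(Is * Iv), Is, Iv) * sig_y / 10^(snr_fmri / 20)
  Yv <- Y_coupled + tcrossprod(N0, P0) + noise_y
  Y <- structure(list(values = Yv, roi_ids = seq_len(Iv),
                      dropped = integer(0), tr = tr),
                 class = "bold_matrix")

  # --- raw EEG with template spikes -----------------------------------------
  spw <- round(fs * tr)
  n_samp <- Is * spw
  bg <- matrix(0, Im, n_samp)
  for (m in seq_len(Im)) {
    ar <- as.numeric(stats::arima.sim(list(ar = 0.95), n_samp))
    bg[m, ] <- ar / stats::sd(ar)
  }
  n_spike <- round(spike_duration * fs)
  tt <- seq_len(n_spike) / n_spike
  template <- sin(2 * pi * tt) * sin(pi * tt)^2      # biphasic, windowed
  topo <- M0[, 1L] / max(M0[, 1L])
  ied_mask <- rep(FALSE, n_samp)
  eeg <- bg
  for (i in which(spike_train > 0)) {
    for (s in seq_len(spike_train[i])) {
      at <- (i - 1L) * spw + sample.int(max(spw - n_spike, 1L), 1L)
      idx <- at:(at + n_spike - 1L)
      idx <- idx[idx <= n_samp]
      eeg[, idx] <- eeg[, idx] +
        spike_amplitude * outer(topo, template[seq_along(idx)])
      ied_mask[idx] <- TRUE
    }
  }
  rec <- eeg_recording(eeg, fs = fs, ied_mask = ied_mask, tr = tr,
                       standardize = TRUE)

  structure(list(
    X = X, Y = Y, eeg = rec,
    truth = list(S0 = S0, G0 = G0, M0 = M0, V0 = V0, B0 = B0,
                 theta0 = theta0, basis0 = basis0, N0 = N0, P0 = P0,
                 spike_train = spike_train, zone_mask = zone_mask,
                 grid = grid, snr_eeg = snr_eeg, snr_fmri = snr_fmri,
                 seed = seed)),
    class = "scmtf_synth")
}
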