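# Independent oracles used across the suite. These deliberately use naive
# double loops / direct index arithmetic, not the package's vectorized code.

# full discrete convolution advanced by `offset` samples, truncated to
# length(s): out[u] = sum_j kernel[j] * s[u - j + 1 + offset]
brute_conv <- function(kernel, offset, s) {
  n <- length(s)
  out <- numeric(n)
  for (u in seq_len(n)) {
    acc <- 0
    for (j in seq_along(kernel)) {
      ti <- u - j + 1L + offset
      if (ti >= 1L && ti <= n) acc <- acc + kernel[j] * s[ti]
    }
    out[u] <- acc
  }
  out
}

# termwise coupled fMRI model: sum_r sum_k (H_k s_r) o (b_k * v_r) + N P'
brute_coupled <- function(S, V, B, basisW, n_pre, N = NULL, P = NULL) {
  Is <- nrow(S); Iv <- nrow(V); R <- ncol(S); K <- ncol(B)
  Y <- matrix(0, Is, Iv)
  for (r in seq_len(R)) {
    for (k in seq_len(K)) {
      hs <- brute_conv(basisW[k, ], n_pre, S[, r])
      for (iv in seq_len(Iv)) {
        Y[, iv] <- Y[, iv] + hs * (B[iv, k] * V[iv, r])
      }
    }
  }
  if (!is.null(N) && ncol(N) > 0) {
    for (q in seq_len(ncol(N))) {
      Y <- Y + outer(N[, q], P[, q])
    }
  }
  Y
}

# multichannel EEG with planted template spikes at a given power SNR (dB)
# relative to the unit-variance white background, inside the spike windows
make_spike_eeg <- function(snr_db, n_spikes = 50, im = 8, fs = 200,
                           tr = 2.2, n = 20000, seed = 1) {
  set.seed(seed)
  bg <- matrix(stats::rnorm(im * n), im, n)
  topo <- exp(-abs(seq_len(im) - 3) / 1.2)
  topo <- topo / sqrt(mean(topo^2))
  len <- 60L
  tt <- seq(0, 1, length.out = len)
  tmpl <- sin(2 * pi * tt) * sin(pi * tt)^2
  tmpl <- tmpl / sqrt(mean(tmpl^2))
  amp <- sqrt(10^(snr_db / 10))
  mask <- rep(FALSE, n)
  eeg <- bg
  at_all <- sort(sample(seq(100L, n - 100L), n_spikes))
  for (at in at_all) {
    idx <- at:(at + len - 1L)
    eeg[, idx] <- eeg[, idx] + amp * outer(topo, tmpl)
    mask[idx] <- TRUE
  }
  list(rec = eeg_recording(eeg, fs, mask, tr = tr, standardize = FALSE),
       spike_samples = at_all, mask = mask)
}

# spike power / background power across channels, given a sample mask
mask_snr <- function(x, mask) mean(x[, mask]^2) / mean(x[, !mask]^2)

# minimal solution object for inference-level tests
make_toy_solution <- function(S, V, B, basis, N = NULL, P = NULL) {
  Is <- nrow(S); Iv <- nrow(V)
  if (is.null(N)) N <- matrix(0, Is, 0L)
  if (is.null(P)) P <- matrix(0, Iv, 0L)
  structure(list(S = S, G = matrix(1, 2, ncol(S)), M = matrix(1, 2, ncol(S)),
                 V = V, B = B, basis = basis, N = N, P = P,
                 lambda_x = rep(1, ncol(S)), lambda_y = rep(1, ncol(S)),
                 cost = NA_real_, converged = TRUE, config = NULL,
                 relerr_x = NA_real_, relerr_y = NA_real_,
                 calibrated = FALSE, degenerate = FALSE),
            class = "scmtf_solution")
}

# impulse "HRF basis" (kernel = 1 at lag zero) for convolution-free designs
impulse_basis <- function() {
  structure(list(waveforms = matrix(1, 1, 1), params = list(),
                 grid = lag_grid(0, 0, 1), scale = 1),
            class = "hrf_basis")
}
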