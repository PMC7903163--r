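test_that("delay embedding stacks lags with the right dimensions", {
  # identity at tau = 0
  x <- matrix(rnorm(3 * 20), 3)
  rec <- eeg_recording(x, fs = 100, standardize = FALSE)
  emb0 <- delay_embed(rec, 0)
  expect_equal(emb0$signals, rec$signals)
  expect_true(all(emb0$valid))

  # row dimension Im * (2 tau + 1) across a grid of cases
  for (im in c(1, 2, 29)) {
    for (tau in c(0, 1, 4)) {
      xx <- matrix(rnorm(im * 60), im)
      emb <- delay_embed(xx, tau)
      expect_equal(nrow(emb$signals), im * (2 * tau + 1))
    }
  }
  expect_equal(nrow(delay_embed(matrix(rnorm(29 * 100), 29), 4)$signals), 261)

  # index-shift oracle for a small case
  sig <- rbind(c(1, 2, 3), c(4, 5, 6))
  emb <- delay_embed(sig, 1)
  # middle column t = 2 holds [x[1]; x[2]; x[3]]
  expect_equal(emb$signals[, 2], c(1, 4, 2, 5, 3, 6))
  expect_equal(emb$valid, c(FALSE, TRUE, FALSE))

  expect_error(delay_embed(matrix(rnorm(4), 2), 2), "invalid parameter")
})

test_that("Wiener filter matches the closed form on crafted covariances", {
  # signals whose class-wise second moments are exactly Rxx = diag(2, 1),
  # Rnn = I: W must be diag(1/2, 0) (only the first generalized eigenvalue
  # exceeds 1)
  n_cls <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  x_cls <- rbind(sqrt(2) * c(1, -1, 1, -1), c(1, 1, -1, -1))
  sig <- cbind(x_cls, n_cls)
  mask <- rep(c(TRUE, FALSE), each = 4)
  emb <- delay_embed(sig, 0)
  filt <- estimate_mwf(emb, mask, shrinkage = 0)
  expect_equal(filt$weights, diag(c(0.5, 0)), tolerance = 1e-10)
  expect_equal(filt$gevd_rank, 1L)
})

test_that("filter vanishes when both mask classes share one process", {
  set.seed(41)
  x <- matrix(rnorm(4 * 60000), 4)
  mask <- rep(c(TRUE, FALSE), length.out = ncol(x))
  filt <- estimate_mwf(delay_embed(x, 1), mask)
  expect_lt(norm(filt$weights, "F") / sqrt(nrow(filt$weights)), 0.1)
})

test_that("dominant GEVD direction aligns with a planted spike subspace", {
  sim <- make_spike_eeg(0, n_spikes = 50, seed = 7)
  emb <- delay_embed(sim$rec, 0)
  filt <- estimate_mwf(emb)
  # planted rank-1 spatial pattern (white background: Rnn ~ I, so the top
  # generalized eigenvector must align with the spike topography)
  topo <- exp(-abs(1:8 - 3) / 1.2)
  z1 <- filt$gevd_vectors[, 1]
  cos_sim <- abs(sum(z1 * topo)) / sqrt(sum(z1^2) * sum(topo^2))
  expect_gt(cos_sim, 0.95)
})

test_that("filter estimation is invariant to global rescaling", {
  sim <- make_spike_eeg(0, seed = 8)
  emb1 <- delay_embed(sim$rec, 2)
  rec2 <- sim$rec
  rec2$signals <- 7 * rec2$signals
  emb2 <- delay_embed(rec2, 2)
  f1 <- estimate_mwf(emb1)
  f2 <- estimate_mwf(emb2)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-10)
})

test_that("apply_mwf behaves like the linear map it is", {
  sim <- make_spike_eeg(0, seed = 9)
  emb <- delay_embed(sim$rec, 1)
  zero <- matrix(0, nrow(emb$signals), nrow(emb$signals))
  expect_true(all(apply_mwf(zero, emb) == 0))
  id <- diag(nrow(emb$signals))
  expect_equal(apply_mwf(id, emb), emb$signals)
  expect_error(apply_mwf(matrix(0, 3, 3), emb), "dimension mismatch")
})

test_that("filtering strictly increases the planted-spike SNR", {
  for (snr_db in c(-5, 0, 5)) {
    sim <- make_spike_eeg(snr_db, seed = 100 + snr_db)
    emb <- delay_embed(sim$rec, 4)
    filt <- estimate_mwf(emb)
    out <- apply_mwf(filt, emb)
    expect_gt(mask_snr(out, sim$mask), mask_snr(sim$rec$signals, sim$mask))
  }
})

test_that("broadband envelope measures per-TR power", {
  # constant unit signal
  expect_equal(broadband_envelope(matrix(1, 1, 1000), 100, 2),
               rep(1, 5))
  # single spike lands in the right window
  x <- matrix(0, 1, 1000)
  x[1, 520] <- 30
  expect_equal(which.max(broadband_envelope(x, 100, 1)), 6)
  # variance additivity over channels
  set.seed(10)
  x2 <- rbind(rnorm(200000), 2 * rnorm(200000))
  expect_equal(mean(broadband_envelope(x2, 100, 2)), 5, tolerance = 0.05)
})

test_that("envelope-to-spike-count correlation improves after filtering", {
  for (snr_db in c(-5, 0, 5)) {
    sim <- make_spike_eeg(snr_db, seed = 200 + snr_db)
    rec <- sim$rec
    spw <- round(rec$fs * rec$tr)
    n_win <- floor(ncol(rec$signals) / spw)
    counts <- tabulate(pmin((sim$spike_samples - 1) %/% spw + 1L, n_win),
                       nbins = n_win)
    enh <- enhance_eeg(rec, tau = 4)
    before <- cor(broadband_envelope(rec$signals, rec$fs, rec$tr), counts)
    after <- cor(enh$envelope, counts)
    expect_gt(after, before)
  }
})
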