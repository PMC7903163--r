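test_that("multitaper spectrogram localizes a pure tone and sizes bins", {
  fs <- 100; tr <- 2
  t <- seq_len(30 * fs) / fs
  x <- matrix(sin(2 * pi * 10 * t), 1)
  sp <- multitaper_spectrogram(x, fs, tr, fmin = 1, fmax = 40)
  expect_equal(dim(sp$values), c(15, 40, 1))
  pow <- colMeans(sp$values[, , 1])
  expect_gt(pow[10] / pow[20], 100)
  expect_equal(which.max(pow), 10)

  # zero signal -> all-zero tensor
  sp0 <- multitaper_spectrogram(matrix(0, 2, 1000), fs, tr)
  expect_true(all(sp0$values == 0))

  expect_error(multitaper_spectrogram(x, fs = 60, tr = tr, fmax = 40),
               "invalid parameter")
})

test_that("spectrogram normalization z-scores fibers and equalizes scale", {
  set.seed(11)
  V <- array(abs(rnorm(40 * 5 * 3)) + 0.5, c(40, 5, 3))
  nz <- normalize_spectrogram(V)
  Vm <- matrix(nz$values, 40, 15)
  expect_lt(max(abs(colMeans(Vm))), 1e-10)
  expect_lt(max(abs(apply(Vm, 2, sd) - 1)), 1e-10)

  # channels with a 10x power offset but identical dynamics coincide
  V2 <- V
  V2[, , 2] <- 10 * V[, , 1]
  nz2 <- normalize_spectrogram(V2)
  expect_equal(nz2$values[, , 2], nz2$values[, , 1], tolerance = 1e-10)

  # fiber (1, 2, 4) -> z-scores (-1, 0, 1) after the log
  V3 <- array(c(1, 2, 4), c(3, 1, 1))
  expect_equal(as.numeric(normalize_spectrogram(V3)$values), c(-1, 0, 1))

  # idempotence
  nz3 <- normalize_spectrogram(nz$values)
  expect_equal(nz3$values, nz$values, tolerance = 1e-8)

  expect_warning(normalize_spectrogram(array(1, c(4, 1, 1))), "constant")
})

test_that("confound regression projects out nuisance structure", {
  set.seed(12)
  n <- 500
  # realistic sub-millimetre motion so no scrubbing regressors are added
  motion <- matrix(0.1 * rnorm(n * 6), n)
  # a series equal to a confound column vanishes
  res <- regress_confounds(motion[, 1], motion = motion)
  expect_lt(max(abs(res)), 1e-8)
  # an orthogonal series is returned unchanged up to mean removal
  y <- rnorm(n)
  y_orth <- y - qr.fitted(qr(cbind(1, motion, motion^2,
                                   rbind(0, diff(motion)))), y)
  res2 <- regress_confounds(y_orth, motion = motion)
  expect_equal(as.numeric(res2), y_orth - mean(y_orth), tolerance = 1e-8)
  # planted signal recovered from signal + 0.7 * motion_1
  sig <- as.numeric(arima.sim(list(ar = 0.5), n))
  res3 <- regress_confounds(sig + 0.7 * motion[, 1], motion = motion)
  expect_gt(cor(res3, sig), 0.98)
  # and it equals the projection of the clean signal itself
  expect_gt(cor(res3, regress_confounds(sig, motion = motion)), 0.9999)
  # collinear columns dropped with a warning
  expect_warning(regress_confounds(y, confounds = cbind(motion[, 1],
                                                        motion[, 1])),
                 "collinear")
})

test_that("band-pass keeps the passband and kills stopband/DC", {
  tr <- 2.2
  n <- 600
  t <- (seq_len(n) - 1) * tr
  inband <- sin(2 * pi * 0.1 * t)
  out <- bandpass_bold(inband, tr)
  mid <- 100:500
  expect_equal(sd(out[mid]), sd(inband[mid]), tolerance = 0.05)
  stopb <- sin(2 * pi * 0.21 * t * 2)  # 0.42 Hz folds; use 0.21*2 > Nyquist guard
  highf <- sin(2 * pi * 0.215 * t)
  out2 <- bandpass_bold(highf, tr)
  expect_lt(sd(out2[mid]) * 10, sd(highf[mid]))
  # constant series -> DC removed
  expect_lt(max(abs(bandpass_bold(rep(5, n), tr))), 1e-6)
  expect_error(bandpass_bold(inband, tr, high = 0.3), "invalid parameter")
})

test_that("parcellation averages by label and z-scores columns", {
  set.seed(13)
  a <- as.numeric(arima.sim(list(ar = 0.6), 50))
  b <- rnorm(50)
  bold <- rbind(a, a, a, b, b)            # voxels x time
  atlas <- c(1L, 1L, 1L, 2L, 2L)
  bm <- parcellate(bold, atlas, tr = 2)
  expect_equal(bm$values[, 1], as.numeric(scale(a)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(bm$roi_ids, c(1L, 2L))
  expect_lt(max(abs(colMeans(bm$values))), 1e-12)

  # empty parcels are dropped and recorded
  expect_warning(bm2 <- parcellate(bold, atlas, labels = 1:3), "empty")
  expect_equal(bm2$dropped, 3L)

  # 4-D input with two runs concatenated in time
  arr1 <- array(rnorm(2 * 2 * 1 * 30), c(2, 2, 1, 30))
  arr2 <- array(rnorm(2 * 2 * 1 * 20), c(2, 2, 1, 20))
  atl <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))
  cc <- parcellate(array(c(arr1, arr2), c(2, 2, 1, 50)), atl)
  expect_equal(nrow(cc$values), 50)

  # averaging commutes with voxelwise linear mixing within a parcel
  w1 <- rnorm(50); w2 <- rnorm(50)
  mixed <- rbind(0.3 * w1 + 0.7 * w2, 0.7 * w1 + 0.3 * w2)
  direct <- parcellate(mixed, c(1L, 1L))
  averaged <- parcellate(rbind(0.5 * (w1 + w2)), 1L)
  expect_equal(direct$values[, 1], averaged$values[, 1], tolerance = 1e-10)

  expect_error(parcellate(bold, rep(0L, 5)), "invalid input")
})
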