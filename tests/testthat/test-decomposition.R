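test_that("whitener keeps the smallest PC count reaching the threshold", {
  # channels with variances ~ (100, 1, 1e-12): two PCs reach 99.99%
  withSeed(4, {
    base <- rbind(rnorm(5000, sd = 10), rnorm(5000, sd = 1))
    x <- rbind(base, 1e-6 * rnorm(5000))
  })
  wh <- fitWhitener(x, 0.9999)
  expect_equal(wh@nPc, 2L)
  # threshold 1 on full-rank data keeps everything
  full <- withSeed(5, matrix(rnorm(4 * 3000), 4))
  expect_equal(fitWhitener(full, 1.0)@nPc, 4L)
  # whitened training data has identity covariance
  z <- micica:::applyWhitener(fitWhitener(full), full)
  expect_lt(norm(cov(t(z)) - diag(nrow(z)), "F"), 1e-6)
})

test_that("FastICA recovers Laplacian sources through random mixings", {
  for (s in 1:3) {
    withSeed(s, {
      S <- matrix(rexp(3 * 4000) * sample(c(-1, 1), 12000, TRUE), 3)
      A <- matrix(rnorm(18), 6, 3)
    })
    ica <- fitIca(A %*% S, seed = s)
    expect_equal(nComponents(ica), 3L)
    rec <- getSources(ica, A %*% S)
    cc <- abs(cor(t(S), t(rec)))
    expect_true(all(apply(cc, 1, max) > 0.95))
  }
})

test_that("FastICA is deterministic given the seed and honest about output", {
  x <- withSeed(9, matrix(rexp(4 * 3000) * sample(c(-1, 1), 12000, TRUE), 4))
  a <- fitIca(x, seed = 42)
  b <- fitIca(x, seed = 42)
  expect_identical(a@unmixing, b@unmixing)
  # sources are unit-variance and decorrelated on training data
  s <- getSources(a, x)
  expect_equal(unname(apply(s, 1, var)), rep(1, 4), tolerance = 0.01)
  cc <- cor(t(s))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.02)
  # Gaussian-only data: no separation claim, but output stays decorrelated
  g <- withSeed(10, matrix(rnorm(3 * 3000), 3))
  icg <- suppressWarnings(fitIca(g, seed = 1))
  sg <- getSources(icg, g)
  ccg <- cor(t(sg))
  expect_lt(max(abs(ccg[upper.tri(ccg)])), 0.05)
})

test_that("component removal is a projection with the expected algebra", {
  ds <- cachedDataset("GN", 1)
  grads <- pickChannels(ds$meg, "grad")
  short <- new("Recording", data = grads@data[, 1:8000],
               channels = grads@channels, sfreq = 200)
  ica <- suppressWarnings(fitIca(short, seed = 1, maxIter = 200))
  # empty exclusion reproduces the PCA-truncated original
  same <- removeComponents(short, ica, integer(0))
  expect_equal(same@data, short@data, tolerance = 1e-6)
  # sequential removal composes like joint removal
  ab <- removeComponents(short, ica, c(2L, 5L))
  seq2 <- removeComponents(removeComponents(short, ica, 2L), ica, 5L)
  expect_equal(ab@data, seq2@data, tolerance = 1e-8)
  # removed component has (near) zero source time course afterwards
  s <- getSources(ica, removeComponents(short, ica, 3L))
  expect_lt(sd(s[3, ]), 1e-6)
  # what was removed lies entirely in the span of the excluded mixing columns
  resid <- short@data - ab@data
  excl <- ica@mixing[, c(2L, 5L)]
  q <- qr.Q(qr(excl))
  offspan <- resid - q %*% crossprod(q, resid)
  expect_lt(max(abs(offspan)), 1e-8 * max(abs(resid)))
  expect_error(removeComponents(short, ica, seq_len(nComponents(ica))),
               "every component")
  expect_error(removeComponents(short, ica, 999L), "1..")
})

test_that("EMG PCA is a variance-ordered, lossless rotation", {
  ds <- cachedDataset("GN", 1)
  emg <- pickChannels(ds$emg, "emg")
  pcs <- emgPca(emg, task = "vocal")
  expect_equal(nrow(pcs@components), 4)
  v <- apply(pcs@components, 1, var)
  expect_true(all(diff(v) <= 1e-12))
  cc <- cor(t(pcs@components))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # duplicate channels: PC1 carries everything
  x <- withSeed(2, rnorm(2000))
  dup <- new("Recording", data = rbind(x, x),
             channels = channelTable(c("EMG1", "EMG2"), "emg"), sfreq = 200)
  dpc <- suppressWarnings(emgPca(dup))
  expect_lt(var(dpc@components[2, ]) / var(dpc@components[1, ]), 1e-20)
  # pre-decorrelated inputs with distinct variances come back up to sign
  y <- withSeed(3, rbind(3 * rnorm(3000), rnorm(3000)))
  rec <- new("Recording", data = y,
             channels = channelTable(c("EMG1", "EMG2"), "emg"), sfreq = 200)
  pc2 <- emgPca(rec)
  expect_gt(abs(cor(pc2@components[1, ], y[1, ])), 0.999)
  expect_gt(abs(cor(pc2@components[2, ], y[2, ])), 0.999)
  expect_error(emgPca(pickChannels(ds$meg, "grad")), "EMG-only")
})

test_that("planted artefact topographies are recovered by the decomposition", {
  ds <- cachedDataset("GN", 1)
  res <- suppressWarnings(selectArtefacts(ds, "GN",
                                          params = list(maxMiSamples = 4000L)))
  m <- matchPlantedComponents(res$ica, ds$truth)
  expect_equal(nrow(m), 3)
  expect_true(all(m$cosine > 0.9))
})
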