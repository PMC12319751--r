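test_that("gradiometer pair combination is the per-pair RMS", {
  ch <- makeGradChannels(1)
  ev <- new("Evoked", data = rbind(3, 4), nave = 1L, tmin = 0, sfreq = 200,
            channels = ch)
  comb <- combineGradPairs(ev)
  expect_equal(nChannels(comb), 1)
  expect_equal(comb@data[1, 1], sqrt(25 / 2))
  # a pair of identical channels returns that amplitude
  x <- withSeed(1, rnorm(100))
  same <- new("Evoked", data = rbind(x, x), nave = 1L, tmin = 0, sfreq = 200,
              channels = ch)
  expect_equal(combineGradPairs(same)@data[1, ], abs(x))
  # random evoked equals the brute-force per-pair computation
  rnd <- new("Evoked", data = withSeed(2, matrix(rnorm(6 * 40), 6)),
             nave = 1L, tmin = 0, sfreq = 200, channels = makeGradChannels(3))
  got <- combineGradPairs(rnd)@data
  for (p in 1:3)
    expect_equal(got[p, ],
                 sqrt((rnd@data[2 * p - 1, ]^2 + rnd@data[2 * p, ]^2) / 2),
                 tolerance = 1e-12)
  # an unpaired gradiometer is an error
  bad <- makeGradChannels(1); bad$pair_id[2] <- 2L
  odd <- new("Evoked", data = rbind(1, 1), nave = 1L, tmin = 0, sfreq = 200,
             channels = bad)
  expect_error(combineGradPairs(odd), "two grad|unpaired|exactly two")
})

test_that("pair combination does not commute with averaging in general", {
  # sign-flipping epochs: average first (cancellation), combine after
  d <- array(0, c(2, 2, 10))
  d[1, , ] <- 1; d[2, , ] <- -1
  ep <- makeEpochs(2, 1, 10, data = d)
  combinedThenAveraged <- averageEpochs(combineGradPairs(ep))@data
  averagedThenCombined <- combineGradPairs(averageEpochs(ep))@data
  expect_equal(max(abs(averagedThenCombined)), 0)
  expect_equal(max(abs(combinedThenAveraged)), 1)
})

test_that("whole-head normalization scales the map to unit maximum", {
  ev <- new("Evoked", data = withSeed(3, abs(matrix(rnorm(3 * 30), 3))),
            nave = 1L, tmin = 0, sfreq = 200,
            channels = pairChannelTableForTest(3))
  nrm <- normalizeEvoked(ev)
  expect_equal(max(nrm@data), 1)
  expect_equal(normalizeEvoked(nrm)@data, nrm@data)
  scaled <- ev; scaled@data <- ev@data * 7
  expect_equal(normalizeEvoked(scaled)@data, nrm@data)
  zero <- ev; zero@data <- ev@data * 0
  expect_error(normalizeEvoked(zero), "all-zero")
})

test_that("RMSD map matches its formula and an independent oracle", {
  ch <- pairChannelTableForTest(4)
  mk <- function(d) new("Evoked", data = d, nave = 1L, tmin = 0, sfreq = 200,
                        channels = ch)
  base <- withSeed(4, abs(matrix(rnorm(4 * 300), 4)))
  a <- mk(base)
  expect_true(all(rmsdMap(a, a)@values == 0))
  # constant offset d on one pair gives exactly |d|
  shifted <- base; shifted[2, ] <- shifted[2, ] + 0.37
  rm1 <- rmsdMap(a, mk(shifted))
  expect_equal(unname(rm1@values[2]), 0.37, tolerance = 1e-12)
  expect_equal(unname(rm1@values[-2]), rep(0, 3))
  # brute-force oracle on random pairs
  b <- mk(withSeed(5, abs(matrix(rnorm(4 * 300), 4))))
  got <- rmsdMap(a, b, window = c(0, 1.5))@values
  for (chn in 1:4) {
    oracle <- 0
    for (i in 1:300) oracle <- oracle + (a@data[chn, i] - b@data[chn, i])^2
    expect_equal(unname(got[chn]), sqrt(oracle / 300), tolerance = 1e-12)
  }
  # symmetry and linear scaling of the difference
  expect_equal(rmsdMap(a, b)@values, rmsdMap(b, a)@values)
  mid <- mk((a@data + b@data) / 2)
  expect_equal(unname(rmsdMap(a, mid)@values), unname(got / 2),
               tolerance = 1e-12)
  bad <- mk(base[, 1:200])
  expect_error(rmsdMap(a, bad), "share")
})

test_that("per-epoch unit scaling is independent across epochs", {
  ep <- makeEpochs(3, 2, 20, seed = 6)
  sc <- scaleEpochsUnit(ep)
  for (i in 1:3) expect_equal(max(abs(sc@data[i, , ])), 1)
  doubled <- ep; doubled@data[2, , ] <- 2 * doubled@data[2, , ]
  expect_equal(scaleEpochsUnit(doubled)@data, sc@data)
  # brute force
  for (i in 1:3)
    expect_equal(sc@data[i, , ], ep@data[i, , ] / max(abs(ep@data[i, , ])))
  ep@data[1, , ] <- 0
  expect_warning(dropped <- scaleEpochsUnit(ep), "dropped")
  expect_equal(nEpochs(dropped), 2)
})

test_that("cluster permutation test finds planted effects and only those", {
  ch <- makeGradChannels(3)
  mkEp <- function(n, seed, shift = NULL) {
    d <- withSeed(seed, array(rnorm(n * 6 * 60), c(n, 6, 60)))
    if (!is.null(shift)) d[, shift$ch, shift$t] <- d[, shift$ch, shift$t] + shift$by
    new("EpochSet", data = d, tmin = 0, tmax = 0.3, sfreq = 200,
        channels = ch, eventRefs = seq_len(n), baseline = numeric(0))
  }
  # identical condition data: every cluster p is ~1
  same <- mkEp(12, 7)
  resSame <- clusterPermutationTest(same, same, nPerm = 100, seed = 1)
  if (length(resSame@pValues)) expect_true(all(resSame@pValues > 0.9))
  # planted amplitude offset on adjacent channels 1-4 (pairs 1-2), samples 20-40
  eff <- mkEp(12, 8, shift = list(ch = 1:4, t = 20:40, by = 2.5))
  resEff <- clusterPermutationTest(eff, mkEp(12, 9), nPerm = 200,
                                   alpha = 0.05, seed = 1)
  sig <- significantClusters(resEff)
  expect_gte(nrow(sig), 1)
  big <- sig[which.max(abs(sig$mass)), ]
  expect_gte(big$n_channels, 3)
  expect_lt(big$t_start, 0.12)
  expect_gt(big$t_end, 0.15)
  # paired design on matched epochs detects a consistent shift
  resPaired <- clusterPermutationTest(eff, same, nPerm = 200, paired = TRUE,
                                      seed = 2)
  expect_true(any(resPaired@pValues < 0.05))
  expect_error(clusterPermutationTest(same, same, nPerm = 0), "at least one")
  expect_error(clusterPermutationTest(same, same, adjacency = list(1:2)),
               "cover")
})

test_that("removal evaluation reproduces the vocal/silent asymmetry", {
  ds <- cachedDataset("GN", 1)
  sel <- suppressWarnings(selectArtefacts(ds, "GN",
                                          params = list(maxMiSamples = 4000L)))
  rep <- evaluateRemoval(ds, sel, params = list(nPerm = 300L,
                                                alphaSensor = 0.01))
  expect_true(rep$vocalSignificant)
  expect_false(rep$silentSignificant)
  # removed vocal evoked activity concentrates where the artefacts live
  expect_gt(max(rep$vocal$rmsd@values), 3 * max(rep$silent$rmsd@values))
  # zero-artefact data with an empty selection: vocal evoked is untouched
  nullDs <- generateDataset("null", seed = 3)
  nullSel <- suppressWarnings(selectArtefacts(nullDs, "GN",
                                              params = list(maxMiSamples = 4000L)))
  nullSel$selection@selectedIcs <- integer(0)
  nullSel$selection@labels <- rep(0L, length(nullSel$selection@labels))
  nullSel$selection@selectedCluster <- 0L
  repNull <- evaluateRemoval(nullDs, nullSel, params = list(nPerm = 50L))
  expect_lt(max(repNull$vocal$rmsd@values), 1e-6)
})
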