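test_that("gesture scheduler reproduces the printed design exactly", {
  ev <- scheduleGesture(gestureParadigmConfig(), seed = 7)
  expect_equal(nrow(ev), 250)                 # 5 sets x 10 gestures x 5 reps
  expect_equal(attr(ev, "run_durations_s"), 800)
  # each set spans exactly 160 s: onsets of set s lie in [(s-1), s) * 160 s
  for (s in 1:5) {
    on <- ev$onset_sample[ev$block == s] / 200
    expect_true(all(on >= (s - 1) * 160 & on < s * 160))
    expect_equal(max(on) - min(on), 160 - 3.2)
    # every gesture appears 5 times consecutively within the set
    labs <- ev$label[ev$block == s]
    expect_equal(as.vector(table(labs)), rep(5, 10))
    expect_equal(length(rle(labs)$lengths), 10)
  }
  # cue spacing is uniform to the sample
  expect_true(all(diff(ev$onset_sample) == 3.2 * 200))
  # minimal config: every gesture exactly once
  tiny <- scheduleGesture(gestureParadigmConfig(nSets = 1, repsPerGesture = 1),
                          seed = 1)
  expect_equal(nrow(tiny), 10)
  expect_setequal(tiny$label, paste0("G", 1:10))
})

test_that("gesture order is permuted per set, deterministically by seed", {
  a <- scheduleGesture(seed = 1)
  b <- scheduleGesture(seed = 1)
  c <- scheduleGesture(seed = 2)
  expect_identical(a, b)
  expect_false(identical(a$label, c$label))
})

test_that("naming scheduler delivers 110 pictures per task over 3 runs", {
  ev <- scheduleNaming(namingParadigmConfig(), seed = 1)
  counts <- table(ev$task)
  expect_equal(unname(counts[c("vocal", "silent", "observation")]),
               rep(110, 3), ignore_attr = TRUE)
  expect_equal(sort(unique(ev$run)), 1:3)
  # per task, the six blocks hold {18,18,18,18,19,19} pictures
  for (task in c("vocal", "silent", "observation")) {
    sizes <- table(paste(ev$run, ev$block)[ev$task == task])
    expect_equal(sort(as.vector(sizes)), c(18, 18, 18, 18, 19, 19))
  }
  # trial spacing: naming 4.0 s, observation 2.0 s
  voc <- ev[ev$task == "vocal" & ev$run == 1 & ev$block ==
              min(ev$block[ev$task == "vocal" & ev$run == 1]), ]
  expect_true(all(diff(voc$onset_sample) == 4 * 200))
  obs <- ev[ev$task == "observation" & ev$run == 1 & ev$block ==
              min(ev$block[ev$task == "observation" & ev$run == 1]), ]
  expect_true(all(diff(obs$onset_sample) == 2 * 200))
  expect_error(namingParadigmConfig(totalPerTask = 200L), "no assignment")
})

test_that("EMG simulation produces event-locked bursts with the gain matrix", {
  cfg <- deskScenarioConfig()
  ev <- scheduleGesture(cfg$gesture, seed = 2)
  n <- as.integer(attr(ev, "run_durations_s") * 200)
  # zero gains: pure baseline
  quiet <- simulateEmg(ev, n, gains = matrix(0, 4, 11,
                         dimnames = dimnames(defaultEmgGains())),
                       baseline = 0.05, seed = 2)
  expect_lt(max(abs(quiet@data)), 1)
  expect_equal(nChannels(quiet), 4)

  # naming: vocal responses burst, silent responses stay at baseline
  nev <- scheduleNaming(cfg$naming, seed = 2)
  nev <- nev[nev$run == 1, ]
  nn <- as.integer(attr(scheduleNaming(cfg$naming, 2), "run_durations_s")[1] * 200)
  emg <- simulateEmg(nev, nn, seed = 2)
  rms <- function(task) {
    mask <- taskSampleMask(nev, task, nn, 200)
    sqrt(mean(emg@data[, mask]^2))
  }
  expect_gt(rms("vocal") / rms("silent"), 5)

  # G2 (broad smile) drives the zygomaticus channel (EMG3) over the chin (EMG4)
  gemg <- simulateEmg(ev, n, seed = 2)
  g2 <- taskSampleMask(ev[ev$label == "G2", ], "gesture", n, 200)
  rmsCh <- function(c) sqrt(mean(gemg@data[c, g2]^2))
  expect_gt(rmsCh(3) / rmsCh(4), 2)
})

test_that("dataset generation is deterministic and exactly linear", {
  a <- generateDataset("GN", seed = 11)
  b <- generateDataset("GN", seed = 11)
  expect_identical(a$meg@data, b$meg@data)
  expect_identical(a$emg@data, b$emg@data)
  expect_identical(a$events, b$events)
  # the residual after subtracting the planted factors is the sensor noise:
  # white, source-free, with the configured scale
  res <- a$meg@data -
    a$truth@artefactTopographies %*% a$truth@artefactSources -
    a$truth@neuralTopographies %*% a$truth@neuralSources
  expect_equal(sd(as.vector(res)), a$config$noiseGain, tolerance = 0.02)
  cc <- abs(cor(t(res[1:5, ])))
  expect_lt(max(cc[upper.tri(cc)]), 0.05)
  expect_error(generateDataset("bogus", 1))
})

test_that("vocal responses carry high-frequency frontotemporal power", {
  ds <- cachedDataset("GN", 1)
  n <- nSamples(ds$meg)
  # left/right frontotemporal channels = extreme layout positions
  ft <- which(abs(ds$meg@channels$pos_x) == 2)
  bandPower <- function(mask) {
    x <- ds$meg@data[ft, mask, drop = FALSE]
    b <- as.numeric(signal::fir1(64, c(60, 95) / 100, type = "pass"))
    p <- apply(x, 1, function(r) mean(signal::filter(b, 1, r)^2))
    mean(p)
  }
  vocal <- bandPower(taskSampleMask(ds$events, "vocal", n, 200))
  silent <- bandPower(taskSampleMask(ds$events, "silent", n, 200))
  expect_gt(vocal / silent, 3)
})

test_that("GN and N scenarios have the expected timeline proportions", {
  gn <- cachedDataset("GN", 1)
  nOnly <- cachedDataset("N", 1)
  expect_gt(nSamples(gn$meg), nSamples(nOnly$meg))
  expect_true(any(gn$events$task == "gesture"))
  expect_false(any(nOnly$events$task == "gesture"))
  # gesture run prepends the naming runs
  expect_equal(length(gn$meg@runStarts), 1 + length(nOnly$meg@runStarts))
})

test_that("planted MI margin: artefact sources beat neural sources", {
  ds <- cachedDataset("GN", 1)
  n <- nSamples(ds$meg)
  mask <- taskSampleMask(ds$events, "vocal", n, 200)
  w <- which(mask)
  pos <- round(seq(1, length(w), length.out = 4000))
  emg <- ds$emg@data[, w[pos]]
  miWith <- function(x) max(vapply(1:4, function(c)
    knnMi(x[w[pos]], emg[c, ]), numeric(1)))
  artMi <- min(vapply(1:3, function(a)
    miWith(ds$truth@artefactSources[a, ]), numeric(1)))
  neuMi <- max(vapply(seq_len(nrow(ds$truth@neuralSources)), function(i)
    miWith(ds$truth@neuralSources[i, ]), numeric(1)))
  expect_gt(artMi, neuMi)
})
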