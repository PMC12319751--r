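test_that("channel picking preserves order and validates kinds", {
  ch <- rbind(makeGradChannels(2),
              channelTable(c("EMG1", "EMG2"), "emg"))
  rec <- new("Recording", data = matrix(rnorm(6 * 100), 6), channels = ch,
             sfreq = 200)
  grads <- pickChannels(rec, "grad")
  expect_equal(nChannels(grads), 4)
  expect_identical(channelNames(grads), ch$name[1:4])
  expect_identical(dataMatrix(pickChannels(rec, c("grad", "emg"))), rec@data)
  expect_error(pickChannels(grads, "mag"), "no channels")
  expect_error(pickChannels(rec, "bogus"), "unknown channel kind")
})

test_that("run concatenation re-offsets events and records seams", {
  recs <- lapply(1:3, function(i) makeRecording(2, 500, seed = i))
  evs <- lapply(1:3, function(i)
    eventTable(c(10L, 200L), "picture", "vocal", run = 1L, duration_s = 1))
  out <- concatTask(recs, evs)
  expect_equal(nSamples(out$recording), 1500)
  expect_identical(out$recording@runStarts, c(0L, 500L, 1000L))
  expect_equal(out$events$onset_sample, c(10, 200, 510, 700, 1010, 1200))
  expect_equal(out$events$run, rep(1:3, each = 2))
  # single input is the identity
  one <- concatTask(recs[1], evs[1])
  expect_identical(one$recording@data, recs[[1]]@data)
  # mismatched channel sets refuse
  expect_error(concatTask(list(recs[[1]], makeRecording(3, 500)), evs[1:2]),
               "channel set")
})

test_that("downsampling passes the band, kills aliases and rescales onsets", {
  t <- seq(1 / 1000, 10, by = 1 / 1000)
  ch <- makeGradChannels(1)
  amp <- function(x) sqrt(2 * mean(x^2))
  rec <- new("Recording",
             data = rbind(sin(2 * pi * 5 * t), sin(2 * pi * 90 * t)),
             channels = ch, sfreq = 1000)
  ev <- eventTable(c(100L, 1001L), "picture", "vocal", duration_s = 1)
  out <- downsampleRecording(rec, 200, ev)
  expect_equal(samplingRate(out$recording), 200)
  expect_equal(nSamples(out$recording), 2000)
  # 5 Hz passes within 1%; 90 Hz (at the 0.9 x Nyquist edge) survives
  mid <- 500:1500
  expect_equal(amp(out$recording@data[1, mid]), 1, tolerance = 0.01)
  expect_gt(amp(out$recording@data[2, mid]), 0.25)
  # onsets rescaled by the decimation factor
  expect_equal(out$events$onset_sample, c(20L, 200L))
  # a 150 Hz component (alias band) is attenuated by far more than 20 dB
  rec2 <- new("Recording", data = rbind(sin(2 * pi * 150 * t), 0 * t),
              channels = ch, sfreq = 1000)
  d2 <- downsampleRecording(rec2, 200)
  expect_lt(amp(d2@data[1, mid]), 0.1)
  expect_error(downsampleRecording(rec, 1000), "below the current rate")
  expect_error(downsampleRecording(rec, 300), "divide")
})

test_that("epoch extraction uses half-open windows and drops bad epochs", {
  rec <- makeRecording(2, 2000, sfreq = 200)
  ev <- eventTable(c(0L, 500L, 1950L), "picture", "vocal", duration_s = 1.5)
  expect_warning(ep <- extractEpochs(rec, ev, 0, 1.5), "dropped")
  expect_equal(nEpochs(ep), 2)  # the event 50 samples before the end is out
  expect_equal(dim(ep@data)[3], 300)
  expect_identical(ep@eventRefs, c(1L, 2L))
  # epochs never straddle a run seam
  rec2 <- makeRecording(2, 2000, sfreq = 200, runStarts = c(0L, 1000L))
  ev2 <- eventTable(c(900L, 1200L), "picture", "vocal",
                    run = c(1L, 2L), duration_s = 1.5)
  expect_warning(ep2 <- extractEpochs(rec2, ev2, 0, 1.5), "dropped")
  expect_identical(ep2@eventRefs, 2L)
  # zero matching events is a valid empty set
  none <- extractEpochs(rec, ev[0, ], 0, 1.5)
  expect_equal(nEpochs(none), 0)
})

test_that("epoch extraction matches the printed naming design at full size", {
  ev <- scheduleNaming(namingParadigmConfig(), seed = 1)
  # collapse the three runs onto one long timeline
  durS <- attr(ev, "run_durations_s")
  off <- cumsum(c(0, durS[-3])) * 200
  ev$onset_sample <- ev$onset_sample + as.integer(off[ev$run])
  ev$run <- 1L
  n <- as.integer(sum(durS) * 200)
  rec <- new("Recording", data = matrix(0, 2, n),
             channels = makeGradChannels(1), sfreq = 200)
  ep <- extractEpochs(rec, ev, 0, 1.5, labels = "picture", tasks = "vocal")
  expect_equal(dim(ep@data), c(110, 2, 300))
})

test_that("epoch averaging is the pointwise mean", {
  ep <- makeEpochs(10, 2, 50, seed = 3)
  ev <- averageEpochs(ep)
  expect_equal(ev@nave, 10L)
  # independent summation oracle
  manual <- matrix(0, 4, 50)
  for (i in 1:10) manual <- manual + ep@data[i, , ]
  expect_equal(ev@data, manual / 10, tolerance = 1e-12)
  # +x / -x cancel
  x <- array(0, c(2, 4, 50)); x[1, , ] <- 1.5; x[2, , ] <- -1.5
  sym <- makeEpochs(2, 2, 50, data = x)
  expect_equal(max(abs(averageEpochs(sym)@data)), 0)
  expect_error(averageEpochs(makeEpochs(0, 2, 50, data = array(0, c(0, 4, 50)))),
               "empty")
})

test_that("constant data survives epoch extraction and averaging exactly", {
  rec <- new("Recording", data = matrix(3.25, 2, 1000),
             channels = makeGradChannels(1), sfreq = 200)
  ev <- eventTable(c(100L, 400L), "picture", "vocal", duration_s = 1.5)
  out <- averageEpochs(extractEpochs(rec, ev, 0, 1.5))
  expect_true(all(out@data == 3.25))
})

test_that("baseline correction subtracts the per-channel baseline mean", {
  rec <- new("Recording", data = matrix(rep(c(2, 5), 500), 2, 500),
             channels = makeGradChannels(1), sfreq = 200)
  rec@data <- rbind(rep(2, 500), rep(5, 500))
  ev <- eventTable(100L, "picture", "vocal", duration_s = 1)
  ep <- extractEpochs(rec, ev, -0.25, 0.75, baseline = c(-0.25, 0))
  expect_equal(max(abs(ep@data)), 0)
})

test_that("event tables enforce their vocabulary and ordering", {
  expect_error(eventTable(c(5L, 1L), "picture", "vocal"), "increasing")
  expect_error(eventTable(1L, "G11", "gesture"), "labels")
  expect_error(eventTable(1L, "picture", "speaking"), "tasks")
  ok <- eventTable(c(1L, 5L), c("G1", "G2"), "gesture", duration_s = 3.2)
  expect_equal(nrow(ok), 2)
})
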