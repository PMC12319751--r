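#' Facial-gesture paradigm configuration
#'
#' The gesture task presents audio cues for 10 facial gestures (G1..G10, each
#' preferentially activating one speech muscle). The paradigm consists of
#' `nSets` sets; within a set every gesture appears once, in random order,
#' repeated `repsPerGesture` times in a row at `cueIntervalS` spacing. With
#' the defaults (5 sets, 10 gestures, 5 reps, 3.2 s cues) each set spans
#' 160 s and the paradigm delivers 250 cues.
#'
#' @param nSets number of sets
#' @param gestures gesture labels
#' @param repsPerGesture consecutive repetitions of each gesture
#' @param cueIntervalS cue spacing in seconds
#' @param sfreq sampling rate the onsets are expressed in (Hz)
#' @return a validated config list
#' @export
gestureParadigmConfig <- function(nSets = 5L, gestures = paste0("G", 1:10),
                                  repsPerGesture = 5L, cueIntervalS = 3.2,
                                  sfreq = 200) {
  cfg <- list(nSets = as.integer(nSets), gestures = gestures,
              repsPerGesture = as.integer(repsPerGesture),
              cueIntervalS = cueIntervalS, sfreq = sfreq)
  cfg$cuesPerSet <- length(gestures) * cfg$repsPerGesture
  cfg$setDurationS <- cfg$cuesPerSet * cueIntervalS
  stopIfNot(cfg$nSets >= 1 && cfg$repsPerGesture >= 1 &&
              length(gestures) >= 1, "invalid gesture paradigm configuration")
  cfg
}

#' Picture-naming paradigm configuration
#'
#' Three runs; within each run the vocal naming, silent naming and observation
#' tasks each occupy two blocks, in one of three predetermined pseudorandom
#' block orders. In the vocal and silent tasks each picture is shown for
#' 500 ms, followed by a 2500 ms response window and a 1000 ms fixation cross
#' (4.0 s trials); in the observation task the picture is followed by a
#' 1500 ms observation period (2.0 s trials). With the default block sizes
#' ({19,18,18,19,18,18} pictures over a task's six blocks) 110 pictures are
#' shown per task across the three runs.
#'
#' @param nRuns number of runs
#' @param blocksPerTaskPerRun blocks per task within one run
#' @param picturesPerBlock `NULL` for the printed-design block sizes, a
#'   single count for uniform blocks, or a length-6 vector per task
#' @param totalPerTask pictures per task over all runs (when
#'   `picturesPerBlock` is `NULL`)
#' @param stimDurationS,responseWindowS,fixationS vocal/silent trial timing (s)
#' @param observationWindowS observation period after the stimulus (s)
#' @param interBlockGapS silence inserted before each block (s)
#' @param sfreq sampling rate the onsets are expressed in (Hz)
#' @return a validated config list
#' @export
namingParadigmConfig <- function(nRuns = 3L, blocksPerTaskPerRun = 2L,
                                 picturesPerBlock = NULL, totalPerTask = 110L,
                                 stimDurationS = 0.5, responseWindowS = 2.5,
                                 fixationS = 1.0, observationWindowS = 1.5,
                                 interBlockGapS = 2.0, sfreq = 200) {
  nBlocks <- as.integer(nRuns) * as.integer(blocksPerTaskPerRun)
  if (is.null(picturesPerBlock)) {
    # blocks of 18-19 pictures whose six per-task blocks sum to totalPerTask
    n19 <- totalPerTask - 18L * nBlocks
    stopIfNot(n19 >= 0 && n19 <= nBlocks,
              "no assignment of 18-19 picture blocks sums to %d over %d blocks",
              totalPerTask, nBlocks)
    counts <- rep(18L, nBlocks)
    if (n19 > 0) counts[round(seq(1, nBlocks, length.out = n19))] <- 19L
  } else if (length(picturesPerBlock) == 1) {
    counts <- rep(as.integer(picturesPerBlock), nBlocks)
    totalPerTask <- sum(counts)
  } else {
    stopIfNot(length(picturesPerBlock) == nBlocks,
              "picturesPerBlock must have one entry per block (%d)", nBlocks)
    counts <- as.integer(picturesPerBlock)
    stopIfNot(sum(counts) == totalPerTask,
              "picturesPerBlock sums to %d, not totalPerTask = %d",
              sum(counts), totalPerTask)
  }
  list(nRuns = as.integer(nRuns),
       blocksPerTaskPerRun = as.integer(blocksPerTaskPerRun),
       blockCounts = counts, totalPerTask = as.integer(totalPerTask),
       stimDurationS = stimDurationS, responseWindowS = responseWindowS,
       fixationS = fixationS, observationWindowS = observationWindowS,
       interBlockGapS = interBlockGapS, sfreq = sfreq,
       namingTrialS = stimDurationS + responseWindowS + fixationS,
       observationTrialS = stimDurationS + observationWindowS)
}

# Three predetermined block orders (each task twice per run), one per run,
# cycled if more runs are requested.
NAMING_BLOCK_ORDERS <- list(
  c("vocal", "silent", "observation", "observation", "silent", "vocal"),
  c("silent", "observation", "vocal", "vocal", "observation", "silent"),
  c("observation", "vocal", "silent", "silent", "vocal", "observation"))

#' Schedule the facial-gesture paradigm
#'
#' Per set, a seeded random permutation of the gestures, each repeated
#' `repsPerGesture` times consecutively at `cueIntervalS` spacing. Event
#' onsets are exact to the sample; the paradigm occupies one run.
#'
#' @param config a [gestureParadigmConfig()]
#' @param seed integer seed for the per-set gesture permutations
#' @return an event table (block = set index, duration = cue interval); the
#'   run duration in seconds is attached as attribute `run_durations_s`
#' @export
scheduleGesture <- function(config = gestureParadigmConfig(), seed = 0L) {
  orders <- withSeed(substreamSeed(seed, "gesture-schedule"), {
    lapply(seq_len(config$nSets), function(s) sample(config$gestures))
  })
  onsets <- integer(0); labels <- character(0); blocks <- integer(0)
  for (s in seq_len(config$nSets)) {
    labs <- rep(orders[[s]], each = config$repsPerGesture)
    t0 <- (s - 1) * config$setDurationS +
      (seq_along(labs) - 1) * config$cueIntervalS
    onsets <- c(onsets, as.integer(round(t0 * config$sfreq)))
    labels <- c(labels, labs)
    blocks <- c(blocks, rep(s, length(labs)))
  }
  ev <- eventTable(onsets, labels, "gesture", run = 1L, block = blocks,
                   duration_s = config$cueIntervalS)
  attr(ev, "run_durations_s") <- config$nSets * config$setDurationS
  ev
}

#' Schedule the picture-naming paradigm
#'
#' `nRuns` runs of six task blocks (two per task) in predetermined
#' pseudorandom orders; per task the block picture counts follow the
#' configuration, with Fig.-3-style trial timing (0.5 s stimulus, then a
#' 2.5 s response window and 1 s fixation for naming, or a 1.5 s observation
#' period). Onsets are run-local; run durations are attached as attribute
#' `run_durations_s`.
#'
#' @param config a [namingParadigmConfig()]
#' @param seed unused (the block orders are predetermined); kept for
#'   interface symmetry
#' @return an event table with one `picture` row per trial
#' @export
scheduleNaming <- function(config = namingParadigmConfig(), seed = 0L) {
  onsets <- integer(0); tasks <- character(0)
  runs <- integer(0); blocks <- integer(0); durs <- numeric(0)
  runDur <- numeric(config$nRuns)
  blockNo <- stats::setNames(rep(0L, 3), c("vocal", "silent", "observation"))
  for (r in seq_len(config$nRuns)) {
    order <- NAMING_BLOCK_ORDERS[[(r - 1) %% length(NAMING_BLOCK_ORDERS) + 1]]
    t <- 0
    for (b in seq_along(order)) {
      task <- order[b]
      blockNo[task] <- blockNo[task] + 1L
      nPics <- config$blockCounts[blockNo[task]]
      trial <- if (task == "observation") config$observationTrialS
               else config$namingTrialS
      t <- t + config$interBlockGapS
      t0 <- t + (seq_len(nPics) - 1) * trial
      onsets <- c(onsets, as.integer(round(t0 * config$sfreq)))
      tasks <- c(tasks, rep(task, nPics))
      runs <- c(runs, rep(r, nPics))
      blocks <- c(blocks, rep(b, nPics))
      durs <- c(durs, rep(trial, nPics))
      t <- t + nPics * trial
    }
    runDur[r] <- t + config$interBlockGapS
  }
  ev <- eventTable(onsets, "picture", tasks, run = runs, block = blocks,
                   duration_s = durs)
  ev <- ev[order(ev$run, ev$onset_sample), ]
  rownames(ev) <- NULL
  attr(ev, "run_durations_s") <- runDur
  ev
}

# Band-limited unit-variance Gaussian noise (FIR band-pass on white noise).
bandNoise <- function(n, sfreq, low, high, order = 128) {
  w <- c(low, high) / (sfreq / 2)
  b <- as.numeric(signal::fir1(order, w, type = "pass"))
  x <- as.numeric(signal::filter(b, 1, rnorm(n + order)))[-(1:order)]
  x / sd(x)
}

# Smooth burst envelope: raised-cosine ramps around a sustained plateau.
burstEnvelope <- function(nSamples, sfreq, rampS = 0.15) {
  nr <- max(2L, round(rampS * sfreq))
  if (2 * nr >= nSamples) return(signal::hanning(nSamples))
  c(0.5 * (1 - cos(pi * seq_len(nr) / nr)), rep(1, nSamples - 2 * nr),
    0.5 * (1 + cos(pi * seq_len(nr) / nr)))
}

#' Default EMG gain matrix
#'
#' Rows are the four EMG channels (EMG1 upper lip / orbicularis oris
#' superioris, EMG2 lower lip / inferioris, EMG3 zygomaticus, EMG4 chin and
#' tongue); columns are the burst drivers G1..G10 and the vocal response.
#' Each gesture drives its preferential muscle's channel hardest but, as with
#' real facial musculature, activations overlap; vocal speech engages all
#' four channels.
#'
#' @return a 4 x 11 non-negative gain matrix
#' @export
defaultEmgGains <- function() {
  g <- matrix(0.5, nrow = 4, ncol = 11,
              dimnames = list(c("EMG1", "EMG2", "EMG3", "EMG4"),
                              c(paste0("G", 1:10), "vocal")))
  g["EMG1", c("G1", "G5")] <- 5
  g["EMG1", c("G2", "G8")] <- 1.5
  g["EMG2", c("G6", "G7")] <- 5
  g["EMG2", c("G8", "G9")] <- 2
  g["EMG3", c("G2", "G4")] <- 5
  g["EMG3", c("G1", "G8")] <- 2
  g["EMG4", c("G3", "G9", "G10")] <- 5
  g["EMG4", "G6"] <- 1.5
  g[, "vocal"] <- c(3.5, 4, 3, 3.5)
  g
}

#' Simulate the facial-EMG channels
#'
#' Each gesture cue and vocal-naming trial triggers, on every EMG channel, a
#' burst of 20-95 Hz band-limited Gaussian noise shaped by a smooth envelope
#' spanning the trial's response period, scaled by the per-(driver, channel)
#' gain matrix. Silent-naming and observation trials trigger no burst; a
#' low-amplitude baseline of the same band is always present. Channel `c` is
#' `carrier_c(t) * (baseline + sum_events gain * envelope(t))`, so the EMG
#' amplitude envelope (not its waveform) carries the event structure.
#'
#' @param events event table with global (concatenated-timeline) onsets
#' @param nSamples total samples of the timeline
#' @param sfreq sampling rate (Hz)
#' @param gains gain matrix as in [defaultEmgGains()]
#' @param baseline baseline envelope amplitude
#' @param seed integer seed
#' @param runStarts run seams of the timeline
#' @return a 4-channel EMG [Recording-class]
#' @export
simulateEmg <- function(events, nSamples, sfreq = 200,
                        gains = defaultEmgGains(), baseline = 0.1, seed = 0L,
                        runStarts = 0L) {
  nCh <- nrow(gains)
  carriers <- withSeed(substreamSeed(seed, "emg-carrier"), {
    vapply(seq_len(nCh), function(i) bandNoise(nSamples, sfreq, 20, 95),
           numeric(nSamples))
  })
  env <- matrix(0, nCh, nSamples)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    driver <- if (ev$label == "picture") {
      if (ev$task == "vocal") "vocal" else NA_character_
    } else ev$label
    if (is.na(driver) || !(driver %in% colnames(gains))) next
    # burst spans the response period: cue/stimulus processing delay first
    lag <- round(0.35 * sfreq)
    len <- round((ev$duration_s - 0.85) * sfreq)
    s0 <- ev$onset_sample + lag
    idx <- (s0 + 1):min(s0 + len, nSamples)
    e <- burstEnvelope(len, sfreq)[seq_along(idx)]
    env[, idx] <- env[, idx] + gains[, driver] %o% e
  }
  dat <- t(carriers) * (baseline + env)
  ch <- channelTable(rownames(gains), rep("emg", nCh))
  new("Recording", data = dat, channels = ch, sfreq = sfreq,
      runStarts = as.integer(runStarts))
}

gradLayout <- function(nPairs) {
  p <- seq_len(nPairs) - 1
  xs <- (p %% 5) - 2
  ys <- (p %/% 5) * 1.0
  names <- as.vector(rbind(sprintf("MEG%03d2", seq_len(nPairs)),
                           sprintf("MEG%03d3", seq_len(nPairs))))
  channelTable(names, "grad", pair_id = rep(seq_len(nPairs), each = 2),
               pos_x = rep(xs, each = 2), pos_y = rep(ys, each = 2))
}

# Gaussian spatial bump over the pair layout, expanded to channels with a
# per-channel orientation factor (the two gradiometers of a pair see the same
# source with different sensitivities and possibly opposite signs).
topographyBump <- function(channels, fx, fy, sigma = 0.8) {
  w <- exp(-((channels$pos_x - fx)^2 + (channels$pos_y - fy)^2) / (2 * sigma^2))
  orient <- runif(nrow(channels), 0.5, 1) * sample(c(-1, 1), nrow(channels),
                                                   replace = TRUE)
  v <- w * orient
  v / sqrt(sum(v^2))
}

# Rectified, low-passed (8 Hz) amplitude envelope of a signal.
amplitudeEnvelope <- function(x, sfreq) {
  b <- as.numeric(signal::fir1(64, 8 / (sfreq / 2)))
  y <- as.numeric(signal::filter(b, 1, c(abs(x), rep(0, 32))))[33:(32 + length(x))]
  pmax(y, 0)
}

#' Simulate the MEG sensor array
#'
#' Sensor data are an exactly linear mixture: neural topographies times
#' neural sources, plus artefact topographies times artefact sources, plus
#' white sensor noise. Neural sources combine 1/f-like ongoing background
#' with stimulus-locked evoked transients (present in every task, including
#' silent naming). Each artefact source is an independent 60-95 Hz noise
#' carrier amplitude-modulated by the envelope of a linear combination of the
#' EMG channels — so artefact components share mutual information with the
#' EMG without resembling it in waveform. Artefact topographies focus on the
#' left and right frontotemporal edges of the layout.
#'
#' @param events event table with global onsets
#' @param emg the simulated EMG [Recording-class] (aligned timeline)
#' @param config list of generator settings; see [deskScenarioConfig()]
#' @param seed integer seed
#' @return list with `recording` (gradiometer [Recording-class]) and `truth`
#'   (a [SimulationTruth-class])
#' @export
simulateMeg <- function(events, emg, config, seed = 0L) {
  nSamples <- nSamples(emg)
  sfreq <- samplingRate(emg)
  channels <- gradLayout(config$nPairs)
  nCh <- nrow(channels)
  nArt <- config$nArtefact

  aTopo <- withSeed(substreamSeed(seed, "artefact-topo"), {
    foci <- list(c(-2, 0.5), c(2, 0.5), c(-1.5, 1), c(1.5, 0),
                 c(-2, 0), c(2, 1))
    vapply(seq_len(nArt), function(a) {
      topographyBump(channels, foci[[(a - 1) %% length(foci) + 1]][1],
                     foci[[(a - 1) %% length(foci) + 1]][2])
    }, numeric(nCh))
  })

  # EMG-envelope-driven artefact sources
  # Artefact sources share a largely common activation envelope (facial
  # muscles co-activate during speech and gestures) with small per-source
  # variation in how the EMG channels contribute. Individual muscle groups
  # fire with different degrees of burstiness, modelled as per-source
  # heavy-tailedness of the high-frequency carrier (Student-t marginals of
  # decreasing df). The distinct amplitude statistics make the mixture
  # ICA-identifiable even though the sources share one envelope, while the
  # envelope-mediated MI against the EMG stays nearly identical across
  # sources — exactly the regime the selection stage assumes.
  gainsMix <- withSeed(substreamSeed(seed, "artefact-mix"), {
    m <- 1 + matrix(runif(nChannels(emg) * nArt, 0, 0.15), nChannels(emg), nArt)
    m / rep(colSums(m), each = nChannels(emg))
  })
  emgEnv <- t(vapply(seq_len(nChannels(emg)), function(c)
    amplitudeEnvelope(emg@data[c, ], sfreq), numeric(nSamples)))
  carrierDf <- exp(seq(log(4), log(60), length.out = nArt))
  aSrc <- withSeed(substreamSeed(seed, "artefact-carrier"), {
    t(vapply(seq_len(nArt), function(a) {
      env <- as.numeric(t(gainsMix[, a]) %*% emgEnv)
      env <- env / sqrt(mean(env^2))
      carr <- stats::qt(stats::pnorm(bandNoise(nSamples, sfreq, 60, 95)),
                        df = carrierDf[a])
      (carr / sd(carr)) * env
    }, numeric(nSamples)))
  })
  # per-run artefact scaling (e.g. weaker articulation during naming)
  if (!is.null(config$runArtefactScale)) {
    bounds <- c(emg@runStarts, nSamples)
    for (r in seq_along(config$runArtefactScale)) {
      idx <- (bounds[r] + 1):bounds[r + 1]
      aSrc[, idx] <- aSrc[, idx] * config$runArtefactScale[r]
    }
  }
  aSrc <- aSrc * config$artefactGain

  # within-trial response envelope over the movement periods (gesture cues
  # and vocal utterances): ongoing neural power in motor/auditory areas
  # waxes and wanes with articulation, which gives non-artefactual
  # components the moderate event-locked EMG dependence seen in real data
  respEnv <- numeric(nSamples)
  for (j in seq_len(nrow(events))) {
    ev <- events[j, ]
    active <- ev$task == "gesture" || (ev$task == "vocal" && ev$label == "picture")
    if (!active) next
    lag <- round(0.35 * sfreq)
    len <- round((ev$duration_s - 0.85) * sfreq)
    s0 <- ev$onset_sample + lag
    idx <- (s0 + 1):min(s0 + len, nSamples)
    respEnv[idx] <- pmax(respEnv[idx], burstEnvelope(len, sfreq)[seq_along(idx)])
  }

  # neural sources: 1/f-ish background + event-locked transients
  nNeu <- config$nNeural
  neural <- withSeed(substreamSeed(seed, "neural"), {
    nTopo <- vapply(seq_len(nNeu), function(i)
      topographyBump(channels, runif(1, -1.5, 1.5), runif(1, 0, 1),
                     sigma = 1.0), numeric(nCh))
    src <- matrix(0, nNeu, nSamples)
    for (i in seq_len(nNeu)) {
      bg <- bandNoise(nSamples, sfreq, 1, 30)
      lat <- runif(1, 0.08, 0.25)
      amp <- runif(1, 0.5, 1.5) * sample(c(-1, 1), 1)
      f <- runif(1, 4, 9)
      len <- round(0.4 * sfreq)
      burst <- sin(2 * pi * f * (seq_len(len) / sfreq)) *
        signal::hanning(len) * amp
      for (j in seq_len(nrow(events))) {
        s0 <- events$onset_sample[j] + round(lat * sfreq)
        idx <- (s0 + 1):min(s0 + len, nSamples)
        src[i, idx] <- src[i, idx] + burst[seq_along(idx)]
      }
      # every source shows some induced movement-locked power modulation of
      # its ongoing activity (ERD/ERS-like), with depths spanning a broad
      # range: non-artefactual components thereby carry a continuum of
      # moderate sample-wise EMG dependence — as real MEG components do —
      # without being myogenic
      mod <- runif(1, 1.0, 4.5)
      sh <- round(runif(1, -0.3, 0.3) * sfreq)
      env <- if (sh == 0) respEnv
             else if (sh > 0) c(rep(0, sh), respEnv[seq_len(nSamples - sh)])
             else c(respEnv[(-sh + 1):nSamples], rep(0, -sh))
      src[i, ] <- src[i, ] + 0.6 * bg * (1 + mod * env)
    }
    list(topo = nTopo, src = src)
  })
  nSrc <- neural$src * config$neuralGain

  noise <- withSeed(substreamSeed(seed, "sensor-noise"), {
    matrix(rnorm(nCh * nSamples, sd = config$noiseGain), nCh, nSamples)
  })

  dat <- aTopo %*% aSrc + neural$topo %*% nSrc + noise
  truth <- new("SimulationTruth", artefactTopographies = aTopo,
               artefactSources = aSrc, neuralTopographies = neural$topo,
               neuralSources = nSrc, emgToArtefactGains = gainsMix,
               plantedIndices = seq_len(nArt))
  rec <- new("Recording", data = dat, channels = channels, sfreq = sfreq,
             runStarts = emg@runStarts)
  list(recording = rec, truth = truth)
}

#' Desk-scale generator configuration
#'
#' The default study conditions for the synthetic datasets: a 20-channel
#' gradiometer layout (10 pairs) plus 4 EMG channels at 200 Hz; a shortened
#' gesture paradigm (2 sets x 10 gestures x 2 reps, paper-timed 3.2 s cues)
#' and naming paradigm (3 runs x 6 blocks x 4 pictures, paper-timed trials);
#' and 3 planted artefact sources. `fullSize = TRUE` restores the full
#' 102-pair layout and printed paradigm sizes.
#'
#' @param fullSize use the full-scale layout and paradigm
#' @return a config list consumed by [generateDataset()]
#' @export
deskScenarioConfig <- function(fullSize = FALSE) {
  list(
    gesture = if (fullSize) gestureParadigmConfig()
              else gestureParadigmConfig(nSets = 2L, repsPerGesture = 2L),
    naming = if (fullSize) namingParadigmConfig()
             else namingParadigmConfig(picturesPerBlock = 4L,
                                       totalPerTask = 24L),
    nPairs = if (fullSize) 102L else 10L,
    nArtefact = 3L, nNeural = 14L,
    artefactGain = 6.0, neuralGain = 1.0, noiseGain = 0.3,
    emgGains = defaultEmgGains(), emgBaseline = 0.05,
    sfreq = 200, runArtefactScale = NULL)
}

#' Generate a complete synthetic dataset
#'
#' Scenarios:
#' \describe{
#'   \item{`"GN"`}{gesture paradigm followed by the naming paradigm (the
#'     timeline the MIC-ICA-GN variant consumes).}
#'   \item{`"N"`}{naming paradigm only.}
#'   \item{`"null"`}{GN timeline with zero artefact gain (no planted
#'     artefacts; the selection stage should elect nothing confidently).}
#'   \item{`"lowsnr"`}{GN timeline with the speech-related artefact scaled
#'     down to 0.15 during the naming runs; gesture bursts keep full
#'     amplitude. The regime where the added gesture paradigm pays off.}
#' }
#' Deterministic given `seed`: the same seed yields bitwise-identical data.
#'
#' @param scenario one of `"GN"`, `"N"`, `"null"`, `"lowsnr"`
#' @param seed integer seed (all stages draw from named substreams of it)
#' @param config generator configuration, see [deskScenarioConfig()]
#' @return list with `meg` (gradiometer recording), `emg`, `events` (global
#'   timeline), `truth` ([SimulationTruth-class]), `scenario`, `seed`
#' @export
generateDataset <- function(scenario = c("GN", "N", "null", "lowsnr"),
                            seed = 0L, config = deskScenarioConfig()) {
  scenario <- match.arg(scenario)
  sfreq <- config$sfreq

  runsEv <- list(); runDur <- numeric(0)
  if (scenario != "N") {
    gev <- scheduleGesture(config$gesture, seed)
    runsEv <- c(runsEv, list(gev))
    runDur <- c(runDur, attr(gev, "run_durations_s"))
  }
  nev <- scheduleNaming(config$naming, seed)
  ndur <- attr(nev, "run_durations_s")
  for (r in seq_len(config$naming$nRuns))
    runsEv <- c(runsEv, list(nev[nev$run == r, , drop = FALSE]))
  runDur <- c(runDur, ndur)

  runSamples <- as.integer(round(runDur * sfreq))
  offsets <- cumsum(c(0L, runSamples[-length(runSamples)]))
  evs <- lapply(seq_along(runsEv), function(i) {
    ev <- runsEv[[i]]
    ev$onset_sample <- ev$onset_sample + offsets[i]
    ev$run <- i
    attr(ev, "run_durations_s") <- NULL
    ev
  })
  events <- do.call(rbind, evs)
  rownames(events) <- NULL
  nSamples <- sum(runSamples)

  cfg <- config
  if (scenario == "null") cfg$artefactGain <- 0
  if (scenario == "lowsnr") {
    scale <- rep(0.15, length(runSamples))
    if (scenario != "N" && length(runSamples) > config$naming$nRuns)
      scale[seq_len(length(runSamples) - config$naming$nRuns)] <- 1
    cfg$runArtefactScale <- scale
  }

  emg <- simulateEmg(events, nSamples, sfreq, gains = cfg$emgGains,
                     baseline = cfg$emgBaseline, seed = seed,
                     runStarts = offsets)
  megSim <- simulateMeg(events, emg, cfg, seed)

  list(meg = megSim$recording, emg = emg, events = events,
       truth = megSim$truth, scenario = scenario, seed = as.integer(seed),
       config = cfg)
}

#' Match planted artefact sources to fitted ICA components
#'
#' Greedy one-to-one assignment of truth artefact topographies to ICA mixing
#' columns by descending absolute cosine similarity.
#'
#' @param ica an [IcaModel-class]
#' @param truth a [SimulationTruth-class]
#' @return data.frame with `source`, `ic`, `cosine`
#' @export
matchPlantedComponents <- function(ica, truth) {
  topo <- truth@artefactTopographies
  mix <- ica@mixing
  cosm <- abs(crossprod(
    topo / rep(sqrt(colSums(topo^2)), each = nrow(topo)),
    mix / rep(sqrt(colSums(mix^2)), each = nrow(mix))))
  out <- data.frame(source = integer(0), ic = integer(0), cosine = numeric(0))
  while (nrow(cosm) > 0 && any(is.finite(cosm))) {
    ij <- which(cosm == max(cosm), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(
      source = as.integer(rownames(cosm)[ij[1]] %||% ij[1]),
      ic = as.integer(colnames(cosm)[ij[2]] %||% ij[2]),
      cosine = cosm[ij[1], ij[2]]))
    cosm[ij[1], ] <- -Inf
    cosm[, ij[2]] <- -Inf
  }
  out[order(out$source), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
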