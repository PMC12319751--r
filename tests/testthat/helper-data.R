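# Shared fixture builders: everything is generated in code at test time.

makeGradChannels <- function(nPairs = 3) {
  channelTable(
    as.vector(rbind(sprintf("MEG%03d2", seq_len(nPairs)),
                    sprintf("MEG%03d3", seq_len(nPairs)))),
    "grad", pair_id = rep(seq_len(nPairs), each = 2),
    pos_x = rep(seq_len(nPairs), each = 2), pos_y = 0)
}

makeRecording <- function(nPairs = 3, nSamples = 1000, sfreq = 200, seed = 1,
                          runStarts = 0L) {
  ch <- makeGradChannels(nPairs)
  withSeed(seed, new("Recording",
                     data = matrix(rnorm(nrow(ch) * nSamples), nrow(ch)),
                     channels = ch, sfreq = sfreq,
                     runStarts = as.integer(runStarts)))
}

makeEpochs <- function(nEpochs, nPairs, nTimes, sfreq = 200, seed = 1,
                       data = NULL) {
  ch <- makeGradChannels(nPairs)
  if (is.null(data))
    data <- withSeed(seed, array(rnorm(nEpochs * nrow(ch) * nTimes),
                                 c(nEpochs, nrow(ch), nTimes)))
  new("EpochSet", data = data, tmin = 0, tmax = nTimes / sfreq, sfreq = sfreq,
      channels = ch, eventRefs = seq_len(nEpochs), baseline = numeric(0))
}

# Channel table shaped like pair-combined output (one channel per element).
pairChannelTableForTest <- function(nPairs) {
  channelTable(sprintf("pair%03d", seq_len(nPairs)), "grad",
               pair_id = seq_len(nPairs), pos_x = seq_len(nPairs), pos_y = 0)
}

# Exact plug-in MI (nats) of the empirical joint histogram of two discrete
# samples — the independent oracle for the kNN estimator on discrete data.
plugInMi <- function(x, y) {
  pj <- table(x, y) / length(x)
  px <- rowSums(pj); py <- colSums(pj)
  pref <- outer(px, py)
  sum(pj[pj > 0] * log(pj[pj > 0] / pref[pj > 0]))
}

# Dataset cache: the default synthetic dataset is reused across test files.
cachedDataset <- local({
  cache <- list()
  function(scenario = "GN", seed = 1) {
    key <- paste(scenario, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generateDataset(scenario, seed)
    cache[[key]]
  }
})
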