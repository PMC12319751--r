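#' Construct a Recording
#'
#' @param data numeric matrix `[n_channels x n_samples]`
#' @param channels channel metadata data.frame (`name`, `kind`, `pair_id`,
#'   `pos_x`, `pos_y`); see [channelTable()]
#' @param sfreq sampling frequency in Hz
#' @param firstSampleTime time of the first sample in seconds
#' @param runStarts 0-based sample indices where concatenated runs begin
#' @return a [Recording-class]
#' @export
#' @examples
#' ch <- channelTable(c("EMG1", "EMG2"), c("emg", "emg"))
#' rec <- Recording(matrix(rnorm(200), 2), ch, sfreq = 100)
#' nSamples(rec)
Recording <- function(data, channels, sfreq, firstSampleTime = 0,
                      runStarts = 0L) {
  new("Recording", data = data, channels = channels, sfreq = sfreq,
      firstSampleTime = firstSampleTime, runStarts = as.integer(runStarts))
}

#' Build a channel metadata table
#'
#' @param names unique channel names
#' @param kinds channel kinds (grad, mag, emg, eog, ecg, stim)
#' @param pair_id integer id shared by the two planar gradiometers of one
#'   sensor element (`NA` for non-grad channels)
#' @param pos_x,pos_y flat layout coordinates (NA allowed)
#' @return data.frame usable as the `channels` slot of a [Recording-class]
#' @export
channelTable <- function(names, kinds, pair_id = NA_integer_,
                         pos_x = NA_real_, pos_y = NA_real_) {
  data.frame(name = as.character(names), kind = as.character(kinds),
              pair_id = as.integer(pair_id), pos_x = as.numeric(pos_x),
              pos_y = as.numeric(pos_y), stringsAsFactors = FALSE)
}

#' Construct an event table
#'
#' Rows describe paradigm events: gesture cues (`G1`..`G10`) or picture
#' onsets (`picture`), with their task, run and block membership and the
#' nominal trial duration (used to delimit task-restricted sample windows).
#' Onsets are 0-based sample indices and must be strictly increasing within
#' each run.
#'
#' @param onset_sample 0-based integer sample indices
#' @param label event labels, from `G1..G10` or `picture`
#' @param task one of `gesture`, `vocal`, `silent`, `observation`
#' @param run run number (1-based)
#' @param block block index within the run
#' @param duration_s nominal trial duration in seconds
#' @return a validated data.frame with those columns
#' @export
eventTable <- function(onset_sample, label, task, run = 1L, block = 1L,
                       duration_s = NA_real_) {
  ev <- data.frame(onset_sample = as.integer(onset_sample),
                   label = as.character(label), task = as.character(task),
                   run = as.integer(run), block = as.integer(block),
                   duration_s = as.numeric(duration_s),
                   stringsAsFactors = FALSE)
  validateEventTable(ev)
  ev
}

validateEventTable <- function(ev) {
  need <- c("onset_sample", "label", "task", "run", "block", "duration_s")
  stopIfNot(is.data.frame(ev) && all(need %in% names(ev)),
            "event table needs columns %s", paste(need, collapse = ", "))
  stopIfNot(all(ev$label %in% EVENT_LABELS),
            "event labels must be drawn from {%s}",
            paste(EVENT_LABELS, collapse = ", "))
  stopIfNot(all(ev$task %in% EVENT_TASKS),
            "event tasks must be drawn from {%s}",
            paste(EVENT_TASKS, collapse = ", "))
  for (r in unique(ev$run)) {
    on <- ev$onset_sample[ev$run == r]
    stopIfNot(!is.unsorted(on, strictly = TRUE),
              "event onsets must be strictly increasing within run %d", r)
  }
  invisible(ev)
}

emptyEventTable <- function() {
  eventTable(integer(0), character(0), character(0), integer(0), integer(0),
             numeric(0))
}

#' Select channels of given kinds
#'
#' @param recording a [Recording-class]
#' @param kinds character vector of channel kinds to keep
#' @return a new [Recording-class] with the matching channels, order preserved
#' @export
#' @examples
#' ds <- generateDataset("N", seed = 1)
#' grads <- pickChannels(ds$meg, "grad")
pickChannels <- function(recording, kinds) {
  stopIfNot(all(kinds %in% CHANNEL_KINDS), "unknown channel kind(s): %s",
            paste(setdiff(kinds, CHANNEL_KINDS), collapse = ", "))
  keep <- which(recording@channels$kind %in% kinds)
  stopIfNot(length(keep) > 0, "no channels of kind(s) {%s} present",
            paste(kinds, collapse = ", "))
  new("Recording", data = recording@data[keep, , drop = FALSE],
      channels = recording@channels[keep, , drop = FALSE],
      sfreq = recording@sfreq, firstSampleTime = recording@firstSampleTime,
      runStarts = recording@runStarts)
}

#' Concatenate runs into one recording
#'
#' Joins per-run recordings along time (inter-run breaks removed), re-offsets
#' event onsets, renumbers runs sequentially and records the seam positions in
#' `runStarts` so downstream epoching never straddles a run boundary.
#'
#' @param recordings list of [Recording-class] with identical channel sets
#'   and sampling rates
#' @param events list of event tables, one per recording
#' @return list with elements `recording` and `events`
#' @export
concatTask <- function(recordings, events) {
  stopIfNot(length(recordings) >= 1, "need at least one recording")
  stopIfNot(length(recordings) == length(events),
            "one event table per recording required")
  ref <- recordings[[1]]
  for (r in recordings[-1]) {
    stopIfNot(identical(r@channels$name, ref@channels$name) &&
                identical(r@channels$kind, ref@channels$kind),
              "all recordings must share one channel set")
    stopIfNot(r@sfreq == ref@sfreq, "all recordings must share one sampling rate")
  }
  ns <- vapply(recordings, nSamples, integer(1))
  offsets <- cumsum(c(0L, ns[-length(ns)]))
  dat <- do.call(cbind, lapply(recordings, function(r) r@data))
  evs <- lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    if (nrow(ev) == 0) return(ev)
    validateEventTable(ev)
    ev$onset_sample <- ev$onset_sample + offsets[i]
    ev$run <- i
    ev
  })
  ev <- do.call(rbind, evs)
  if (is.null(ev)) ev <- emptyEventTable()
  list(recording = new("Recording", data = dat, channels = ref@channels,
                       sfreq = ref@sfreq,
                       firstSampleTime = ref@firstSampleTime,
                       runStarts = as.integer(offsets)),
       events = ev)
}

# Linear-phase FIR low-pass, applied with group-delay compensation so the
# output is zero-phase after a single pass (a filtfilt double pass would
# double the attenuation at the cutoff).
firLowpass <- function(x, wc, order = 96) {
  b <- as.numeric(signal::fir1(order, wc))
  half <- order / 2
  n <- length(x)
  y <- signal::filter(b, 1, c(x, rep(0, half)))
  as.numeric(y[(half + 1):(half + n)])
}

#' Downsample a recording with anti-alias filtering
#'
#' Applies a zero-phase FIR low-pass at 0.9 x the target Nyquist frequency,
#' then decimates. Event onsets (and run seams) are rescaled with
#' round-half-to-even.
#'
#' @param recording a [Recording-class]
#' @param targetSfreq target sampling rate in Hz; must divide the current
#'   rate by an integer factor and be strictly lower
#' @param events optional event table to rescale alongside
#' @return the downsampled [Recording-class], or a list `(recording, events)`
#'   when `events` is given
#' @export
downsampleRecording <- function(recording, targetSfreq, events = NULL) {
  stopIfNot(targetSfreq < recording@sfreq,
            "target rate (%g Hz) must be below the current rate (%g Hz)",
            targetSfreq, recording@sfreq)
  q <- recording@sfreq / targetSfreq
  stopIfNot(abs(q - round(q)) < 1e-9,
            "target rate must divide the current rate (got factor %.4f)", q)
  q <- round(q)
  wc <- 0.9 * (targetSfreq / 2) / (recording@sfreq / 2)
  filt <- t(apply(recording@data, 1, firLowpass, wc = wc))
  idx <- seq(1, ncol(filt), by = q)
  out <- new("Recording", data = filt[, idx, drop = FALSE],
             channels = recording@channels, sfreq = targetSfreq,
             firstSampleTime = recording@firstSampleTime,
             runStarts = as.integer(round(recording@runStarts / q)))
  if (is.null(events)) return(out)
  ev <- events
  ev$onset_sample <- as.integer(round(ev$onset_sample / q))
  list(recording = out, events = ev)
}

#' Extract fixed-length epochs around events
#'
#' Windows are half-open `[tmin, tmax)` relative to each event onset, so an
#' epoch holds exactly `round((tmax - tmin) * sfreq)` samples. Epochs that
#' would run outside the recording or straddle a run seam are dropped with a
#' warning.
#'
#' @param recording a [Recording-class]
#' @param events an event table
#' @param tmin,tmax window edges in seconds relative to the event
#' @param labels optional label filter (e.g. `"picture"`)
#' @param tasks optional task filter (e.g. `"vocal"`)
#' @param baseline optional `c(start, end)` interval (s) whose per-channel
#'   mean is subtracted from each epoch; `NULL` (default) applies none
#' @return an [EpochSet-class]
#' @export
extractEpochs <- function(recording, events, tmin, tmax, labels = NULL,
                          tasks = NULL, baseline = NULL) {
  validateEventTable(events)
  keep <- rep(TRUE, nrow(events))
  if (!is.null(labels)) keep <- keep & events$label %in% labels
  if (!is.null(tasks)) keep <- keep & events$task %in% tasks
  rows <- which(keep)
  nt <- round((tmax - tmin) * recording@sfreq)
  stopIfNot(nt >= 1, "epoch window is empty")
  bounds <- c(recording@runStarts, nSamples(recording))
  starts <- events$onset_sample[rows] + round(tmin * recording@sfreq)
  ok <- logical(length(rows))
  for (i in seq_along(rows)) {
    s <- starts[i]; e <- s + nt  # [s, e), 0-based
    seg <- findInterval(s, bounds)  # run the epoch starts in
    ok[i] <- s >= 0 && e <= nSamples(recording) &&
      seg >= 1 && seg <= length(recording@runStarts) && e <= bounds[seg + 1]
  }
  if (any(!ok))
    warning(sprintf("%d epoch(s) dropped (outside the data or across a run seam)",
                    sum(!ok)))
  rows <- rows[ok]; starts <- starts[ok]
  nch <- nChannels(recording)
  arr <- array(0, dim = c(length(rows), nch, nt))
  for (i in seq_along(rows))
    arr[i, , ] <- recording@data[, (starts[i] + 1):(starts[i] + nt), drop = FALSE]
  if (!is.null(baseline)) {
    tgrid <- tmin + (seq_len(nt) - 1) / recording@sfreq
    bidx <- which(tgrid >= baseline[1] & tgrid < baseline[2])
    stopIfNot(length(bidx) > 0, "baseline interval contains no samples")
    for (i in seq_len(dim(arr)[1])) {
      bmean <- rowMeans(matrix(arr[i, , bidx], nrow = nch))
      arr[i, , ] <- arr[i, , ] - bmean
    }
  }
  new("EpochSet", data = arr, tmin = tmin, tmax = tmax,
      sfreq = recording@sfreq, channels = recording@channels,
      eventRefs = as.integer(rows),
      baseline = if (is.null(baseline)) numeric(0) else as.numeric(baseline))
}

#' Average epochs into an evoked response
#'
#' @param epochs an [EpochSet-class] with at least one epoch
#' @return an [Evoked-class] (pointwise arithmetic mean, `nave` set)
#' @export
averageEpochs <- function(epochs) {
  stopIfNot(nEpochs(epochs) >= 1, "cannot average an empty EpochSet")
  m <- apply(epochs@data, c(2, 3), mean)
  new("Evoked", data = m, nave = nEpochs(epochs), tmin = epochs@tmin,
      sfreq = epochs@sfreq, channels = epochs@channels)
}
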