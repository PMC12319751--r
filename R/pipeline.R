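#' Restrict a recording and events to a subset of runs
#'
#' @param recording a [Recording-class]
#' @param events event table on the same timeline
#' @param runs run numbers to keep (1-based, in timeline order)
#' @return list `(recording, events)` with runs renumbered sequentially
#' @export
subsetRuns <- function(recording, events, runs) {
  nRuns <- length(recording@runStarts)
  stopIfNot(all(runs >= 1 & runs <= nRuns), "runs must lie in 1..%d", nRuns)
  bounds <- c(recording@runStarts, nSamples(recording))
  pieces <- lapply(runs, function(r)
    recording@data[, (bounds[r] + 1):bounds[r + 1], drop = FALSE])
  lens <- vapply(pieces, ncol, integer(1))
  newStarts <- cumsum(c(0L, lens[-length(lens)]))
  evs <- lapply(seq_along(runs), function(i) {
    r <- runs[i]
    ev <- events[events$run == r, , drop = FALSE]
    ev$onset_sample <- ev$onset_sample - bounds[r] + newStarts[i]
    ev$run <- i
    ev
  })
  ev <- do.call(rbind, evs)
  rownames(ev) <- NULL
  list(recording = new("Recording", data = do.call(cbind, pieces),
                       channels = recording@channels, sfreq = recording@sfreq,
                       firstSampleTime = recording@firstSampleTime,
                       runStarts = as.integer(newStarts)),
       events = ev)
}

#' Logical mask of the samples belonging to a task
#'
#' The union of each task event's trial window
#' `[onset, onset + duration_s * sfreq)`.
#'
#' @param events event table
#' @param task task name
#' @param nSamples timeline length
#' @param sfreq sampling rate (Hz)
#' @return logical vector of length `nSamples`
#' @export
taskSampleMask <- function(events, task, nSamples, sfreq) {
  mask <- logical(nSamples)
  rows <- which(events$task == task)
  for (i in rows) {
    s0 <- events$onset_sample[i]
    s1 <- min(s0 + round(events$duration_s[i] * sfreq), nSamples)
    if (s1 > s0) mask[(s0 + 1):s1] <- TRUE
  }
  mask
}

#' Select artefact components with the MIC-ICA procedure
#'
#' Orchestrates the full selection: the ICA is fitted on the naming-paradigm
#' gradiometer data (variant `"N"`) or on the concatenated gesture + naming
#' data (variant `"GN"`); component time courses and EMG principal components
#' are restricted per task (vocal naming for N; facial gesture and vocal
#' naming for GN — silent naming and observation samples are never used); the
#' normalized MI matrix is built and the components are clustered, electing
#' the cluster with the highest mean MI sum.
#'
#' @param dataset dataset list with `meg`, `emg`, `events` (see
#'   [generateDataset()]); for `"GN"` the timeline must contain gesture data
#' @param variant `"N"` (naming only) or `"GN"` (gesture + naming)
#' @param params optional overrides: `varThreshold` (0.9999), `kNn` (3),
#'   `kClusters` (5), `maxMiSamples` (20000), `maxIter` (300; the
#'   artefactual components stabilise early and the residual update drift
#'   lives in the noise subspace), `seed`, `elbowRange`
#' @param elbow also compute the inertia curve over `elbowRange`
#' @return list with `selection` ([SelectionResult-class]), `ica`
#'   ([IcaModel-class]), `miMatrix` ([MiMatrix-class])
#' @export
selectArtefacts <- function(dataset, variant = c("N", "GN"), params = list(),
                            elbow = FALSE) {
  variant <- match.arg(variant)
  p <- utils::modifyList(list(varThreshold = 0.9999, kNn = 3L, kClusters = 5L,
                              maxMiSamples = 20000L, maxIter = 300L,
                              seed = dataset$seed %||% 0L,
                              elbowRange = 2:20), params)
  events <- dataset$events
  validateEventTable(events)
  hasGesture <- any(events$task == "gesture")
  if (variant == "GN")
    stopIfNot(hasGesture, "variant GN requires gesture-paradigm data")

  grads <- pickChannels(dataset$meg, "grad")
  emg <- pickChannels(dataset$emg, "emg")
  stopIfNot(nSamples(grads) == nSamples(emg),
            "MEG and EMG timelines are not aligned")

  if (variant == "N" && hasGesture) {
    namingRuns <- sort(unique(events$run[events$task != "gesture"]))
    sub <- subsetRuns(grads, events, namingRuns)
    subEmg <- subsetRuns(emg, events, namingRuns)
    grads <- sub$recording; events <- sub$events; emg <- subEmg$recording
  }

  ica <- fitIca(grads, seed = substreamSeed(p$seed, "ica"),
                varThreshold = p$varThreshold, maxIter = p$maxIter)
  sources <- getSources(ica, grads)

  tasks <- if (variant == "GN") c("gesture", "vocal") else "vocal"
  sourcesByTask <- list(); emgPcsByTask <- list()
  for (task in tasks) {
    mask <- taskSampleMask(events, task, nSamples(grads), grads@sfreq)
    stopIfNot(any(mask), "no %s-task samples found", task)
    sourcesByTask[[task]] <- sources[, mask, drop = FALSE]
    emgPcsByTask[[task]] <- emgPca(emg, task = task, sampleMask = mask)
  }

  mi <- buildMiMatrix(sourcesByTask, emgPcsByTask, kNn = p$kNn,
                      maxSamples = p$maxMiSamples,
                      seed = substreamSeed(p$seed, "mi"))
  sel <- clusterComponents(mi, kClusters = p$kClusters,
                           seed = substreamSeed(p$seed, "select"))
  sel@provenance <- c(sel@provenance,
                      list(variant = variant, varThreshold = p$varThreshold,
                           maxMiSamples = p$maxMiSamples, seed = p$seed,
                           icaSeed = ica@seed, icaConverged = ica@converged))
  out <- list(selection = sel, ica = ica, miMatrix = mi)
  if (elbow)
    out$inertiaCurve <- elbowCurve(mi, kRange = p$elbowRange,
                                   seed = substreamSeed(p$seed, "elbow"))
  out
}
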