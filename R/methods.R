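#' @describeIn nChannels channels of a recording
setMethod("nChannels", "Recording", function(x) nrow(x@data))
#' @describeIn nChannels channels of an epoch set
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2])
#' @describeIn nChannels channels of an evoked response
setMethod("nChannels", "Evoked", function(x) nrow(x@data))

#' @describeIn nSamples samples of a recording
setMethod("nSamples", "Recording", function(x) ncol(x@data))
#' @describeIn nSamples time points of an evoked response
setMethod("nSamples", "Evoked", function(x) ncol(x@data))

#' @describeIn nEpochs epochs in the set
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[1])

#' @describeIn samplingRate of a recording
setMethod("samplingRate", "Recording", function(x) x@sfreq)
#' @describeIn samplingRate of an epoch set
setMethod("samplingRate", "EpochSet", function(x) x@sfreq)
#' @describeIn samplingRate of an evoked response
setMethod("samplingRate", "Evoked", function(x) x@sfreq)

#' @describeIn channelNames of a recording
setMethod("channelNames", "Recording", function(x) x@channels$name)
#' @describeIn channelNames of an epoch set
setMethod("channelNames", "EpochSet", function(x) x@channels$name)
#' @describeIn channelNames of an evoked response
setMethod("channelNames", "Evoked", function(x) x@channels$name)

#' @describeIn channelKinds of a recording
setMethod("channelKinds", "Recording", function(x) x@channels$kind)
#' @describeIn channelKinds of an epoch set
setMethod("channelKinds", "EpochSet", function(x) x@channels$kind)
#' @describeIn channelKinds of an evoked response
setMethod("channelKinds", "Evoked", function(x) x@channels$kind)

#' @describeIn channelInfo of a recording
setMethod("channelInfo", "Recording", function(x) x@channels)
#' @describeIn channelInfo of an epoch set
setMethod("channelInfo", "EpochSet", function(x) x@channels)
#' @describeIn channelInfo of an evoked response
setMethod("channelInfo", "Evoked", function(x) x@channels)

#' @describeIn dataMatrix channel-by-sample matrix of a recording
setMethod("dataMatrix", "Recording", function(x) x@data)
#' @describeIn dataMatrix epoch-by-channel-by-time array
setMethod("dataMatrix", "EpochSet", function(x) x@data)
#' @describeIn dataMatrix channel-by-time matrix of an evoked response
setMethod("dataMatrix", "Evoked", function(x) x@data)

#' @describeIn nComponents of a fitted ICA
setMethod("nComponents", "IcaModel", function(x) x@nIc)
#' @describeIn nComponents columns of the MI matrix
setMethod("nComponents", "MiMatrix", function(x) ncol(x@values))

#' @describeIn miValues matrix accessor
setMethod("miValues", "MiMatrix", function(x) x@values)

#' @describeIn selectedComponents elected set accessor
setMethod("selectedComponents", "SelectionResult", function(x) x@selectedIcs)

#' @describeIn confidentSelection empty when any quality flag is raised
setMethod("confidentSelection", "SelectionResult", function(x) {
  if (any(vapply(x@flags, isTRUE, logical(1)))) integer(0) else x@selectedIcs
})

#' @describeIn significantClusters summary restricted to `p < alpha`
setMethod("significantClusters", "ClusterTestResult", function(x, alpha = NULL) {
  if (is.null(alpha)) alpha <- x@alpha
  keep <- which(x@pValues < alpha)
  rows <- lapply(keep, function(id) {
    cells <- which(x@labels == id, arr.ind = TRUE)
    data.frame(cluster = id, mass = x@masses[id], p = x@pValues[id],
               n_channels = length(unique(cells[, 1])),
               t_start = min(x@times[cells[, 2]]),
               t_end = max(x@times[cells[, 2]]))
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(cluster = integer(0), mass = numeric(0), p = numeric(0),
                  n_channels = integer(0), t_start = numeric(0),
                  t_end = numeric(0))
})

setMethod("show", "Recording", function(object) {
  k <- table(factor(object@channels$kind, levels = CHANNEL_KINDS))
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s, %d run%s)\n",
              nChannels(object), nSamples(object), object@sfreq,
              nSamples(object) / object@sfreq, length(object@runStarts),
              if (length(object@runStarts) == 1) "" else "s"))
  cat("  channels:", paste(sprintf("%s=%d", names(k)[k > 0], k[k > 0]),
                           collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epochs x %d channels x %d times, window [%g, %g) s @ %g Hz\n",
              nEpochs(object), nChannels(object), dim(object@data)[3],
              object@tmin, object@tmax, object@sfreq))
})

setMethod("show", "Evoked", function(object) {
  cat(sprintf("Evoked: %d channels x %d times @ %g Hz, nave=%d, tmin=%g s\n",
              nChannels(object), nSamples(object), object@sfreq,
              object@nave, object@tmin))
})

setMethod("show", "Whitener", function(object) {
  cat(sprintf("Whitener: %d PCs retained (cumulative variance %.6f)\n",
              object@nPc, sum(object@explainedVarianceRatio[seq_len(object@nPc)])))
})

setMethod("show", "IcaModel", function(object) {
  cat(sprintf("IcaModel: %d components over %d channels (seed %d, %s in %d iter)\n",
              object@nIc, length(object@channelNames), object@seed,
              if (object@converged) "converged" else "NOT converged",
              object@nIter))
})

setMethod("show", "MiMatrix", function(object) {
  cat(sprintf("MiMatrix: %d rows (task x EMG-PC) x %d ICs, k=%d, max rho=%.3f\n",
              nrow(object@values), ncol(object@values), object@kNn,
              max(object@values)))
})

setMethod("show", "SelectionResult", function(object) {
  flg <- names(object@flags)[vapply(object@flags, isTRUE, logical(1))]
  cat(sprintf("SelectionResult: k=%d clusters over %d ICs; elected cluster %d -> ICs {%s}%s\n",
              object@kClusters, length(object@labels), object@selectedCluster,
              paste(sort(object@selectedIcs), collapse = ", "),
              if (length(flg)) paste0(" [flags: ", paste(flg, collapse = ", "), "]")
              else ""))
})

setMethod("show", "RmsdMap", function(object) {
  cat(sprintf("RmsdMap over %d gradiometer pairs, window [%g, %g] s; max=%.4f at pair %s\n",
              length(object@values), object@window[1], object@window[2],
              max(object@values), names(object@values)[which.max(object@values)]))
})

setMethod("show", "ClusterTestResult", function(object) {
  sig <- sum(object@pValues < object@alpha)
  cat(sprintf("ClusterTestResult: %d cluster(s), %d significant at alpha=%g (%d permutations)\n",
              length(object@masses), sig, object@alpha, object@nPermutations))
})
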