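#' Number of channels
#' @param x a [Recording-class], [EpochSet-class] or [Evoked-class]
#' @return integer
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of time samples
#' @param x a [Recording-class] or [Evoked-class]
#' @return integer
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Number of epochs
#' @param x an [EpochSet-class]
#' @return integer
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' Sampling frequency in Hz
#' @param x a data object with a time axis
#' @return numeric
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel names
#' @param x a data object carrying channel metadata
#' @return character vector
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Channel kinds (grad, mag, emg, eog, ecg, stim)
#' @param x a data object carrying channel metadata
#' @return character vector
#' @export
setGeneric("channelKinds", function(x) standardGeneric("channelKinds"))

#' Channel metadata table
#' @param x a data object carrying channel metadata
#' @return data.frame with columns name, kind, pair_id, pos_x, pos_y
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))

#' Raw data matrix / array
#' @param x a data object
#' @return the underlying numeric matrix or array
#' @export
setGeneric("dataMatrix", function(x) standardGeneric("dataMatrix"))

#' Number of independent components
#' @param x an [IcaModel-class] or [MiMatrix-class]
#' @return integer
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Component time courses of a fitted ICA applied to a recording
#'
#' @param ica an [IcaModel-class]
#' @param recording a [Recording-class] with the training channel set
#' @return numeric matrix `[n_ic x n_samples]`
#' @export
setGeneric("getSources", function(ica, recording) standardGeneric("getSources"))

#' Normalized MI values
#' @param x a [MiMatrix-class]
#' @return numeric matrix `[n_rows x n_ic]`
#' @export
setGeneric("miValues", function(x) standardGeneric("miValues"))

#' Components elected for removal
#' @param x a [SelectionResult-class]
#' @return integer component indices
#' @export
setGeneric("selectedComponents", function(x) standardGeneric("selectedComponents"))

#' Confidently elected components
#'
#' The elected set, or `integer(0)` when the selection carries a quality
#' warning (oversize, degenerate or low-contrast cluster) and should not be
#' trusted without inspection.
#' @param x a [SelectionResult-class]
#' @return integer component indices
#' @export
setGeneric("confidentSelection", function(x) standardGeneric("confidentSelection"))

#' RMS-combine planar-gradiometer pairs
#'
#' Per sensor element, the two orthogonal planar gradiometers a and b are
#' combined as `sqrt((a^2 + b^2) / 2)` at every time point, yielding one
#' non-negative channel per pair.
#' @param x an [Evoked-class] or [EpochSet-class] whose grad channels are all paired
#' @return an object of the same class with one channel per pair
#' @export
setGeneric("combineGradPairs", function(x) standardGeneric("combineGradPairs"))

#' Significant clusters of a permutation test
#' @param x a [ClusterTestResult-class]
#' @param alpha significance level; defaults to the level the test was run with
#' @return data.frame with cluster id, mass, p-value, channel and time extent
#' @export
setGeneric("significantClusters",
           function(x, alpha = NULL) standardGeneric("significantClusters"))
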