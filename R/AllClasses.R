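#' @useDynLib micica, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor kmeans prcomp qnorm qt quantile rnorm runif sd var
#' @importFrom utils head tail
NULL

CHANNEL_KINDS <- c("grad", "mag", "emg", "eog", "ecg", "stim")
EVENT_TASKS <- c("gesture", "vocal", "silent", "observation")
EVENT_LABELS <- c(paste0("G", 1:10), "picture")

validChannelTable <- function(ch) {
  msg <- character()
  need <- c("name", "kind", "pair_id", "pos_x", "pos_y")
  if (!is.data.frame(ch) || !all(need %in% names(ch)))
    return(sprintf("channels must be a data.frame with columns %s",
                   paste(need, collapse = ", ")))
  if (anyDuplicated(ch$name)) msg <- c(msg, "channel names must be unique")
  if (!all(ch$kind %in% CHANNEL_KINDS))
    msg <- c(msg, sprintf("channel kinds must be in {%s}",
                          paste(CHANNEL_KINDS, collapse = ", ")))
  grad <- ch[ch$kind == "grad", , drop = FALSE]
  if (nrow(grad) > 0) {
    if (anyNA(grad$pair_id)) {
      msg <- c(msg, "every grad channel needs a pair_id")
    } else {
      sizes <- table(grad$pair_id)
      if (!all(sizes == 2))
        msg <- c(msg, "each grad pair_id must group exactly two grad channels")
    }
  }
  if (length(msg)) msg else TRUE
}

#' Multichannel electrophysiological recording
#'
#' Continuous multichannel time series (rows = channels) with per-channel
#' metadata, a sampling rate and a time origin. Planar-gradiometer channels
#' carry a `pair_id` grouping the two orthogonal gradiometers of one sensor
#' element; `pos_x`/`pos_y` hold a flat sensor-layout coordinate used for
#' topographies and spatial adjacency. `runStarts` records the 0-based sample
#' index at which each concatenated run begins, so that epoching never
#' straddles a run seam.
#'
#' @slot data numeric matrix `[n_channels x n_samples]`; gradiometers in T/m,
#'   EMG in V.
#' @slot channels data.frame with columns `name`, `kind` (one of grad, mag,
#'   emg, eog, ecg, stim), `pair_id`, `pos_x`, `pos_y`.
#' @slot sfreq sampling frequency in Hz.
#' @slot firstSampleTime time of the first sample in seconds.
#' @slot runStarts integer vector of 0-based run start samples (first is 0).
#' @exportClass Recording
setClass("Recording",
  representation(data = "matrix", channels = "data.frame", sfreq = "numeric",
                 firstSampleTime = "numeric", runStarts = "integer"),
  prototype(firstSampleTime = 0, runStarts = 0L))

setValidity("Recording", function(object) {
  msg <- character()
  v <- validChannelTable(object@channels)
  if (!isTRUE(v)) msg <- c(msg, v)
  if (nrow(object@data) != nrow(object@channels))
    msg <- c(msg, "data row count must equal channel count")
  if (length(object@sfreq) != 1 || object@sfreq <= 0)
    msg <- c(msg, "sfreq must be a single positive number")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "data must be finite")
  if (length(object@runStarts) < 1 || object@runStarts[1] != 0L ||
      is.unsorted(object@runStarts, strictly = TRUE))
    msg <- c(msg, "runStarts must be strictly increasing and begin at 0")
  if (length(msg)) msg else TRUE
})

#' Set of fixed-length epochs extracted around events
#'
#' Epoch windows use the half-open convention `[tmin, tmax)` so that
#' `n_times = round((tmax - tmin) * sfreq)` exactly.
#'
#' @slot data numeric array `[n_epochs x n_channels x n_times]`.
#' @slot tmin,tmax window edges in seconds relative to the event onset.
#' @slot sfreq sampling frequency in Hz.
#' @slot channels channel metadata table (as in [Recording-class]).
#' @slot eventRefs integer row indices into the event table the epochs came from.
#' @slot baseline numeric length-2 baseline interval, or `numeric(0)` for none.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(data = "array", tmin = "numeric", tmax = "numeric",
                 sfreq = "numeric", channels = "data.frame",
                 eventRefs = "integer", baseline = "numeric"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3) return("data must be a 3-d array [epochs x channels x times]")
  nt <- round((object@tmax - object@tmin) * object@sfreq)
  if (d[3] != nt)
    msg <- c(msg, sprintf("n_times (%d) must equal round((tmax-tmin)*sfreq) = %d",
                          d[3], nt))
  if (d[2] != nrow(object@channels))
    msg <- c(msg, "channel dimension must match channel table")
  if (d[1] != length(object@eventRefs))
    msg <- c(msg, "eventRefs must have one entry per epoch")
  if (length(msg)) msg else TRUE
})

#' Averaged (evoked) response
#'
#' @slot data numeric matrix `[n_channels x n_times]`.
#' @slot nave number of epochs averaged (>= 1).
#' @slot tmin time of the first column in seconds.
#' @slot sfreq sampling frequency in Hz.
#' @slot channels channel metadata table.
#' @exportClass Evoked
setClass("Evoked",
  representation(data = "matrix", nave = "integer", tmin = "numeric",
                 sfreq = "numeric", channels = "data.frame"))

setValidity("Evoked", function(object) {
  msg <- character()
  if (object@nave < 1L) msg <- c(msg, "nave must be >= 1")
  if (nrow(object@data) != nrow(object@channels))
    msg <- c(msg, "data rows must match channel table")
  if (length(msg)) msg else TRUE
})

#' PCA pre-whitening transform
#'
#' Maps centred sensor data to `n_pc` unit-variance principal directions,
#' where `n_pc` is the smallest count whose cumulative explained-variance
#' ratio reaches the requested threshold (99.99% by default upstream).
#'
#' @slot mean per-channel mean removed before projection.
#' @slot projection matrix `[n_pc x n_channels]`; rows scaled so the whitened
#'   training output has unit variance.
#' @slot explainedVarianceRatio variance ratio of every principal direction.
#' @slot nPc number of retained components.
#' @exportClass Whitener
setClass("Whitener",
  representation(mean = "numeric", projection = "matrix",
                 explainedVarianceRatio = "numeric", nPc = "integer"))

#' Fitted ICA decomposition
#'
#' Holds the whitening transform plus the FastICA unmixing/mixing pair.
#' `unmixing %*% whiten(data)` yields unit-variance, decorrelated component
#' time courses; `mixing` maps components back to sensors.
#'
#' @slot whitener the [Whitener-class] fitted on the training data.
#' @slot unmixing matrix `[n_ic x n_pc]` (orthogonal in whitened space).
#' @slot mixing matrix `[n_channels x n_ic]`, the pseudo-inverse map to sensors.
#' @slot nIc number of components (equals `n_pc`).
#' @slot seed integer seed used for initialisation.
#' @slot converged logical convergence flag (honest; non-convergence warns).
#' @slot nIter iterations used.
#' @slot channelNames training channel names, checked on application.
#' @exportClass IcaModel
setClass("IcaModel",
  representation(whitener = "Whitener", unmixing = "matrix", mixing = "matrix",
                 nIc = "integer", seed = "integer", converged = "logical",
                 nIter = "integer", channelNames = "character"))

#' Principal components of the facial EMG channels
#'
#' Full (untruncated) PCA of the task-restricted EMG data: as many components
#' as channels, variance-ordered, mutually uncorrelated. A rotation only; no
#' variance scaling, which is immaterial for MI (invariant to monotone maps).
#'
#' @slot task task the EMG samples were restricted to.
#' @slot components matrix `[n_pc x n_samples]` of component time courses.
#' @slot loadings matrix `[n_channels x n_pc]` of PCA loadings.
#' @slot center per-channel means removed before rotation.
#' @exportClass EmgPcs
setClass("EmgPcs",
  representation(task = "character", components = "matrix",
                 loadings = "matrix", center = "numeric"))

#' Normalized mutual-information matrix
#'
#' Rows are (task, EMG principal component) pairs; columns are independent
#' components. Entries are the MI correlation coefficient
#' `rho = 1 - exp(-2 I)` of the Kraskov kNN mutual-information estimate,
#' so all values lie in `[0, 1)`.
#'
#' @slot values numeric matrix `[n_rows x n_ic]`.
#' @slot rowInfo data.frame with columns `task`, `emg_pc`.
#' @slot kNn neighbour count used by the estimator.
#' @exportClass MiMatrix
setClass("MiMatrix",
  representation(values = "matrix", rowInfo = "data.frame", kNn = "integer"))

setValidity("MiMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != nrow(object@rowInfo))
    msg <- c(msg, "rowInfo must describe every row")
  if (any(object@values < 0) || any(object@values >= 1))
    msg <- c(msg, "values must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Result of k-means artefact-component election
#'
#' Components are clustered on their MI profiles; the cluster with the highest
#' mean per-IC MI sum is elected, and all of its members are selected for
#' removal. `flags` carries quality warnings: `oversize` (elected cluster
#' holds more than a quarter of the ICs), `degenerate` (clustering collapsed),
#' `lowContrast` (elected cluster barely exceeds the remaining components).
#'
#' @slot kClusters number of clusters used.
#' @slot labels integer cluster label per IC.
#' @slot miSum per-IC sum of the normalized MI over matrix rows.
#' @slot selectedCluster elected cluster id.
#' @slot selectedIcs integer indices of the elected components.
#' @slot inertiaCurve named numeric, k-means inertia per candidate k (elbow).
#' @slot seed integer seed.
#' @slot flags named list of logical warning flags.
#' @slot provenance named list of resolved parameters and seeds.
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(kClusters = "integer", labels = "integer", miSum = "numeric",
                 selectedCluster = "integer", selectedIcs = "integer",
                 inertiaCurve = "numeric", seed = "integer", flags = "list",
                 provenance = "list"))

setValidity("SelectionResult", function(object) {
  sel <- which(object@labels == object@selectedCluster)
  if (!identical(sort(sel), sort(object@selectedIcs)))
    return("selectedIcs must be exactly the members of selectedCluster")
  TRUE
})

#' Ground truth of a simulated dataset
#'
#' @slot artefactTopographies matrix `[n_channels x n_artefact]`, unit-norm columns.
#' @slot artefactSources matrix `[n_artefact x n_samples]` of planted artefact
#'   time courses (high-frequency carriers amplitude-modulated by EMG envelopes).
#' @slot neuralTopographies,neuralSources the planted neural factors.
#' @slot emgToArtefactGains non-negative matrix `[n_emg x n_artefact]`.
#' @slot plantedIndices indices of the artefact sources (ground truth).
#' @exportClass SimulationTruth
setClass("SimulationTruth",
  representation(artefactTopographies = "matrix", artefactSources = "matrix",
                 neuralTopographies = "matrix", neuralSources = "matrix",
                 emgToArtefactGains = "matrix", plantedIndices = "integer"))

setValidity("SimulationTruth", function(object) {
  msg <- character()
  nrm <- sqrt(colSums(object@artefactTopographies^2))
  if (any(abs(nrm - 1) > 1e-8))
    msg <- c(msg, "artefact topography columns must be unit-norm")
  if (any(object@emgToArtefactGains < 0))
    msg <- c(msg, "EMG-to-artefact gains must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-gradiometer-pair RMSD map of removed evoked activity
#'
#' @slot values numeric RMSD per gradiometer pair (named by pair id).
#' @slot pairIds integer pair identifiers.
#' @slot window evaluation window in seconds.
#' @exportClass RmsdMap
setClass("RmsdMap",
  representation(values = "numeric", pairIds = "integer", window = "numeric"))

setValidity("RmsdMap", function(object) {
  if (any(object@values < 0)) "RMSD values must be non-negative" else TRUE
})

#' Sensor-level cluster-based permutation test result
#'
#' @slot labels integer matrix `[n_channels x n_times]`, 0 = sub-threshold,
#'   otherwise cluster id.
#' @slot masses signed summed statistic per cluster.
#' @slot pValues permutation p-value per cluster (includes the observed
#'   labelling, so the smallest attainable value is `1/(n_perm+1)`).
#' @slot nPermutations,alpha,clusterThreshold test parameters.
#' @slot channelNames,times the grid the test ran on.
#' @exportClass ClusterTestResult
setClass("ClusterTestResult",
  representation(labels = "matrix", masses = "numeric", pValues = "numeric",
                 nPermutations = "integer", alpha = "numeric",
                 clusterThreshold = "numeric", channelNames = "character",
                 times = "numeric"))
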