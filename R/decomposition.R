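#' Fit a PCA pre-whitening transform
#'
#' Retains the smallest number of principal components whose cumulative
#' explained-variance ratio reaches `varThreshold` (99.99% by default, chosen
#' to avoid information loss before ICA), and scales each retained direction
#' to unit variance. If the threshold would reach into numerically zero
#' directions, the projection is capped at the numerical rank with a warning.
#'
#' @param data numeric matrix `[n_channels x n_samples]`, `n_samples > n_channels`
#' @param varThreshold cumulative explained-variance target in (0, 1]
#' @return a [Whitener-class]
#' @export
fitWhitener <- function(data, varThreshold = 0.9999) {
  stopIfNot(ncol(data) > nrow(data),
            "need more samples (%d) than channels (%d)", ncol(data), nrow(data))
  mu <- rowMeans(data)
  x0 <- data - mu
  eg <- eigen(tcrossprod(x0) / (ncol(data) - 1), symmetric = TRUE)
  vars <- pmax(eg$values, 0)
  ratio <- vars / sum(vars)
  nPc <- which(cumsum(ratio) >= varThreshold - 1e-12)[1]
  if (is.na(nPc)) nPc <- length(ratio)
  rank <- sum(vars > max(vars) * 1e-20)
  if (nPc > rank) {
    warning(sprintf(
      "variance threshold %g unreachable at numerical rank %d; keeping %d PCs",
      varThreshold, rank, rank))
    nPc <- rank
  }
  proj <- diag(1 / sqrt(vars[seq_len(nPc)]), nPc) %*%
    t(eg$vectors[, seq_len(nPc), drop = FALSE])
  new("Whitener", mean = mu, projection = proj,
      explainedVarianceRatio = ratio, nPc = as.integer(nPc))
}

applyWhitener <- function(whitener, data) {
  whitener@projection %*% (data - whitener@mean)
}

#' Fit a FastICA decomposition
#'
#' Symmetric fixed-point FastICA with the log-cosh contrast on PCA-whitened
#' data. The number of components equals the number of retained principal
#' components. Deterministic given the seed; non-convergence returns the model
#' with `converged = FALSE` and a warning rather than silently retrying.
#'
#' For long recordings the fixed-point iterations run on a seeded uniform
#' subsample of `maxFitSamples` time points — far more than the decomposition
#' needs statistically — while the whitener and all source projections use
#' every sample.
#'
#' @param recording a [Recording-class] whose channels are all planar
#'   gradiometers, or a plain numeric matrix `[n_channels x n_samples]`
#' @param seed integer seed for the random orthogonal initialisation
#' @param varThreshold explained-variance threshold for pre-whitening
#' @param maxIter maximum fixed-point iterations
#' @param tol convergence tolerance on the unmixing update
#' @param maxFitSamples cap on the time points used by the iterations
#' @return an [IcaModel-class]
#' @export
fitIca <- function(recording, seed = 0L, varThreshold = 0.9999,
                   maxIter = 1000L, tol = 1e-4, maxFitSamples = 20000L) {
  if (is(recording, "Recording")) {
    stopIfNot(all(recording@channels$kind == "grad"),
              "ICA expects a gradiometer-only recording; use pickChannels()")
    x <- recording@data
    chn <- recording@channels$name
  } else {
    x <- recording
    chn <- if (is.null(rownames(x))) sprintf("ch%03d", seq_len(nrow(x)))
           else rownames(x)
  }
  wh <- fitWhitener(x, varThreshold)
  z <- applyWhitener(wh, x)
  nPc <- wh@nPc
  if (ncol(z) > maxFitSamples)
    z <- z[, withSeed(substreamSeed(seed, "ica-subsample"),
                      sort(sample(ncol(z), maxFitSamples))), drop = FALSE]

  w0 <- withSeed(substreamSeed(seed, "ica-init"), {
    qr.Q(qr(matrix(rnorm(nPc * nPc), nPc)))
  })
  fit <- fastica_core(z, w0, as.integer(maxIter), tol)
  w <- fit$W
  it <- fit$iter
  converged <- fit$converged
  if (!converged)
    warning(sprintf("FastICA did not converge in %d iterations", maxIter))

  # mixing: pseudo-inverse of (W %*% projection); with projection = D^-1/2 U'
  # and W orthogonal this is U D^1/2 W'.
  projPinv <- t(wh@projection) %*%
    solve(wh@projection %*% t(wh@projection))
  mixing <- projPinv %*% t(w)
  new("IcaModel", whitener = wh, unmixing = w, mixing = mixing,
      nIc = as.integer(nPc), seed = as.integer(seed), converged = converged,
      nIter = as.integer(it), channelNames = chn)
}

#' @describeIn getSources unmixing applied to a recording with the training
#'   channel set
setMethod("getSources", signature("IcaModel", "Recording"),
  function(ica, recording) {
    stopIfNot(identical(recording@channels$name, ica@channelNames),
              "recording channels do not match the ICA training channels")
    ica@unmixing %*% applyWhitener(ica@whitener, recording@data)
  })

#' @describeIn getSources unmixing applied to a raw channel-by-sample matrix
setMethod("getSources", signature("IcaModel", "matrix"),
  function(ica, recording) {
    stopIfNot(nrow(recording) == length(ica@channelNames),
              "matrix has %d rows; ICA was trained on %d channels",
              nrow(recording), length(ica@channelNames))
    ica@unmixing %*% applyWhitener(ica@whitener, recording)
  })

#' Project independent components out of a recording
#'
#' Reconstructs the sensor data from the non-excluded components (plus the
#' removed channel means). With an empty exclusion set this returns the
#' PCA-truncated original.
#'
#' @param recording a [Recording-class] with the ICA training channel set
#' @param ica an [IcaModel-class]
#' @param exclude integer indices of the components to remove
#' @return a cleaned [Recording-class] of the same shape
#' @export
removeComponents <- function(recording, ica, exclude = integer(0)) {
  exclude <- as.integer(exclude)
  stopIfNot(all(exclude >= 1 & exclude <= ica@nIc),
            "component indices must lie in 1..%d", ica@nIc)
  keep <- setdiff(seq_len(ica@nIc), exclude)
  stopIfNot(length(keep) > 0, "refusing to remove every component")
  s <- getSources(ica, recording)
  clean <- ica@mixing[, keep, drop = FALSE] %*% s[keep, , drop = FALSE] +
    ica@whitener@mean
  new("Recording", data = clean, channels = recording@channels,
      sfreq = recording@sfreq, firstSampleTime = recording@firstSampleTime,
      runStarts = recording@runStarts)
}

#' Principal components of the EMG channels
#'
#' Full PCA (one component per channel, no truncation) of task-restricted EMG
#' data: a variance-ordered rotation of the centred channels. No variance
#' scaling is applied; the kNN MI downstream is invariant to monotone
#' marginal maps, so rotation-only and whitened conventions select the same
#' components. An optional high-pass is available for recordings where the
#' EMG baseline drifts; off by default.
#'
#' @param emgRecording a [Recording-class] whose channels are all `emg`
#' @param task task name the samples were restricted to (bookkeeping)
#' @param sampleMask optional logical or integer index restricting the samples
#' @param highpassHz optional high-pass edge in Hz applied before the PCA
#' @return an [EmgPcs-class]
#' @export
emgPca <- function(emgRecording, task = "vocal", sampleMask = NULL,
                   highpassHz = NULL) {
  stopIfNot(all(emgRecording@channels$kind == "emg"),
            "emgPca expects an EMG-only recording; use pickChannels()")
  stopIfNot(nChannels(emgRecording) >= 2, "need at least two EMG channels")
  x <- emgRecording@data
  if (!is.null(highpassHz)) {
    wc <- highpassHz / (emgRecording@sfreq / 2)
    b <- as.numeric(signal::fir1(96, wc, type = "high"))
    x <- t(apply(x, 1, function(row) {
      y <- signal::filter(b, 1, c(row, rep(0, 48)))
      as.numeric(y[49:(48 + length(row))])
    }))
  }
  if (!is.null(sampleMask)) x <- x[, sampleMask, drop = FALSE]
  mu <- rowMeans(x)
  x0 <- x - mu
  sv <- svd(x0, nu = nrow(x0), nv = 0)
  if (any(sv$d < max(sv$d) * 1e-10))
    warning("near-constant EMG channel: zero-variance PC retained")
  comps <- t(sv$u) %*% x0
  new("EmgPcs", task = task, components = comps, loadings = sv$u, center = mu)
}
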