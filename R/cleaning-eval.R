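pairGroups <- function(channels) {
  stopIfNot(all(channels$kind == "grad"),
            "pair combination expects gradiometer-only data")
  stopIfNot(!anyNA(channels$pair_id), "all gradiometers must carry a pair_id")
  split(seq_len(nrow(channels)), channels$pair_id)
}

pairChannelTable <- function(channels) {
  groups <- pairGroups(channels)
  ids <- as.integer(names(groups))
  first <- vapply(groups, `[`, integer(1), 1)
  channelTable(sprintf("pair%03d", ids), "grad", pair_id = ids,
               pos_x = channels$pos_x[first], pos_y = channels$pos_y[first])
}

#' @describeIn combineGradPairs evoked response, one channel per pair
setMethod("combineGradPairs", "Evoked", function(x) {
  groups <- pairGroups(x@channels)
  out <- t(vapply(groups, function(idx) {
    stopIfNot(length(idx) == 2, "unpaired gradiometer channel")
    sqrt((x@data[idx[1], ]^2 + x@data[idx[2], ]^2) / 2)
  }, numeric(ncol(x@data))))
  dimnames(out) <- NULL
  new("Evoked", data = out, nave = x@nave, tmin = x@tmin, sfreq = x@sfreq,
      channels = pairChannelTable(x@channels))
})

#' @describeIn combineGradPairs epoch set, one channel per pair per epoch
setMethod("combineGradPairs", "EpochSet", function(x) {
  groups <- pairGroups(x@channels)
  d <- dim(x@data)
  out <- array(0, dim = c(d[1], length(groups), d[3]))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    stopIfNot(length(idx) == 2, "unpaired gradiometer channel")
    out[, g, ] <- sqrt((x@data[, idx[1], ]^2 + x@data[, idx[2], ]^2) / 2)
  }
  new("EpochSet", data = out, tmin = x@tmin, tmax = x@tmax, sfreq = x@sfreq,
      channels = pairChannelTable(x@channels), eventRefs = x@eventRefs,
      baseline = x@baseline)
})

#' Normalize an evoked response by its whole-head maximum
#'
#' Divides every value by the maximum absolute value over all channels and
#' time points. After pair combination all values are non-negative, so the
#' map's maximum becomes exactly 1. Idempotent and scale-invariant.
#'
#' @param evoked an [Evoked-class]
#' @return the normalized [Evoked-class]
#' @export
normalizeEvoked <- function(evoked) {
  m <- max(abs(evoked@data))
  stopIfNot(m > 0, "cannot normalize an all-zero evoked response")
  new("Evoked", data = evoked@data / m, nave = evoked@nave,
      tmin = evoked@tmin, sfreq = evoked@sfreq, channels = evoked@channels)
}

#' RMSD map between original and cleaned evoked responses
#'
#' Per gradiometer pair `ch`, over the `t` samples of the evaluation window:
#' `RMSD_ch = sqrt( sum_i (EVhat_i,ch - EV_i,ch)^2 / t )`, where `EVhat` is
#' the original and `EV` the artefact-free evoked response. Both inputs must
#' already be pair-combined and whole-head-normalized, in that order. Lower
#' values mean less removed evoked activity on that sensor element.
#'
#' @param evokedOrig,evokedClean pair-combined, normalized [Evoked-class]
#'   objects on the same grid
#' @param window evaluation window `c(start, end)` in seconds (inclusive)
#' @return an [RmsdMap-class]
#' @export
rmsdMap <- function(evokedOrig, evokedClean, window = c(0, 1.5)) {
  stopIfNot(identical(dim(evokedOrig@data), dim(evokedClean@data)) &&
              identical(evokedOrig@channels$name, evokedClean@channels$name) &&
              evokedOrig@sfreq == evokedClean@sfreq &&
              evokedOrig@tmin == evokedClean@tmin,
            "evoked responses must share channels, sfreq and time grid")
  times <- evokedOrig@tmin +
    (seq_len(ncol(evokedOrig@data)) - 1) / evokedOrig@sfreq
  idx <- which(times >= window[1] & times <= window[2])
  stopIfNot(length(idx) > 0, "evaluation window contains no samples")
  diff <- evokedOrig@data[, idx, drop = FALSE] -
    evokedClean@data[, idx, drop = FALSE]
  vals <- sqrt(rowSums(diff^2) / length(idx))
  ids <- evokedOrig@channels$pair_id
  new("RmsdMap", values = stats::setNames(vals, as.character(ids)),
      pairIds = as.integer(ids), window = as.numeric(window))
}

#' Scale epochs individually to unit maximum
#'
#' Each epoch is divided by its own maximum absolute value over all channels
#' and time points (applied after pair combination, where values are
#' non-negative, this scales each epoch into `[0, 1]`). Zero-valued epochs
#' are dropped with a warning.
#'
#' @param epochs an [EpochSet-class]
#' @return the scaled [EpochSet-class]
#' @export
scaleEpochsUnit <- function(epochs) {
  n <- nEpochs(epochs)
  maxima <- vapply(seq_len(n), function(i) max(abs(epochs@data[i, , ])),
                   numeric(1))
  keep <- maxima > 0
  if (any(!keep))
    warning(sprintf("%d zero-valued epoch(s) dropped before scaling",
                    sum(!keep)))
  dat <- epochs@data[keep, , , drop = FALSE]
  for (i in seq_len(sum(keep))) dat[i, , ] <- dat[i, , ] / maxima[keep][i]
  new("EpochSet", data = dat, tmin = epochs@tmin, tmax = epochs@tmax,
      sfreq = epochs@sfreq, channels = epochs@channels,
      eventRefs = epochs@eventRefs[keep], baseline = epochs@baseline)
}

#' Spatial adjacency from the sensor layout
#'
#' Channels are neighbours when their layout positions are within `maxDist`.
#'
#' @param channels a channel metadata table with `pos_x`, `pos_y`
#' @param maxDist neighbourhood radius in layout units
#' @return list of 1-based neighbour index vectors, one per channel
#' @export
layoutAdjacency <- function(channels, maxDist = 1.01) {
  pos <- cbind(channels$pos_x, channels$pos_y)
  stopIfNot(!anyNA(pos), "layout positions required for adjacency")
  d <- as.matrix(stats::dist(pos))
  lapply(seq_len(nrow(pos)), function(i) {
    nb <- which(d[i, ] <= maxDist)
    as.integer(setdiff(nb, i))
  })
}

pointwiseT <- function(a, b, paired) {
  if (paired) {
    d <- a - b
    n <- nrow(d)
    m <- colMeans(d)
    v <- (colSums(d^2) - n * m^2) / (n - 1)
    m / sqrt(v / n)
  } else {
    nA <- nrow(a); nB <- nrow(b)
    mA <- colMeans(a); mB <- colMeans(b)
    vA <- (colSums(a^2) - nA * mA^2) / (nA - 1)
    vB <- (colSums(b^2) - nB * mB^2) / (nB - 1)
    sp <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    (mA - mB) / sqrt(sp * (1 / nA + 1 / nB))
  }
}

#' Sensor-level cluster-based permutation test
#'
#' Pointwise t statistics (paired across matched epochs, or pooled-variance
#' two-sample) are thresholded at the two-sided t quantile for
#' `clusterAlpha`; supra-threshold (channel, time) cells of equal sign are
#' merged into clusters under the spatial adjacency crossed with temporal
#' contiguity, and each cluster's mass is its summed statistic. The null
#' distribution is the maximum absolute cluster mass over label permutations
#' (sign flips for the paired design), and
#' `p = (1 + #(null >= observed)) / (nPerm + 1)` — the observed labelling is
#' included so p can never reach zero. A cluster is significant when
#' `p < alpha`.
#'
#' @param epochsA,epochsB [EpochSet-class] objects on the same grid; for the
#'   paired design the epochs must be matched in order
#' @param adjacency channel adjacency list, or `NULL` to derive it from the
#'   layout via [layoutAdjacency()]
#' @param nPerm number of permutations
#' @param alpha cluster significance level
#' @param clusterAlpha two-sided cluster-forming threshold level
#' @param paired use the paired (sign-flip) design
#' @param seed integer seed for the permutations
#' @return a [ClusterTestResult-class]
#' @export
clusterPermutationTest <- function(epochsA, epochsB, adjacency = NULL,
                                   nPerm = 1000L, alpha = 0.05,
                                   clusterAlpha = 0.05, paired = FALSE,
                                   seed = 0L) {
  stopIfNot(nPerm >= 1, "need at least one permutation")
  stopIfNot(identical(dim(epochsA@data)[2:3], dim(epochsB@data)[2:3]) &&
              identical(epochsA@channels$name, epochsB@channels$name),
            "epoch sets must share the channel/time grid")
  if (is.null(adjacency)) adjacency <- layoutAdjacency(epochsA@channels)
  stopIfNot(length(adjacency) == dim(epochsA@data)[2],
            "adjacency must cover every channel")
  nch <- dim(epochsA@data)[2]; nt <- dim(epochsA@data)[3]
  flat <- function(e) {
    d <- e@data
    dim(d) <- c(dim(d)[1], nch * nt)
    d
  }
  a <- flat(epochsA); b <- flat(epochsB)

  if (paired) {
    stopIfNot(nrow(a) == nrow(b), "paired design needs matched epoch counts")
    n <- nrow(a)
    thr <- qt(1 - clusterAlpha / 2, df = n - 1)
  } else {
    thr <- qt(1 - clusterAlpha / 2, df = nrow(a) + nrow(b) - 2)
  }

  tobs <- pointwiseT(a, b, paired)
  tmat <- matrix(tobs, nch, nt)
  lab <- cluster_label_cpp(tmat, thr, adjacency)
  masses <- lab$masses

  nullMax <- withSeed(substreamSeed(seed, "perm"), {
    vapply(seq_len(nPerm), function(p) {
      if (paired) {
        s <- sample(c(-1, 1), nrow(a), replace = TRUE)
        d <- (a - b) * s
        n <- nrow(d)
        m <- colMeans(d)
        v <- (colSums(d^2) - n * m^2) / (n - 1)
        tp <- m / sqrt(v / n)
      } else {
        pool <- rbind(a, b)
        idx <- sample(nrow(pool), nrow(a))
        tp <- pointwiseT(pool[idx, , drop = FALSE],
                         pool[-idx, , drop = FALSE], FALSE)
      }
      tp[!is.finite(tp)] <- 0
      max_cluster_mass_cpp(matrix(tp, nch, nt), thr, adjacency)
    }, numeric(1))
  })

  pvals <- vapply(masses, function(m) {
    (1 + sum(nullMax >= abs(m))) / (nPerm + 1)
  }, numeric(1))

  times <- epochsA@tmin + (seq_len(nt) - 1) / epochsA@sfreq
  new("ClusterTestResult", labels = lab$labels, masses = masses,
      pValues = pvals, nPermutations = as.integer(nPerm), alpha = alpha,
      clusterThreshold = thr, channelNames = epochsA@channels$name,
      times = times)
}

#' Evaluate artefact removal on the vocal and silent naming tasks
#'
#' Projects the elected components out of the gradiometer data, then, for the
#' vocal and the silent naming task separately: extracts picture epochs over
#' the evaluation window, averages them, pair-combines and normalizes the
#' evoked responses, computes the RMSD map of removed evoked activity, and
#' runs the sensor-level cluster permutation test (paired across epochs,
#' per-epoch unit scaling) between the original and cleaned data. A
#' successful removal shows significant vocal-task differences and none in
#' the silent task.
#'
#' @param dataset a dataset list as returned by [generateDataset()] or read
#'   from fixtures
#' @param selection result of [selectArtefacts()] (list with `selection` and
#'   `ica`)
#' @param params optional overrides: `epochWindow`, `nPerm`, `alphaSensor`,
#'   `clusterAlpha`, `seed`
#' @return a report list with per-task evoked responses, [RmsdMap-class],
#'   [ClusterTestResult-class], and summary flags `vocalSignificant`,
#'   `silentSignificant`
#' @export
evaluateRemoval <- function(dataset, selection, params = list()) {
  p <- utils::modifyList(list(epochWindow = c(0, 1.5), nPerm = 1000L,
                              alphaSensor = 0.001, clusterAlpha = 0.05,
                              seed = dataset$seed %||% 0L), params)
  grads <- pickChannels(dataset$meg, "grad")
  excl <- selectedComponents(selection$selection)
  clean <- if (length(excl)) removeComponents(grads, selection$ica, excl)
           else grads

  evalTask <- function(task) {
    eo <- extractEpochs(grads, dataset$events, p$epochWindow[1],
                        p$epochWindow[2], labels = "picture", tasks = task)
    ec <- extractEpochs(clean, dataset$events, p$epochWindow[1],
                        p$epochWindow[2], labels = "picture", tasks = task)
    evokedO <- normalizeEvoked(combineGradPairs(averageEpochs(eo)))
    evokedC <- normalizeEvoked(combineGradPairs(averageEpochs(ec)))
    rmsd <- rmsdMap(evokedO, evokedC, p$epochWindow)
    # independent-samples design on the pair-combined, per-epoch-scaled
    # amplitudes: artefact removal shows up as a group-level amplitude
    # reduction, while a paired design on rectified data would flag any
    # removal as a trivially systematic decrease
    test <- clusterPermutationTest(
      scaleEpochsUnit(combineGradPairs(eo)),
      scaleEpochsUnit(combineGradPairs(ec)),
      nPerm = p$nPerm, alpha = p$alphaSensor,
      clusterAlpha = p$clusterAlpha, paired = FALSE,
      seed = substreamSeed(p$seed, paste0("eval-", task)))
    list(evokedOriginal = evokedO, evokedClean = evokedC, rmsd = rmsd,
         test = test,
         significant = any(test@pValues < p$alphaSensor))
  }

  vocal <- evalTask("vocal")
  silent <- evalTask("silent")
  list(vocal = vocal, silent = silent,
       vocalSignificant = vocal$significant,
       silentSignificant = silent$significant,
       removed = excl, params = p)
}
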