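#' Kraskov k-nearest-neighbour mutual information
#'
#' Estimates `I(x; y)` in nats with the Kraskov-Stoegbauer-Grassberger
#' estimator (algorithm 1): `I = psi(k) + psi(n) - <psi(n_x + 1) + psi(n_y + 1)>`
#' with Chebyshev-ball neighbour counts. Inputs are jittered by a seeded
#' infinitesimal amount to break ties, then rank-transformed to marginal
#' normality (standard practice for this estimator family; MI is invariant to
#' strictly monotone marginal maps, and the transform stabilises the
#' neighbourhood geometry). Estimates are clipped below at zero.
#'
#' @param x,y numeric sample vectors of equal length `n > kNn`
#' @param kNn number of neighbours (3, the customary default)
#' @param rankNormal apply the rank-to-normal marginal transform (default TRUE)
#' @param seed seed for the tie-breaking jitter
#' @return the MI estimate in nats (non-negative)
#' @export
#' @examples
#' withr <- function(s, e) e  # illustrative; estimator is deterministic given seed
#' x <- stats::rnorm(2000); y <- 0.9 * x + sqrt(1 - 0.81) * stats::rnorm(2000)
#' knnMi(x, y)  # close to -0.5 * log(1 - 0.81)
knnMi <- function(x, y, kNn = 3L, rankNormal = TRUE, seed = 0L) {
  n <- length(x)
  stopIfNot(length(y) == n, "x and y must have equal length")
  stopIfNot(n > kNn, "need more than kNn = %d samples (got %d)", kNn, n)
  stopIfNot(all(is.finite(x)) && all(is.finite(y)), "inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input; MI is 0 by convention")
    return(0)
  }
  jit <- withSeed(substreamSeed(seed, "mi-jitter"),
                  list(runif(n, 0, 1e-9), runif(n, 0, 1e-9)))
  xj <- x + sd(x) * jit[[1]]
  yj <- y + sd(y) * jit[[2]]
  if (rankNormal) {
    xj <- qnorm((rank(xj) - 0.5) / n)
    yj <- qnorm((rank(yj) - 0.5) / n)
  }
  max(0, ksg_mi_cpp(xj, yj, as.integer(kNn)))
}

#' MI correlation coefficient
#'
#' Normalizes a mutual-information value (nats) to `[0, 1)` as
#' `rho = 1 - exp(-2 I)`: zero iff `I = 0`, strictly increasing, approaching
#' 1 as `I` grows. Negative inputs (estimator noise) are clipped to zero with
#' a warning. `sqrtCompat = TRUE` gives the textbook information correlation
#' coefficient `sqrt(1 - exp(-2 I))`; the two are monotone-equivalent, so the
#' downstream component election is unaffected by the choice.
#'
#' @param I mutual information in nats (vectorized)
#' @param sqrtCompat use the square-root form
#' @return values in `[0, 1)`
#' @export
miCoefficient <- function(I, sqrtCompat = FALSE) {
  if (any(I < 0)) {
    warning("negative MI estimate(s) clipped to 0")
    I <- pmax(I, 0)
  }
  rho <- 1 - exp(-2 * I)
  if (sqrtCompat) sqrt(rho) else rho
}

#' Build the normalized MI matrix
#'
#' One value per (task, EMG principal component) row and independent-component
#' column: `rho = miCoefficient(knnMi(ic, emg_pc))` on the task-restricted,
#' sample-aligned series. Long series are capped by seeded uniform
#' subsampling for tractability.
#'
#' @param sourcesByTask named list: task -> IC time courses `[n_ic x n_samples]`
#' @param emgPcsByTask named list: task -> [EmgPcs-class] on the same samples
#' @param kNn neighbour count for the MI estimator
#' @param maxSamples subsampling cap per task
#' @param seed seed for subsampling and tie-breaking
#' @return a [MiMatrix-class] with rows grouped by task
#' @export
buildMiMatrix <- function(sourcesByTask, emgPcsByTask, kNn = 3L,
                          maxSamples = 20000L, seed = 0L) {
  tasks <- names(emgPcsByTask)
  stopIfNot(length(tasks) > 0 && all(tasks %in% names(sourcesByTask)),
            "every EMG task must have matching IC sources")
  rows <- list(); info <- list()
  nIc <- nrow(sourcesByTask[[tasks[1]]])
  for (task in tasks) {
    src <- sourcesByTask[[task]]
    pcs <- emgPcsByTask[[task]]@components
    stopIfNot(ncol(src) == ncol(pcs),
              "task '%s': IC sources (%d) and EMG PCs (%d) are not sample-aligned",
              task, ncol(src), ncol(pcs))
    stopIfNot(nrow(src) == nIc, "IC count differs between tasks")
    idx <- seq_len(ncol(src))
    if (length(idx) > maxSamples)
      idx <- withSeed(substreamSeed(seed, paste0("mi-subsample-", task)),
                      sort(sample(length(idx), maxSamples)))
    for (j in seq_len(nrow(pcs))) {
      vals <- vapply(seq_len(nIc), function(i) {
        suppressWarnings(
          miCoefficient(knnMi(src[i, idx], pcs[j, idx], kNn = kNn, seed = seed)))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- vals
      info[[length(info) + 1L]] <- data.frame(task = task, emg_pc = j)
    }
  }
  new("MiMatrix", values = do.call(rbind, rows),
      rowInfo = do.call(rbind, info), kNn = as.integer(kNn))
}

bestKmeans <- function(x, k, nStart, seed, label) {
  withSeed(substreamSeed(seed, label),
           suppressWarnings(kmeans(x, centers = k, nstart = nStart,
                                   iter.max = 200)))
}

#' Cluster components on their MI against the EMG and elect the artefact set
#'
#' Each IC's `mi_sum` is its summed normalized MI over all (task, EMG-PC)
#' rows; components are clustered by k-means (best of `nStart` seeded
#' initialisations), the cluster with the highest mean `mi_sum` is elected,
#' and all of its members are selected for removal. Ties are broken by the
#' higher maximum `mi_sum`, then the lower cluster id.
#'
#' By default the k-means feature is the scalar `mi_sum` itself
#' (`features = "sum"`): artefactual components separate from the brain
#' components along this one ordering, and a shared cluster tolerates the
#' moderate differences in how individual artefact sources couple to the four
#' EMG channels. `features = "profile"` instead clusters the full per-IC MI
#' row vectors; that variant is stricter about profile shape and tends to
#' fragment a multi-component artefact family into singleton clusters, so it
#' is offered for diagnostics rather than as the default.
#'
#' Quality flags: `oversize` when the elected cluster holds more than a
#' quarter of the ICs (in practice a removal of more than a handful of
#' components signals a failed selection), `degenerate` when the features
#' cannot support `kClusters` distinct clusters, `lowContrast` when the
#' elected cluster's mean `mi_sum` is less than twice that of the remaining
#' components (no clearly artefactual cluster, e.g. artefact-free data).
#'
#' @param miMatrix a [MiMatrix-class]
#' @param kClusters number of clusters (>= 2)
#' @param seed seed for the k-means initialisations
#' @param nStart number of k-means restarts
#' @param sumRaw sum raw MI (nats) instead of normalized rho for `mi_sum`
#' @param features cluster on the scalar `"sum"` (default) or the full MI
#'   `"profile"` vectors
#' @return a [SelectionResult-class]
#' @export
clusterComponents <- function(miMatrix, kClusters = 5L, seed = 0L,
                              nStart = 10L, sumRaw = FALSE,
                              features = c("sum", "profile")) {
  features <- match.arg(features)
  stopIfNot(kClusters >= 2, "kClusters must be >= 2")
  vals <- miMatrix@values
  nIc <- ncol(vals)
  stopIfNot(nIc >= kClusters, "need at least kClusters ICs (have %d)", nIc)
  miSum <- if (sumRaw) colSums(-0.5 * log1p(-vals)) else colSums(vals)
  feats <- if (features == "sum") matrix(miSum, ncol = 1) else t(vals)

  flags <- list(oversize = FALSE, degenerate = FALSE, lowContrast = FALSE)
  nDistinct <- nrow(unique(feats))
  if (nDistinct < kClusters) {
    warning(sprintf(
      "only %d distinct MI profiles for k=%d clusters; degenerate selection",
      nDistinct, kClusters))
    flags$degenerate <- TRUE
    labels <- rep(1L, nIc)
    selCluster <- 1L
    inertia <- c(`1` = sum(scale(feats, scale = FALSE)^2))
  } else {
    km <- bestKmeans(feats, kClusters, nStart, seed, "kmeans")
    labels <- as.integer(km$cluster)
    means <- vapply(seq_len(kClusters), function(c) mean(miSum[labels == c]),
                    numeric(1))
    top <- which(means == max(means))
    if (length(top) > 1) {
      mx <- vapply(top, function(c) max(miSum[labels == c]), numeric(1))
      top <- top[mx == max(mx)]
    }
    selCluster <- as.integer(min(top))
    inertia <- stats::setNames(km$tot.withinss, as.character(kClusters))
  }
  selected <- which(labels == selCluster)
  if (length(selected) > 0.25 * nIc) {
    warning(sprintf(
      "elected cluster holds %d of %d ICs (> 25%%); selection likely failed",
      length(selected), nIc))
    flags$oversize <- TRUE
  }
  # a credible artefact cluster is separated from the best remaining
  # component by a clear margin; without planted artefacts the elected
  # cluster is just the top of the continuum of ordinary components
  rest <- setdiff(seq_len(nIc), selected)
  if (length(rest) > 0 && min(miSum[selected]) < 1.5 * max(miSum[rest]))
    flags$lowContrast <- TRUE

  new("SelectionResult", kClusters = as.integer(kClusters), labels = labels,
      miSum = miSum, selectedCluster = selCluster,
      selectedIcs = as.integer(selected), inertiaCurve = inertia,
      seed = as.integer(seed), flags = flags,
      provenance = list(kNn = miMatrix@kNn, nStart = nStart, sumRaw = sumRaw,
                        features = features))
}

#' Elbow curve of k-means inertia over candidate cluster counts
#'
#' Inertia (total within-cluster sum of squares) per `k`, used to confirm the
#' cluster count. The curve is non-increasing in `k` up to k-means
#' local-optimum noise; when an inversion appears the fit is retried with more
#' restarts.
#'
#' @param miMatrix a [MiMatrix-class]
#' @param kRange candidate cluster counts (capped at the number of ICs)
#' @param seed seed for the k-means initialisations
#' @param nStart restarts per k
#' @param features feature space, as in [clusterComponents()]
#' @return named numeric vector, inertia per k
#' @export
elbowCurve <- function(miMatrix, kRange = 2:20, seed = 0L, nStart = 10L,
                       features = c("sum", "profile")) {
  features <- match.arg(features)
  feats <- if (features == "sum") matrix(colSums(miMatrix@values), ncol = 1)
           else t(miMatrix@values)
  nIc <- nrow(feats)
  kRange <- kRange[kRange <= nIc]
  stopIfNot(length(kRange) > 0, "no feasible k in kRange (n_ic = %d)", nIc)
  out <- numeric(length(kRange))
  prev <- Inf
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    if (k == nIc) {
      out[i] <- 0
    } else {
      km <- bestKmeans(feats, k, nStart, seed, paste0("elbow-", k))
      if (km$tot.withinss > prev) {
        km2 <- bestKmeans(feats, k, 5L * nStart, seed, paste0("elbow-retry-", k))
        if (km2$tot.withinss < km$tot.withinss) km <- km2
      }
      out[i] <- km$tot.withinss
    }
    prev <- out[i]
  }
  stats::setNames(out, as.character(kRange))
}
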