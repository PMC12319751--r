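test_that("kNN MI matches closed forms and detects independence", {
  withSeed(1, {
    x <- rnorm(5000)
    y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(5000)
    u <- rnorm(5000); v <- rnorm(5000)
  })
  expect_lt(abs(knnMi(x, y) - (-0.5 * log(1 - 0.81))), 0.05)
  expect_lt(abs(knnMi(u, v)), 0.02)
})

test_that("kNN MI is invariant to strictly monotone marginal transforms", {
  withSeed(2, {
    x <- rnorm(3000)
    y <- x^3 + 0.5 * rnorm(3000)
  })
  base <- knnMi(x, y)
  warped <- knnMi(exp(x), sign(y) * abs(y)^1.7)
  expect_lt(abs(base - warped), 0.05)
  # rank-transformed estimates are exactly equal, not just close
  expect_equal(knnMi(exp(x), y), knnMi(x, y))
})

test_that("kNN MI agrees with the exact plug-in MI on discrete data", {
  withSeed(3, {
    xl <- sample(1:8, 6000, TRUE)
    yl <- (xl + sample(0:2, 6000, TRUE)) %% 8
  })
  expect_lt(abs(knnMi(xl, yl) - plugInMi(xl, yl)), 0.05)
})

test_that("kNN MI validates input and degrades gracefully", {
  expect_error(knnMi(1:10, 1:9), "equal length")
  expect_error(knnMi(1:3, 1:3, kNn = 3), "more than")
  expect_error(knnMi(c(1, NA, 3, 4, 5), c(1, 2, 3, 4, 5)), "finite")
  expect_warning(I0 <- knnMi(rep(1, 100), rnorm(100)), "constant")
  expect_equal(I0, 0)
  expect_gte(knnMi(rnorm(200), rnorm(200), seed = 1), 0)
})

test_that("the MI correlation coefficient follows its analytic form", {
  expect_equal(miCoefficient(0), 0)
  expect_equal(miCoefficient(log(2) / 2), 0.5)
  grid <- seq(0, 8, by = 0.25)
  rho <- miCoefficient(grid)
  expect_true(all(diff(rho) > 0))
  expect_true(all(rho >= 0 & rho < 1))
  expect_lt(1 - miCoefficient(20), 1e-15)
  expect_warning(z <- miCoefficient(-0.1), "clipped")
  expect_equal(z, 0)
  expect_equal(miCoefficient(log(2) / 2, sqrtCompat = TRUE), sqrt(0.5))
})

test_that("the MI matrix has one row per task and EMG component", {
  ds <- cachedDataset("GN", 1)
  res <- suppressWarnings(selectArtefacts(ds, "GN",
                                          params = list(maxMiSamples = 4000L)))
  expect_equal(nrow(miValues(res$miMatrix)), 8)   # 2 tasks x 4 EMG PCs
  expect_equal(ncol(miValues(res$miMatrix)), nComponents(res$ica))
  expect_equal(res$miMatrix@rowInfo$task, rep(c("gesture", "vocal"), each = 4))
  expect_true(all(miValues(res$miMatrix) >= 0 & miValues(res$miMatrix) < 1))
  # planted artefact columns carry the row maxima
  m <- matchPlantedComponents(res$ica, ds$truth)
  best <- apply(miValues(res$miMatrix), 1, which.max)
  expect_true(all(best %in% m$ic))
  # the N variant uses vocal rows only
  resN <- suppressWarnings(selectArtefacts(ds, "N",
                                           params = list(maxMiSamples = 4000L)))
  expect_equal(nrow(miValues(resN$miMatrix)), 4)
  expect_equal(unique(resN$miMatrix@rowInfo$task), "vocal")
})

test_that("misaligned task series are rejected", {
  pcs <- new("EmgPcs", task = "vocal",
             components = matrix(rnorm(40), 4), loadings = diag(4),
             center = rep(0, 4))
  expect_error(buildMiMatrix(list(vocal = matrix(rnorm(45), 3)),
                             list(vocal = pcs)),
               "not sample-aligned")
})

test_that("clustering elects the clearly artefactual components", {
  withSeed(5, {
    vals <- matrix(runif(8 * 20, 0, 0.1), 8, 20)
    vals[, c(4, 17)] <- 0.9 + matrix(runif(16, -0.005, 0.005), 8, 2)
  })
  mi <- new("MiMatrix", values = vals,
            rowInfo = data.frame(task = rep(c("gesture", "vocal"), each = 4),
                                 emg_pc = rep(1:4, 2)), kNn = 3L)
  for (k in 2:5) {
    sel <- clusterComponents(mi, kClusters = k, seed = 1)
    expect_setequal(selectedComponents(sel), c(4L, 17L))
    expect_false(sel@flags$lowContrast)
  }
  expect_error(clusterComponents(mi, kClusters = 1), ">= 2")
  expect_error(clusterComponents(mi, kClusters = 25), "at least")
})

test_that("degenerate and oversize selections are flagged, not hidden", {
  flat <- new("MiMatrix", values = matrix(0.2, 4, 10),
              rowInfo = data.frame(task = "vocal", emg_pc = 1:4), kNn = 3L)
  w <- testthat::capture_warnings(sel <- clusterComponents(flat, seed = 1))
  expect_true(any(grepl("degenerate", w)))
  expect_true(sel@flags$degenerate)
  expect_length(confidentSelection(sel), 0)
  # more than a quarter of the ICs elected -> oversize warning
  withSeed(6, {
    vals <- matrix(runif(4 * 12, 0, 0.4), 4, 12)
    vals[, 1:6] <- 0.85 + matrix(runif(24, -0.005, 0.005), 4, 6)
  })
  wide <- new("MiMatrix", values = vals,
              rowInfo = data.frame(task = "vocal", emg_pc = 1:4), kNn = 3L)
  expect_warning(sel2 <- clusterComponents(wide, seed = 1), "oversize|25%")
  expect_true(sel2@flags$oversize)
  expect_setequal(selectedComponents(sel2), 1:6)
})

test_that("component election is stable under the rho/raw-I choice", {
  # the elected set does not depend on whether mi_sum aggregates the
  # normalized coefficient or the raw information (monotone equivalence on
  # clearly separated data)
  withSeed(7, {
    vals <- matrix(runif(8 * 15, 0, 0.3), 8, 15)
    vals[, c(2, 9, 11)] <- matrix(runif(24, 0.7, 0.9), 8, 3)
  })
  mi <- new("MiMatrix", values = vals,
            rowInfo = data.frame(task = rep(c("gesture", "vocal"), each = 4),
                                 emg_pc = rep(1:4, 2)), kNn = 3L)
  a <- clusterComponents(mi, seed = 3)
  b <- clusterComponents(mi, seed = 3, sumRaw = TRUE)
  expect_setequal(selectedComponents(a), selectedComponents(b))
})

test_that("elbow inertia is non-increasing and hits zero at k = n", {
  withSeed(8, vals <- matrix(runif(4 * 12), 4, 12))
  mi <- new("MiMatrix", values = vals,
            rowInfo = data.frame(task = "vocal", emg_pc = 1:4), kNn = 3L)
  for (s in 1:3) {
    curve <- elbowCurve(mi, kRange = 2:12, seed = s)
    expect_true(all(diff(curve) <= 1e-9))
    expect_equal(unname(curve["12"]), 0)
  }
  # two tight separated blobs: the k=1 -> 2 drop dominates, flat after
  blob <- cbind(matrix(rnorm(4 * 6, 0, 0.01), 4), matrix(rnorm(4 * 6, 5, 0.01), 4))
  blob <- (blob - min(blob)) / (max(blob) - min(blob)) * 0.9
  mib <- new("MiMatrix", values = blob,
             rowInfo = data.frame(task = "vocal", emg_pc = 1:4), kNn = 3L)
  cv <- elbowCurve(mib, kRange = c(1, 2, 3, 4), seed = 1)
  expect_gt(cv["1"] / max(cv["2"], 1e-12), 100)
})

test_that("variant contracts: GN needs gesture data, N runs without it", {
  nOnly <- cachedDataset("N", 1)
  expect_error(selectArtefacts(nOnly, "GN"), "gesture")
  res <- suppressWarnings(selectArtefacts(nOnly, "N",
                                          params = list(maxMiSamples = 4000L)))
  expect_s4_class(res$selection, "SelectionResult")
})

test_that("artefact-free data yield no confident selection", {
  ds <- generateDataset("null", seed = 5)
  res <- suppressWarnings(selectArtefacts(ds, "GN",
                                          params = list(maxMiSamples = 4000L)))
  expect_true(any(unlist(res$selection@flags)))
  expect_length(confidentSelection(res$selection), 0)
})
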