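test_that("depth profiles enforce ordering and expose fits", {
  p <- syntheticProfile(c(0, 50, 100), aBar = c(6, 5, 4))
  expect_s4_class(p, "DepthProfile")
  expect_equal(depths(p), c(0, 50, 100))
  expect_equal(fits(p)$a_bar, c(6, 5, 4))
  expect_error(syntheticProfile(c(0, 100, 50), aBar = 1), "increasing")
})

test_that("depth binning summarizes alignment and orientations per 100-um bin", {
  # one record per bin
  p <- syntheticProfile(c(20, 150, 250), aBar = c(6, 6, 5))
  b <- binByDepth(p, 100)
  expect_equal(b$bin_lo_um, c(0, 100, 200))
  expect_equal(b$a_bar_mean, c(6, 6, 5))
  # two records in one bin: mean 3, sample SD with n-1 denominator
  p2 <- syntheticProfile(c(10, 60), aBar = c(2, 4))
  b2 <- binByDepth(p2, 100)
  expect_equal(b2$a_bar_mean, 3)
  expect_equal(b2$a_bar_sd, stats::sd(c(2, 4)))
  # axial angles average on the doubled circle, never to zero
  p3 <- syntheticProfile(c(10, 60), aBar = 3, alpha1 = c(85, -85),
                         alpha2 = c(-89, -89), w = 0.6)
  b3 <- binByDepth(p3, 100)
  expect_equal(abs(b3$alpha1_deg), 90)
  # isotropic records: counted in alignment (as zero), excluded from angles
  p4 <- syntheticProfile(c(10, 60), aBar = c(4, 0), alpha1 = 30, alpha2 = -30,
                         isotropic = c(FALSE, TRUE))
  b4 <- binByDepth(p4, 100)
  expect_equal(b4$n, 2L)
  expect_equal(b4$n_oriented, 1L)
  expect_equal(b4$a_bar_mean, 2)          # (4 + 0) / 2
  expect_equal(b4$alpha1_deg, 30)         # isotropic layer left out
  # record conservation across bins
  p5 <- syntheticProfile(seq(0, 440, by = 40), aBar = 2)
  expect_equal(sum(binByDepth(p5, 100)$n), 12L)
  expect_error(binByDepth(syntheticProfile(numeric(0), numeric(0)), 100),
               "empty")
})

test_that("bivariate depth correlation matches the direct formula", {
  directC <- function(X) {
    # element-wise evaluation of the correlation sum across samples
    n <- ncol(X)
    C <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      xi <- X[, i]; xj <- X[, j]
      num <- sum((xi - mean(xi)) * (xj - mean(xj)))
      den <- sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
      C[i, j] <- num / den
    }
    C
  }
  set.seed(41)
  depthsG <- c(0, 50, 100, 150)
  X <- matrix(stats::runif(12, 1, 6), nrow = 3)  # 3 samples x 4 depths
  profs <- lapply(1:3, function(i)
    syntheticProfile(depthsG, aBar = X[i, ], sampleId = paste0("S", i),
                     zStepUm = 50))
  cm <- bivariateCorrelation(profs, depthGrid = depthsG)
  expect_equal(cm@values, directC(X), tolerance = 1e-12)
  expect_equal(diag(cm@values), rep(1, 4))
  expect_equal(cm@values, t(cm@values))
  expect_true(all(abs(cm@values) <= 1 + 1e-12))
  expect_true(all(cm@nPairs == 3L))
})

test_that("perfectly linear profiles give correlation plus or minus one", {
  depthsG <- c(0, 50)
  base <- c(1, 2, 3)
  profs <- lapply(1:3, function(i)
    syntheticProfile(depthsG, aBar = c(base[i], -2 * base[i] + 7),
                     sampleId = paste0("S", i), zStepUm = 50))
  cm <- bivariateCorrelation(profs, depthGrid = depthsG)
  expect_equal(cm@values[1, 1], 1)
  expect_equal(cm@values[1, 2], -1)
})

test_that("depths with insufficient sample pairs stay blank", {
  # third sample stops at 50 um; a grid depth beyond every profile has < 2
  # complete pairs only if fewer than two samples reach it
  profs <- list(
    syntheticProfile(c(0, 50, 100), aBar = c(1, 2, 3), sampleId = "A",
                     zStepUm = 50),
    syntheticProfile(c(0, 50), aBar = c(2, 1), sampleId = "B", zStepUm = 50),
    syntheticProfile(c(0, 50), aBar = c(4, 3), sampleId = "C", zStepUm = 50))
  cm <- bivariateCorrelation(profs, depthGrid = c(0, 50, 100))
  expect_equal(cm@nPairs[3, 3], 1L)
  expect_true(is.na(cm@values[3, 3]))
  expect_true(is.na(cm@values[1, 3]))
  expect_false(is.na(cm@values[1, 2]))
  # nearest-slice matching never fabricates beyond half a z-step
  cm2 <- bivariateCorrelation(profs[1:2], depthGrid = c(0, 200))
  expect_equal(cm2@nPairs[2, 2], 0L)
})

test_that("distribution maps stack per-depth densities in depth order", {
  tr <- vonMisesParams(5, 5, 20, 20, 1)
  dists <- lapply(c(0, 5), function(z) vmAngularDistribution(tr, depthUm = z))
  fitsList <- lapply(dists, fitMixture)
  prof <- depthProfile(fitsList, depthsUm = c(0, 5), sampleId = "S",
                       zStepUm = 5, distributions = dists)
  m <- distributionMap(prof)
  expect_equal(dim(m), c(2L, 180L))
  expect_equal(rownames(m), c("0", "5"))
  expect_equal(unname(m[1, ]), angularDensity(dists[[1]]))
  expect_equal(unname(rowSums(m)) * pi / 180, c(1, 1), tolerance = 1e-9)
  # profiles fitted without stored distributions refuse to build a map
  bare <- depthProfile(fitsList, depthsUm = c(0, 5))
  expect_error(distributionMap(bare), "keepDistributions")
})

test_that("image-derived maps track the generator's orientation across depth", {
  # constant-orientation (control-like) mini stack: per-row argmax stays near
  # the truth angle at every depth; spectral speckle leaves a few degrees of
  # per-slice jitter, so the band is wider than the fit-based tolerances
  spec <- stackSpec("control_like", nSlices = 4, zStepUm = 50,
                    imageSizePx = 256, nFibers = 300, alpha0Deg = 20,
                    seed = 42)
  st <- renderStack(spec)
  prof <- fitStack(st$stack)
  m <- distributionMap(prof)
  modes <- angleGrid()[apply(m, 1, which.max)]
  expect_true(all(abs(wrapAngle(modes - 20)) <= 6))
})
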