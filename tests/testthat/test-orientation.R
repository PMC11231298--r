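test_that("Tukey windowing matches its rectangular and Hann limits", {
  set.seed(11)
  sl <- matrix(stats::runif(32 * 32), 32, 32)
  expect_equal(applyWindow(sl, taper = 0), sl)
  con <- matrix(1, 33, 33)
  w1 <- applyWindow(con, taper = 1)
  expect_equal(w1[17, 17], 1)            # center preserved
  expect_equal(w1[1, 1], 0)              # corners attenuated to zero
  expect_equal(w1[33, 33], 0)
  imp <- matrix(0, 33, 33); imp[17, 17] <- 3
  expect_equal(applyWindow(imp, taper = 0.5), imp)  # window = 1 at center
  bad <- sl; bad[2, 2] <- NA
  expect_error(applyWindow(bad), "non-finite")
})

test_that("power spectrum is DC-centered, point-symmetric and obeys Parseval", {
  n <- 64
  cen <- floor(n / 2) + 1L
  # constant image: all energy in the DC bin
  ps <- powerSpectrum(matrix(2, n, n))
  expect_equal(ps[cen, cen], (2 * n * n)^2)
  expect_equal(sum(ps) - ps[cen, cen], 0, tolerance = 1e-6)
  # horizontal cosine grating at 8 cycles: two symmetric peaks on the
  # horizontal frequency axis
  img <- matrix(cos(2 * pi * 8 * (col(matrix(0, n, n)) - 1) / n), n, n)
  ps <- powerSpectrum(img)
  pk <- which(ps > max(ps) / 2, arr.ind = TRUE)
  expect_equal(nrow(pk), 2L)
  expect_equal(sort(pk[, "col"]), c(cen - 8L, cen + 8L))
  expect_equal(unname(pk[, "row"]), c(cen, cen))
  # Parseval (unnormalized DFT): sum(|F|^2) = N * sum(x^2)
  set.seed(12)
  x <- matrix(stats::rnorm(48 * 32), 48, 32)
  expect_equal(sum(powerSpectrum(x)), 48 * 32 * sum(x^2), tolerance = 1e-9)
  # point symmetry about the DC-centered origin for real input
  ps <- powerSpectrum(x)
  expect_equal(ps[2:48, 2:32], ps[48:2, 32:2], tolerance = 1e-9)
})

test_that("wedge filtering partitions the annulus and finds line orientations", {
  n <- 128
  # partition: raw wedge sums conserve the annulus energy
  set.seed(13)
  x <- matrix(stats::rnorm(n * n), n, n)
  ps <- powerSpectrum(x)
  e <- wedgeExtract(ps, 0.1, 0.8)
  cen <- floor(n / 2) + 1L
  u <- (col(ps) - cen) / n; v <- (row(ps) - cen) / n
  rfrac <- sqrt(u^2 + v^2) / 0.5
  expect_equal(sum(e), sum(ps[rfrac >= 0.1 & rfrac <= 0.8 & rfrac > 0]))
  # parallel lines at 30 degrees (y up): wedge argmax within 1 degree
  xs <- col(matrix(0, n, n)); ys <- -row(matrix(0, n, n))
  for (ang in c(-60, 0, 30)) {
    th <- ang * pi / 180
    phase <- -sin(th) * xs + cos(th) * ys   # constant along the fiber direction
    img <- cos(2 * pi * phase / 8)
    e <- wedgeExtract(powerSpectrum(applyWindow(img - mean(img), 0.5)),
                      0.05, 0.95)
    expect_lte(abs(wrapAngle(angleGrid()[which.max(e)] - ang)), 1)
  }
  # empty annulus errors
  expect_error(wedgeExtract(ps, 0.0001, 0.0002), "annulus")
})

test_that("circular smoothing conserves energy and wraps axially", {
  # impulse spreads into 7 equal parts
  x <- numeric(180); x[90] <- 1
  s <- smoothCircular(x, 7)
  expect_equal(which(s > 0), 87:93)
  expect_equal(unique(round(s[s > 0], 12)), 1 / 7)
  # wraparound at the -89 end: mass appears at the +90 end
  x <- numeric(180); x[1] <- 1
  s <- smoothCircular(x, 7)
  expect_equal(sort(which(s > 0)), c(1:4, 178:180))
  expect_equal(sum(s), 1)
  # uniform input unchanged; even windows rejected
  u <- rep(0.25, 180)
  expect_equal(smoothCircular(u, 7), u)
  expect_error(smoothCircular(u, 6), "odd")
})

test_that("quantifySlice yields a normalized tissue-frame distribution", {
  sp <- phantomSpec(imageSizePx = 256, nFibers = 300,
                    truth = vonMisesParams(20, 20, 30, 30, 1), seed = 21)
  img <- renderPhantom(sp)$image
  d <- quantifySlice(img)
  expect_s4_class(d, "AngularDistribution")
  expect_equal(sum(angularDensity(d)) * pi / 180, 1, tolerance = 1e-9)
  # highly concentrated phantom: mode at the truth angle
  expect_lte(abs(wrapAngle(angleGrid()[which.max(angularDensity(d))] - 30)), 1)
  # contrast invariance: affine intensity changes leave the result untouched
  d2 <- quantifySlice(3.7 * img + 11)
  expect_equal(angularDensity(d2), angularDensity(d), tolerance = 1e-6)
  # circumferential reference shifts the reported angles
  d3 <- quantifySlice(img, circumferentialRefDeg = 30)
  expect_lte(abs(wrapAngle(angleGrid()[which.max(angularDensity(d3))])), 1)
  expect_error(quantifySlice(matrix(0, 64, 64)), "no signal")
})

test_that("rotating a slice rotates the distribution by the same angle", {
  sp <- phantomSpec(imageSizePx = 256, nFibers = 300,
                    truth = vonMisesParams(8, 8, 10, 10, 1), seed = 22)
  img <- renderPhantom(sp)$image
  circMean <- function(im) {
    d <- angularDensity(quantifySlice(im))
    axialMean(angleGrid(), w = d)
  }
  base <- circMean(img)
  for (delta in c(10, 45, 90)) {
    shift <- wrapAngle(circMean(rotateSlice(img, delta)) - base)
    expect_lte(abs(shift - delta), 1.5,
               label = sprintf("circular-mean shift for %d-degree rotation", delta))
  }
  # the fitted dominant orientation follows a 45-degree rotation as well
  # fitted mean orientation of the mixture (weight-averaged on the axial
  # circle); for a single-family truth this is the dominant orientation
  dominantAngle <- function(f) axialMean(c(f@alpha1Deg, f@alpha2Deg), w = c(f@w, 1 - f@w))
  f0 <- fitMixture(quantifySlice(img))
  f45 <- fitMixture(quantifySlice(rotateSlice(img, 45)))
  expect_lte(abs(wrapAngle(dominantAngle(f45) - dominantAngle(f0)) - 45), 1.5)
})

test_that("isotropic noise yields a flat expected distribution", {
  # 20 seeds of pure noise; per-bin t statistics against the uniform density
  # should behave like standard normals (chi-square on 180 bins, alpha 0.01)
  set.seed(23)
  D <- vapply(1:20, function(i)
    angularDensity(quantifySlice(matrix(stats::rnorm(128^2), 128, 128))),
    numeric(180))
  tstat <- (rowMeans(D) - 1 / pi) / (apply(D, 1, stats::sd) / sqrt(20))
  chi <- sum(tstat^2)
  expect_gt(stats::pchisq(chi, df = 180, lower.tail = FALSE), 0.01)
  # and the average max/min wedge ratio approaches one
  expect_lt(max(rowMeans(D)) / min(rowMeans(D)), 1.15)
})
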