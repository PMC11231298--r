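test_that("the mixture density matches its closed forms and normalizes", {
  g <- angleGrid()
  # uniform limit: zero concentration gives 1/pi everywhere
  expect_equal(vmDensity(g, vonMisesParams(0, 0, 10, -10, 0.3)),
               rep(1 / pi, 180))
  # single family closed-form peak ratio: density(alpha)/density(alpha+90) = exp(2a)
  p <- vonMisesParams(3, 3, 0, 0, 1)
  expect_equal(vmDensity(0, p) / vmDensity(90, p), exp(6), tolerance = 1e-10)
  expect_equal(vmDensity(0, p), exp(3) / (pi * besselI(3, 0)), tolerance = 1e-12)
  # pi-periodicity
  p2 <- vonMisesParams(3, 1, 40, -35, 0.6)
  expect_equal(vmDensity(g + 180, p2), vmDensity(g, p2))
  # quadrature oracle: unit integral over a half turn
  q <- stats::integrate(function(th) vmDensity(th, p2) * pi / 180,
                        -90, 90, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-8)
  # property: normalization holds over random parameter draws
  set.seed(31)
  for (i in 1:200) {
    pr <- vonMisesParams(stats::runif(1, 0, 20), stats::runif(1, 0, 20),
                         stats::runif(1, -90, 90), stats::runif(1, -90, 90),
                         stats::runif(1))
    q <- stats::integrate(function(th) vmDensity(th, pr) * pi / 180,
                          -90, 90, rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
})

test_that("meanAlignment is the weight-averaged concentration", {
  expect_equal(meanAlignment(vonMisesParams(4, 2, 30, -30, 0.5)), 3)
  expect_equal(meanAlignment(vonMisesParams(5, 17, 30, -30, 1)), 5)
  expect_equal(meanAlignment(vonMisesParams(0, 0, 30, -30, 0.4)), 0)
  expect_equal(meanAlignment(vonMisesParams(0, 0, NA, NA, 0.5,
                                            isotropic = TRUE)), 0)
})

test_that("fitting recovers exact mixture parameters and is label-stable", {
  truth <- vonMisesParams(6, 2, 25, -5, 0.7)
  f <- fitMixture(vmAngularDistribution(truth))
  expect_lte(abs(f@alpha1Deg - 25), 2)
  expect_lte(abs(f@alpha2Deg - -5), 2)
  expect_lte(abs(f@a1 / 6 - 1), 0.05)
  expect_lte(abs(f@a2 / 2 - 1), 0.05)
  expect_lte(abs(f@w - 0.7), 0.05)
  expect_gt(f@r2, 0.999)
  # permuting the family labels in the truth changes nothing after relabeling
  swapped <- vonMisesParams(2, 6, -5, 25, 0.3)
  fs <- fitMixture(vmAngularDistribution(swapped))
  expect_equal(fs@alpha1Deg, f@alpha1Deg, tolerance = 1e-3)
  expect_equal(fs@w, f@w, tolerance = 1e-3)
  expect_gte(f@alpha1Deg, f@alpha2Deg)  # labeling convention
})

test_that("single-family and uniform targets are handled", {
  one <- vonMisesParams(4, 4, 30, 30, 1)
  f <- fitMixture(vmAngularDistribution(one))
  expect_lte(abs(f@aBar / 4 - 1), 0.05)
  dom <- if (f@w >= 0.5) f@alpha1Deg else f@alpha2Deg
  expect_lte(abs(wrapAngle(dom - 30)), 2)
  # exact uniform density: isotropic classification with zero alignment
  u <- new("AngularDistribution", density = rep(1 / pi, 180) /
             (sum(rep(1 / pi, 180)) * pi / 180), depthUm = 0,
           sourceId = "u", isotropic = FALSE)
  fu <- fitMixture(u)
  expect_true(fu@isotropic)
  expect_equal(meanAlignment(fu), 0)
  expect_true(is.na(fu@alpha1Deg))
})

test_that("fitting tolerates multiplicative measurement noise", {
  # 10 percent CV noise on exact densities: median angle error <= 3 degrees,
  # median relative alignment error <= 10 percent
  set.seed(32)
  errA <- errAbar <- numeric(60)
  for (i in 1:60) {
    truth <- vonMisesParams(stats::runif(1, 2, 6), stats::runif(1, 1, 4),
                            stats::runif(1, 0, 60), stats::runif(1, -60, 0),
                            stats::runif(1, 0.4, 0.8))
    d <- vmDensity(angleGrid(), truth) * (1 + 0.1 * stats::rnorm(180))
    d[d < 0] <- 0
    dist <- new("AngularDistribution", density = d / (sum(d) * pi / 180),
                depthUm = 0, sourceId = "noisy", isotropic = FALSE)
    f <- fitMixture(dist)
    errA[i] <- abs(wrapAngle(f@alpha1Deg - truth@alpha1Deg))
    errAbar[i] <- abs(f@aBar / truth@aBar - 1)
  }
  expect_lte(stats::median(errA), 3)
  expect_lte(stats::median(errAbar), 0.10)
})

test_that("isotropy classification matches a likelihood-ratio oracle near the boundary", {
  # nearly-uniform truth (a = 0.05), 200 sampled fibers per seed; compare the
  # package rule against a brute-force LR test (single von Mises vs uniform
  # on the raw angles) -- the two should agree in at least 90% of seeds
  lrOracle <- function(th) {
    nll <- function(p) -sum(log(.vm1grid(th, p[1], p[2])))
    fits <- lapply(c(0, 45, 90, 135), function(al0)
      stats::optim(c(0.5, al0 * pi / 180), nll, method = "L-BFGS-B",
                   lower = c(0, -pi), upper = c(50, pi)))
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    lr <- 2 * (-best$value - length(th) * log(1 / pi))
    stats::pchisq(lr, df = 2, lower.tail = FALSE) < 0.05  # TRUE = anisotropic
  }
  .vm1grid <- function(thetaRad, aConc, alphaRad)
    exp(aConc * (cos(2 * (thetaRad - alphaRad)) - 1)) /
      (pi * besselI(aConc, 0, expon.scaled = TRUE))
  agree <- logical(50)
  for (s in 1:50) {
    th <- sampleOrientations(200, vonMisesParams(0.05, 0.05, 0, 0, 1),
                             seed = 3300 + s) * pi / 180
    # density estimate: smoothed circular histogram of the sample
    bins <- (round(th * 180 / pi) + 89L) %% 180L + 1L
    h <- smoothCircular(tabulate(bins, 180), 7)
    dist <- new("AngularDistribution", density = h / (sum(h) * pi / 180),
                depthUm = 0, sourceId = "sample", isotropic = FALSE)
    pkg <- !fitMixture(dist)@isotropic
    agree[s] <- pkg == lrOracle(th)
  }
  expect_gte(mean(agree), 0.9)
})

test_that("classifyIsotropic zeroes alignment below threshold and not above", {
  sharp <- fitMixture(vmAngularDistribution(vonMisesParams(6, 6, 20, 20, 1)),
                      classify = FALSE)
  expect_false(classifyIsotropic(sharp)@isotropic)
  weak <- vonMisesParams(0.05, 0.05, 10, -10, 0.5, sse = 1e-5, r2 = 0.05)
  cls <- classifyIsotropic(weak)
  expect_true(cls@isotropic)
  expect_equal(cls@aBar, 0)
})

test_that("angleBetween is the axial distance, symmetric and bounded", {
  expect_equal(angleBetween(40, -35), 75)
  expect_equal(angleBetween(85, -85), 10)
  expect_equal(angleBetween(11, -11), 22)
  set.seed(33)
  a <- stats::runif(200, -90, 90); b <- stats::runif(200, -90, 90)
  d1 <- angleBetween(a, b); d2 <- angleBetween(b, a)
  expect_equal(d1, d2)
  expect_true(all(d1 >= 0 & d1 <= 90))
  expect_error(angleBetween(NA, 10), "isotropic")
})

test_that("axialMean averages on the doubled circle", {
  expect_equal(abs(axialMean(c(85, -85))), 90)
  expect_equal(axialMean(c(30, 30, 30)), 30)
  expect_equal(axialMean(c(10, 20, NA)), 15, tolerance = 0.1)
  expect_true(is.na(axialMean(numeric(0))))
  expect_equal(axialMean(c(0, 40), w = c(1, 0)), 0, tolerance = 1e-9)
})
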