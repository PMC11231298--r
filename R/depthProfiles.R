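## Per-sample depth profiles, depth-bin summaries, angle-by-depth
## distribution maps and the bivariate depth-correlation matrix.

#' Fit a full depth profile from an image stack
#'
#' Runs the complete per-sample pipeline: quantify each slice
#' ([quantifySlice()]), fit the two-family von Mises mixture
#' ([fitMixture()]) and classify isotropic layers, assembling the
#' depth-ordered parameter table of a [DepthProfile].
#'
#' @param stack a [SampleStack].
#' @param keepDistributions logical; retain the per-depth
#'   [AngularDistribution] objects (needed for [distributionMap()]).
#' @inheritParams quantifySlice
#' @inheritParams fitMixture
#' @return a [DepthProfile].
#' @export
fitStack <- function(stack, taper = 0.5, rMinFrac = 0.05, rMaxFrac = 0.95,
                     smoothWindowDeg = 7, maxConcentration = 50,
                     isotropicAEq = 0.25, isotropicAbar = 0.1,
                     isotropicR2 = 0.1, keepDistributions = TRUE) {
  dists <- quantifyStack(stack, taper = taper, rMinFrac = rMinFrac,
                         rMaxFrac = rMaxFrac,
                         smoothWindowDeg = smoothWindowDeg)
  fitsList <- lapply(dists, fitMixture, maxConcentration = maxConcentration,
                     isotropicAEq = isotropicAEq,
                     isotropicAbar = isotropicAbar, isotropicR2 = isotropicR2)
  depthProfile(fitsList,
               depthsUm = vapply(dists, slot, numeric(1), "depthUm"),
               sampleId = stack@sampleId, patientId = stack@patientId,
               group = stack@group, segment = stack@segment,
               zStepUm = stack@zStepUm,
               distributions = if (keepDistributions) dists else list())
}

#' Assemble a DepthProfile from fitted parameters
#'
#' @param fitsList list of [VonMisesFit] objects, one per depth.
#' @param depthsUm strictly increasing depths (micrometers).
#' @param sampleId,patientId,group,segment sample metadata.
#' @param zStepUm acquisition z-step (micrometers).
#' @param distributions optional list of [AngularDistribution] objects
#'   parallel to \code{fitsList}.
#' @return a [DepthProfile].
#' @export
depthProfile <- function(fitsList, depthsUm, sampleId = "", patientId = "",
                         group = "control", segment = "",
                         zStepUm = NA_real_, distributions = list()) {
  stopifnot(length(fitsList) == length(depthsUm))
  fits <- data.frame(
    depth_um = as.numeric(depthsUm),
    a1 = vapply(fitsList, slot, numeric(1), "a1"),
    a2 = vapply(fitsList, slot, numeric(1), "a2"),
    alpha1_deg = vapply(fitsList, slot, numeric(1), "alpha1Deg"),
    alpha2_deg = vapply(fitsList, slot, numeric(1), "alpha2Deg"),
    w = vapply(fitsList, slot, numeric(1), "w"),
    a_bar = vapply(fitsList, slot, numeric(1), "aBar"),
    isotropic = vapply(fitsList, slot, logical(1), "isotropic"),
    sse = vapply(fitsList, slot, numeric(1), "sse"),
    r2 = vapply(fitsList, slot, numeric(1), "r2"),
    row.names = NULL)
  if (is.na(zStepUm) && length(depthsUm) > 1L)
    zStepUm <- min(diff(sort(depthsUm)))
  new("DepthProfile", sampleId = sampleId, patientId = patientId,
      group = group, segment = segment, fits = fits,
      distributions = unname(distributions), zStepUm = zStepUm)
}

#' Depth-bin summary of one profile
#'
#' Groups the per-depth fits into half-open depth bins
#' \code{[k*binUm, (k+1)*binUm)} and summarizes each bin: mean and sample SD
#' (n-1 denominator) of the average alignment \eqn{\bar a}, axial circular
#' means of the two preferred orientations, and the mean per-record angle
#' between orientations. Isotropic records contribute \eqn{\bar a = 0} to the
#' alignment summaries but are excluded from all orientation summaries.
#'
#' @param profile a [DepthProfile].
#' @param binUm bin width in micrometers (default 100).
#' @return data.frame with one row per occupied bin: bin_lo_um, bin_hi_um,
#'   n, n_oriented, a_bar_mean, a_bar_sd, alpha1_deg, alpha2_deg,
#'   delta_alpha_deg.
#' @export
binByDepth <- function(profile, binUm = 100) {
  stopifnot(is(profile, "DepthProfile"), binUm > 0)
  f <- profile@fits
  if (!nrow(f)) stop("empty profile")
  bin <- floor(f$depth_um / binUm)
  out <- lapply(sort(unique(bin)), function(b) {
    g <- f[bin == b, ]
    o <- g[!g$isotropic, ]
    data.frame(
      bin_lo_um = b * binUm, bin_hi_um = (b + 1) * binUm,
      n = nrow(g), n_oriented = nrow(o),
      a_bar_mean = mean(g$a_bar),
      a_bar_sd = if (nrow(g) > 1L) stats::sd(g$a_bar) else NA_real_,
      alpha1_deg = axialMean(o$alpha1_deg),
      alpha2_deg = axialMean(o$alpha2_deg),
      delta_alpha_deg = if (nrow(o)) {
        mean(angleBetween(o$alpha1_deg, o$alpha2_deg))
      } else NA_real_)
  })
  do.call(rbind, out)
}

#' Bivariate depth-correlation matrix of alignment
#'
#' For each pair of depths (z, z'), the Pearson correlation across samples of
#' the alignment values measured at those depths:
#' \deqn{C(z, z') = \frac{\sum_i (X(z_i)-\bar X(z)) (X(z'_i)-\bar X(z'))}
#'  {\sqrt{\sum_i (X(z_i)-\bar X(z))^2 \sum_i (X(z'_i)-\bar X(z'))^2}}.}
#' Each profile is matched to the depth grid by the nearest acquired slice
#' within half a z-step (no interpolation). Because samples end at different
#' depths, each cell uses the samples with values at both depths
#' (complete-pairs policy); cells with fewer than two pairs, or with zero
#' variance at either depth, are left blank (NA), never imputed. Isotropic
#' layers enter as alignment 0 (they are real measurements of alignment).
#'
#' @param profiles list of [DepthProfile] objects (at least 2), normally all
#'   from one group.
#' @param depthGrid ordered numeric depths; default: the union of acquired
#'   depths across profiles.
#' @param binUm optional bin width; when given, alignment is first averaged
#'   within depth bins (via [binByDepth()]) and the correlation computed on
#'   bin centers.
#' @return a [DepthCorrelation].
#' @export
bivariateCorrelation <- function(profiles, depthGrid = NULL, binUm = NULL) {
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, is, logical(1), "DepthProfile")))
  grp <- unique(vapply(profiles, groupLabel, character(1)))
  if (!is.null(binUm)) {
    vals <- lapply(profiles, function(p) {
      b <- binByDepth(p, binUm)
      stats::setNames(b$a_bar_mean, (b$bin_lo_um + b$bin_hi_um) / 2)
    })
    if (is.null(depthGrid))
      depthGrid <- sort(unique(as.numeric(unlist(lapply(vals, names)))))
    X <- vapply(vals, function(v) v[as.character(depthGrid)],
                numeric(length(depthGrid)))
  } else {
    if (is.null(depthGrid))
      depthGrid <- sort(unique(unlist(lapply(profiles, depths))))
    X <- vapply(profiles, function(p) {
      zs <- depths(p)
      tol <- zStep(p) / 2
      idx <- vapply(depthGrid, function(z) {
        k <- which.min(abs(zs - z))
        if (abs(zs[k] - z) <= tol) k else NA_integer_
      }, integer(1))
      p@fits$a_bar[idx]
    }, numeric(length(depthGrid)))
  }
  n <- length(depthGrid)
  vals <- matrix(NA_real_, n, n)
  npairs <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    ok <- which(is.finite(X[i, ]) & is.finite(X[j, ]))
    npairs[i, j] <- npairs[j, i] <- length(ok)
    if (length(ok) >= 2L) {
      xi <- X[i, ok]; xj <- X[j, ok]
      if (stats::var(xi) > 0 && stats::var(xj) > 0)
        vals[i, j] <- vals[j, i] <- stats::cor(xi, xj)
    }
  }
  new("DepthCorrelation", depthsUm = as.numeric(depthGrid), values = vals,
      nPairs = npairs, group = if (length(grp) == 1L) grp else "")
}

#' Angle-by-depth distribution map
#'
#' Stacks the per-depth angular distributions of one sample into a matrix of
#' density by (depth, angle) — the planar-collagen content map. Row order
#' matches depth order; every row integrates to one over a half turn.
#'
#' @param profile a [DepthProfile] built with \code{keepDistributions = TRUE}.
#' @return numeric matrix with one row per depth (rownames = depth in um) and
#'   180 columns (colnames = [angleGrid()]).
#' @seealso [plotDistributionMap()]
#' @export
distributionMap <- function(profile) {
  stopifnot(is(profile, "DepthProfile"))
  if (!length(profile@distributions))
    stop("profile holds no distributions; refit with keepDistributions = TRUE")
  m <- do.call(rbind, lapply(profile@distributions, angularDensity))
  rownames(m) <- vapply(profile@distributions, slot, numeric(1), "depthUm")
  colnames(m) <- angleGrid()
  m
}

#' Heatmap of an angle-by-depth distribution map
#'
#' @param map matrix from [distributionMap()].
#' @param main plot title.
#' @return invisibly, NULL. Draws on the current graphics device.
#' @export
plotDistributionMap <- function(map, main = "Collagen fiber distribution") {
  ang <- as.numeric(colnames(map))
  dep <- as.numeric(rownames(map))
  graphics::image(x = ang, y = dep, z = t(map[rev(seq_len(nrow(map))), ]),
                  ylim = rev(range(dep)), xlab = "angle (deg)",
                  ylab = "depth (um)", main = main,
                  col = grDevices::hcl.colors(64, "viridis"))
  invisible(NULL)
}

#' Heatmap of a depth-correlation matrix
#'
#' Blank (NA) cells — depth pairs supported by fewer than two samples — are
#' drawn in white.
#'
#' @param corr a [DepthCorrelation].
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plotDepthCorrelation <- function(corr, main = "Alignment depth correlation") {
  z <- corr@values
  graphics::image(x = corr@depthsUm, y = corr@depthsUm, z = z,
                  zlim = c(-1, 1), xlab = "depth z (um)",
                  ylab = "depth z' (um)", main = main,
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
  invisible(NULL)
}

#' Write per-depth fits to CSV
#'
#' @param profile a [DepthProfile].
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeProfileCsv <- function(profile, path) {
  f <- fits(profile)
  f$sample_id <- sampleId(profile)
  f$patient_id <- patientId(profile)
  f$group <- groupLabel(profile)
  utils::write.csv(f, path, row.names = FALSE)
  invisible(path)
}
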