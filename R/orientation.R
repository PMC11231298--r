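## Slice -> angular fiber distribution: Tukey window, 2D power spectrum,
## wedge filter on the 1-degree axial grid, circular moving average.
##
## Angle convention: angles are measured counterclockwise from the image
## x-axis (columns) with y pointing up, i.e. in the image as displayed with
## the origin at the bottom-left. Fibers oriented at theta concentrate
## spectral energy along theta + 90 degrees, so the wedge filter indexes
## spectral angle and reports theta after a 90-degree rotation.

.tukey1d <- function(n, taper) {
  # cosine-taper (Tukey) window; taper 0 = rectangular, 1 = Hann
  if (n == 1L) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  if (taper > 0) {
    lo <- x < taper / 2
    hi <- x > 1 - taper / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / taper - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / taper - 2 / taper + 1)))
  }
  w
}

#' Apply a 2D Tukey window to a slice
#'
#' Multiplies the slice by the outer product of two 1D Tukey (cosine-taper)
#' windows, attenuating the borders to suppress spectral leakage from the
#' image edges. \code{taper = 0} leaves the slice unchanged (rectangular
#' window); \code{taper = 1} is the Hann limit.
#'
#' @param slice numeric matrix of finite intensities.
#' @param taper cosine-taper fraction in [0, 1].
#' @return windowed matrix of the same dimensions.
#' @export
applyWindow <- function(slice, taper = 0.5) {
  stopifnot(is.matrix(slice), taper >= 0, taper <= 1)
  if (any(!is.finite(slice))) stop("slice contains non-finite pixels")
  outer(.tukey1d(nrow(slice), taper), .tukey1d(ncol(slice), taper)) * slice
}

#' 2D power spectrum with DC at the center
#'
#' Fourier transforms the (windowed) slice and multiplies by the complex
#' conjugate, returning \eqn{|DFT|^2} with the zero-frequency component
#' shifted to the array center. For real input the spectrum is symmetric
#' under point reflection about the center.
#'
#' @param windowed real-valued numeric matrix.
#' @return nonnegative matrix of the same dimensions.
#' @export
powerSpectrum <- function(windowed) {
  stopifnot(is.matrix(windowed), all(is.finite(windowed)))
  F <- stats::fft(windowed)
  .fftshift2(Re(F * Conj(F)))
}

.fftshift2 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  i <- c((floor(n / 2) + 1L):n, 1L:floor(n / 2))
  j <- c((floor(p / 2) + 1L):p, 1L:floor(p / 2))
  m[i, j]
}

## Wedge geometry is fixed by (dims, rMinFrac, rMaxFrac, refDeg); cache the
## pixel-to-bin assignment so repeated slices of one stack reuse it.
.wedgeCache <- new.env(parent = emptyenv())

.wedgeMap <- function(dims, rMinFrac, rMaxFrac, refDeg) {
  key <- paste(dims[1], dims[2], rMinFrac, rMaxFrac, refDeg, sep = "|")
  hit <- .wedgeCache[[key]]
  if (!is.null(hit)) return(hit)
  n <- dims[1]; p <- dims[2]
  cy <- floor(n / 2) + 1L; cx <- floor(p / 2) + 1L
  fy <- (seq_len(n) - cy) / n          # cycles/px along rows (y down)
  fx <- (seq_len(p) - cx) / p          # cycles/px along columns
  u <- matrix(fx, n, p, byrow = TRUE)
  v <- matrix(fy, n, p)
  rfrac <- sqrt(u^2 + v^2) / 0.5       # fraction of the Nyquist radius
  keep <- which(rfrac >= rMinFrac & rfrac <= rMaxFrac & rfrac > 0)
  # spectral angle (y up) -> fiber angle via the 90-degree rotation,
  # then into the tissue frame
  fiber <- wrapAngle(atan2(-v[keep], u[keep]) * 180 / pi + 90 - refDeg)
  bin <- (as.integer(round(fiber)) + 89L) %% 180L + 1L
  map <- list(keep = keep, bin = bin, counts = tabulate(bin, 180L))
  .wedgeCache[[key]] <- map
  map
}

#' Extract angular energies with a wedge filter
#'
#' Sums power-spectral energy inside each 1-degree double wedge (both
#' point-symmetric halves) of the axial grid, restricted to a radial annulus
#' expressed as fractions of the Nyquist radius. Every retained frequency
#' sample is assigned to exactly one wedge (nearest bin center); the DC
#' component is always excluded. Spectral angles are converted to fiber
#' angles by a 90-degree rotation and reported in the tissue frame when
#' \code{refDeg} is nonzero.
#'
#' @param spectrum DC-centered nonnegative matrix from [powerSpectrum()].
#' @param rMinFrac,rMaxFrac radial annulus bounds as fractions of the Nyquist
#'   radius, \code{0 <= rMinFrac < rMaxFrac <= 1}. For non-square images the
#'   fraction is measured in physical frequency so the annulus is circular.
#' @param refDeg image-frame angle of the circumferential direction, rounded
#'   to the nearest degree when binning.
#' @param equalize logical; divide each wedge sum by its pixel count so the
#'   energies are per unit frequency area. The discrete wedge partition
#'   assigns slightly different pixel counts to different angles (about 1
#'   percent systematic modulation); equalization removes this footprint and
#'   makes the expected output on isotropic input exactly flat. Default
#'   FALSE: raw sums, which conserve total spectral energy.
#' @return numeric vector of 180 raw energies on the [angleGrid()].
#' @export
wedgeExtract <- function(spectrum, rMinFrac = 0.05, rMaxFrac = 0.95,
                         refDeg = 0, equalize = FALSE) {
  stopifnot(is.matrix(spectrum), rMinFrac >= 0, rMaxFrac <= 1,
            rMinFrac < rMaxFrac)
  map <- .wedgeMap(dim(spectrum), rMinFrac, rMaxFrac, round(refDeg))
  if (!length(map$keep)) stop("radial annulus excludes all frequency samples")
  e <- numeric(180)
  s <- rowsum(spectrum[map$keep], map$bin)
  e[as.integer(rownames(s))] <- s
  if (equalize) {
    ok <- map$counts > 0
    e[ok] <- e[ok] / map$counts[ok] * mean(map$counts[ok])
  }
  e
}

#' Circular moving average on the axial grid
#'
#' Centered boxcar average with period-180-degree wraparound; total energy is
#' conserved. The 7-degree default matches a 7-bin window on the 1-degree
#' grid.
#'
#' @param x numeric vector of 180 angular energies.
#' @param windowDeg odd positive integer window width in degrees.
#' @return smoothed vector of the same length.
#' @export
smoothCircular <- function(x, windowDeg = 7) {
  stopifnot(length(x) == 180L, windowDeg >= 1)
  if (windowDeg %% 2 == 0) stop("smoothing window must be odd")
  if (windowDeg == 1) return(x)
  as.numeric(stats::filter(x, rep(1 / windowDeg, windowDeg),
                           method = "convolution", sides = 2,
                           circular = TRUE))
}

#' Quantify the fiber distribution of one slice
#'
#' Full per-slice pipeline: subtract the slice mean, apply the 2D Tukey
#' window, compute the power spectrum, extract pixel-count-equalized wedge
#' energies on the 1-degree axial grid, smooth with a circular moving
#' average, and normalize to unit integral over a half turn. Angles are
#' reported in the tissue frame (0 = circumferential). Subtracting the mean
#' before windowing makes the result exactly invariant to affine intensity
#' changes \code{c * slice + b}, \code{c > 0}; count equalization makes the
#' expected distribution on isotropic input exactly uniform.
#'
#' @param slice numeric matrix of intensities.
#' @param taper Tukey taper fraction (default 0.5).
#' @param rMinFrac,rMaxFrac radial annulus (fractions of Nyquist; defaults
#'   0.05 and 0.95 suppress illumination gradients near DC and the corner
#'   anisotropy of the square frequency grid).
#' @param smoothWindowDeg circular moving-average width (odd; default 7).
#' @param circumferentialRefDeg image-frame angle of the circumferential
#'   direction (default 0).
#' @param depthUm,sourceId metadata attached to the result.
#' @return an [AngularDistribution].
#' @seealso [quantifyStack()], [fitMixture()]
#' @export
quantifySlice <- function(slice, taper = 0.5, rMinFrac = 0.05,
                          rMaxFrac = 0.95, smoothWindowDeg = 7,
                          circumferentialRefDeg = 0,
                          depthUm = NA_real_, sourceId = "") {
  stopifnot(is.matrix(slice))
  if (all(slice == 0))
    stop("all-zero slice: no signal at this depth")
  if (stats::var(as.vector(slice)) == 0)
    stop("constant slice: no signal at this depth")
  w <- applyWindow(slice - mean(slice), taper)
  e <- wedgeExtract(powerSpectrum(w), rMinFrac, rMaxFrac,
                    refDeg = circumferentialRefDeg, equalize = TRUE)
  e <- smoothCircular(e, smoothWindowDeg)
  new("AngularDistribution", density = e / (sum(e) * pi / 180),
      depthUm = depthUm, sourceId = sourceId, isotropic = FALSE)
}

#' Quantify every slice of a stack
#'
#' Applies [quantifySlice()] to each slice, skipping signal-free (all-zero)
#' slices with a warning so stacks that run past the tissue boundary degrade
#' gracefully.
#'
#' @param stack a [SampleStack].
#' @inheritParams quantifySlice
#' @return list of [AngularDistribution] objects, named by depth.
#' @export
quantifyStack <- function(stack, taper = 0.5, rMinFrac = 0.05,
                          rMaxFrac = 0.95, smoothWindowDeg = 7) {
  stopifnot(is(stack, "SampleStack"))
  zs <- depths(stack)
  out <- vector("list", length(zs))
  keep <- logical(length(zs))
  for (k in seq_along(zs)) {
    sl <- stack@slices[[k]]
    if (all(sl == 0)) {
      warning(sprintf("slice %d (depth %g um) has no signal; skipped", k, zs[k]))
      next
    }
    out[[k]] <- quantifySlice(
      sl, taper = taper, rMinFrac = rMinFrac, rMaxFrac = rMaxFrac,
      smoothWindowDeg = smoothWindowDeg,
      circumferentialRefDeg = stack@circumferentialRefDeg,
      depthUm = zs[k], sourceId = stack@sampleId)
    keep[k] <- TRUE
  }
  names(out) <- zs
  out[keep]
}

#' Rotate a slice counterclockwise
#'
#' Bilinear rotation about the image center (positive angles rotate fiber
#' orientations by the same amount in the package's angle convention), used
#' for rotation-equivariance checks. The canvas grows to contain the rotated
#' frame; uncovered pixels are zero-filled.
#'
#' @param slice numeric matrix.
#' @param deg rotation angle in degrees (counterclockwise).
#' @return rotated numeric matrix.
#' @export
rotateSlice <- function(slice, deg) {
  stopifnot(is.matrix(slice))
  # EBImage images are indexed (x, y) with y increasing downward, and
  # rotate() turns the displayed image counterclockwise for positive angles;
  # transposing to (x, y) and back keeps our y-up angle convention intact.
  img <- EBImage::rotate(t(slice), -deg, bg.col = 0)
  t(as.matrix(EBImage::imageData(img)))
}
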