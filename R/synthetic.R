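## Synthetic fiber phantoms with known von Mises mixture ground truth.
## Straight anti-aliased fiber segments on a dark background emulate planar
## SHG acquisitions of collagen; depth-varying truth tracks emulate the
## layered architecture of valve leaflets (aligned fibrosa over dispersed
## deeper layers).

#' Specification of one fiber phantom image
#'
#' Defaults emulate an SHG acquisition of planar collagen at roughly the
#' study scale: a 512-pixel canvas at 0.91 um/px (465 um field of view),
#' several hundred fiber segments tens of micrometers long and a few
#' micrometers wide, mild optical blur and detector noise.
#'
#' @param imageSizePx canvas side length in pixels (default 512).
#' @param pixelSizeUm pixel size (default 465/512 um).
#' @param nFibers number of fiber segments (default 600).
#' @param fiberLengthPx length range in pixels, drawn uniformly.
#' @param fiberWidthPx width range in pixels.
#' @param intensity per-fiber peak intensity range.
#' @param truth a [VonMisesFit] giving the orientation mixture the fiber
#'   angles are drawn from.
#' @param backgroundNoiseSd SD of additive Gaussian noise (default 0.02).
#' @param blurSigmaPx Gaussian blur sigma in pixels (default 1).
#' @param seed integer fixing all randomness of the phantom.
#' @return named list (class \code{"phantomSpec"}).
#' @seealso [renderPhantom()]
#' @export
phantomSpec <- function(imageSizePx = 512, pixelSizeUm = 465 / 512,
                        nFibers = 600, fiberLengthPx = c(60, 180),
                        fiberWidthPx = c(2, 4), intensity = c(0.5, 1),
                        truth = vonMisesParams(6, 6, 30, 30, 1),
                        backgroundNoiseSd = 0.02, blurSigmaPx = 1,
                        seed = 1L) {
  stopifnot(nFibers >= 0, imageSizePx >= 8, is(truth, "VonMisesFit"))
  structure(list(imageSizePx = imageSizePx, pixelSizeUm = pixelSizeUm,
                 nFibers = nFibers, fiberLengthPx = fiberLengthPx,
                 fiberWidthPx = fiberWidthPx, intensity = intensity,
                 truth = truth, backgroundNoiseSd = backgroundNoiseSd,
                 blurSigmaPx = blurSigmaPx, seed = as.integer(seed)),
            class = "phantomSpec")
}

#' Sample fiber orientations from a von Mises mixture
#'
#' Draws axial angles from the two-family mixture: the family is chosen
#' Bernoulli(w), then the doubled angle is drawn from the circular von Mises
#' distribution with concentration a via the Best-Fisher rejection sampler
#' and halved back to (-90, 90]. Deterministic given the seed.
#'
#' @param n number of angles.
#' @param truth a [VonMisesFit].
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return numeric vector of n angles in (-90, 90].
#' @export
sampleOrientations <- function(n, truth, seed = NULL) {
  stopifnot(n >= 0, is(truth, "VonMisesFit"))
  if (n == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  fam1 <- stats::runif(n) < truth@w
  out <- numeric(n)
  for (f in 1:2) {
    idx <- if (f == 1) which(fam1) else which(!fam1)
    if (!length(idx)) next
    aConc <- if (f == 1) truth@a1 else truth@a2
    alpha <- if (f == 1) truth@alpha1Deg else truth@alpha2Deg
    phi <- .rvonmises(length(idx), aConc)          # doubled angle about 0
    out[idx] <- wrapAngle(alpha + phi * 90 / pi)   # halve and recenter
  }
  out
}

## Best & Fisher (1979) wrapped-Cauchy rejection sampler for the circular
## von Mises distribution with mean 0; returns angles in (-pi, pi].
.rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    acc <- f[ok]
    if (length(acc)) {
      th <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, acc)))
      take <- min(length(th), n - got)
      out[(got + 1L):(got + take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  out
}

#' Render a fiber phantom image
#'
#' Draws \code{nFibers} anti-aliased straight segments with centers uniform
#' over the canvas, orientations from [sampleOrientations()], and lengths,
#' widths and intensities uniform in their ranges; intensities add where
#' fibers overlap. Optional Gaussian blur and additive Gaussian background
#' noise (clamped at zero) complete the image. Angles follow the package
#' convention (counterclockwise from the x-axis, y up).
#'
#' @param spec a [phantomSpec()].
#' @return list with elements \code{image} (numeric matrix), \code{truth}
#'   (the [VonMisesFit] ground truth) and \code{angles} (the realized fiber
#'   orientation sample).
#' @export
renderPhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  set.seed(spec$seed)
  S <- spec$imageSizePx
  img <- matrix(0, S, S)
  n <- spec$nFibers
  if (n > 0) {
    angles <- sampleOrientations(n, spec$truth, seed = NULL)
    cx <- stats::runif(n, 1, S)
    cy <- stats::runif(n, 1, S)
    len <- stats::runif(n, spec$fiberLengthPx[1], spec$fiberLengthPx[2])
    wid <- stats::runif(n, spec$fiberWidthPx[1], spec$fiberWidthPx[2])
    amp <- stats::runif(n, spec$intensity[1], spec$intensity[2])
    ## additive anti-aliased segments: coverage = clamp(w/2 + 0.5 - dist, 0, 1)
    ## with dist the distance from the pixel center to the segment; x = column,
    ## y = -row (y up); only each fiber's bounding box is touched. Drawing is
    ## inlined so the canvas is updated in place (no per-fiber copies).
    th <- angles * pi / 180
    for (i in seq_len(n)) {
      dx <- cos(th[i]) * len[i] / 2
      dy <- sin(th[i]) * len[i] / 2      # y-up component
      pad <- wid[i] / 2 + 1.5
      c0 <- max(1, floor(cx[i] - abs(dx) - pad))
      c1 <- min(S, ceiling(cx[i] + abs(dx) + pad))
      r0 <- max(1, floor(cy[i] - abs(dy) - pad))
      r1 <- min(S, ceiling(cy[i] + abs(dy) + pad))
      if (c0 > c1 || r0 > r1) next
      cols <- c0:c1; rows <- r0:r1
      vx <- matrix(cols - cx[i], length(rows), length(cols), byrow = TRUE)
      vy <- -(matrix(rows - cy[i], length(rows), length(cols)))
      tt <- pmax(-len[i] / 2, pmin(len[i] / 2,
                                   vx * cos(th[i]) + vy * sin(th[i])))
      d2 <- (vx - tt * cos(th[i]))^2 + (vy - tt * sin(th[i]))^2
      cov <- pmin(1, pmax(0, wid[i] / 2 + 0.5 - sqrt(d2)))
      img[rows, cols] <- img[rows, cols] + amp[i] * cov
    }
  } else {
    angles <- numeric(0)
  }
  if (spec$blurSigmaPx > 0 && n > 0)
    img <- t(as.matrix(EBImage::imageData(
      EBImage::gblur(t(img), sigma = spec$blurSigmaPx))))
  if (spec$backgroundNoiseSd > 0)
    img <- img + matrix(stats::rnorm(S * S, 0, spec$backgroundNoiseSd), S, S)
  img[img < 0] <- 0
  list(image = img, truth = spec$truth, angles = angles)
}

#' Specification of a depth-varying phantom stack
#'
#' Encodes the depth architecture templates used throughout: per-slice truth
#' parameters follow the group template.
#' \describe{
#'   \item{control_like}{single dominant family, highly aligned (a = 6) with
#'     constant orientation over the first 300 um (the fibrosa), dispersed
#'     (a = 2) below.}
#'   \item{FED_like}{two families about 40 degrees apart, moderately aligned
#'     (a = 3.5) throughout.}
#'   \item{BD_like}{two families about 50 degrees apart, weakly aligned
#'     (a = 2) throughout, with the mean orientation drifting linearly by 40
#'     degrees over the stack depth.}
#' }
#'
#' @param template one of \code{"control_like"}, \code{"FED_like"},
#'   \code{"BD_like"}.
#' @param nSlices number of slices (default 180 at 5-um steps = 900 um; tests
#'   use fewer).
#' @param zStepUm axial step (default 5).
#' @param alpha0Deg base orientation of the first family (default 20).
#' @param imageSizePx,nFibers,seed passed to the per-slice [phantomSpec()];
#'   each slice gets its own RNG stream derived from (seed, slice index).
#' @param ... further arguments forwarded to [phantomSpec()].
#' @return named list (class \code{"stackSpec"}) with a \code{truthTrack}
#'   list of per-slice [phantomSpec()] objects.
#' @export
stackSpec <- function(template = c("control_like", "FED_like", "BD_like"),
                      nSlices = 180, zStepUm = 5, alpha0Deg = 20,
                      imageSizePx = 512, nFibers = 600, seed = 1L, ...) {
  template <- match.arg(template)
  seed <- as.integer(seed)
  zs <- (seq_len(nSlices) - 1L) * zStepUm
  zMax <- max(zs, 1)
  truthTrack <- lapply(seq_len(nSlices), function(k) {
    z <- zs[k]
    truth <- switch(template,
      control_like = if (z < 300) {
        vonMisesParams(6, 6, alpha0Deg, alpha0Deg, 1)
      } else {
        vonMisesParams(2, 2, alpha0Deg, alpha0Deg, 1)
      },
      FED_like = vonMisesParams(3.5, 3.5, alpha0Deg + 20, alpha0Deg - 20, 0.6),
      BD_like = {
        drift <- 40 * z / zMax
        vonMisesParams(2, 2, alpha0Deg + 25 + drift, alpha0Deg - 25 + drift, 0.55)
      })
    phantomSpec(imageSizePx = imageSizePx, nFibers = nFibers, truth = truth,
                seed = (seed * 10007L + k) %% 2147483647L, ...)
  })
  structure(list(template = template, nSlices = nSlices, zStepUm = zStepUm,
                 truthTrack = truthTrack, seed = seed),
            class = "stackSpec")
}

#' Render a depth-varying phantom stack
#'
#' Renders one phantom per slice following the truth track of a
#' [stackSpec()] and assembles a [SampleStack] plus the per-slice ground
#' truth table.
#'
#' @param spec a [stackSpec()].
#' @param sampleId,patientId,segment metadata for the stack.
#' @param group group label; default inferred from the template
#'   (\code{control_like} -> \code{control}, etc.).
#' @return list with elements \code{stack} (a [SampleStack]) and
#'   \code{truth} (data.frame: slice, depth_um, a1, a2, alpha1_deg,
#'   alpha2_deg, w, a_bar).
#' @export
renderStack <- function(spec, sampleId = spec$template, patientId = "P1",
                        segment = "", group = NULL) {
  stopifnot(inherits(spec, "stackSpec"))
  if (is.null(group))
    group <- c(control_like = "control", FED_like = "FED",
               BD_like = "BD")[[spec$template]]
  imgs <- vector("list", spec$nSlices)
  truth <- vector("list", spec$nSlices)
  for (k in seq_len(spec$nSlices)) {
    ph <- renderPhantom(spec$truthTrack[[k]])
    imgs[[k]] <- ph$image
    tr <- ph$truth
    truth[[k]] <- data.frame(
      slice = k, depth_um = (k - 1L) * spec$zStepUm,
      a1 = tr@a1, a2 = tr@a2, alpha1_deg = tr@alpha1Deg,
      alpha2_deg = tr@alpha2Deg, w = tr@w, a_bar = tr@aBar)
  }
  stack <- sampleStack(
    slices = imgs, pixelSizeUm = spec$truthTrack[[1]]$pixelSizeUm,
    zStepUm = spec$zStepUm, sampleId = sampleId, patientId = patientId,
    group = group, segment = segment)
  list(stack = stack, truth = do.call(rbind, truth))
}
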