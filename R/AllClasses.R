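#' @import methods
#' @importFrom stats fft aov pf sd var cor rnorm runif
NULL

.GROUPS <- c("control", "FED", "BD")

#' SampleStack: a grayscale z-stack with spatial metadata
#'
#' Container for one second harmonic generation (SHG) style acquisition: an
#' ordered list of 2D grayscale slices imaged at increasing depth from the
#' ventricular surface, together with the spatial calibration and the group
#' label used downstream.
#'
#' Depth of slice \code{k} (1-based) is \code{z0Um + (k-1) * zStepUm}.
#' Intensities are stored exactly as loaded; the analysis pipeline normalizes
#' internally, so no rescaling happens at load time.
#'
#' @slot slices list of numeric matrices, all with identical dimensions.
#' @slot pixelSizeUm positive numeric, lateral pixel size in micrometers.
#' @slot zStepUm positive numeric, axial step between slices in micrometers.
#' @slot z0Um numeric, depth of the first slice (default 0 = ventricular surface).
#' @slot circumferentialRefDeg numeric, image-frame angle (degrees) of the
#'   tissue circumferential direction; fiber angles are reported relative to it.
#' @slot sampleId,patientId character identifiers.
#' @slot group character, one of \code{"control"}, \code{"FED"}, \code{"BD"}.
#' @slot segment character, optional leaflet segment label (e.g. "P2").
#'
#' @seealso [loadStack()], [writeStack()], [renderStack()], [fitStack()]
#' @export
setClass("SampleStack",
  representation(
    slices = "list",
    pixelSizeUm = "numeric",
    zStepUm = "numeric",
    z0Um = "numeric",
    circumferentialRefDeg = "numeric",
    sampleId = "character",
    patientId = "character",
    group = "character",
    segment = "character"
  ),
  prototype(z0Um = 0, circumferentialRefDeg = 0, sampleId = "",
            patientId = "", group = "control", segment = "")
)

setValidity("SampleStack", function(object) {
  msg <- character()
  if (length(object@slices) == 0L)
    msg <- c(msg, "stack must contain at least one slice")
  dims <- lapply(object@slices, dim)
  if (length(dims) > 1L && !all(vapply(dims, identical, logical(1), dims[[1]])))
    msg <- c(msg, "all slices must share identical dimensions")
  if (!all(vapply(object@slices, is.matrix, logical(1))))
    msg <- c(msg, "slices must be numeric matrices")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(object@zStepUm) != 1L || !is.finite(object@zStepUm) ||
      object@zStepUm <= 0)
    msg <- c(msg, "zStepUm must be a single positive number")
  if (!object@group %in% .GROUPS)
    msg <- c(msg, sprintf("group must be one of %s",
                          paste(.GROUPS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' AngularDistribution: normalized fiber-orientation density at one depth
#'
#' Axial (180-degree periodic) fiber-orientation density on the canonical
#' 1-degree grid with bin centers -89, -88, ..., 90 degrees, expressed in the
#' tissue frame (0 = circumferential). The density integrates to one over a
#' half turn: \code{sum(density) * pi / 180 == 1}.
#'
#' @slot density numeric vector of 180 nonnegative bin densities (per radian).
#' @slot depthUm numeric, acquisition depth of the source slice.
#' @slot sourceId character, identifier of the originating sample/slice.
#' @slot isotropic logical flag, set downstream by [classifyIsotropic()].
#'
#' @seealso [quantifySlice()], [angleGrid()], [fitMixture()]
#' @export
setClass("AngularDistribution",
  representation(
    density = "numeric",
    depthUm = "numeric",
    sourceId = "character",
    isotropic = "logical"
  ),
  prototype(depthUm = NA_real_, sourceId = "", isotropic = FALSE)
)

setValidity("AngularDistribution", function(object) {
  msg <- character()
  if (length(object@density) != 180L)
    msg <- c(msg, "density must have exactly 180 bins (1-degree grid)")
  if (any(!is.finite(object@density)) || any(object@density < 0))
    msg <- c(msg, "density must be finite and nonnegative")
  else if (abs(sum(object@density) * pi / 180 - 1) > 1e-6)
    msg <- c(msg, "density must integrate to 1 over a half turn")
  if (length(msg)) msg else TRUE
})

#' VonMisesFit: two-family pi-periodic von Mises mixture parameters
#'
#' Parameters of the axial von Mises mixture
#' \deqn{\rho(\theta) = w \frac{\exp\{a_1\cos[2(\theta-\alpha_1)]\}}{\pi I_0(a_1)}
#'   + (1-w) \frac{\exp\{a_2\cos[2(\theta-\alpha_2)]\}}{\pi I_0(a_2)}}
#' together with the derived average alignment parameter
#' \eqn{\bar a = a_1 w + a_2 (1-w)} and fit diagnostics. Families are labeled
#' so that \code{alpha1Deg >= alpha2Deg}. Isotropic layers carry
#' \code{aBar = 0} and undefined (NA) angles.
#'
#' @slot a1,a2 nonnegative concentration parameters (dimensionless).
#' @slot alpha1Deg,alpha2Deg preferred orientations in degrees, in (-90, 90];
#'   NA when isotropic.
#' @slot w mixture weight of family 1, in [0, 1].
#' @slot aBar derived average alignment \eqn{a_1 w + a_2(1-w)}.
#' @slot isotropic logical, TRUE when the layer shows no preferred orientation.
#' @slot sse residual sum of squares of the density fit.
#' @slot r2 coefficient of determination versus the uniform density.
#'
#' @seealso [fitMixture()], [vmDensity()], [meanAlignment()]
#' @export
setClass("VonMisesFit",
  representation(
    a1 = "numeric", a2 = "numeric",
    alpha1Deg = "numeric", alpha2Deg = "numeric",
    w = "numeric", aBar = "numeric",
    isotropic = "logical",
    sse = "numeric", r2 = "numeric"
  ),
  prototype(isotropic = FALSE, sse = NA_real_, r2 = NA_real_)
)

setValidity("VonMisesFit", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L
  if (!all(vapply(list(object@a1, object@a2, object@w, object@aBar),
                  num1, logical(1))))
    msg <- c(msg, "parameters must be single numbers")
  if (object@a1 < 0 || object@a2 < 0)
    msg <- c(msg, "concentrations a1, a2 must be nonnegative")
  if (object@w < 0 || object@w > 1)
    msg <- c(msg, "weight w must lie in [0, 1]")
  if (object@isotropic) {
    if (object@aBar != 0)
      msg <- c(msg, "isotropic fits must have aBar == 0")
  } else {
    if (abs(object@aBar - (object@a1 * object@w +
                           object@a2 * (1 - object@w))) > 1e-8)
      msg <- c(msg, "aBar must equal a1*w + a2*(1-w)")
    if (is.finite(object@alpha1Deg) && is.finite(object@alpha2Deg) &&
        object@alpha1Deg < object@alpha2Deg)
      msg <- c(msg, "families must be labeled so alpha1Deg >= alpha2Deg")
  }
  if (length(msg)) msg else TRUE
})

#' DepthProfile: per-depth mixture fits for one sample
#'
#' Depth-ordered von Mises mixture parameters for one imaged sample, the
#' \eqn{X(z)} entering the bivariate depth-correlation function, plus the
#' underlying angular distributions for building distribution maps.
#'
#' @slot sampleId,patientId,group,segment sample metadata (see [SampleStack]).
#' @slot fits data.frame with columns depth_um, a1, a2, alpha1_deg,
#'   alpha2_deg, w, a_bar, isotropic, sse, r2; depths strictly increasing.
#' @slot distributions list of [AngularDistribution] objects, parallel to the
#'   rows of \code{fits} (may be empty if distributions were not retained).
#' @slot zStepUm numeric, acquisition z-step (used for depth-grid matching).
#'
#' @seealso [fitStack()], [binByDepth()], [bivariateCorrelation()],
#'   [distributionMap()]
#' @export
setClass("DepthProfile",
  representation(
    sampleId = "character", patientId = "character",
    group = "character", segment = "character",
    fits = "data.frame",
    distributions = "list",
    zStepUm = "numeric"
  ),
  prototype(segment = "", distributions = list(), zStepUm = NA_real_)
)

setValidity("DepthProfile", function(object) {
  msg <- character()
  need <- c("depth_um", "a1", "a2", "alpha1_deg", "alpha2_deg", "w",
            "a_bar", "isotropic", "sse", "r2")
  if (!all(need %in% names(object@fits)))
    msg <- c(msg, paste("fits must contain columns:",
                        paste(need, collapse = ", ")))
  else if (nrow(object@fits) > 1L && any(diff(object@fits$depth_um) <= 0))
    msg <- c(msg, "depths must be strictly increasing")
  if (!object@group %in% .GROUPS)
    msg <- c(msg, sprintf("group must be one of %s",
                          paste(.GROUPS, collapse = ", ")))
  if (length(object@distributions) &&
      length(object@distributions) != nrow(object@fits))
    msg <- c(msg, "distributions must be empty or parallel to fits rows")
  if (length(msg)) msg else TRUE
})

#' DepthCorrelation: bivariate depth-correlation matrix
#'
#' Pearson correlation, across samples, of alignment values at every pair of
#' depths: \deqn{C(z, z') = \frac{\sum_i (X(z_i)-\bar X(z))(X(z'_i)-\bar X(z'))}
#' {\sqrt{\sum_i (X(z_i)-\bar X(z))^2 \sum_i (X(z'_i)-\bar X(z'))^2}}.}
#' Cells supported by fewer than two complete sample pairs are NA (blank),
#' never imputed; \code{nPairs} records the per-cell sample count.
#'
#' @slot depthsUm ordered numeric depth grid.
#' @slot values square symmetric numeric matrix in [-1, 1] with NA blanks.
#' @slot nPairs integer matrix of complete sample pairs per cell.
#' @slot group character, group whose samples entered the matrix ("" if mixed).
#'
#' @seealso [bivariateCorrelation()]
#' @export
setClass("DepthCorrelation",
  representation(
    depthsUm = "numeric",
    values = "matrix",
    nPairs = "matrix",
    group = "character"
  ),
  prototype(group = "")
)

setValidity("DepthCorrelation", function(object) {
  msg <- character()
  n <- length(object@depthsUm)
  if (!all(dim(object@values) == c(n, n)) || !all(dim(object@nPairs) == c(n, n)))
    msg <- c(msg, "values and nPairs must be n x n for n depths")
  v <- object@values
  if (any(abs(v[!is.na(v)]) > 1 + 1e-12))
    msg <- c(msg, "correlation values must lie in [-1, 1]")
  if (any(!is.na(v) & !is.na(t(v)) & abs(v - t(v)) > 1e-12))
    msg <- c(msg, "correlation matrix must be symmetric")
  if (length(msg)) msg else TRUE
})
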