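#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: slice lists, depth
#' vectors, fitted-parameter tables and metadata. Accessors are the supported
#' way to reach slot contents.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("slices", function(object) standardGeneric("slices"))

#' @rdname accessors
#' @export
setGeneric("depths", function(object) standardGeneric("depths"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("zStep", function(object) standardGeneric("zStep"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))

#' @rdname accessors
#' @export
setGeneric("angularDensity", function(object) standardGeneric("angularDensity"))

#' @rdname accessors
#' @export
setGeneric("fits", function(object) standardGeneric("fits"))

#' @rdname accessors
#' @export
setGeneric("meanAlignment", function(object) standardGeneric("meanAlignment"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("slices", "SampleStack", function(object) object@slices)

#' @rdname accessors
#' @export
setMethod("depths", "SampleStack", function(object)
  object@z0Um + (seq_along(object@slices) - 1L) * object@zStepUm)

#' @rdname accessors
#' @export
setMethod("depths", "DepthProfile", function(object) object@fits$depth_um)

#' @rdname accessors
#' @export
setMethod("depths", "DepthCorrelation", function(object) object@depthsUm)

#' @rdname accessors
#' @export
setMethod("pixelSize", "SampleStack", function(object) object@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("zStep", "SampleStack", function(object) object@zStepUm)

#' @rdname accessors
#' @export
setMethod("zStep", "DepthProfile", function(object) object@zStepUm)

#' @rdname accessors
#' @export
setMethod("sampleId", "SampleStack", function(object) object@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleId", "DepthProfile", function(object) object@sampleId)

#' @rdname accessors
#' @export
setMethod("patientId", "SampleStack", function(object) object@patientId)

#' @rdname accessors
#' @export
setMethod("patientId", "DepthProfile", function(object) object@patientId)

#' @rdname accessors
#' @export
setMethod("groupLabel", "SampleStack", function(object) object@group)

#' @rdname accessors
#' @export
setMethod("groupLabel", "DepthProfile", function(object) object@group)

#' @rdname accessors
#' @export
setMethod("groupLabel", "DepthCorrelation", function(object) object@group)

#' @rdname accessors
#' @export
setMethod("angularDensity", "AngularDistribution", function(object) object@density)

#' @rdname accessors
#' @export
setMethod("fits", "DepthProfile", function(object) object@fits)

#' Average alignment parameter of a fitted mixture
#'
#' Returns the weight-averaged concentration \eqn{\bar a = a_1 w + a_2(1-w)},
#' the per-depth scalar summary of fiber alignment. Isotropic fits return 0.
#'
#' @param object a [VonMisesFit].
#' @return single nonnegative numeric.
#' @examples
#' meanAlignment(vonMisesParams(a1 = 4, a2 = 2, alpha1Deg = 30,
#'                              alpha2Deg = -30, w = 0.5))  # 3
#' @export
setMethod("meanAlignment", "VonMisesFit", function(object)
  if (object@isotropic) 0 else object@a1 * object@w + object@a2 * (1 - object@w))

## ---- show ----------------------------------------------------------------

setMethod("show", "SampleStack", function(object) {
  d <- dim(object@slices[[1]])
  cat(sprintf(
    "SampleStack '%s' (patient %s, group %s%s)\n  %d slices of %d x %d px, %.3g um/px\n  depths %.4g-%.4g um (z-step %.4g um)\n",
    object@sampleId, object@patientId, object@group,
    if (nzchar(object@segment)) paste0(", segment ", object@segment) else "",
    length(object@slices), d[1], d[2], object@pixelSizeUm,
    min(depths(object)), max(depths(object)), object@zStepUm))
})

setMethod("show", "AngularDistribution", function(object) {
  g <- angleGrid()
  cat(sprintf(
    "AngularDistribution (%s, depth %.4g um)%s\n  mode at %d deg, integral %.6f over a half turn\n",
    object@sourceId, object@depthUm,
    if (object@isotropic) " [isotropic]" else "",
    g[which.max(object@density)], sum(object@density) * pi / 180))
})

setMethod("show", "VonMisesFit", function(object) {
  if (object@isotropic) {
    cat(sprintf("VonMisesFit: isotropic (aBar = 0; R2 = %.3f)\n", object@r2))
  } else {
    cat(sprintf(
      "VonMisesFit: a1 = %.3g @ %.1f deg, a2 = %.3g @ %.1f deg, w = %.3f\n  aBar = %.3g, R2 = %.3f\n",
      object@a1, object@alpha1Deg, object@a2, object@alpha2Deg,
      object@w, object@aBar, object@r2))
  }
})

setMethod("show", "DepthProfile", function(object) {
  f <- object@fits
  cat(sprintf(
    "DepthProfile '%s' (patient %s, group %s): %d depths, %.4g-%.4g um\n  mean aBar %.3g (%d isotropic layers)\n",
    object@sampleId, object@patientId, object@group, nrow(f),
    min(f$depth_um), max(f$depth_um), mean(f$a_bar), sum(f$isotropic)))
})

setMethod("show", "DepthCorrelation", function(object) {
  cat(sprintf(
    "DepthCorrelation%s: %d x %d depths (%.4g-%.4g um), %d blank cells\n",
    if (nzchar(object@group)) paste0(" [", object@group, "]") else "",
    nrow(object@values), ncol(object@values),
    min(object@depthsUm), max(object@depthsUm), sum(is.na(object@values))))
})
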