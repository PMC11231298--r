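#' The canonical axial angle grid
#'
#' Fiber orientations are axial (theta and theta + 180 degrees are the same
#' direction) and are binned on a fixed 1-degree grid with centers
#' -89, -88, ..., 90 degrees covering one half turn.
#'
#' @return integer vector of the 180 bin centers in degrees.
#' @export
angleGrid <- function() -89:90

#' Wrap angles into the axial range (-90, 90]
#'
#' @param thetaDeg numeric vector of angles in degrees.
#' @return angles wrapped modulo 180 into (-90, 90].
#' @examples
#' wrapAngle(c(95, -90, 270))  # -85, 90, 90
#' @export
wrapAngle <- function(thetaDeg) {
  w <- thetaDeg %% 180
  w[w > 90] <- w[w > 90] - 180
  w
}

#' Convert an image-frame angle to the tissue frame
#'
#' The tissue frame takes the circumferential direction (parallel to the valve
#' annulus) as 0 degrees. Given the image-frame angle of that direction, any
#' image-frame fiber angle maps to \code{angleImageDeg - circumferentialRefDeg}
#' wrapped into (-90, 90].
#'
#' @param angleImageDeg numeric vector, angles in the image frame (degrees).
#' @param circumferentialRefDeg single numeric, image-frame angle of the
#'   circumferential direction.
#' @return tissue-frame angles in (-90, 90].
#' @examples
#' toTissueFrame(95, 0)   # -85
#' toTissueFrame(10, 40)  # -30
#' @export
toTissueFrame <- function(angleImageDeg, circumferentialRefDeg) {
  stopifnot(is.finite(angleImageDeg), length(circumferentialRefDeg) == 1L,
            is.finite(circumferentialRefDeg))
  wrapAngle(angleImageDeg - circumferentialRefDeg)
}

#' Construct a SampleStack
#'
#' @param slices list of numeric matrices (identical dimensions) ordered from
#'   the ventricular towards the atrial side.
#' @param pixelSizeUm,zStepUm lateral pixel size and axial step (micrometers).
#' @param z0Um depth of the first slice (default 0, the ventricular surface).
#' @param circumferentialRefDeg image-frame angle of the circumferential
#'   direction (degrees; default 0).
#' @param sampleId,patientId,group,segment sample metadata; \code{group} is one
#'   of \code{"control"}, \code{"FED"}, \code{"BD"}.
#' @return a [SampleStack].
#' @export
sampleStack <- function(slices, pixelSizeUm, zStepUm, z0Um = 0,
                        circumferentialRefDeg = 0, sampleId = "",
                        patientId = "", group = "control", segment = "") {
  new("SampleStack", slices = slices, pixelSizeUm = pixelSizeUm,
      zStepUm = zStepUm, z0Um = z0Um,
      circumferentialRefDeg = circumferentialRefDeg,
      sampleId = sampleId, patientId = patientId,
      group = group, segment = segment)
}

.requiredMeta <- c("pixel_size_um", "z_step_um")

.readMetadata <- function(metadata) {
  if (is.character(metadata) && length(metadata) == 1L) {
    if (!file.exists(metadata)) stop("metadata file not found: ", metadata)
    metadata <- yaml::read_yaml(metadata)
  }
  if (!is.list(metadata)) stop("metadata must be a list or a YAML/JSON path")
  missing <- setdiff(.requiredMeta, names(metadata))
  if (length(missing))
    stop("metadata missing required keys: ", paste(missing, collapse = ", "))
  metadata
}

#' Load an image z-stack from disk
#'
#' Reads a multi-page grayscale TIFF, or a directory of single-slice image
#' files ordered by filename (zero-padded indices recommended), into a
#' [SampleStack]. Slice order equals acquisition order (ventricular to
#' atrial). Integer intensities are preserved without rescaling.
#'
#' @param path path to a multi-page TIFF file or a directory of TIFF slices.
#' @param metadata named list, or path to a YAML sidecar, with keys
#'   \code{pixel_size_um}, \code{z_step_um} (required) and optionally
#'   \code{z0_um}, \code{circumferential_ref_deg}, \code{group},
#'   \code{sample_id}, \code{patient_id}, \code{segment}.
#' @return a [SampleStack].
#' @seealso [writeStack()]
#' @export
loadStack <- function(path, metadata) {
  meta <- .readMetadata(metadata)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no TIFF slices found in directory: ", path)
    slices <- unlist(lapply(files, .readPages), recursive = FALSE)
  } else {
    if (!file.exists(path)) stop("stack file not found: ", path)
    slices <- .readPages(path)
  }
  ## a sidecar written by writeStack records the [0,1] scale factor; undo it
  if (!is.null(meta$intensity_scale))
    slices <- lapply(slices, `*`, as.numeric(meta$intensity_scale))
  sampleStack(
    slices = slices,
    pixelSizeUm = as.numeric(meta$pixel_size_um),
    zStepUm = as.numeric(meta$z_step_um),
    z0Um = as.numeric(meta$z0_um %||% 0),
    circumferentialRefDeg = as.numeric(meta$circumferential_ref_deg %||% 0),
    sampleId = as.character(meta$sample_id %||% basename(path)),
    patientId = as.character(meta$patient_id %||% ""),
    group = as.character(meta$group %||% "control"),
    segment = as.character(meta$segment %||% "")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.asSliceMatrix <- function(x) {
  if (length(dim(x)) == 3L) x <- x[, , 1L]  # collapse trivial channel axis
  storage.mode(x) <- "double"
  x
}

## read all pages of one TIFF; 8/16-bit integer pages keep their native
## integer values (no [0,1] rescaling), 32-bit pages are IEEE float
.readPages <- function(path) {
  info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
  plain <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(plain)) plain <- list(plain)
  bits <- if (is.data.frame(info)) info$bits.per.sample else info[["bits.per.sample"]]
  if (length(bits) == 1L) bits <- rep(bits, length(plain))
  lapply(seq_along(plain), function(k) {
    if (bits[k] < 32L) {
      m <- .asSliceMatrix(plain[[k]])
      round(m * (2^bits[k] - 1))   # undo readTIFF's integer scaling
    } else {
      .asSliceMatrix(plain[[k]])
    }
  })
}

#' Write a SampleStack to a multi-page TIFF with a YAML sidecar
#'
#' Intensities are stored as 32-bit floats scaled into [0, 1] by
#' \code{maxIntensity} (default: the stack maximum), so a round trip through
#' [loadStack()] preserves values to single precision. The sidecar records the
#' scale factor along with the spatial metadata.
#'
#' @param stack a [SampleStack].
#' @param tiffPath output TIFF path.
#' @param metaPath output YAML path (default: \code{tiffPath} with .yaml).
#' @param maxIntensity positive scale used to map intensities into [0, 1].
#' @return invisibly, the paths written.
#' @export
writeStack <- function(stack, tiffPath,
                       metaPath = sub("\\.tiff?$", ".yaml", tiffPath),
                       maxIntensity = NULL) {
  stopifnot(is(stack, "SampleStack"))
  if (is.null(maxIntensity))
    maxIntensity <- max(1e-12, max(vapply(stack@slices, max, numeric(1))))
  pages <- lapply(stack@slices, function(m) pmin(pmax(m / maxIntensity, 0), 1))
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 32L)
  meta <- list(
    pixel_size_um = stack@pixelSizeUm, z_step_um = stack@zStepUm,
    z0_um = stack@z0Um, circumferential_ref_deg = stack@circumferentialRefDeg,
    sample_id = stack@sampleId, patient_id = stack@patientId,
    group = stack@group, segment = stack@segment,
    intensity_scale = maxIntensity
  )
  yaml::write_yaml(meta, metaPath)
  invisible(c(tiff = tiffPath, meta = metaPath))
}
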