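# Shared fixtures: all synthetic, built in code at test time.

# Average the angular distributions of several phantom fields imaged from one
# orientation truth -- the per-condition estimate used in the recovery
# studies (mirrors imaging several fields of view of one sample).
averagedFieldDistribution <- function(truth, seeds, imageSizePx = 512,
                                      nFibers = 600, ...) {
  dsum <- numeric(180)
  for (s in seeds) {
    sp <- phantomSpec(imageSizePx = imageSizePx, nFibers = nFibers,
                      truth = truth, seed = s, ...)
    dsum <- dsum + angularDensity(quantifySlice(renderPhantom(sp)$image))
  }
  new("AngularDistribution", density = dsum / (sum(dsum) * pi / 180),
      depthUm = 0, sourceId = "field-average", isotropic = FALSE)
}

# Minimal valid slice list for SampleStack construction tests
tinySlices <- function(n = 3, side = 16, value = 1) {
  lapply(seq_len(n), function(k) matrix(value * k, side, side))
}

# DepthProfile with prescribed parameters (no imaging), for summary and
# correlation tests
syntheticProfile <- function(depths, aBar, alpha1 = 30, alpha2 = -30,
                             w = 0.6, isotropic = FALSE, sampleId = "S",
                             patientId = "P", group = "control",
                             zStepUm = NULL) {
  n <- length(depths)
  rec <- function(x) rep_len(x, n)
  fitsList <- lapply(seq_len(n), function(i) {
    iso <- rec(isotropic)[i]
    if (iso) {
      vonMisesParams(0, 0, NA, NA, 0.5, isotropic = TRUE)
    } else {
      ab <- rec(aBar)[i]
      vonMisesParams(ab, ab, rec(alpha1)[i], rec(alpha2)[i], rec(w)[i])
    }
  })
  depthProfile(fitsList, depthsUm = depths, sampleId = sampleId,
               patientId = patientId, group = group,
               zStepUm = if (is.null(zStepUm)) NA_real_ else zStepUm)
}
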