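## Reproducibility studies: seeded end-to-end experiments on synthetic
## phantoms that measure how faithfully the pipeline recovers known ground
## truth. Used by the test suite and the acceptance script; also the
## recommended way to re-validate the pipeline after changing its
## configuration.

#' Per-condition angular distribution from several phantom fields
#'
#' Renders \code{nFields} independent phantoms of one orientation truth and
#' averages their angular distributions — the synthetic analogue of imaging
#' several fields of view of one sample, which suppresses the spectral
#' speckle noise of a single acquisition by roughly the square root of the
#' number of fields.
#'
#' @param truth a [VonMisesFit] ground truth.
#' @param nFields number of phantom fields to average (default 6).
#' @param seed integer; field k uses seed \code{seed + k}.
#' @param imageSizePx,nFibers forwarded to [phantomSpec()].
#' @param ... further [phantomSpec()] arguments.
#' @return an [AngularDistribution].
#' @export
fieldAveragedDistribution <- function(truth, nFields = 6, seed = 1L,
                                      imageSizePx = 512, nFibers = 600, ...) {
  dsum <- numeric(180)
  for (k in seq_len(nFields)) {
    sp <- phantomSpec(imageSizePx = imageSizePx, nFibers = nFibers,
                      truth = truth, seed = seed + k, ...)
    dsum <- dsum + angularDensity(quantifySlice(renderPhantom(sp)$image))
  }
  new("AngularDistribution", density = dsum / (sum(dsum) * pi / 180),
      depthUm = 0, sourceId = "field-average", isotropic = FALSE)
}

#' Single-family orientation accuracy study
#'
#' For each seed, draws a concentration uniformly from \code{aRange}, takes
#' the next angle from \code{alphas}, renders a field-averaged phantom
#' distribution and records where its mode lands and where the fitted
#' dominant orientation lands relative to the truth.
#'
#' @param nSeeds number of independent conditions (default 50).
#' @param aRange concentration range the truth is drawn from (default 2-8).
#' @param alphas cycle of truth orientations in degrees.
#' @param nFields fields averaged per condition (default 6).
#' @param imageSizePx,nFibers phantom scale.
#' @param seed master seed.
#' @return data.frame with one row per seed: a, alpha_deg, mode_err_deg,
#'   alpha_err_deg.
#' @export
orientationAccuracyStudy <- function(nSeeds = 50, aRange = c(2, 8),
                                     alphas = c(-60, -30, 0, 30, 60),
                                     nFields = 6, imageSizePx = 512,
                                     nFibers = 600, seed = 1L) {
  res <- vector("list", nSeeds)
  for (s in seq_len(nSeeds)) {
    set.seed(seed + s)
    a <- stats::runif(1, aRange[1], aRange[2])
    al <- alphas[(s - 1L) %% length(alphas) + 1L]
    truth <- vonMisesParams(a, a, al, al, 1)
    d <- fieldAveragedDistribution(truth, nFields = nFields,
                                   seed = seed * 1000L + s * nFields,
                                   imageSizePx = imageSizePx,
                                   nFibers = nFibers)
    f <- fitMixture(d)
    dom <- if (f@isotropic) NA_real_ else
      if (f@w >= 0.5) f@alpha1Deg else f@alpha2Deg
    res[[s]] <- data.frame(
      a = a, alpha_deg = al,
      mode_err_deg = abs(wrapAngle(angleGrid()[which.max(angularDensity(d))] - al)),
      alpha_err_deg = abs(wrapAngle(dom - al)))
  }
  do.call(rbind, res)
}

#' Two-family parameter recovery study
#'
#' For each seed, builds a two-family truth with the next angular separation
#' from \code{deltaAlphas} (families at +/- half the separation around zero,
#' concentrations \code{aTrue}, weight \code{wTrue}), renders a
#' field-averaged phantom distribution, fits the mixture, and records the
#' errors of the weight, both preferred orientations and the average
#' alignment.
#'
#' @param seedsPerDelta seeds per separation (default 15).
#' @param deltaAlphas angular separations in degrees (default 30, 45, 75).
#' @param aTrue,wTrue truth concentration and weight (defaults 3.5 and 0.6).
#' @param nFields fields averaged per condition (default 6).
#' @param imageSizePx,nFibers phantom scale.
#' @param seed master seed.
#' @return data.frame per seed: delta_alpha_deg, w_err, alpha1_err_deg,
#'   alpha2_err_deg, abar_rel_err.
#' @export
recoveryStudy <- function(seedsPerDelta = 15, deltaAlphas = c(30, 45, 75),
                          aTrue = 3.5, wTrue = 0.6, nFields = 6,
                          imageSizePx = 512, nFibers = 600, seed = 1L) {
  res <- list()
  for (da in deltaAlphas) for (s in seq_len(seedsPerDelta)) {
    truth <- vonMisesParams(aTrue, aTrue, da / 2, -da / 2, wTrue)
    d <- fieldAveragedDistribution(
      truth, nFields = nFields,
      seed = seed * 1000L + da * 101L + s * nFields,
      imageSizePx = imageSizePx, nFibers = nFibers)
    f <- fitMixture(d)
    res[[length(res) + 1L]] <- data.frame(
      delta_alpha_deg = da,
      w_err = abs(f@w - wTrue),
      alpha1_err_deg = abs(wrapAngle(f@alpha1Deg - da / 2)),
      alpha2_err_deg = abs(wrapAngle(f@alpha2Deg + da / 2)),
      abar_rel_err = abs(f@aBar / aTrue - 1))
  }
  do.call(rbind, res)
}

#' Type-I error calibration of the group comparison
#'
#' Simulates the null: three groups of patients drawn from one normal
#' distribution of alignment values, compared with [anovaBetweenGroups()];
#' reports the fraction of simulations rejecting at the 5 percent level.
#'
#' @param nReps simulations (default 1000).
#' @param nPerGroup patients per group (default 9).
#' @param seed master seed.
#' @return single numeric, the empirical type-I error rate.
#' @export
anovaCalibrationStudy <- function(nReps = 1000, nPerGroup = 9, seed = 1L) {
  set.seed(seed)
  n <- 3 * nPerGroup
  grp <- rep(c("control", "FED", "BD"), each = nPerGroup)
  rej <- logical(nReps)
  for (r in seq_len(nReps)) {
    pats <- data.frame(patient_id = sprintf("p%03d", seq_len(n)), group = grp,
                       a_bar = stats::rnorm(n, mean = 3, sd = 1))
    rej[r] <- anovaBetweenGroups(pats, "a_bar")$p.value < 0.05
  }
  mean(rej)
}

#' Control-like versus BD-like stack discrimination study
#'
#' Renders several control-like and BD-like stacks, runs the full per-slice
#' pipeline, and compares the mean fitted alignment over the first
#' \code{fibrosaDepthUm} micrometers between the groups — the depth range
#' where healthy fibrosa collagen is highly aligned while Barlow's-disease
#' tissue stays dispersed.
#'
#' @param nStacksPerGroup stacks per group (default 3).
#' @param nSlices slices per stack (default 19).
#' @param zStepUm axial step (default 50, i.e. 0-900 um coverage).
#' @param imageSizePx,nFibers phantom scale.
#' @param fibrosaDepthUm depth bound of the comparison (default 300).
#' @param seed master seed.
#' @return list with mean fitted alignment per group over the fibrosa range
#'   (control_abar, bd_abar), their ratio, and the per-stack profiles.
#' @export
stackDiscriminationStudy <- function(nStacksPerGroup = 3, nSlices = 19,
                                     zStepUm = 50, imageSizePx = 512,
                                     nFibers = 600, fibrosaDepthUm = 300,
                                     seed = 1L) {
  run <- function(template, k) {
    spec <- stackSpec(template, nSlices = nSlices, zStepUm = zStepUm,
                      imageSizePx = imageSizePx, nFibers = nFibers,
                      seed = seed * 100L + k)
    st <- renderStack(spec, sampleId = sprintf("%s_%d", template, k),
                      patientId = sprintf("p_%s_%d", template, k))
    fitStack(st$stack, keepDistributions = FALSE)
  }
  ctl <- lapply(seq_len(nStacksPerGroup), run, template = "control_like")
  bd <- lapply(seq_len(nStacksPerGroup) + nStacksPerGroup, run,
               template = "BD_like")
  fib <- function(p) {
    f <- fits(p)
    f$a_bar[f$depth_um < fibrosaDepthUm]
  }
  ctlAbar <- mean(unlist(lapply(ctl, fib)))
  bdAbar <- mean(unlist(lapply(bd, fib)))
  list(control_abar = ctlAbar, bd_abar = bdAbar,
       ratio = ctlAbar / bdAbar, control = ctl, bd = bd)
}
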