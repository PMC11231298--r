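## Patient-level aggregation and between-group inference: per-patient
## averages, one-way ANOVA (linear variables), Watson-Williams circular
## ANOVA on doubled angles (orientations), and the depth-binned group report.

#' Per-patient averages of alignment and orientation
#'
#' Collapses the depth profiles of each patient to one record: the average
#' alignment \eqn{\bar a} over all measured depths (isotropic layers enter as
#' 0) and over the first \code{fibrosaDepthUm} micrometers (the fibrosa
#' layer), plus axial circular means of the two preferred orientations and
#' the mean angle between them (isotropic layers excluded from all
#' orientation summaries). Patients contributing two samples (e.g. segments
#' A2 and P2, or two diseased samples) are averaged sample-first, then
#' across samples; orientation angles across samples use the axial circular
#' mean.
#'
#' @param profiles list of [DepthProfile] objects (possibly several per
#'   patient; patient identity from \code{patientId}).
#' @param fibrosaDepthUm depth bound of the fibrosa-restricted average
#'   (default 300).
#' @return data.frame with one row per patient: patient_id, group,
#'   n_samples, a_bar, a_bar_fibrosa, alpha1_deg, alpha2_deg,
#'   delta_alpha_deg.
#' @export
perPatientAverage <- function(profiles, fibrosaDepthUm = 300) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, is, logical(1), "DepthProfile")))
  perSample <- lapply(profiles, function(p) {
    f <- p@fits
    o <- f[!f$isotropic, ]
    fib <- f[f$depth_um < fibrosaDepthUm, ]
    data.frame(
      patient_id = patientId(p), group = groupLabel(p),
      a_bar = mean(f$a_bar),
      a_bar_fibrosa = if (nrow(fib)) mean(fib$a_bar) else NA_real_,
      alpha1_deg = axialMean(o$alpha1_deg),
      alpha2_deg = axialMean(o$alpha2_deg),
      delta_alpha_deg = if (nrow(o)) {
        mean(angleBetween(o$alpha1_deg, o$alpha2_deg))
      } else NA_real_)
  })
  ps <- do.call(rbind, perSample)
  out <- lapply(split(ps, ps$patient_id), function(g) {
    data.frame(
      patient_id = g$patient_id[1], group = g$group[1], n_samples = nrow(g),
      a_bar = mean(g$a_bar),
      a_bar_fibrosa = mean(g$a_bar_fibrosa, na.rm = TRUE),
      alpha1_deg = axialMean(g$alpha1_deg),
      alpha2_deg = axialMean(g$alpha2_deg),
      delta_alpha_deg = mean(g$delta_alpha_deg, na.rm = TRUE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Best/Fisher approximation of the inverse of A1(kappa) = I1/I0
.a1inv <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal mean directions
#'
#' Circular one-way ANOVA for axial orientation data: angles are doubled
#' (mapping the 180-degree period onto the full circle), per-group and
#' pooled resultant lengths are compared through the F statistic
#' \deqn{F = K \frac{(N-k)\,(\sum_i R_i - R)}{(k-1)\,(N - \sum_i R_i)},}
#' with the standard correction \eqn{K = 1 + 3/(8\hat\kappa)} where
#' \eqn{\hat\kappa} is estimated from the mean resultant length. Valid for
#' reasonably concentrated samples (\eqn{\hat\kappa \gtrsim 1}); a warning is
#' issued otherwise.
#'
#' @param angles numeric vector of axial angles in degrees (NA dropped).
#' @param groups factor or character vector parallel to \code{angles}.
#' @return list with elements statistic (F), p.value, df, kappa, method.
#' @export
watsonWilliamsTest <- function(angles, groups) {
  ok <- is.finite(angles)
  angles <- angles[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  N <- length(angles)
  if (k < 2L || any(table(groups) < 2L))
    stop("need at least two groups with at least two observations each")
  th <- angles * pi / 90  # doubled angles in radians
  Ri <- vapply(split(th, groups), function(x)
    sqrt(sum(cos(x))^2 + sum(sin(x))^2), numeric(1))
  R <- sqrt(sum(cos(th))^2 + sum(sin(th))^2)
  rbar <- sum(Ri) / N
  kappa <- .a1inv(rbar)
  if (rbar < 0.45)
    warning("low concentration (mean resultant < 0.45): Watson-Williams F-test may be unreliable")
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * ((N - k) * (sum(Ri) - R)) / ((k - 1) * (N - sum(Ri)))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  list(statistic = Fstat, p.value = p, df = c(k - 1, N - k),
       kappa = kappa, method = "Watson-Williams")
}

#' Between-group comparison of patient-level variables
#'
#' One-way ANOVA across groups of the per-patient records from
#' [perPatientAverage()]. Linear variables (\code{a_bar},
#' \code{a_bar_fibrosa}, \code{delta_alpha_deg}) use the classical F-test;
#' angular variables (\code{alpha1_deg}, \code{alpha2_deg}) use the
#' Watson-Williams test on doubled angles by default (orientation data are
#' circular), with \code{method = "linear"} available for comparison.
#' Boxplot summaries (median, quartiles, whiskers, outliers beyond 1.5 IQR)
#' are attached per group.
#'
#' @param patients data.frame from [perPatientAverage()].
#' @param variable one of \code{"a_bar"}, \code{"a_bar_fibrosa"},
#'   \code{"alpha1_deg"}, \code{"alpha2_deg"}, \code{"delta_alpha_deg"}.
#' @param method \code{"auto"} (circular for orientations, linear otherwise),
#'   \code{"linear"} or \code{"circular"}.
#' @return list with statistic (F), p.value, df, method, n (per group) and
#'   boxplot (per-group \code{grDevices::boxplot.stats}).
#' @export
anovaBetweenGroups <- function(patients, variable = "a_bar",
                               method = c("auto", "linear", "circular")) {
  method <- match.arg(method)
  stopifnot(variable %in% names(patients))
  x <- patients[[variable]]
  g <- factor(patients$group)
  ok <- is.finite(x)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("need at least two groups with at least two patients each")
  angular <- variable %in% c("alpha1_deg", "alpha2_deg")
  if (method == "auto") method <- if (angular) "circular" else "linear"
  if (method == "circular") {
    ww <- watsonWilliamsTest(x, g)
    res <- list(statistic = ww$statistic, p.value = ww$p.value, df = ww$df,
                method = "Watson-Williams")
  } else {
    fit <- stats::aov(x ~ g)
    s <- summary(fit)[[1]]
    res <- list(statistic = s[["F value"]][1], p.value = s[["Pr(>F)"]][1],
                df = c(s[["Df"]][1], s[["Df"]][2]), method = "one-way ANOVA")
  }
  res$n <- table(g)
  res$boxplot <- lapply(split(x, g), grDevices::boxplot.stats)
  res
}

#' Average row of a depth-binned report column
#'
#' Collapses the nine (or however many) depth-bin summaries of one report
#' column to the table's Average row: the arithmetic mean of the bin values,
#' rounded to the reporting precision (2 decimals for the alignment
#' \eqn{\bar a}, whole degrees for orientations and angle differences).
#'
#' @param binValues numeric vector of per-bin means (or SDs).
#' @param digits rounding digits (2 for alignment, 0 for angles).
#' @return single rounded numeric.
#' @examples
#' table1AverageRow(c(6.02, 6.47, 4.76, 2.61, 2.14, 2.01, 1.76, 2.24, 3.86),
#'                  digits = 2)  # 3.54
#' @export
table1AverageRow <- function(binValues, digits = 2) {
  round(mean(binValues), digits)
}

#' Depth-binned group report (mean (SD) per depth bin per group)
#'
#' Builds the group summary table: for every group and depth bin, the across-
#' sample mean and sample SD of \eqn{\bar a}, the two preferred orientations
#' and the angle between them; bins reaching only one sample report SD 0.
#' Per sample, bin values come from [binByDepth()]; orientations are averaged
#' across samples with the axial circular mean. An Average row per group
#' gives the arithmetic mean of the bin means (and of the bin SDs), rounded
#' to the reporting precision via [table1AverageRow()].
#'
#' @param profiles list of [DepthProfile] objects with group labels.
#' @param binUm bin width (default 100).
#' @param maxDepthUm report depth range (default 900, i.e. nine 100-um bins).
#' @return data.frame with columns group, bin (label or "Average"),
#'   bin_lo_um, n_samples, a_bar_mean, a_bar_sd, alpha1_deg, alpha1_sd,
#'   alpha2_deg, alpha2_sd, delta_alpha_deg, delta_alpha_sd. Mean columns in
#'   Average rows are rounded (2 decimals for alignment, whole degrees for
#'   angles); bin rows are unrounded.
#' @export
buildTable1 <- function(profiles, binUm = 100, maxDepthUm = 900) {
  stopifnot(all(vapply(profiles, is, logical(1), "DepthProfile")))
  binned <- lapply(profiles, binByDepth, binUm = binUm)
  groups <- vapply(profiles, groupLabel, character(1))
  lo <- seq(0, maxDepthUm - binUm, by = binUm)
  rows <- list()
  for (g in intersect(.GROUPS, unique(groups))) {
    gb <- binned[groups == g]
    cells <- lapply(lo, function(b) {
      per <- lapply(gb, function(d) d[d$bin_lo_um == b, , drop = FALSE])
      per <- do.call(rbind, per[vapply(per, nrow, integer(1)) > 0])
      if (is.null(per) || !nrow(per)) return(NULL)
      sd0 <- function(x) if (sum(is.finite(x)) > 1L) stats::sd(x, na.rm = TRUE) else 0
      ## axial SD of per-sample circular means, measured around their axial
      ## mean so the spread is wrap-free
      axialSd <- function(a) {
        a <- a[is.finite(a)]
        if (length(a) < 2L) return(0)
        stats::sd(wrapAngle(a - axialMean(a)))
      }
      data.frame(
        group = g, bin = sprintf("%d-%d", b, b + binUm), bin_lo_um = b,
        n_samples = nrow(per),
        a_bar_mean = mean(per$a_bar_mean), a_bar_sd = sd0(per$a_bar_mean),
        alpha1_deg = axialMean(per$alpha1_deg),
        alpha1_sd = axialSd(per$alpha1_deg),
        alpha2_deg = axialMean(per$alpha2_deg),
        alpha2_sd = axialSd(per$alpha2_deg),
        delta_alpha_deg = mean(per$delta_alpha_deg, na.rm = TRUE),
        delta_alpha_sd = sd0(per$delta_alpha_deg))
    })
    cells <- do.call(rbind, cells)
    if (is.null(cells)) next
    avg <- data.frame(
      group = g, bin = "Average", bin_lo_um = NA_real_,
      n_samples = max(cells$n_samples),
      a_bar_mean = table1AverageRow(cells$a_bar_mean, 2),
      a_bar_sd = table1AverageRow(cells$a_bar_sd, 2),
      alpha1_deg = table1AverageRow(cells$alpha1_deg, 0),
      alpha1_sd = table1AverageRow(cells$alpha1_sd, 0),
      alpha2_deg = table1AverageRow(cells$alpha2_deg, 0),
      alpha2_sd = table1AverageRow(cells$alpha2_sd, 0),
      delta_alpha_deg = table1AverageRow(cells$delta_alpha_deg, 0),
      delta_alpha_sd = table1AverageRow(cells$delta_alpha_sd, 0))
    rows[[g]] <- rbind(cells, avg)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
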