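#' Hounsfield-unit thresholds for bone classification
#'
#' Voxels with HU `>= cortical_min` are cortical bone, voxels in
#' `[cancellous_min, cortical_min)` are cancellous bone, and everything
#' below `cancellous_min` is sub-threshold (marrow, fat, soft tissue).
#' The defaults (219 and 867 HU) are the calibration-phantom means used
#' throughout the package; they apply to raw HU with no per-specimen
#' rescaling, which is appropriate when all scans share one scanner and
#' protocol.
#'
#' @param cancellous_min Lower HU bound of cancellous bone.
#' @param cortical_min Lower HU bound of cortical bone
#'   (`> cancellous_min`).
#' @param provenance `"default"` or a list recorded by
#'   [derive_thresholds()].
#' @return Object of class `density_thresholds`.
#' @export
density_thresholds <- function(cancellous_min = 219, cortical_min = 867,
                               provenance = "default") {
  if (!is.finite(cancellous_min) || !is.finite(cortical_min)) {
    stop("thresholds must be finite", call. = FALSE)
  }
  if (cancellous_min >= cortical_min) {
    stop("cancellous_min must be < cortical_min", call. = FALSE)
  }
  structure(list(cancellous_min = cancellous_min,
                 cortical_min = cortical_min, provenance = provenance),
            class = "density_thresholds")
}

#' @export
print.density_thresholds <- function(x, ...) {
  prov <- if (is.character(x$provenance)) x$provenance
          else sprintf("calibrated from %d scan(s)", x$provenance$n_scans)
  cat(sprintf("<density_thresholds> cancellous >= %g HU, cortical >= %g HU (%s)\n",
              x$cancellous_min, x$cortical_min, prov))
  invisible(x)
}

#' Derive classification thresholds from calibration-phantom scans
#'
#' Each scan contributes one (cancellous-insert mean, cortical-insert
#' mean) HU pair; the thresholds are the across-scan means rounded to
#' the nearest integer HU, with per-scan means and SDs recorded as
#' provenance.
#'
#' @param phantom_means Two-column matrix or data frame; column 1 =
#'   cancellous ROI mean, column 2 = cortical ROI mean, one row per scan.
#' @return A [density_thresholds()] with calibrated provenance.
#' @export
derive_thresholds <- function(phantom_means) {
  pm <- as.matrix(phantom_means)
  if (ncol(pm) != 2L || nrow(pm) < 1L) {
    stop("phantom_means must have >= 1 row of (cancellous, cortical) means",
         call. = FALSE)
  }
  stopifnot_finite(pm, "phantom ROI means")
  if (any(pm[, 1] >= pm[, 2])) {
    stop("calibration error: a scan has cancellous mean >= cortical mean",
         call. = FALSE)
  }
  mu <- round(colMeans(pm))
  sds <- if (nrow(pm) > 1L) apply(pm, 2L, stats::sd) else c(NA_real_, NA_real_)
  density_thresholds(mu[1], mu[2],
                     provenance = list(n_scans = nrow(pm),
                                       scan_means = unname(pm),
                                       sd = unname(sds)))
}

#' Classify HU values into bone compartments
#'
#' @param hu Numeric vector of finite HU values.
#' @param th A [density_thresholds()].
#' @return Factor with levels `cortical`, `cancellous`, `sub_threshold`;
#'   the three classes partition every finite HU value.
#' @export
classify_hu <- function(hu, th = density_thresholds()) {
  stopifnot(inherits(th, "density_thresholds"))
  if (any(!is.finite(hu))) {
    stop("HU values must be finite", call. = FALSE)
  }
  cls <- ifelse(hu >= th$cortical_min, "cortical",
                ifelse(hu >= th$cancellous_min, "cancellous",
                       "sub_threshold"))
  factor(cls, levels = c("cortical", "cancellous", "sub_threshold"))
}
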