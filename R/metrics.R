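#' Density and volume metrics for one dowel-body ROI
#'
#' Computes the per-trajectory, per-body metrics: mean HU over the whole
#' ROI (`a_t`), over its cortical voxels (`a_c`) and cancellous voxels
#' (`a_ca`), the corresponding voxel counts, and the bone fraction
#' `(n_cortical + n_cancellous) / n_total`. The ROI total is the dowel
#' intersected with one body's mask, so sub-threshold voxels *inside*
#' the body count toward the total (extra-osseous dowel voxels do not).
#' Means over empty classes are `NA`, never 0.
#'
#' @param v A [voxel_volume()].
#' @param body_roi Logical 3D array: the dowel restricted to one body.
#' @param th A [density_thresholds()].
#' @param specimen,trajectory,body Identifier columns copied into the
#'   output row.
#' @return One-row data frame with columns `specimen`, `trajectory`,
#'   `body`, `n_total`, `n_cortical`, `n_cancellous`, `a_t`, `a_c`,
#'   `a_ca`, `bone_fraction`.
#' @export
compute_roi_metrics <- function(v, body_roi, th = density_thresholds(),
                                specimen = NA_character_,
                                trajectory = NA_character_,
                                body = NA_character_) {
  stopifnot(inherits(v, "voxel_volume"), is.logical(body_roi))
  if (!all(dim(body_roi) == dim(v$data))) {
    stop("ROI mask and volume are not congruent", call. = FALSE)
  }
  hu <- v$data[body_roi]
  n_total <- length(hu)
  if (n_total == 0L) {
    warning("empty body ROI: all metrics undefined", call. = FALSE)
    return(data.frame(specimen = specimen, trajectory = trajectory,
                      body = body, n_total = 0L, n_cortical = 0L,
                      n_cancellous = 0L, a_t = NA_real_, a_c = NA_real_,
                      a_ca = NA_real_, bone_fraction = NA_real_,
                      stringsAsFactors = FALSE))
  }
  cls <- classify_hu(hu, th)
  n_cort <- sum(cls == "cortical")
  n_canc <- sum(cls == "cancellous")
  data.frame(specimen = specimen, trajectory = trajectory, body = body,
             n_total = n_total, n_cortical = n_cort, n_cancellous = n_canc,
             a_t = mean(hu),
             a_c = if (n_cort > 0L) mean(hu[cls == "cortical"]) else NA_real_,
             a_ca = if (n_canc > 0L) mean(hu[cls == "cancellous"]) else NA_real_,
             bone_fraction = bone_fraction(n_cort, n_canc, n_total),
             stringsAsFactors = FALSE)
}

#' Bone fraction from voxel counts
#'
#' The fraction of an ROI's voxels classified as bone (cortical plus
#' cancellous) out of its total voxel count; `NA` when the total is 0.
#'
#' @param n_cortical,n_cancellous,n_total Non-negative voxel counts with
#'   `n_cortical + n_cancellous <= n_total` (vectorized).
#' @return Numeric fraction(s) in `[0, 1]`.
#' @export
bone_fraction <- function(n_cortical, n_cancellous, n_total) {
  if (any(n_cortical < 0 | n_cancellous < 0 | n_total < 0)) {
    stop("voxel counts must be non-negative", call. = FALSE)
  }
  if (any(n_cortical + n_cancellous > n_total)) {
    stop("count inconsistency: cortical + cancellous exceeds total",
         call. = FALSE)
  }
  ifelse(n_total > 0, (n_cortical + n_cancellous) / n_total, NA_real_)
}

#' Aggregate per-specimen metrics into a cohort summary
#'
#' Cell means are means of *per-specimen* values (mean of per-specimen
#' bone fractions, not a ratio of summed counts); SDs use the n-1
#' denominator. Cells with a single specimen keep their mean but get an
#' `NA` SD with a warning; cells missing specimens relative to the
#' fullest cell are flagged `incomplete`.
#'
#' @param metrics Data frame of [compute_roi_metrics()] rows (one per
#'   specimen x trajectory x body).
#' @param gaps Optional data frame with columns `specimen`, `trajectory`,
#'   `gap_mm` (one per specimen x trajectory).
#' @return List of class `cohort_summary` with data frames `metrics`
#'   (trajectory x body cells) and `gaps` (trajectory cells, or `NULL`).
#' @export
aggregate_cohort <- function(metrics, gaps = NULL) {
  stopifnot(is.data.frame(metrics))
  value_cols <- c("n_total", "n_cortical", "n_cancellous", "a_t", "a_c",
                  "a_ca", "bone_fraction")
  value_cols <- intersect(value_cols, names(metrics))
  cells <- unique(metrics[c("trajectory", "body")])
  cells <- cells[order(cells$trajectory, cells$body), , drop = FALSE]
  n_max <- max(table(paste(metrics$trajectory, metrics$body)))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- metrics[metrics$trajectory == cells$trajectory[i] &
                     metrics$body == cells$body[i], , drop = FALSE]
    out <- data.frame(trajectory = cells$trajectory[i],
                      body = cells$body[i], n_specimens = nrow(sub),
                      incomplete = nrow(sub) < n_max,
                      stringsAsFactors = FALSE)
    if (nrow(sub) == 1L) {
      warning(sprintf("single specimen in cell %s/%s: SD undefined",
                      cells$trajectory[i], cells$body[i]), call. = FALSE)
    }
    for (vc in value_cols) {
      vals <- sub[[vc]]
      out[[paste0(vc, "_mean")]] <- mean(vals, na.rm = TRUE)
      out[[paste0(vc, "_sd")]] <- if (nrow(sub) > 1L) {
        stats::sd(vals, na.rm = TRUE)
      } else NA_real_
    }
    out
  })
  metrics_summary <- do.call(rbind, rows)
  gaps_summary <- NULL
  if (!is.null(gaps)) {
    stopifnot(all(c("specimen", "trajectory", "gap_mm") %in% names(gaps)))
    tr <- sort(unique(gaps$trajectory))
    gaps_summary <- do.call(rbind, lapply(tr, function(t) {
      g <- gaps$gap_mm[gaps$trajectory == t]
      data.frame(trajectory = t, n_specimens = length(g),
                 gap_mean_mm = mean(g),
                 gap_sd_mm = if (length(g) > 1L) stats::sd(g) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(metrics = metrics_summary, gaps = gaps_summary),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$metrics, digits = 4)
  if (!is.null(x$gaps)) {
    cat("joint gaps:\n")
    print(x$gaps, digits = 4)
  }
  invisible(x)
}
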