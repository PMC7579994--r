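#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs: input mode (synthetic
#' phantom cohort or files on disk), dowel diameter, classification
#' thresholds, trajectory list, output directory and seed.
#'
#' @param mode `"synthetic"` (generate a phantom cohort) or `"files"`
#'   (read volumes, masks and fiducials from disk).
#' @param n_specimens Cohort size in synthetic mode.
#' @param base_spec Optional [phantom_spec()] whose parameters define the
#'   synthetic cohort (its seed is replaced per specimen); defaults to
#'   the package's standard two-body scene.
#' @param hu_jitter_sd Between-specimen SD (HU) applied to the cancellous
#'   means in synthetic mode, so cohort cells have realistic variance.
#' @param gap_jitter_sd Between-specimen SD (mm) of the joint gaps in
#'   synthetic mode.
#' @param files In `"files"` mode: list of per-specimen lists with
#'   elements `id`, `volume`, `mask`, `fiducials` (paths).
#' @param diameter_mm Dowel diameter (default 12 mm).
#' @param thresholds A [density_thresholds()] (defaults 219 / 867 HU).
#' @param trajectories Trajectory names to analyse.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing files.
#' @param seed Mandatory seed for every source of randomness.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), n_specimens = 9L,
                       base_spec = NULL, hu_jitter_sd = 25,
                       gap_jitter_sd = 0.4, files = NULL, diameter_mm = 12,
                       thresholds = density_thresholds(),
                       trajectories = c("top", "middle", "bottom",
                                        "PL1", "PL2"),
                       out_dir = NULL, seed) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && (missing(seed) || !is.finite(seed))) {
    stop("seed is mandatory in synthetic mode", call. = FALSE)
  }
  if (missing(seed)) seed <- 1L
  if (!is.finite(diameter_mm) || diameter_mm <= 0) {
    stop("diameter must be > 0", call. = FALSE)
  }
  stopifnot(inherits(thresholds, "density_thresholds"))
  if (mode == "files" && length(files) == 0L) {
    stop("files mode needs a non-empty `files` list", call. = FALSE)
  }
  if (is.null(base_spec)) base_spec <- phantom_spec(seed = 0L)
  structure(list(mode = mode, n_specimens = as.integer(n_specimens),
                 base_spec = base_spec, hu_jitter_sd = hu_jitter_sd,
                 gap_jitter_sd = gap_jitter_sd, files = files, diameter_mm = diameter_mm,
                 thresholds = thresholds, trajectories = trajectories,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Simulate a cohort of phantom specifications
#'
#' Derives one [phantom_spec()] per specimen from a base spec: each gets
#' its own sub-seed, cancellous HU means jittered by a between-specimen
#' Gaussian of SD `hu_jitter_sd`, and joint gaps jittered by
#' `gap_jitter_sd` (truncated at 0), so cohort cells carry realistic
#' anatomical variance.
#'
#' @param n Number of specimens.
#' @param base_spec Base [phantom_spec()].
#' @param seed Cohort seed.
#' @param hu_jitter_sd Between-specimen SD of the cancellous HU means.
#' @param gap_jitter_sd Between-specimen SD (mm) of the anterior and
#'   posterior joint gaps.
#' @return List of `n` phantom specs, names `S1`...`Sn`.
#' @export
simulate_cohort <- function(n, base_spec, seed, hu_jitter_sd = 25,
                            gap_jitter_sd = 0.4) {
  stopifnot(inherits(base_spec, "phantom_spec"), n >= 1L)
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    jit <- matrix(stats::rnorm(2L * n, 0, hu_jitter_sd), ncol = 2L)
    gjit <- matrix(stats::rnorm(2L * n, 0, gap_jitter_sd), ncol = 2L)
  })
  out <- lapply(seq_len(n), function(i) {
    sp <- base_spec
    canc <- sp$hu_cancellous + jit[i, ]
    # keep the material ordering invariant intact under jitter
    canc <- pmin(pmax(canc, sp$hu_soft_tissue + 50), sp$hu_cortical - 50)
    sp$hu_cancellous <- stats::setNames(canc, c("ilium", "sacrum"))
    sp$gap_mm <- max(0, sp$gap_mm + gjit[i, 1])
    sp$posterior_gap_mm <- max(0, sp$posterior_gap_mm + gjit[i, 2])
    sp$seed <- sub_seeds[i]
    sp
  })
  stats::setNames(out, paste0("S", seq_len(n)))
}

#' Analyze one specimen along its trajectories
#'
#' For each trajectory: build the dowel, split its voxels by body,
#' compute density/volume metrics per body, and measure the joint gap
#' between the two bodies' surfaces inside the dowel.
#'
#' @param volume A [voxel_volume()].
#' @param mask The paired [label_mask()] (must contain bodies `ilium`
#'   and `sacrum` for the gap computation).
#' @param fiducials Named list of [trajectory()] objects.
#' @param thresholds A [density_thresholds()].
#' @param diameter_mm Dowel diameter (mm).
#' @param specimen Specimen identifier.
#' @return List with data frames `metrics` (one row per trajectory x
#'   body) and `gaps` (one row per trajectory, including the
#'   extra-osseous dowel voxel tally).
#' @export
analyze_specimen <- function(volume, mask, fiducials,
                             thresholds = density_thresholds(),
                             diameter_mm = 12, specimen = "S1") {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "label_mask"))
  if (!same_geometry(volume, mask)) {
    stop("volume and label mask are not congruent", call. = FALSE)
  }
  bodies <- intersect(c("ilium", "left_ilium", "right_ilium", "sacrum"),
                      names(mask$table))
  surf <- list()
  if (all(c("ilium", "sacrum") %in% names(mask$table))) {
    surf$ilium <- extract_surface_points(mask, "ilium")
    surf$sacrum <- extract_surface_points(mask, "sacrum")
  }
  metrics <- list(); gaps <- list()
  for (tr in fiducials) {
    roi <- build_cylinder(tr, diameter_mm)
    cm <- cylinder_mask(roi, volume)
    parts <- split_by_body(cm, mask)
    for (b in bodies) {
      metrics[[paste(tr$name, b)]] <-
        compute_roi_metrics(volume, parts[[b]], thresholds,
                            specimen = specimen, trajectory = tr$name,
                            body = b)
    }
    if (length(surf) == 2L) {
      gr <- joint_gap_distance(surf$ilium, surf$sacrum, roi,
                               specimen = specimen,
                               contact_spacing_mm = volume$spacing)
      gaps[[tr$name]] <- data.frame(specimen = specimen,
                                    trajectory = tr$name,
                                    gap_mm = gr$gap_mm,
                                    n_extra_osseous = sum(parts$extra_osseous),
                                    stringsAsFactors = FALSE)
    }
  }
  list(metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
       gaps = if (length(gaps)) do.call(rbind, c(gaps, list(make.row.names = FALSE))) else NULL)
}

#' Cohort-level statistical comparisons
#'
#' The analysis-of-variance battery run on a cohort's per-specimen
#' results: a repeated-measures ANOVA of joint gap by trajectory with
#' Bonferroni-corrected pairwise post hoc tests, and a univariate
#' two-way ANOVA (body x trajectory) per density/volume outcome.
#'
#' @param metrics Per-specimen metrics data frame (see
#'   [analyze_specimen()]).
#' @param gaps Per-specimen gap data frame.
#' @param outcomes Outcome columns for the two-way ANOVAs.
#' @return List with `gap_rm_anova`, `gap_pairwise`, `two_way`.
#' @export
cohort_statistics <- function(metrics, gaps,
                              outcomes = c("a_t", "a_c", "a_ca",
                                           "n_cortical", "bone_fraction")) {
  gm <- gap_matrix(gaps)
  res <- list(gap_rm_anova = rm_anova(gm),
              gap_pairwise = bonferroni_pairwise(gm))
  tw <- list()
  for (oc in outcomes) {
    if (anyNA(metrics[[oc]])) {
      warning(sprintf("outcome %s has undefined cells; skipped", oc),
              call. = FALSE)
      next
    }
    tw[[oc]] <- two_way_anova(metrics, oc)
  }
  res$two_way <- do.call(rbind, c(tw, list(make.row.names = FALSE)))
  res
}

gap_matrix <- function(gaps) {
  tr <- unique(gaps$trajectory)
  sp <- unique(gaps$specimen)
  m <- matrix(NA_real_, nrow = length(sp), ncol = length(tr),
              dimnames = list(sp, tr))
  m[cbind(match(gaps$specimen, sp), match(gaps$trajectory, tr))] <- gaps$gap_mm
  m
}

#' Run the full trajectory-analysis pipeline
#'
#' Orchestrates phantom generation (or file ingestion), dowel ROI
#' construction, HU classification, per-trajectory metrics, joint-gap
#' measurement, cohort aggregation and statistics. With an `out_dir`,
#' writes `metrics.tsv` (tidy, one row per specimen x trajectory x
#' body), `gaps.tsv`, `summary.tsv` (one row per trajectory with ilium
#' and sacrum metric groups plus the gap column), `stats.tsv`, and a
#' `provenance.json` record of the configuration; the same config and
#' seed give byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list: `metrics`, `gaps`, `summary`
#'   (a [aggregate_cohort()] result), `summary_table` (wide layout),
#'   `stats`, `warnings`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  warn_log <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  per_spec <- list()
  if (cfg$mode == "synthetic") {
    specs <- simulate_cohort(cfg$n_specimens, cfg$base_spec, cfg$seed,
                             cfg$hu_jitter_sd, cfg$gap_jitter_sd)
    for (id in names(specs)) {
      ph <- make_two_body_phantom(specs[[id]])
      fid <- make_trajectory_landmarks(specs[[id]], cfg$trajectories,
                                       phantom = ph,
                                       diameter_mm = cfg$diameter_mm)
      per_spec[[id]] <- collect(
        analyze_specimen(ph$volume, ph$mask, fid, cfg$thresholds,
                         cfg$diameter_mm, specimen = id))
    }
  } else {
    for (f in cfg$files) {
      vol <- read_volume(f$volume)
      msk <- read_label_mask(f$mask)
      fid <- read_fiducials(f$fiducials)
      fid <- fid[intersect(cfg$trajectories, names(fid))]
      per_spec[[f$id]] <- collect(
        analyze_specimen(vol, msk, fid, cfg$thresholds, cfg$diameter_mm,
                         specimen = f$id))
    }
  }
  metrics <- do.call(rbind, c(lapply(per_spec, `[[`, "metrics"),
                              list(make.row.names = FALSE)))
  gaps <- do.call(rbind, c(lapply(per_spec, `[[`, "gaps"),
                           list(make.row.names = FALSE)))
  summary <- collect(aggregate_cohort(metrics, gaps))
  stats_res <- NULL
  if (!is.null(gaps) && length(unique(gaps$specimen)) >= 2L &&
      length(unique(gaps$trajectory)) >= 2L) {
    stats_res <- collect(cohort_statistics(metrics, gaps))
  } else {
    warn_log <- c(warn_log,
                  "cohort statistics skipped: need >= 2 specimens and >= 2 trajectories with gaps")
  }
  wide <- summary_table(summary)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv <- function(df, name) {
      utils::write.table(df, file.path(cfg$out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_tsv(metrics, "metrics.tsv")
    if (!is.null(gaps)) write_tsv(gaps, "gaps.tsv")
    write_tsv(wide, "summary.tsv")
    if (!is.null(stats_res)) write_tsv(flatten_stats(stats_res), "stats.tsv")
    prov <- list(
      mode = cfg$mode, seed = cfg$seed, n_specimens = length(per_spec),
      diameter_mm = cfg$diameter_mm,
      thresholds = list(cancellous_min = cfg$thresholds$cancellous_min,
                        cortical_min = cfg$thresholds$cortical_min),
      trajectories = cfg$trajectories,
      base_spec = if (cfg$mode == "synthetic") unclass(cfg$base_spec),
      package_version = as.character(utils::packageVersion("sijdowel")),
      warnings = warn_log)
    jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(metrics = metrics, gaps = gaps, summary = summary,
                 summary_table = wide, stats = stats_res,
                 warnings = warn_log))
}

# Wide, one row per trajectory: ilium and sacrum metric groups + gap.
summary_table <- function(summary) {
  ms <- summary$metrics
  tr <- unique(ms$trajectory)
  cols <- c("n_cortical", "n_cancellous", "n_total", "bone_fraction")
  rows <- lapply(tr, function(t) {
    row <- data.frame(trajectory = t, stringsAsFactors = FALSE)
    for (b in c("ilium", "sacrum")) {
      cell <- ms[ms$trajectory == t & ms$body == b, , drop = FALSE]
      for (cc in cols) {
        row[[paste(b, cc, "mean", sep = "_")]] <-
          if (nrow(cell)) cell[[paste0(cc, "_mean")]] else NA_real_
        row[[paste(b, cc, "sd", sep = "_")]] <-
          if (nrow(cell)) cell[[paste0(cc, "_sd")]] else NA_real_
      }
    }
    if (!is.null(summary$gaps)) {
      gc <- summary$gaps[summary$gaps$trajectory == t, , drop = FALSE]
      row$gap_mean_mm <- if (nrow(gc)) gc$gap_mean_mm else NA_real_
      row$gap_sd_mm <- if (nrow(gc)) gc$gap_sd_mm else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}

flatten_stats <- function(st) {
  rm <- data.frame(test = "gap_rm_anova", term = st$gap_rm_anova$effect,
                   statistic = st$gap_rm_anova$F,
                   df1 = st$gap_rm_anova$df1, df2 = st$gap_rm_anova$df2,
                   p = st$gap_rm_anova$p, p_adj = NA_real_,
                   stringsAsFactors = FALSE)
  pw <- data.frame(test = "gap_pairwise", term = st$gap_pairwise$comparison,
                   statistic = st$gap_pairwise$t,
                   df1 = st$gap_pairwise$df, df2 = NA_real_,
                   p = st$gap_pairwise$p, p_adj = st$gap_pairwise$p_adj,
                   stringsAsFactors = FALSE)
  tw <- data.frame(test = paste0("two_way_", st$two_way$outcome),
                   term = st$two_way$effect, statistic = st$two_way$F,
                   df1 = st$two_way$df1, df2 = st$two_way$df2,
                   p = st$two_way$p, p_adj = NA_real_,
                   stringsAsFactors = FALSE)
  rbind(rm, pw, tw)
}
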