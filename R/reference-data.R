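#' Reference cadaveric cohort tables
#'
#' Two small tables from a nine-specimen cadaveric sacroiliac cohort
#' ship with the package as worked-example inputs:
#'
#' * `sij_demographics()` — per-specimen age, sex, height, weight,
#'   L4 bone mineral density (g/cm^2) and DXA T-score.
#' * `sij_reference_summary()` — per-trajectory cohort summary (mean and
#'   SD of cortical/cancellous/total voxel counts and bone fraction for
#'   ilium and sacrum, plus the joint-gap distance in mm) for the three
#'   lateral (top/middle/bottom) and two posterolateral (PL1/PL2)
#'   trajectories.
#'
#' @return A data frame.
#' @export
sij_demographics <- function() {
  read_demographics(system.file("extdata", "cohort_demographics.csv",
                                package = "sijdowel", mustWork = TRUE))
}

#' @rdname sij_demographics
#' @export
sij_reference_summary <- function() {
  utils::read.csv(system.file("extdata", "reference_trajectory_summary.csv",
                              package = "sijdowel", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
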