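#' Read a specimen demographics table
#'
#' Expects a CSV with columns `specimen`, `age`, `sex`, `height_in`,
#' `weight_lbs`, `l4_bmd`, `t_score`. A nine-specimen cadaveric example
#' ships with the package:
#' `system.file("extdata", "cohort_demographics.csv", package = "sijdowel")`.
#'
#' @param path CSV file path.
#' @return Data frame, one row per specimen.
#' @export
read_demographics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "age", "sex", "height_in", "weight_lbs", "l4_bmd",
            "t_score")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("demographics table lacks columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(df$age <= 0) || any(df$l4_bmd <= 0)) {
    stop("age and BMD must be positive", call. = FALSE)
  }
  df
}

#' Summarize cohort demographics
#'
#' Per-variable mean and sample SD (n - 1 denominator) of the numeric
#' demographic columns.
#'
#' @param rows Demographics data frame (see [read_demographics()]).
#' @return Data frame with columns `variable`, `n`, `mean`, `sd`.
#' @export
summarize_demographics <- function(rows) {
  vars <- intersect(c("age", "height_in", "weight_lbs", "l4_bmd", "t_score"),
                    names(rows))
  if (nrow(rows) < 2L) {
    warning("fewer than 2 specimens: SD undefined", call. = FALSE)
  }
  do.call(rbind, lapply(vars, function(v) {
    x <- rows[[v]]
    data.frame(variable = v, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' WHO T-score classification
#'
#' Standard WHO densitometry bands: normal for T >= -1.0, osteopenia for
#' -2.5 < T < -1.0, osteoporosis for T <= -2.5.
#'
#' @param t Numeric vector of finite T-scores.
#' @return Factor with levels `normal`, `osteopenia`, `osteoporosis`.
#' @export
classify_t_score <- function(t) {
  if (any(!is.finite(t))) stop("T-scores must be finite", call. = FALSE)
  cls <- ifelse(t >= -1.0, "normal",
                ifelse(t > -2.5, "osteopenia", "osteoporosis"))
  factor(cls, levels = c("normal", "osteopenia", "osteoporosis"))
}

#' Repeated-measures one-way ANOVA
#'
#' Within-subject F test of a trajectory effect on a complete
#' specimen x trajectory matrix: the subject effect is absorbed as a
#' block, giving the trajectory F on (k - 1, (k - 1)(n - 1)) degrees of
#' freedom. No sphericity correction is applied. A zero trajectory sum
#' of squares yields F = 0, p = 1.
#'
#' @param values Numeric matrix, rows = specimens, columns = conditions
#'   (trajectories); no missing cells.
#' @return One-row data frame: `effect`, `F`, `df1`, `df2`, `p`, plus
#'   sums of squares `ss_subject`, `ss_effect`, `ss_residual`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells are not allowed", call. = FALSE)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) {
    stop("need >= 2 specimens and >= 2 trajectories", call. = FALSE)
  }
  cond <- colnames(values)
  if (is.null(cond)) cond <- paste0("c", seq_len(k))
  long <- data.frame(y = as.vector(values),
                     subject = factor(rep(seq_len(n), times = k)),
                     condition = factor(rep(cond, each = n), levels = cond))
  # degenerate (zero-SS) fits are handled explicitly below, so the
  # perfect-fit warning from anova() is noise here
  tab <- quiet_perfect_fit(
    stats::anova(stats::lm(y ~ subject + condition, data = long)))
  ss <- tab[["Sum Sq"]]; names(ss) <- rownames(tab)
  df2 <- tab["Residuals", "Df"]
  ms_res <- ss[["Residuals"]] / df2
  f <- if (ss[["condition"]] <= .Machine$double.eps * sum(ss)) 0 else {
    if (ms_res == 0) Inf else (ss[["condition"]] / (k - 1)) / ms_res
  }
  p <- if (f == 0) 1 else stats::pf(f, k - 1, df2, lower.tail = FALSE)
  data.frame(effect = "trajectory", F = f, df1 = k - 1L, df2 = df2, p = p,
             ss_subject = unname(ss[["subject"]]),
             ss_effect = unname(ss[["condition"]]),
             ss_residual = unname(ss[["Residuals"]]),
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected pairwise paired t tests
#'
#' Two-sided paired t test for each requested column pair, with the
#' Bonferroni adjustment `p_adj = min(1, p * n_pairs)`. Pairs whose
#' differences have zero variance get p = 1 with a warning.
#'
#' @param values Specimen x condition matrix as in [rm_anova()].
#' @param pairs List of length-2 vectors of column names or indices;
#'   defaults to all pairs.
#' @return Data frame: `comparison`, `t`, `df`, `p`, `p_adj`.
#' @export
bonferroni_pairwise <- function(values, pairs = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells are not allowed", call. = FALSE)
  cond <- colnames(values)
  if (is.null(cond)) cond <- paste0("c", seq_len(ncol(values)))
  colnames(values) <- cond
  if (is.null(pairs)) {
    pairs <- utils::combn(cond, 2L, simplify = FALSE)
  }
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    d <- values[, pr[1]] - values[, pr[2]]
    if (stats::sd(d) == 0) {
      warning(sprintf("zero-variance differences for %s vs %s: p set to 1",
                      pr[1], pr[2]), call. = FALSE)
      return(data.frame(comparison = paste(pr[1], "vs", pr[2]),
                        t = NA_real_, df = length(d) - 1L, p = 1,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(values[, pr[1]], values[, pr[2]], paired = TRUE)
    data.frame(comparison = paste(pr[1], "vs", pr[2]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * m)
  out
}

#' Two-way ANOVA per outcome over body and trajectory
#'
#' Univariate two-way fixed-effects ANOVA (main effects and interaction)
#' of one outcome over the crossed factors body (ilium/sacrum) and
#' trajectory, on a balanced design.
#'
#' @param data Long data frame with columns `body`, `trajectory`, and the
#'   outcome.
#' @param outcome Name of the outcome column.
#' @return Data frame with one row per effect (`body`, `trajectory`,
#'   `body:trajectory`): `F`, `df1`, `df2`, `p`.
#' @export
two_way_anova <- function(data, outcome) {
  stopifnot(all(c("body", "trajectory", outcome) %in% names(data)))
  data$body <- factor(data$body)
  data$trajectory <- factor(data$trajectory)
  counts <- table(data$body, data$trajectory)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0L)) {
    stop("unbalanced design: every body x trajectory cell needs the same number of observations",
         call. = FALSE)
  }
  y <- data[[outcome]]
  if (anyNA(y)) stop("outcome contains missing values", call. = FALSE)
  fit <- stats::lm(y ~ body * trajectory, data = data)
  tab <- quiet_perfect_fit(stats::anova(fit))
  eff <- c("body", "trajectory", "body:trajectory")
  df2 <- tab["Residuals", "Df"]
  # sums of squares at rounding-noise scale count as exactly zero
  ss_floor <- .Machine$double.eps * length(y) * (sum(y^2) + 1)
  ms_res <- tab["Residuals", "Sum Sq"] / df2
  out <- do.call(rbind, lapply(eff, function(e) {
    ss <- tab[e, "Sum Sq"]
    f <- if (ss <= ss_floor) 0
         else if (tab["Residuals", "Sum Sq"] <= ss_floor) Inf
         else tab[e, "F value"]
    p <- if (f == 0) 1 else if (is.infinite(f)) 0 else tab[e, "Pr(>F)"]
    data.frame(effect = e, F = f, df1 = tab[e, "Df"], df2 = df2, p = p,
               stringsAsFactors = FALSE)
  }))
  out$outcome <- outcome
  out[c("outcome", "effect", "F", "df1", "df2", "p")]
}

quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
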