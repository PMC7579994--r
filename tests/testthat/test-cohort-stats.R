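test_that("demographics summary reproduces the reference cohort statistics", {
  demo <- sij_demographics()
  smry <- summarize_demographics(demo)
  bmd <- smry[smry$variable == "l4_bmd", ]
  expect_equal(round(bmd$mean, 3), 0.948)
  expect_equal(round(bmd$sd, 3), 0.194)
  age <- smry[smry$variable == "age", ]
  expect_equal(round(age$mean), 60)
  expect_equal(round(age$sd), 18)
  expect_warning(summarize_demographics(demo[1, ]), "SD undefined")
  expect_equal(summarize_demographics(demo[c(1, 1), ])$sd,
               rep(0, 5))
})

test_that("WHO T-score bands give the reference 2/4/3 split and boundaries", {
  demo <- sij_demographics()
  counts <- table(classify_t_score(demo$t_score))
  expect_identical(as.integer(counts[c("normal", "osteopenia", "osteoporosis")]),
                   c(2L, 4L, 3L))
  expect_identical(as.character(classify_t_score(c(-1.0, -2.5, 0, -1.0001, -2.4999))),
                   c("normal", "osteoporosis", "normal", "osteopenia",
                     "osteopenia"))
  expect_error(classify_t_score(NaN), "finite")
})

test_that("repeated-measures ANOVA matches first-principles sums of squares", {
  m <- rbind(c(3, 5, 9), c(2, 4, 7), c(6, 6, 10), c(1, 3, 6))
  colnames(m) <- c("top", "middle", "PL1")
  got <- rm_anova(m)
  # oracle: raw within-subject partition computed from the definitions
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_cond <- n * sum((colMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_res <- ss_tot - ss_subj - ss_cond
  f_oracle <- (ss_cond / (k - 1)) / (ss_res / ((n - 1) * (k - 1)))
  expect_equal(got$F, f_oracle, tolerance = 1e-10)
  expect_identical(c(got$df1, got$df2), c(k - 1L, (n - 1L) * (k - 1L)))
  expect_equal(got$p, pf(f_oracle, k - 1, (n - 1) * (k - 1),
                         lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(got$ss_effect, ss_cond, tolerance = 1e-10)
  expect_equal(got$ss_subject, ss_subj, tolerance = 1e-10)
})

test_that("rm_anova absorbs subject effects and degenerates to F = 0", {
  m <- rbind(c(3, 5, 9), c(2, 4, 7), c(6, 6, 10), c(1, 3, 6))
  shifted <- m; shifted[2, ] <- shifted[2, ] + 100
  expect_equal(rm_anova(shifted)$F, rm_anova(m)$F, tolerance = 1e-9)

  flat <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)  # no trajectory effect
  got <- rm_anova(flat)
  expect_identical(got$F, 0)
  expect_identical(got$p, 1)
  expect_equal(got$ss_effect, 0)

  expect_error(rm_anova(matrix(c(1, NA, 3, 4), 2)), "missing")
  expect_error(rm_anova(matrix(1:3, 1)), ">= 2")
})

test_that("Bonferroni pairwise tests match the paired-t oracle and cap at 1", {
  m <- cbind(top = c(1.2, 1.5, 1.1, 1.8, 1.4),
             middle = c(1.0, 1.3, 1.2, 1.5, 1.1),
             PL1 = c(6.1, 6.9, 6.4, 7.2, 6.6))
  got <- bonferroni_pairwise(m)
  expect_identical(nrow(got), 3L)  # all pairs of 3 columns
  d <- m[, "top"] - m[, "middle"]
  t_o <- mean(d) / (sd(d) / sqrt(length(d)))
  p_o <- 2 * pt(-abs(t_o), length(d) - 1)
  row <- got[got$comparison == "top vs middle", ]
  expect_equal(row$t, t_o, tolerance = 1e-12)
  expect_equal(row$p, p_o, tolerance = 1e-12)
  expect_equal(row$p_adj, min(1, p_o * 3), tolerance = 1e-12)
  # the multiplicative adjustment caps at 1 and is monotone
  expect_true(all(got$p_adj <= 1))
  expect_true(all(got$p_adj >= got$p))

  mz <- cbind(a = c(1, 2, 3), b = c(2, 3, 4))  # constant difference
  expect_warning(gz <- bonferroni_pairwise(mz), "zero-variance")
  expect_identical(gz$p, 1)
})

test_that("two-way ANOVA matches a manual sums-of-squares oracle", {
  set.seed(55)
  df <- expand.grid(body = c("ilium", "sacrum"),
                    trajectory = c("top", "middle", "PL1"),
                    rep = 1:3, stringsAsFactors = FALSE)
  df$y <- round(rnorm(nrow(df), 400, 50) +
                  ifelse(df$body == "ilium", 80, 0))
  got <- two_way_anova(df, "y")
  # oracle from cell/marginal means
  a <- 2; b <- 3; r <- 3
  gm <- mean(df$y)
  mu_a <- tapply(df$y, df$body, mean)
  mu_b <- tapply(df$y, df$trajectory, mean)
  mu_ab <- tapply(df$y, list(df$body, df$trajectory), mean)
  ss_a <- b * r * sum((mu_a - gm)^2)
  ss_b <- a * r * sum((mu_b - gm)^2)
  ss_ab <- r * sum((sweep(sweep(mu_ab, 1, mu_a - gm), 2, mu_b - gm) - gm)^2)
  ss_res <- sum((df$y - mu_ab[cbind(df$body, df$trajectory)])^2)
  df2 <- a * b * (r - 1)
  f_a <- (ss_a / (a - 1)) / (ss_res / df2)
  f_b <- (ss_b / (b - 1)) / (ss_res / df2)
  f_ab <- (ss_ab / ((a - 1) * (b - 1))) / (ss_res / df2)
  expect_equal(got$F[got$effect == "body"], f_a, tolerance = 1e-9)
  expect_equal(got$F[got$effect == "trajectory"], f_b, tolerance = 1e-9)
  expect_equal(got$F[got$effect == "body:trajectory"], f_ab, tolerance = 1e-9)
  expect_true(all(got$df2 == df2))
})

test_that("two-way ANOVA degenerate and invalid designs behave", {
  df <- expand.grid(body = c("ilium", "sacrum"),
                    trajectory = c("top", "PL1"), rep = 1:3,
                    stringsAsFactors = FALSE)
  df$y <- 7
  got <- two_way_anova(df, "y")    # constant outcome: no effects
  expect_true(all(got$F == 0) && all(got$p == 1))

  df$y <- ifelse(df$body == "ilium", 1, -1)  # pure body effect, no noise
  got2 <- two_way_anova(df, "y")
  expect_gt(got2$F[got2$effect == "body"], 1e6)
  expect_lt(got2$p[got2$effect == "body"], 1e-20)
  expect_identical(got2$F[got2$effect == "trajectory"], 0)

  expect_error(two_way_anova(df[-1, ], "y"), "unbalanced")
})
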