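test_that("summary t test reproduces printed group comparisons", {
  # mean cap thickness row: pooled Student
  fct <- summary_t_test(186, 65, 56, 232, 80, 24, variant = "student")
  expect_equal(fct$df, 78)
  expect_lt(abs(fct$p - 0.009), 0.001)
  # MLA row: Welch
  mla <- summary_t_test(2.93, 2.03, 56, 2.00, 1.26, 24, variant = "welch")
  expect_lt(abs(mla$p - 0.015), 0.001)
  # identical groups
  same <- summary_t_test(5, 1, 20, 5, 1, 20)
  expect_equal(same$p, 1)
  expect_error(summary_t_test(1, 0, 10, 2, 1, 10), "sd")
  expect_error(summary_t_test(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("Student and Welch agree for equal n and equal sd", {
  s <- summary_t_test(3, 1.2, 18, 4.1, 1.2, 18, variant = "student")
  w <- summary_t_test(3, 1.2, 18, 4.1, 1.2, 18, variant = "welch")
  expect_equal(s$t, w$t)
  expect_equal(s$df, w$df)
  expect_equal(s$p, w$p)
})

test_that("chi-square without continuity correction matches printed p-values", {
  expect_lt(abs(chi_square_2x2(21, 35, 17, 7)$p - 0.006), 5e-4)
  expect_lt(abs(chi_square_2x2(27, 29, 19, 5)$p - 0.010), 5e-4)
  expect_lt(abs(chi_square_2x2(26, 30, 18, 6)$p - 0.019), 5e-4)
  prop <- chi_square_2x2(10, 20, 5, 10)   # perfectly proportional
  expect_equal(prop$chi2, 0)
  expect_equal(prop$p, 1)
  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")
  expect_error(chi_square_2x2(1.5, 2, 3, 4), "integers")
})

test_that("chi-square equals the textbook sum (O-E)^2/E and chisq.test", {
  set.seed(7)
  for (k in 1:20) {
    m <- matrix(rpois(4, 20) + 1, 2)
    ours <- chi_square_2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(ours$chi2, sum((m - e)^2 / e), tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney: exact small-sample p, sane behavior", {
  # 20 arrangements of ranks -> one-sided 1/20, two-sided 0.1
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(5)
  big <- mann_whitney(rnorm(56, 0), rnorm(24, 3))
  expect_lt(big$p, 0.001)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("each test holds its nominal 5% type-I rate under the null", {
  set.seed(123)
  n_rep <- 1000
  t_hits <- mw_hits <- chi_hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    a <- rnorm(25)
    b <- rnorm(25)
    t_hits[r] <- summary_t_test(mean(a), sd(a), 25, mean(b), sd(b), 25)$p < 0.05
    mw_hits[r] <- mann_whitney(a[1:12], b[1:12])$p < 0.05
    m <- matrix(rbinom(2, 40, 0.5), ncol = 1)
    chi_hits[r] <- chi_square_2x2(m[1], 40 - m[1], m[2], 40 - m[2])$p < 0.05
  }
  expect_lt(abs(mean(t_hits) - 0.05), 0.02)
  expect_lt(abs(mean(mw_hits) - 0.05), 0.025)  # exact test is conservative
  expect_lt(abs(mean(chi_hits) - 0.05), 0.025)
})

test_that("comparison table: summaries, test routing and formatting", {
  set.seed(31)
  df_a <- data.frame(x = rnorm(30, 10, 2), flag = rep(c(TRUE, FALSE), 15),
                     skew = rexp(30))
  df_b <- data.frame(x = rnorm(30, 12, 2), flag = rep(c(TRUE, FALSE),
                                                      c(24, 6)),
                     skew = rexp(30, 0.5))
  tab <- build_comparison_table(df_a, df_b)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$test_used[tab$variable == "x"], "student_t")
  expect_equal(tab$test_used[tab$variable == "skew"], "mann_whitney")
  expect_equal(tab$test_used[tab$variable == "flag"], "chi_square")
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))

  # n (%) formatting convention
  expect_equal(plaqrupt:::fmt_n_pct(18, 24), "18 (75.0)")
  expect_equal(format_p(0.0004), "<0.001")
  expect_equal(format_p(0.0192), "0.019")

  # an all-missing variable yields a missing-p row
  df_a$gone <- NA_real_
  df_b$gone <- NA_real_
  tab2 <- build_comparison_table(df_a, df_b, variables = "gone")
  expect_true(is.na(tab2$p_value))
})

test_that("cohort comparisons: calibrated type-I, power concentrated on true differences", {
  n_rep <- 50
  hits <- matrix(NA, n_rep, 3,
                 dimnames = list(NULL, c("mean_fct_um", "mla_mm2",
                                         "prox_ref_area_mm2")))
  null_hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    a <- simulate_cohort(group_params("PR-NV", 56, seed = 5000 + r))
    b <- simulate_cohort(group_params("PR-NA", 24, seed = 7000 + r))
    tab <- build_comparison_table(a, b, variables = colnames(hits))
    hits[r, ] <- tab$p_value < 0.05
    a2 <- simulate_cohort(group_params("PR-NV", 24, seed = 9000 + r))
    null_hits[r] <- build_comparison_table(
      a, a2, variables = "mla_mm2")$p_value < 0.05
  }
  # reference areas differ strongly (printed p < 0.001): near-certain detection
  expect_gte(mean(hits[, "prox_ref_area_mm2"]), 0.8)
  # FCT and MLA carry the printed effect sizes (p = 0.009 / 0.015), which
  # imply moderate replicate power: well above the alpha rate
  expect_gte(mean(hits[, "mean_fct_um"]), 0.4)
  expect_gte(mean(hits[, "mla_mm2"]), 0.25)
  # same-population comparison stays at the alpha rate
  expect_lte(mean(null_hits), 0.16)
})
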