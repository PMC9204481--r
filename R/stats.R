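## Two-group comparison engine with clinical-table reporting conventions:
## mean +/- SD or n (%) summaries, t / Mann-Whitney / chi-square tests,
## p to three decimals with "<0.001" below that, and no Yates correction
## (the convention that reproduces printed 2x2 p-values from printed counts).

#' Two-sample t test from summary statistics
#'
#' Pooled-variance (Student) or Welch t test computed directly from group
#' means, SDs and sizes — the form needed when only printed summaries are
#' available.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries; `n >= 2`,
#'   `sd > 0`.
#' @param variant `"student"` (pooled variance, df = n_a + n_b - 2) or
#'   `"welch"` (Welch-Satterthwaite df).
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' summary_t_test(186, 65, 56, 232, 80, 24)$p  # ~0.009
#' @export
summary_t_test <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (n_a < 2 || n_b < 2) stop("each group needs n >= 2")
  if (sd_a <= 0 || sd_b <= 0) stop("sd must be positive")
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  if (variant == "student") {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 table, no continuity correction
#'
#' `chi2 = sum (O - E)^2 / E` on the table `rbind(c(a, b), c(c, d))` with
#' df = 1. Yates continuity correction is deliberately NOT applied.
#'
#' @param a,b first row (e.g. group A: feature present, absent).
#' @param c_,d_ second row.
#' @return List with `chi2` and two-sided `p`.
#' @examples
#' chi_square_2x2(21, 35, 17, 7)$p  # ~0.006
#' @export
chi_square_2x2 <- function(a, b, c_, d_) {
  counts <- c(a, b, c_, d_)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  n <- sum(counts)
  r1 <- a + b; r2 <- c_ + d_; c1 <- a + c_; c2 <- b + d_
  if (min(r1, r2, c1, c2) == 0) stop("zero margin in 2x2 table")
  chi2 <- n * (a * d_ - b * c_)^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Mann-Whitney U test
#'
#' Wraps `stats::wilcox.test`: exact two-sided p for small untied samples
#' (both n <= 20), normal approximation with tie and continuity correction
#' otherwise. The reported `U` is the rank-sum statistic for the first
#' sample.
#'
#' @param sample_a,sample_b numeric vectors, each non-empty.
#' @return List with `U` and two-sided `p`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  ties <- any(duplicated(c(sample_a, sample_b)))
  exact <- length(sample_a) <= 20 && length(sample_b) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Format a p-value in table style
#'
#' @param p p-value.
#' @return `"<0.001"` below 0.001, else three decimals.
#' @export
format_p <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "<0.001" else sprintf("%.3f", round_half_up(p, 3))
}

fmt_mean_sd <- function(x, digits = 1) {
  x <- x[is.finite(x)]
  sprintf("%.*f ± %.*f", digits, mean(x), digits, stats::sd(x))
}

fmt_n_pct <- function(n, total) {
  sprintf("%d (%.1f)", n, prevalence_pct(n, total))
}

#' Build a two-group comparison table
#'
#' For each requested variable, summarizes both groups and tests the
#' difference with the convention used in clinical lesion tables: continuous
#' variables get a Shapiro-Wilk normality screen (alpha = 0.05, both
#' groups); normal variables use the t test (pooled Student by default),
#' non-normal ones the Mann-Whitney U test. Logical (or 0/1) variables use
#' the Pearson chi-square without continuity correction and are summarized
#' as `n (%)`.
#'
#' @param df_a,df_b data.frames of per-lesion metrics for the two groups.
#' @param variables character vector of column names to compare; defaults to
#'   all columns shared by both groups that are numeric or logical.
#' @param t_variant `"student"` or `"welch"`.
#' @param digits decimals for mean +/- SD formatting (recycled over
#'   variables).
#' @return A data.frame with columns `variable`, `group_a`, `group_b`,
#'   `test_used`, `statistic`, `p_value`, `p_formatted`.
#' @export
build_comparison_table <- function(df_a, df_b, variables = NULL,
                                   t_variant = c("student", "welch"),
                                   digits = 1) {
  t_variant <- match.arg(t_variant)
  if (is.null(variables)) {
    shared <- intersect(names(df_a), names(df_b))
    variables <- shared[vapply(shared, function(v) {
      is.numeric(df_a[[v]]) || is.logical(df_a[[v]])
    }, logical(1))]
  }
  digits <- rep_len(digits, length(variables))
  rows <- lapply(seq_along(variables), function(k) {
    v <- variables[k]
    xa <- df_a[[v]]
    xb <- df_b[[v]]
    if (!length(stats::na.omit(xa)) || !length(stats::na.omit(xb))) {
      return(data.frame(variable = v, group_a = NA_character_,
                        group_b = NA_character_, test_used = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        p_formatted = NA_character_, stringsAsFactors = FALSE))
    }
    binary <- is.logical(xa) ||
      all(stats::na.omit(c(xa, xb)) %in% c(0, 1))
    if (binary) {
      xa <- as.logical(stats::na.omit(xa))
      xb <- as.logical(stats::na.omit(xb))
      res <- tryCatch(
        chi_square_2x2(sum(xa), sum(!xa), sum(xb), sum(!xb)),
        error = function(e) list(chi2 = NA_real_, p = NA_real_))
      return(data.frame(
        variable = v,
        group_a = fmt_n_pct(sum(xa), length(xa)),
        group_b = fmt_n_pct(sum(xb), length(xb)),
        test_used = "chi_square", statistic = res$chi2, p_value = res$p,
        p_formatted = format_p(res$p), stringsAsFactors = FALSE))
    }
    xa <- xa[is.finite(xa)]
    xb <- xb[is.finite(xb)]
    if (length(xa) < 2 || length(xb) < 2) {
      return(data.frame(variable = v, group_a = NA_character_,
                        group_b = NA_character_, test_used = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        p_formatted = NA_character_, stringsAsFactors = FALSE))
    }
    normal <- function(x) {
      if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
      stats::shapiro.test(x)$p.value >= 0.05
    }
    if (normal(xa) && normal(xb)) {
      res <- summary_t_test(mean(xa), stats::sd(xa), length(xa),
                            mean(xb), stats::sd(xb), length(xb),
                            variant = t_variant)
      test <- if (t_variant == "student") "student_t" else "welch_t"
      stat <- res$t
    } else {
      res <- mann_whitney(xa, xb)
      test <- "mann_whitney"
      stat <- res$U
    }
    data.frame(variable = v,
               group_a = fmt_mean_sd(xa, digits[k]),
               group_b = fmt_mean_sd(xb, digits[k]),
               test_used = test, statistic = stat, p_value = res$p,
               p_formatted = format_p(res$p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
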