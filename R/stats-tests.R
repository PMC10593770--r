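# Group comparisons and descriptive statistics in one tabular result
# schema: Student/Welch t, Mann-Whitney, ANOVA + Tukey, Kruskal-Wallis +
# Dunn, Fisher's exact, BH adjustment, and the t-based cohort descriptives.
# Test choice is always explicit: Shapiro-Wilk normality screening is
# reported alongside but never switches the method.

.result_row <- function(test, statistic, p_value, estimate_1, estimate_2,
                        n_1, n_2, ...) {
  tibble(test = test, statistic = statistic, p_value = p_value,
         estimate_1 = estimate_1, estimate_2 = estimate_2,
         n_1 = n_1, n_2 = n_2, ...)
}

#' Two-group comparison
#'
#' Two-tailed unpaired comparison of `value` between the two levels of
#' `group`: pooled-variance Student's t (`"student_t"`), Welch t
#' (`"welch_t"`), or Mann-Whitney U with mid-rank ties (`"mann_whitney"`).
#' Shapiro-Wilk p-values per group are reported as advisory columns only.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the measurement and the
#'   two-level grouping factor.
#' @param method One of `"student_t"`, `"welch_t"`, `"mann_whitney"`.
#' @return One-row tibble: `test`, `statistic`, `p_value`, group means (t)
#'   or medians (MW) as `estimate_1`/`estimate_2`, group sizes, group
#'   labels, and `shapiro_p_1`/`shapiro_p_2`.
#' @export
two_group_test <- function(data, value, group,
                           method = c("student_t", "welch_t", "mann_whitney")) {
  method <- match.arg(method)
  v <- data[[value]]; g <- factor(data[[group]])
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  if (nlevels(g) != 2L) abort("`group` must have exactly 2 levels")
  lv <- levels(g)
  x <- v[g == lv[1L]]; y <- v[g == lv[2L]]
  min_n <- if (method == "mann_whitney") 1L else 2L
  if (length(x) < min_n || length(y) < min_n) {
    abort(sprintf("need >= %d values per group for %s", min_n, method))
  }
  sw <- function(z) {
    if (length(z) >= 3L && length(z) <= 5000L && sd(z) > 0) {
      shapiro.test(z)$p.value
    } else NA_real_
  }
  if (method == "mann_whitney") {
    if (length(unique(c(x, y))) == 1L) {
      # every value tied: mid-ranks make U = n1*n2/2 exactly, p = 1
      res <- .result_row("mann_whitney", length(x) * length(y) / 2, 1,
                         median(x), median(y), length(x), length(y))
    } else {
      ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
      res <- .result_row("mann_whitney", unname(ht$statistic), ht$p.value,
                         median(x), median(y), length(x), length(y))
    }
  } else {
    if (sd(c(x, y)) == 0) {
      res <- .result_row(method, 0, 1, mean(x), mean(y), length(x), length(y))
    } else {
      ht <- t.test(x, y, var.equal = method == "student_t")
      res <- .result_row(method, unname(ht$statistic), ht$p.value,
                         mean(x), mean(y), length(x), length(y))
    }
  }
  res |> mutate(group_1 = lv[1L], group_2 = lv[2L],
                shapiro_p_1 = sw(x), shapiro_p_2 = sw(y))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement over one declared
#' family of p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Multi-group comparison with post hoc pairwise tests
#'
#' Thin wrappers in the shared result schema: one-way ANOVA with Tukey's
#' HSD (`"anova_tukey"`) or Kruskal-Wallis with Dunn's pairwise rank test
#' (`"kruskal_dunn"`, BH-adjusted).
#'
#' @param data Data frame.
#' @param value,group Column names (strings); `group` may have > 2 levels.
#' @param method `"anova_tukey"` or `"kruskal_dunn"`.
#' @return List: `omnibus` (one-row tibble with `test`, `statistic`,
#'   `p_value`) and `pairwise` (tibble with `comparison`, `estimate`,
#'   `p_value`, `p_adjusted`).
#' @export
multi_group_test <- function(data, value, group,
                             method = c("anova_tukey", "kruskal_dunn")) {
  method <- match.arg(method)
  v <- data[[value]]; g <- factor(data[[group]])
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 3L) abort("use two_group_test() for 2 groups")
  if (method == "anova_tukey") {
    fit <- aov(v ~ g)
    an <- summary(fit)[[1L]]
    tk <- TukeyHSD(fit)$g
    pairwise <- tibble(comparison = rownames(tk),
                       estimate = tk[, "diff"],
                       p_value = tk[, "p adj"],
                       p_adjusted = tk[, "p adj"])
    omnibus <- tibble(test = "one_way_anova",
                      statistic = an[["F value"]][1L],
                      p_value = an[["Pr(>F)"]][1L])
  } else {
    kw <- kruskal.test(v, g)
    # Dunn's test: pairwise z on mean ranks with tie correction
    r <- rank(v)
    N <- length(v)
    ties <- table(v)
    tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
    lv <- levels(g)
    combs <- utils::combn(lv, 2L)
    pw <- apply(combs, 2L, function(pair) {
      i <- g == pair[1L]; j <- g == pair[2L]
      se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / sum(i) + 1 / sum(j)))
      zst <- (mean(r[i]) - mean(r[j])) / se
      c(z = zst, p = 2 * pnorm(-abs(zst)))
    })
    pairwise <- tibble(comparison = paste(combs[2L, ], combs[1L, ], sep = "-"),
                       estimate = pw["z", ],
                       p_value = pw["p", ],
                       p_adjusted = bh_adjust(pw["p", ]))
    omnibus <- tibble(test = "kruskal_wallis",
                      statistic = unname(kw$statistic),
                      p_value = kw$p.value)
  }
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities no greater than the
#' observed table's (the probability-summation convention).
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return One-row tibble: `test`, `odds_ratio`, `p_value`.
#' @examples
#' fisher_exact_test(matrix(c(2, 5, 9, 11), nrow = 2))
#' @export
fisher_exact_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) abort("`counts` must be 2x2")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  ht <- fisher.test(counts)
  tibble(test = "fisher_exact", odds_ratio = unname(ht$estimate),
         p_value = ht$p.value)
}

#' Cohort descriptives: mean with t-based 95% CI
#'
#' mean ± t(0.975, n-1) * SD / sqrt(n).
#'
#' @param values Numeric vector (n >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `n`, `mean`, `sd`, `ci_lower`, `ci_upper`.
#' @export
mean_ci_t <- function(values, conf_level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) abort("need >= 2 values")
  m <- mean(values); s <- sd(values)
  half <- qt(1 - (1 - conf_level) / 2, df = n - 1L) * s / sqrt(n)
  tibble(n = n, mean = m, sd = s, ci_lower = m - half, ci_upper = m + half)
}
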