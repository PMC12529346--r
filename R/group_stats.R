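# Longitudinal, cross-sectional and demographic statistics.
#
# All reported p-values are unadjusted two-sided; multiple comparisons are
# handled by Bonferroni *families*: a family of m tests keeps its nominal
# alpha by flagging significance at alpha / m.

#' Construct a test result record
#'
#' @param name test label.
#' @param statistic test statistic (t, r, chi-square, F ...).
#' @param df degrees of freedom (may be length 2 for F; stored as text).
#' @param p unadjusted two-sided p-value.
#' @param n sample size used.
#' @param family Bonferroni family name (NA if unfamilied).
#' @param alpha_adjusted significance threshold applied (alpha / m).
#' @param estimate optional effect estimate (mean difference, r, ...).
#' @return one-row data.frame of class `cap_test`.
#' @export
cap_test_result <- function(name, statistic, df, p, n, family = NA_character_,
                            alpha_adjusted = 0.05, estimate = NA_real_) {
  stopifnot(p >= 0, p <= 1)
  out <- data.frame(name = name, statistic = statistic,
                    df = paste(df, collapse = ","), p = p, n = n,
                    family = family, alpha_adjusted = alpha_adjusted,
                    significant = p < alpha_adjusted,
                    direction = sign(statistic), estimate = estimate,
                    stringsAsFactors = FALSE)
  class(out) <- c("cap_test", "data.frame")
  out
}

#' Percent change in a mood score
#'
#' Literal definition: (post - baseline) / post. A zero post score makes
#' the ratio undefined and yields NA with a warning.
#'
#' @param baseline,post numeric scores (vectorized).
#' @return fraction(s); negative values are improvements for severity
#'   scales when post < baseline.
#' @export
#' @examples
#' percent_change(19, 8.4)  # -1.2619...
percent_change <- function(baseline, post) {
  out <- (post - baseline) / post
  zero <- !is.na(post) & post == 0
  if (any(zero)) {
    warning(sprintf("%d zero post score(s): percent change undefined", sum(zero)))
    out[zero] <- NA_real_
  }
  out
}

#' Paired t-test across timepoints
#'
#' Classical paired t on post - baseline differences; pairs with a missing
#' value on either side are dropped.
#'
#' @param baseline,post per-subject values at the two timepoints.
#' @param name test label.
#' @param family,alpha_adjusted family bookkeeping.
#' @return a [cap_test_result()].
#' @export
paired_change_tests <- function(baseline, post, name = "paired",
                                family = NA_character_, alpha_adjusted = 0.05) {
  ok <- stats::complete.cases(baseline, post)
  d <- post[ok] - baseline[ok]
  n <- length(d)
  if (n < 2) stop(sprintf("%s: need >= 2 complete pairs (got %d)", name, n))
  if (stats::sd(d) < 1e-14) stop(sprintf("%s: zero variance of differences", name))
  tt <- stats::t.test(d)
  cap_test_result(name, unname(tt$statistic), n - 1, tt$p.value, n,
                  family, alpha_adjusted, estimate = mean(d))
}

#' Pearson correlation between a brain change and a mood change
#'
#' @param delta_metric per-subject change in a CAP metric.
#' @param pct_change_mood per-subject percent change in a mood score.
#' @param name,family,alpha_adjusted as in [paired_change_tests()].
#' @return a [cap_test_result()] with `estimate` = r and a t statistic on
#'   n - 2 degrees of freedom.
#' @export
correlate_change_with_mood <- function(delta_metric, pct_change_mood, name = "correlation",
                                       family = NA_character_, alpha_adjusted = 0.05) {
  ok <- stats::complete.cases(delta_metric, pct_change_mood)
  x <- delta_metric[ok]; y <- pct_change_mood[ok]
  n <- length(x)
  if (n < 4) stop(sprintf("%s: need >= 4 complete pairs", name))
  if (stats::sd(x) < 1e-14 || stats::sd(y) < 1e-14)
    stop(sprintf("%s: zero variance", name))
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), n - 2)
  cap_test_result(name, t, n - 2, p, n, family, alpha_adjusted, estimate = r)
}

#' Covariate-adjusted group comparison
#'
#' "Independent-samples t-test controlling for age and sex": an OLS model
#' metric ~ group + age + sex, reporting the t of the group coefficient
#' (residual df = n - 4). A `residualize` method (residualize the metric on
#' age + sex, then plain two-sample t) is available as a robustness option.
#'
#' @param metric outcome values.
#' @param group two-level factor/character (first level is the reference).
#' @param age,sex covariates.
#' @param name,family,alpha_adjusted bookkeeping.
#' @param method "ols" (default) or "residualize".
#' @return a [cap_test_result()].
#' @export
adjusted_group_comparison <- function(metric, group, age, sex, name = "group",
                                      family = NA_character_, alpha_adjusted = 0.05,
                                      method = c("ols", "residualize")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(metric, group, age, sex)
  df <- data.frame(metric = metric[ok], group = factor(group[ok]),
                   age = age[ok], sex = factor(sex[ok]))
  if (nlevels(df$group) != 2) stop(sprintf("%s: need exactly 2 groups", name))
  if (min(table(df$group)) < 3) stop(sprintf("%s: both groups need >= 3 subjects", name))
  n <- nrow(df)
  if (method == "ols") {
    fit <- stats::lm(metric ~ group + age + sex, data = df)
    if (anyNA(stats::coef(fit))) stop(sprintf("%s: collinear covariates", name))
    sm <- summary(fit)$coefficients
    row <- grep("^group", rownames(sm))
    cap_test_result(name, sm[row, "t value"], stats::df.residual(fit),
                    sm[row, "Pr(>|t|)"], n, family, alpha_adjusted,
                    estimate = sm[row, "Estimate"])
  } else {
    res <- stats::residuals(stats::lm(metric ~ age + sex, data = df))
    tt <- stats::t.test(res[df$group == levels(df$group)[2]],
                        res[df$group == levels(df$group)[1]], var.equal = TRUE)
    cap_test_result(name, unname(tt$statistic), unname(tt$parameter), tt$p.value,
                    n, family, alpha_adjusted,
                    estimate = unname(diff(rev(tt$estimate))) * -1)
  }
}

#' Bonferroni family specification and flags
#'
#' Threshold = alpha / m; reported p-values stay unadjusted, significance
#' is flagged at the family threshold.
#'
#' @param pvals unadjusted p-values (may be empty).
#' @param m family size (>= 1).
#' @param alpha family-wise error rate, default 0.05.
#' @return list of class `family_spec`: `family`, `m`, `alpha`,
#'   `threshold`, `significant` flags.
#' @param family family name.
#' @export
#' @examples
#' bonferroni_family(c(0.004, 0.02), m = 6)$threshold  # 0.008333...
bonferroni_family <- function(pvals, m, alpha = 0.05, family = "family") {
  if (m < 1) stop("family size m must be >= 1")
  threshold <- alpha / m
  structure(list(family = family, m = as.integer(m), alpha = alpha,
                 threshold = threshold, significant = pvals < threshold),
            class = "family_spec")
}

#' Enumerate the transition-probability test family
#'
#' Transition probabilities are tested only for states with a significant
#' occupancy or dwell-time effect: for each selected state s, the tests are
#' the transitions into s from every other state, giving a family of
#' |selected| * (K - 1) tests.
#'
#' @param significant_states integer states selected by FT/MDT results.
#' @param K total number of states.
#' @return data.frame with columns `from`, `to` (empty if no selection).
#' @export
#' @examples
#' nrow(tp_test_family(c(1, 6), 6))  # 10
tp_test_family <- function(significant_states, K) {
  significant_states <- unique(as.integer(significant_states))
  if (length(significant_states) == 0)
    return(data.frame(from = integer(0), to = integer(0)))
  if (any(significant_states < 1 | significant_states > K))
    stop("selected states outside 1..K")
  do.call(rbind, lapply(significant_states, function(s) {
    data.frame(from = setdiff(seq_len(K), s), to = s)
  }))
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom, computed
#' from printed group means, standard deviations and sizes (used for
#' demographic tables where raw values are unavailable).
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param name,family,alpha_adjusted bookkeeping.
#' @return a [cap_test_result()]; statistic is (mean2 - mean1) / se.
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2, name = "welch",
                            family = NA_character_, alpha_adjusted = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean2 - mean1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  cap_test_result(name, t, round(df, 2), p, n1 + n2, family, alpha_adjusted,
                  estimate = mean2 - mean1)
}

#' Pearson chi-square for a 2x2 table
#'
#' Without continuity correction: N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)),
#' df = 1 (the convention that reproduces printed demographic
#' chi-squares).
#'
#' @param a,b first row counts; \code{c_},\code{d} second row counts.
#' @param name,family,alpha_adjusted bookkeeping.
#' @return a [cap_test_result()].
#' @export
chi2_2x2 <- function(a, b, c_, d, name = "chi2",
                     family = NA_character_, alpha_adjusted = 0.05) {
  cnt <- c(a, b, c_, d)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be non-negative integers")
  N <- sum(cnt)
  marg <- c(a + b, c_ + d, a + c_, b + d)
  if (any(marg == 0)) stop("zero marginal: chi-square undefined")
  stat <- N * (a * d - b * c_)^2 / prod(marg)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  cap_test_result(name, stat, 1, p, N, family, alpha_adjusted)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects F test across >= 2 groups, df = (g - 1, N - g);
#' used for group differences in frame-to-centroid similarity and in
#' per-state head motion.
#'
#' @param values numeric outcomes.
#' @param groups group labels (>= 2 groups, each with >= 2 values).
#' @param name,family,alpha_adjusted bookkeeping.
#' @return a [cap_test_result()] with the F statistic.
#' @export
oneway_anova <- function(values, groups, name = "anova",
                         family = NA_character_, alpha_adjusted = 0.05) {
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2) stop("ANOVA needs >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 values")
  N <- length(values); g <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  ss_b <- sum(tabulate(groups) * (gm - mean(values))^2)
  ss_w <- sum((values - gm[groups])^2)
  Fstat <- (ss_b / (g - 1)) / (ss_w / (N - g))
  p <- stats::pf(Fstat, g - 1, N - g, lower.tail = FALSE)
  cap_test_result(name, Fstat, c(g - 1, N - g), p, N, family, alpha_adjusted)
}
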