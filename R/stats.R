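# Treatment-response stratification and group statistics.
#
# Every comparison returns a `group_comparison` object: the statistic,
# its kind, degrees of freedom (possibly fractional for Welch), a
# two-tailed p value, and the group descriptives that produced it.
# Summary-statistic input (n, mean, sd) is accepted everywhere so that
# published tables can be re-analysed without raw data.

group_comparison <- function(kind, value, df, p, groups = NULL, extra = NULL) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(list(kind = kind, value = value, df = df, p = p,
                 groups = groups, extra = extra),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  dfs <- if (is.null(x$df) || all(is.na(x$df))) "" else {
    sprintf(", df = %s", paste(signif(x$df, 5), collapse = ", "))
  }
  cat(sprintf("%s = %s%s, p = %s\n", x$kind, signif(x$value, digits), dfs,
              format.pval(x$p, digits = 3)))
  if (!is.null(x$groups)) {
    print(x$groups, row.names = FALSE)
  }
  invisible(x)
}

as_summary <- function(g) {
  # accept raw values or list(n, mean, sd)
  if (is.list(g) && all(c("n", "mean", "sd") %in% names(g))) {
    list(n = g$n, mean = g$mean, sd = g$sd)
  } else {
    v <- as.numeric(g)
    if (length(v) < 2) stopf("need raw values (>= 2) or a list(n, mean, sd)")
    list(n = length(v), mean = mean(v), sd = stats::sd(v))
  }
}

#' Classify treatment response from BDI scores
#'
#' Response is a strict >50% reduction in BDI from baseline to
#' follow-up; remission is a post-treatment BDI strictly below 10.
#'
#' @param bdi_pre,bdi_post baseline and follow-up BDI scores
#'   (vectors; `bdi_pre` must be positive).
#' @return Data frame with `bdi_change_pct`
#'   (= 100 * (pre - post) / pre), `responder`, `remitter`.
#' @examples
#' classify_response(30, 14)  # 53.3%, responder
#' classify_response(30, 15)  # exactly 50%, not a responder
#' @export
classify_response <- function(bdi_pre, bdi_post) {
  if (any(bdi_pre <= 0)) {
    stopf("percent change undefined: bdi_pre must be > 0")
  }
  pct <- 100 * (bdi_pre - bdi_post) / bdi_pre
  data.frame(bdi_change_pct = pct,
             responder = pct > 50,
             remitter = bdi_post < 10)
}

#' Median split into low/high LDAEP groups
#'
#' Values strictly below the sample median are labelled `"low"`,
#' values at or above it `"high"`; with an odd number of distinct
#' values the high group is the larger by one.
#'
#' @param values numeric vector (n >= 2).
#' @return Factor with levels `low`, `high`.
#' @examples
#' table(median_split(c(1, 2, 3, 4, 5)))  # 2 low, 3 high
#' @export
median_split <- function(values) {
  if (length(values) < 2) stopf("need >= 2 values")
  if (max(values) == min(values)) {
    stopf("degenerate split: all values identical")
  }
  med <- stats::median(values)
  factor(ifelse(values < med, "low", "high"), levels = c("low", "high"))
}

#' Two-sample t test (pooled, Welch, or variance-gated)
#'
#' Accepts raw values or published summaries (`list(n, mean, sd)`)
#' per group.  `"pooled"` is the classical equal-variance Student t
#' with `n1 + n2 - 2` df; `"welch"` uses the Welch-Satterthwaite
#' fractional df; `"auto"` chooses Welch when an F test of variance
#' equality rejects at 0.05 and the pooled test otherwise.
#'
#' @param group_a,group_b numeric vectors or `list(n, mean, sd)`.
#' @param mode `"pooled"`, `"welch"` or `"auto"`.
#' @return A `group_comparison` (kind `t_pooled` or `t_welch`).
#' @examples
#' two_sample_t(list(n = 16, mean = 0.58, sd = 0.40),
#'              list(n = 25, mean = 1.06, sd = 0.82), mode = "welch")
#' @export
two_sample_t <- function(group_a, group_b,
                         mode = c("auto", "pooled", "welch")) {
  mode <- match.arg(mode)
  a <- as_summary(group_a)
  b <- as_summary(group_b)
  if (a$n < 2 || b$n < 2) stopf("need n >= 2 per group")
  if (a$sd < 0 || b$sd < 0) stopf("sd must be >= 0")
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean) {
    stopf("t undefined: zero variance in both groups with equal means")
  }
  if (mode == "auto") {
    fstat <- max(a$sd, b$sd)^2 / min(a$sd, b$sd)^2
    df_num <- ifelse(a$sd >= b$sd, a$n, b$n) - 1
    df_den <- ifelse(a$sd >= b$sd, b$n, a$n) - 1
    p_var <- 2 * min(stats::pf(fstat, df_num, df_den, lower.tail = FALSE),
                     stats::pf(fstat, df_num, df_den))
    mode <- if (is.finite(p_var) && p_var < 0.05) "welch" else "pooled"
  }
  if (mode == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    kind <- "t_pooled"
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    kind <- "t_welch"
  }
  if (se == 0) stopf("t undefined: zero standard error")
  tval <- (a$mean - b$mean) / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  group_comparison(kind, tval, df, p,
                   groups = data.frame(group = c("a", "b"),
                                       n = c(a$n, b$n),
                                       mean = c(a$mean, b$mean),
                                       sd = c(a$sd, b$sd)))
}

#' Paired t test on pre/post values
#'
#' @param pre,post equal-length numeric vectors (n >= 2).
#' @return A `group_comparison` (kind `t_paired`, df `n - 1`).
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stopf("pre/post lengths differ")
  n <- length(pre)
  if (n < 2) stopf("need >= 2 pairs")
  d <- pre - post
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) {
      return(group_comparison("t_paired", 0, n - 1, 1,
                              groups = data.frame(n = n, mean_diff = 0,
                                                  sd_diff = 0)))
    }
    stopf("t undefined: zero-variance nonzero differences")
  }
  tval <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(abs(tval), n - 1, lower.tail = FALSE)
  group_comparison("t_paired", tval, n - 1, p,
                   groups = data.frame(n = n, mean_diff = mean(d),
                                       sd_diff = sdd))
}

#' Pearson chi-square on a 2x2 table (no continuity correction)
#'
#' @param tbl 2x2 matrix of counts.
#' @return A `group_comparison` (kind `chi2`, df 1).
#' @examples
#' chi_square_2x2(matrix(c(9, 16, 11, 5), 2))
#' @export
chi_square_2x2 <- function(tbl) {
  tbl <- as.matrix(tbl)
  if (!all(dim(tbl) == c(2, 2))) stopf("need a 2x2 table")
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    stopf("zero marginal total")
  }
  # chisq.test warns about the asymptotic approximation for small
  # expected counts; expected counts are validated here instead
  ct <- suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
  if (any(ct$expected <= 0)) stopf("expected count <= 0")
  group_comparison("chi2", unname(ct$statistic), unname(ct$parameter),
                   ct$p.value, extra = list(expected = ct$expected))
}

#' Group-versus-total relative odds (and the conventional odds ratio)
#'
#' The primary ratio compares the odds of the event within one group
#' to the odds in the whole sample; the conventional 2x2 cross-product
#' odds ratio is returned alongside, clearly labelled, with a
#' log-scale Wald confidence interval for each.
#'
#' @param group_counts length-2 vector `c(event, nonevent)` within the
#'   group.
#' @param total_counts length-2 vector `c(event, nonevent)` in the
#'   whole sample (must dominate `group_counts`).
#' @param conf_level confidence level (default 0.95).
#' @return A `group_comparison` (kind `odds_vs_total`); `extra`
#'   carries `ci`, `conventional_or` and `conventional_or_ci`.
#' @examples
#' relative_odds(c(11, 9), c(16, 25))  # 1.91
#' @export
relative_odds <- function(group_counts, total_counts, conf_level = 0.95) {
  g <- as.numeric(group_counts)
  t <- as.numeric(total_counts)
  if (any(c(g, t) == 0)) {
    stopf(paste("zero cell; apply an explicit continuity adjustment",
                "(e.g. add 0.5 to all cells) before calling"))
  }
  if (any(t - g < 0)) stopf("total counts must dominate group counts")
  ratio <- (g[1] / g[2]) / (t[1] / t[2])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # Wald interval on the log scale; the 'rest of sample' cells give the
  # variance for the conventional OR, the group/total cells for the ratio
  se_ratio <- sqrt(sum(1 / c(g, t)))
  ci <- exp(log(ratio) + c(-1, 1) * z * se_ratio)
  rest <- t - g
  conv_or <- (g[1] / g[2]) / (rest[1] / rest[2])
  se_or <- sqrt(sum(1 / c(g, rest)))
  or_ci <- exp(log(conv_or) + c(-1, 1) * z * se_or)
  group_comparison("odds_vs_total", ratio, NA_real_, NA_real_,
                   extra = list(ci = ci, conventional_or = conv_or,
                                conventional_or_ci = or_ci))
}

#' Cohen's d from group summaries or raw values
#'
#' Absolute standardized mean difference with the (n-1)-weighted
#' pooled SD.
#'
#' @inheritParams two_sample_t
#' @return Numeric effect size.
#' @export
cohens_d <- function(group_a, group_b) {
  a <- as_summary(group_a)
  b <- as_summary(group_b)
  if (a$n < 2 || b$n < 2) stopf("need n >= 2 per group")
  sp <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
  if (sp == 0) stopf("d undefined: zero pooled SD")
  abs(a$mean - b$mean) / sp
}

#' Group effect controlling for sex (general linear model)
#'
#' Fits `outcome ~ sex + group` and reports the F statistic for the
#' group term given sex.
#'
#' @param outcome numeric vector.
#' @param group,sex factors or character vectors of the same length.
#' @return A `group_comparison` (kind `F`, df `c(1, residual)`).
#' @export
glm_group_sex <- function(outcome, group, sex) {
  if (length(unique(sex)) < 2) stopf("both sexes must be present")
  if (length(outcome) < 3) stopf("need >= 3 subjects")
  dat <- data.frame(outcome = outcome, group = factor(group),
                    sex = factor(sex))
  fit <- stats::lm(outcome ~ sex + group, data = dat)
  if (fit$rank < 3) stopf("rank-deficient design (collinear group and sex)")
  an <- stats::anova(fit)
  i <- match("group", rownames(an))
  group_comparison("F", an[i, "F value"],
                   c(an[i, "Df"], an["Residuals", "Df"]),
                   an[i, "Pr(>F)"])
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests against a normal with the sample's mean and SD.  Intended as
#' a reported gate, never as an automatic method switch.
#'
#' @param values numeric vector (n >= 5, nonzero SD).
#' @return A `group_comparison` (kind `ks`).
#' @export
ks_normality <- function(values) {
  if (length(values) < 5) stopf("need n >= 5")
  s <- stats::sd(values)
  if (s == 0) stopf("degenerate input: zero SD")
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s))
  group_comparison("ks", unname(kt$statistic), NA_real_, kt$p.value)
}
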