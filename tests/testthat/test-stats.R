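test_that("response classification uses strict thresholds", {
  r <- classify_response(30, 14)
  expect_equal(r$bdi_change_pct, 100 * 16 / 30, tolerance = 1e-12)
  expect_true(r$responder)
  expect_false(classify_response(30, 15)$responder)  # exactly 50%
  expect_false(classify_response(30, 10)$remitter)   # exactly 10
  expect_true(classify_response(30, 9)$remitter)
  expect_error(classify_response(0, 0), "bdi_pre")
})

test_that("median split puts sub-median values low and is order-invariant", {
  set.seed(2)
  v <- rnorm(41)
  g <- median_split(v)
  expect_equal(as.vector(table(g)), c(20L, 21L))
  expect_true(all(v[g == "low"] < median(v)))
  expect_equal(median_split(c(1, 2, 3, 4))[1:2],
               factor(c("low", "low"), levels = c("low", "high")))
  perm <- sample(41)
  expect_identical(median_split(v[perm]), g[perm])
  expect_error(median_split(rep(1, 5)), "degenerate")
  expect_error(median_split(1), ">= 2")
})

test_that("two-sample t reproduces published group comparisons", {
  w <- two_sample_t(list(n = 16, mean = 0.58, sd = 0.40),
                    list(n = 25, mean = 1.06, sd = 0.82), mode = "welch")
  expect_equal(w$value, -2.498, tolerance = 0.01 / 2.498)
  expect_equal(w$df, 37.02, tolerance = 0.05 / 37.02)
  p <- two_sample_t(list(n = 16, mean = 0.95, sd = 0.59),
                    list(n = 25, mean = 1.47, sd = 0.83), mode = "pooled")
  expect_equal(p$value, -2.176, tolerance = 0.01 / 2.176)
  expect_equal(p$df, 39)
})

test_that("two-sample t matches stats::t.test on raw data (both modes)", {
  set.seed(10)
  for (i in 1:200) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    tp <- two_sample_t(a, b, mode = "pooled")
    rp <- t.test(a, b, var.equal = TRUE)
    expect_equal(tp$value, unname(rp$statistic), tolerance = 1e-10)
    expect_equal(tp$p, rp$p.value, tolerance = 1e-10)
    tw <- two_sample_t(a, b, mode = "welch")
    rw <- t.test(a, b)
    expect_equal(tw$value, unname(rw$statistic), tolerance = 1e-10)
    expect_equal(tw$df, unname(rw$parameter), tolerance = 1e-10)
    expect_lte(tw$df, tp$df + 1e-12)   # Welch df never exceeds pooled df
  }
})

test_that("welch equals pooled for equal sizes and variances; degenerate input errors", {
  a <- list(n = 10, mean = 1, sd = 2)
  b <- list(n = 10, mean = 2.5, sd = 2)
  expect_equal(two_sample_t(a, b, "welch")$value,
               two_sample_t(a, b, "pooled")$value, tolerance = 1e-12)
  expect_equal(two_sample_t(a, b, "welch")$df, 18)
  z <- list(n = 5, mean = 1, sd = 0)
  expect_error(two_sample_t(z, z), "undefined")
  ident <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$value, 0)
  expect_equal(ident$p, 1)
})

test_that("the auto mode gates on an F variance-ratio test", {
  a <- list(n = 16, mean = 0.58, sd = 0.40)
  b <- list(n = 25, mean = 1.06, sd = 0.82)
  expect_equal(two_sample_t(a, b, "auto")$kind, "t_welch")
  a2 <- list(n = 16, mean = 0.95, sd = 0.59)
  b2 <- list(n = 25, mean = 1.47, sd = 0.83)
  expect_equal(two_sample_t(a2, b2, "auto")$kind, "t_pooled")
})

test_that("paired t equals the one-sample t on differences", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(3:15, 1)
    pre <- rnorm(n, 25, 8)
    post <- pre - rnorm(n, 5, 4)
    pt <- paired_t(pre, post)
    ref <- t.test(pre - post)
    expect_equal(pt$value, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(pt$p, ref$p.value, tolerance = 1e-10)
    expect_equal(pt$df, n - 1)
  }
  expect_equal(paired_t(1:5, 1:5)$value, 0)
  expect_error(paired_t(1:5, 1:5 + 2), "zero-variance")
  expect_error(paired_t(1:4, 1:5), "lengths")
})

test_that("chi-square matches the direct formula and is symmetric", {
  direct <- function(tbl) {
    e <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
    sum((tbl - e)^2 / e)
  }
  set.seed(30)
  for (i in 1:200) {
    tbl <- matrix(sample(1:30, 4, replace = TRUE), 2)
    x <- chi_square_2x2(tbl)
    expect_equal(x$value, direct(tbl), tolerance = 1e-10)
    expect_equal(chi_square_2x2(t(tbl))$value, x$value, tolerance = 1e-10)
    expect_equal(chi_square_2x2(tbl[2:1, ])$value, x$value,
                 tolerance = 1e-10)
  }
  expect_equal(chi_square_2x2(matrix(c(10, 20, 10, 20), 2))$value, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "marginal")
})

test_that("group-vs-total relative odds reproduce published ratios", {
  lo <- relative_odds(c(11, 9), c(16, 25))
  expect_equal(lo$value, 1.91, tolerance = 0.01 / 1.91)
  hi <- relative_odds(c(5, 16), c(16, 25))
  expect_equal(hi$value, 0.49, tolerance = 0.01 / 0.49)
  eq <- relative_odds(c(4, 10), c(8, 20))
  expect_equal(eq$value, 1)
  expect_error(relative_odds(c(0, 5), c(4, 10)), "continuity")
  # conventional cross-product OR is reported alongside, labelled
  expect_equal(lo$extra$conventional_or, (11 / 9) / (5 / 16),
               tolerance = 1e-12)
})

test_that("Cohen's d follows the pooled-SD definition", {
  d <- cohens_d(list(n = 20, mean = 37.2, sd = 40.9),
                list(n = 21, mean = 70.2, sd = 36.2))
  expect_equal(d, 33 / sqrt((19 * 40.9^2 + 20 * 36.2^2) / 39),
               tolerance = 1e-12)
  expect_equal(cohens_d(list(n = 5, mean = 1, sd = 2),
                        list(n = 5, mean = 1, sd = 2)), 0)
  d1 <- cohens_d(list(n = 8, mean = 0, sd = 1), list(n = 8, mean = 1, sd = 1))
  d2 <- cohens_d(list(n = 8, mean = 0, sd = 2), list(n = 8, mean = 1, sd = 2))
  expect_equal(d1 / 2, d2, tolerance = 1e-12)
})

test_that("the sex-adjusted group F reduces to t^2 without a sex effect", {
  set.seed(40)
  n <- 200
  group <- rep(c("a", "b"), each = n / 2)
  sex <- rep(c("m", "f"), n / 2)   # balanced, orthogonal to group
  y <- rnorm(n) + (group == "b") * 0.5
  fres <- glm_group_sex(y, group, sex)
  tres <- two_sample_t(y[group == "a"], y[group == "b"], "pooled")
  expect_equal(fres$value, tres$value^2, tolerance = 0.02)
  # perfectly separated outcome
  sep <- glm_group_sex(c(rnorm(10), rnorm(10) + 100),
                       rep(c("a", "b"), each = 10), rep(c("m", "f"), 10))
  expect_lt(sep$p, 1e-6)
  expect_error(glm_group_sex(rnorm(10), rep("a", 10), rep("m", 10)), "sex")
})

test_that("KS normality gate behaves on known samples", {
  set.seed(50)
  expect_gt(ks_normality(rnorm(1000))$p, 0.05)
  expect_lt(ks_normality(runif(1000))$p, 0.01)
  expect_error(ks_normality(rep(3, 10)), "zero SD")
  expect_error(ks_normality(rnorm(4)), "n >= 5")
})

test_that("summary tables report group descriptives, counts and responder rates", {
  ch <- generate_cohort(cohort_spec(n_subjects = 800, seed = 23))
  rep_ <- build_summary_tables(ch$table)
  t3 <- rep_$by_ldaep
  row <- t3[t3$variable == "bdi_change_pct", ]
  cfg <- ch$spec$reduction
  expect_equal(row$mean_1, cfg$low[1], tolerance = 3 * cfg$low[2] /
                 sqrt(row$n_1) / cfg$low[1])
  expect_equal(row$mean_2, cfg$high[1], tolerance = 3 * cfg$high[2] /
                 sqrt(row$n_2) / cfg$high[1])
  resp <- t3[t3$variable == "responder", ]
  st <- stratify_cohort(ch$table)
  expect_equal(unname(rep_$responder_pct[["low"]]),
               100 * mean(st$responder[st$ldaep_group == "low"]))
  expect_equal(resp$mean_1 + resp$sd_1, sum(st$ldaep_group == "low"))
  expect_gt(rep_$n_tests, 10)
})

test_that("non-computable strata are flagged, not fatal", {
  ch <- generate_cohort(cohort_spec(n_subjects = 30, seed = 5,
                                    male_fraction = 0))
  rep_ <- build_summary_tables(ch$table)
  sex_row <- rep_$by_ldaep[rep_$by_ldaep$variable == "sex_male", ]
  expect_equal(sex_row$kind, "not-computable")
  expect_true(is.na(sex_row$p))
})
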