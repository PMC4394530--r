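# Cohort generator: clinical tables with a configurable coupling
# between pretreatment LDAEP group and percent BDI reduction.

#' Specification of a simulated treatment cohort
#'
#' Defaults mirror the reference 41-patient SSRI cohort: 7/34
#' male/female, 15 first-episode, 10 smokers, 21 on hypnotics, low and
#' high median-split LDAEP groups with the published component slope
#' summaries, and group-conditional percent BDI reduction of
#' 37.2 +/- 40.9 (low) and 70.2 +/- 36.2 (high).
#'
#' @param n_subjects cohort size.
#' @param male_fraction,first_episode_fraction,smoker_fraction,hypnotic_fraction
#'   demographic fractions in `[0, 1]` (counts are rounded and assigned
#'   exactly).
#' @param ldaep_groups per-group `mean`/`sd` pairs for the N1, P2 and
#'   N1/P2 slopes (uV/dB).  N1 and P2 are drawn jointly with the
#'   correlation implied by the three SDs, so the N1/P2 slope
#'   (= P2 - N1) matches its configured mean and SD.
#' @param bdi_pre per-group `mean`/`sd` of the baseline BDI score.
#' @param age per-group `mean`/`sd` of age in years.
#' @param reduction per-group `mean`/`sd` of percent BDI reduction;
#'   draws are truncated to `reduction_bounds` by a moment-matched
#'   mixture so the truncated mean/SD equal the configured values.
#' @param reduction_bounds truncation bounds for percent reduction
#'   (default `c(-50, 100)`).
#' @param seed integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 41,
                        male_fraction = 7 / 41,
                        first_episode_fraction = 15 / 41,
                        smoker_fraction = 10 / 41,
                        hypnotic_fraction = 21 / 41,
                        ldaep_groups = list(
                          low = list(n1 = c(-0.18, 0.42), p2 = c(0.44, 0.44),
                                     n1p2 = c(0.62, 0.36)),
                          high = list(n1 = c(-0.61, 0.54), p2 = c(1.28, 0.70),
                                      n1p2 = c(1.89, 0.52))
                        ),
                        bdi_pre = list(low = c(28.6, 10.6),
                                       high = c(33.4, 13.7)),
                        age = list(low = c(44.2, 14.6),
                                   high = c(36.4, 15.1)),
                        reduction = list(low = c(37.2, 40.9),
                                         high = c(70.2, 36.2)),
                        reduction_bounds = c(-50, 100),
                        seed = 1) {
  if (!is_number(n_subjects) || n_subjects <= 0) {
    stopf("'n_subjects' must be positive")
  }
  fr <- c(male_fraction, first_episode_fraction, smoker_fraction,
          hypnotic_fraction)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]")
  for (g in names(reduction)) {
    if (reduction[[g]][2] < 0) stopf("reduction SD must be >= 0")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         male_fraction = male_fraction,
         first_episode_fraction = first_episode_fraction,
         smoker_fraction = smoker_fraction,
         hypnotic_fraction = hypnotic_fraction,
         ldaep_groups = ldaep_groups, bdi_pre = bdi_pre, age = age,
         reduction = reduction, reduction_bounds = reduction_bounds,
         seed = seed),
    class = "cohort_spec"
  )
}

# --- truncated-normal machinery ------------------------------------------

tnorm_moments <- function(mu, sig, a, b) {
  al <- (a - mu) / sig
  be <- (b - mu) / sig
  Z <- stats::pnorm(be) - stats::pnorm(al)
  m <- mu + sig * (stats::dnorm(al) - stats::dnorm(be)) / Z
  v <- sig^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z -
                  ((stats::dnorm(al) - stats::dnorm(be)) / Z)^2)
  c(mean = m, var = v)
}

rtnorm <- function(n, mu, sig, a, b) {
  pa <- stats::pnorm(a, mu, sig)
  pb <- stats::pnorm(b, mu, sig)
  stats::qnorm(stats::runif(n, pa, pb), mu, sig)
}

#' Calibrate the percent-reduction mixture for one group
#'
#' Percent BDI reduction on a bounded interval with a mean close to
#' the ceiling and a large SD cannot be a single truncated normal; the
#' generator uses a two-component mixture of truncated normals -- a
#' narrow "near-complete remission" component at 95% and a broad
#' partial-response component -- whose weight and broad-component
#' parameters are moment-matched so the mixture has exactly the
#' configured mean and SD on the truncation interval.
#'
#' @param target_mean,target_sd configured group mean/SD (percent).
#' @param bounds truncation interval.
#' @return list(`p` spike weight, `mu2`, `sd2`, `mu1`, `sd1`,
#'   `achieved` c(mean, sd)).
#' @export
calibrate_reduction_mixture <- function(target_mean, target_sd,
                                        bounds = c(-50, 100)) {
  mu1 <- 95
  s1 <- 5
  a <- bounds[1]
  b <- bounds[2]
  mix_mom <- function(p, m, s) {
    c1 <- tnorm_moments(mu1, s1, a, b)
    c2 <- tnorm_moments(m, s, a, b)
    mn <- p * c1[1] + (1 - p) * c2[1]
    m2 <- p * (c1[2] + c1[1]^2) + (1 - p) * (c2[2] + c2[1]^2)
    c(mn, sqrt(pmax(0, m2 - mn^2)))
  }
  obj <- function(th) {
    mm <- mix_mom(stats::plogis(th[1]), th[2], exp(th[3]))
    sum((mm - c(target_mean, target_sd))^2)
  }
  best <- NULL
  for (st in list(c(0, target_mean, log(max(target_sd, 5))),
                  c(1, 20, log(30)),
                  c(-2, target_mean, log(max(target_sd, 5))))) {
    o <- stats::optim(st, obj, control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- stats::plogis(best$par[1])
  m <- best$par[2]
  s <- exp(best$par[3])
  list(p = p, mu2 = m, sd2 = s, mu1 = mu1, sd1 = s1,
       achieved = mix_mom(p, m, s))
}

draw_reduction <- function(n, calib, bounds) {
  spike <- stats::runif(n) < calib$p
  out <- numeric(n)
  out[spike] <- rtnorm(sum(spike), calib$mu1, calib$sd1, bounds[1], bounds[2])
  out[!spike] <- rtnorm(sum(!spike), calib$mu2, calib$sd2,
                        bounds[1], bounds[2])
  out
}

# --------------------------------------------------------------------------

#' Generate a simulated treatment cohort
#'
#' Draws per-subject demographics, pretreatment LDAEP component slopes
#' (jointly normal N1/P2 per group) and percent BDI reduction from the
#' group-conditional calibrated distribution, then derives
#' `bdi_post = round(bdi_pre * (1 - reduction / 100))` clipped at 0.
#' Group sizes follow a median split (`floor(n/2)` low,
#' `ceiling(n/2)` high).
#'
#' @param spec a [cohort_spec()].
#' @param with_ground_truth logical: also return a [ground_truth()] object
#'   per subject (for EEG simulation) built from the drawn component
#'   slopes.
#' @return Object of class `cohort`: list with `table` (one row per
#'   subject: id, sex, age, episode, smoker, hypnotic, drug, dose_mg,
#'   bdi_pre, bdi_post, plus the drawn `ldaep_n1`, `ldaep_p2`,
#'   `ldaep_n1p2`, `ldaep_group`, and the latent
#'   `bdi_change_pct_drawn`), `ground_truth` (optional list), `spec`.
#' @examples
#' ch <- generate_cohort(cohort_spec(n_subjects = 41, seed = 7))
#' table(ch$table$sex)
#' @export
generate_cohort <- function(spec = cohort_spec(), with_ground_truth = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_seed(spec$seed, {
    n_low <- n %/% 2L
    group <- c(rep("low", n_low), rep("high", n - n_low))
    assign_flag <- function(frac) {
      k <- round(frac * n)
      sample(c(rep(TRUE, k), rep(FALSE, n - k)))
    }
    sex <- ifelse(assign_flag(spec$male_fraction), "male", "female")
    episode <- ifelse(assign_flag(spec$first_episode_fraction),
                      "first", "recurrent")
    smoker <- assign_flag(spec$smoker_fraction)
    hypnotic <- assign_flag(spec$hypnotic_fraction)
    # antidepressant assignment: metadata only
    drugs <- sample(c(rep("escitalopram", round(32 / 41 * n)),
                      rep("sertraline", round(7 / 41 * n))))
    drugs <- c(drugs, rep("paroxetine_cr", n - length(drugs)))
    dose_tbl <- list(escitalopram = c(10.0, 4.0), sertraline = c(78.6, 26.7),
                     paroxetine_cr = c(18.8, 8.8))
    dose <- vapply(drugs, function(d) {
      round(max(stats::rnorm(1, dose_tbl[[d]][1], dose_tbl[[d]][2]),
                dose_tbl[[d]][1] / 4), 1)
    }, numeric(1))
    age <- numeric(n)
    bdi_pre <- integer(n)
    n1 <- numeric(n)
    p2 <- numeric(n)
    red <- numeric(n)
    for (g in c("low", "high")) {
      idx <- which(group == g)
      m <- length(idx)
      age[idx] <- pmin(pmax(round(stats::rnorm(
        m, spec$age[[g]][1], spec$age[[g]][2])), 18), 80)
      bdi_pre[idx] <- pmin(pmax(round(stats::rnorm(
        m, spec$bdi_pre[[g]][1], spec$bdi_pre[[g]][2])), 5L), 63L)
      gg <- spec$ldaep_groups[[g]]
      s_n1 <- gg$n1[2]
      s_p2 <- gg$p2[2]
      s_pp <- gg$n1p2[2]
      rho <- (s_n1^2 + s_p2^2 - s_pp^2) / (2 * s_n1 * s_p2)
      rho <- min(max(rho, -0.99), 0.99)
      z1 <- stats::rnorm(m)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
      n1[idx] <- gg$n1[1] + s_n1 * z1
      p2[idx] <- gg$p2[1] + s_p2 * z2
      rd <- spec$reduction[[g]]
      if (rd[2] == 0) {
        red[idx] <- rd[1]
      } else {
        calib <- calibrate_reduction_mixture(rd[1], rd[2],
                                             spec$reduction_bounds)
        red[idx] <- draw_reduction(m, calib, spec$reduction_bounds)
      }
    }
    bdi_post <- pmax(0L, as.integer(round(bdi_pre * (1 - red / 100))))
    tab <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      sex = sex, age = age, episode = episode, smoker = smoker,
      hypnotic = hypnotic, drug = drugs, dose_mg = unname(dose),
      bdi_pre = bdi_pre, bdi_post = bdi_post,
      ldaep_n1 = n1, ldaep_p2 = p2, ldaep_n1p2 = p2 - n1,
      ldaep_group = group, bdi_change_pct_drawn = red,
      stringsAsFactors = FALSE
    )
    gt <- NULL
    if (with_ground_truth) {
      gt <- lapply(seq_len(n), function(i) {
        ground_truth(slope_n1 = n1[i], slope_p2 = p2[i])
      })
      names(gt) <- tab$subject_id
    }
    structure(list(table = tab, ground_truth = gt, spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  t <- x$table
  cat(sprintf(
    "Simulated cohort: %d subjects (%d male / %d female), N1/P2 LDAEP %.2f +/- %.2f uV/dB\n",
    nrow(t), sum(t$sex == "male"), sum(t$sex == "female"),
    mean(t$ldaep_n1p2), stats::sd(t$ldaep_n1p2)))
  invisible(x)
}
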