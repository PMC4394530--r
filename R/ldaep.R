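# The core estimator: LDAEP as the ordinary least-squares slope of
# evoked-response amplitude on stimulus intensity.

#' Fit an LDAEP slope
#'
#' The loudness dependence of auditory evoked potentials is the slope
#' of the linear regression of response amplitude on stimulus
#' intensity in dB.  `ldaep()` fits that regression by ordinary least
#' squares and returns a small model object with the usual accessor
#' methods.
#'
#' @param amplitudes response amplitudes (uV for scalp data,
#'   standardized density for source data), one per intensity.
#' @param intensities stimulus intensities in dB SPL
#'   (default 55, 65, 75, 85, 95).
#' @param component optional label ("N1", "P2", "N1/P2", ...) carried
#'   in printouts.
#' @return Object of class `ldaep` with elements `coefficients`
#'   (`intercept`, `slope` in amplitude units per dB), `r_squared`,
#'   `fitted`, `residuals`, `data`, `component`.
#' @examples
#' fit <- ldaep(c(2.0, 2.5, 3.5, 4.0, 5.0))
#' coef(fit)["slope"]   # 0.075 uV/dB
#' summary(fit)
#' @seealso [compute_scalp_ldaep()], [compute_source_ldaep()]
#' @export
ldaep <- function(amplitudes, intensities = c(55, 65, 75, 85, 95),
                  component = NULL) {
  if (length(amplitudes) != length(intensities)) {
    stopf("%d amplitudes for %d intensities",
          length(amplitudes), length(intensities))
  }
  if (length(unique(intensities)) < 2) {
    stopf("need >= 2 distinct intensities to fit a slope")
  }
  if (anyNA(amplitudes) || anyNA(intensities)) stopf("missing values")
  fit <- stats::lm(amplitudes ~ intensities)
  beta <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((amplitudes - mean(amplitudes))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(
      coefficients = c(intercept = unname(beta[1]), slope = unname(beta[2])),
      r_squared = r2,
      fitted = unname(stats::fitted(fit)),
      residuals = unname(stats::residuals(fit)),
      data = data.frame(intensity = intensities, amplitude = amplitudes),
      component = component
    ),
    class = "ldaep"
  )
}

#' @export
coef.ldaep <- function(object, ...) object$coefficients

#' @export
residuals.ldaep <- function(object, ...) object$residuals

#' @export
fitted.ldaep <- function(object, ...) object$fitted

#' @export
predict.ldaep <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$intensity else {
    if (is.list(newdata)) newdata$intensity else newdata
  }
  object$coefficients[["intercept"]] + object$coefficients[["slope"]] * x
}

#' @export
print.ldaep <- function(x, digits = 4, ...) {
  lbl <- if (is.null(x$component)) "LDAEP" else paste(x$component, "LDAEP")
  cat(sprintf("%s: slope %.*g per dB (intercept %.*g, R^2 %.3f)\n",
              lbl, digits, x$coefficients[["slope"]],
              digits, x$coefficients[["intercept"]],
              x$r_squared))
  invisible(x)
}

#' @export
summary.ldaep <- function(object, ...) {
  structure(list(fit = object), class = "summary.ldaep")
}

#' @export
print.summary.ldaep <- function(x, ...) {
  print(x$fit)
  cat("\nPer-intensity amplitudes:\n")
  df <- x$fit$data
  df$fitted <- x$fit$fitted
  df$residual <- x$fit$residuals
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ldaep <- function(x, ...) {
  lbl <- if (is.null(x$component)) "LDAEP" else paste(x$component, "LDAEP")
  graphics::plot(x$data$intensity, x$data$amplitude,
                 xlab = "Intensity (dB SPL)", ylab = "Amplitude",
                 main = sprintf("%s: slope %.3g per dB", lbl,
                                x$coefficients[["slope"]]), ...)
  graphics::abline(x$coefficients[["intercept"]],
                   x$coefficients[["slope"]], col = "steelblue")
  invisible(x)
}

#' @export
simulate.ldaep <- function(object, nsim = 1, seed = NULL, ...) {
  sd_res <- stats::sd(object$residuals)
  n <- nrow(object$data)
  draw <- function() object$fitted + stats::rnorm(n, 0, sd_res)
  if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
}

#' Least-squares LDAEP slope with intercept and fit quality
#'
#' Convenience wrapper around [ldaep()] returning the slope,
#' intercept and R-squared as a named vector.
#'
#' @inheritParams ldaep
#' @return Named numeric vector `slope`, `intercept`, `r_squared`.
#' @examples
#' fit_ldaep_slope(c(1, 2, 3, 4, 5))  # slope 0.1 uV/dB
#' @export
fit_ldaep_slope <- function(amplitudes, intensities = c(55, 65, 75, 85, 95)) {
  fit <- ldaep(amplitudes, intensities)
  c(slope = fit$coefficients[["slope"]],
    intercept = fit$coefficients[["intercept"]],
    r_squared = fit$r_squared)
}
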