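# Scalp LDAEP: N1/P2 peak detection at the vertex and the three
# intensity-dependence slopes.

#' Detect N1 and P2 peaks per intensity
#'
#' For each intensity's averaged waveform at one channel, the N1 peak
#' is the most negative sample in the N1 window (default 80-130 ms)
#' and the P2 peak the most positive sample in the P2 window (default
#' 130-230 ms), window endpoints inclusive, ties broken toward the
#' earliest latency.  A waveform that is flat over a search window is
#' flagged and returns the degenerate extremum.
#'
#' @param evoked an `evoked_set` from [average_by_intensity()].
#' @param channel channel label (default `"Cz"`).
#' @param n1_window,p2_window search windows in ms; must lie inside
#'   the epoch.
#' @return Data frame with one row per intensity: `intensity`,
#'   `n1_amplitude`, `n1_latency`, `p2_amplitude`, `p2_latency`,
#'   `peak_to_peak` (= p2 - n1) and `flat`.
#' @export
detect_n1_p2_peaks <- function(evoked, channel = "Cz",
                               n1_window = c(80, 130),
                               p2_window = c(130, 230)) {
  stopifnot(inherits(evoked, "evoked_set"))
  ch <- match(channel, evoked$channels)
  if (is.na(ch)) stopf("channel '%s' not in the evoked set", channel)
  rng <- range(evoked$times)
  for (w in list(n1_window, p2_window)) {
    if (w[1] < rng[1] || w[2] > rng[2]) {
      stopf("search window [%g, %g] ms outside the epoch [%g, %g] ms",
            w[1], w[2], rng[1], rng[2])
    }
  }
  sel_n1 <- which(evoked$times >= n1_window[1] & evoked$times <= n1_window[2])
  sel_p2 <- which(evoked$times >= p2_window[1] & evoked$times <= p2_window[2])
  out <- lapply(seq_along(evoked$intensities), function(k) {
    w <- evoked$data[[k]][ch, ]
    xn <- w[sel_n1]
    xp <- w[sel_p2]
    i_n1 <- sel_n1[which.min(xn)]   # which.min/max take the earliest tie
    i_p2 <- sel_p2[which.max(xp)]
    flat <- (max(xn) == min(xn)) || (max(xp) == min(xp))
    data.frame(
      intensity = evoked$intensities[k],
      n1_amplitude = w[i_n1], n1_latency = evoked$times[i_n1],
      p2_amplitude = w[i_p2], p2_latency = evoked$times[i_p2],
      peak_to_peak = w[i_p2] - w[i_n1],
      flat = flat
    )
  })
  do.call(rbind, out)
}

#' Scalp LDAEP at one channel
#'
#' Runs peak detection per intensity and fits the three LDAEP slopes:
#' N1 (on the signed N1 amplitude, hence typically negative), P2, and
#' the N1/P2 peak-to-peak difference.  By linearity of least squares
#' the N1/P2 slope equals the P2 slope minus the N1 slope.
#'
#' @inheritParams detect_n1_p2_peaks
#' @return Object of class `scalp_ldaep`: list with `slopes` (named
#'   vector `n1`, `p2`, `n1p2` in uV/dB), `fits` (the three [ldaep()]
#'   objects), `peaks` (the per-intensity measurements), `channel`.
#' @examples
#' \dontrun{
#' res <- compute_scalp_ldaep(evoked)
#' res$slopes
#' }
#' @export
compute_scalp_ldaep <- function(evoked, channel = "Cz",
                                n1_window = c(80, 130),
                                p2_window = c(130, 230)) {
  peaks <- detect_n1_p2_peaks(evoked, channel, n1_window, p2_window)
  if (nrow(peaks) < 2) stopf("need >= 2 intensities")
  fits <- list(
    n1 = ldaep(peaks$n1_amplitude, peaks$intensity, component = "N1"),
    p2 = ldaep(peaks$p2_amplitude, peaks$intensity, component = "P2"),
    n1p2 = ldaep(peaks$peak_to_peak, peaks$intensity, component = "N1/P2")
  )
  slopes <- vapply(fits, function(f) coef(f)[["slope"]], numeric(1))
  structure(
    list(slopes = slopes, fits = fits, peaks = peaks, channel = channel),
    class = "scalp_ldaep"
  )
}

#' @export
print.scalp_ldaep <- function(x, digits = 4, ...) {
  cat(sprintf("Scalp LDAEP at %s (uV/dB):\n", x$channel))
  print(round(x$slopes, digits))
  invisible(x)
}

#' @export
coef.scalp_ldaep <- function(object, ...) object$slopes

#' @export
plot.scalp_ldaep <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  for (f in x$fits) plot(f, ...)
  invisible(x)
}

#' Export per-subject LDAEP results as a table row
#' @noRd
scalp_ldaep_row <- function(res, subject_id) {
  data.frame(subject_id = subject_id,
             slope_n1 = res$slopes[["n1"]],
             slope_p2 = res$slopes[["p2"]],
             slope_n1p2 = res$slopes[["n1p2"]],
             r2_n1p2 = res$fits$n1p2$r_squared,
             channel = res$channel)
}
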