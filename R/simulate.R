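# Synthetic auditory-evoked EEG with known ground-truth LDAEP slopes.
#
# Each tone adds a negative N1 deflection and a positive P2 deflection
# (Gaussian-windowed, sigma 15 ms) whose vertex amplitudes follow
# baseline + slope x (intensity - 75 dB).  The scalp topography is the
# projection of a bilateral superior-temporal source pair through the
# package's spherical forward model, scaled so the linked-mastoid
# referenced Cz amplitude equals the nominal amplitude exactly;
# background activity is 1/f noise with an alpha peak, plus blinks on
# the EOG/frontal channels and occasional high-amplitude artifact
# epochs.

#' Ground truth for one simulated subject
#'
#' @param slope_n1,slope_p2 true LDAEP slopes at the (linked-mastoid
#'   referenced) vertex, in uV/dB.  The implied N1/P2 slope is
#'   `slope_p2 - slope_n1`.
#' @param amp_n1_75,amp_p2_75 component amplitudes at 75 dB (uV).
#' @param n1_latency_ms,p2_latency_ms peak latencies.
#' @param noise_sd background noise standard deviation (uV).
#' @param blink_rate blinks per minute.
#' @param artifact_epoch_fraction fraction of events that receive a
#'   high-amplitude (> 70 uV) transient.
#' @return Object of class `ground_truth` (a validated list; the
#'   derived `slope_n1p2` field is included).
#' @export
ground_truth <- function(slope_n1 = -0.3, slope_p2 = 0.6,
                         amp_n1_75 = -10, amp_p2_75 = 15,
                         n1_latency_ms = 100, p2_latency_ms = 180,
                         noise_sd = 4, blink_rate = 10,
                         artifact_epoch_fraction = 0.03) {
  stopifnot(is_number(slope_n1), is_number(slope_p2),
            is_number(noise_sd), noise_sd >= 0,
            is_number(blink_rate), blink_rate >= 0,
            is_number(artifact_epoch_fraction),
            artifact_epoch_fraction >= 0, artifact_epoch_fraction <= 1)
  structure(
    list(slope_n1 = slope_n1, slope_p2 = slope_p2,
         slope_n1p2 = slope_p2 - slope_n1,
         amp_n1_75 = amp_n1_75, amp_p2_75 = amp_p2_75,
         n1_latency_ms = n1_latency_ms, p2_latency_ms = p2_latency_ms,
         noise_sd = noise_sd, blink_rate = blink_rate,
         artifact_epoch_fraction = artifact_epoch_fraction),
    class = "ground_truth"
  )
}

#' 1/f + alpha background noise, unit variance
#' @noRd
background_noise <- function(n, srate) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) / n * srate
  f <- pmin(f, srate - f)               # two-sided spectrum
  shape <- 1 / sqrt(pmax(f, 0.5)) + 0.6 * exp(-(f - 10)^2 / (2 * 2^2))
  shape[1] <- 0                          # no DC
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Blink propagation factors from montage geometry
#' @noRd
default_blink_propagation <- function(montage) {
  eye <- c(0, 0.095, 0.01)
  d <- sqrt((montage$x - eye[1])^2 + (montage$y - eye[2])^2 +
              (montage$z - eye[3])^2)
  prop <- 0.45 * exp(-d / 0.05)
  prop[montage$type == "eog"] <- 0       # EOG handled separately
  stats::setNames(prop, montage$label)
}

#' Evoked scalp topography of a bilateral auditory source pair
#'
#' Projected through the spherical forward model and normalized so the
#' linked-mastoid referenced Cz value is exactly 1.
#' @noRd
aep_topography <- function(montage) {
  eeg <- montage[montage$type == "eeg", ]
  sens <- as.matrix(eeg[, c("x", "y", "z")])
  ctr <- c(-0.94, -0.10, 0.33)
  ctr <- ctr / sqrt(sum(ctr^2))
  pos <- rbind(ctr, ctr * c(-1, 1, 1)) * 0.078
  mom <- rbind(c(0, 0, 1e-8), c(0, 0, 1e-8))   # superior-oriented pair
  V <- rowSums(spherical_potential(pos, mom, sens))
  names(V) <- eeg$label
  ref <- V[["Cz"]] - mean(c(V[["M1"]], V[["M2"]]))
  topo <- stats::setNames(numeric(nrow(montage)), montage$label)
  topo[eeg$label] <- V / ref
  topo
}

#' Simulate one subject's raw auditory-evoked EEG
#'
#' @param seq a [generate_stimulus_sequence()] object.
#' @param truth a [ground_truth()] object.
#' @param montage electrode table from [standard_montage()]; must
#'   contain Cz and at least two EOG channels.
#' @param seed integer seed; identical inputs and seed give an
#'   identical recording.
#' @param srate sampling rate in Hz (default 1000).
#' @param blink_propagation optional named vector of per-channel blink
#'   propagation factors overriding the geometric default.
#' @return An [eeg_recording()] with attributes `"ground_truth"`,
#'   `"artifact_events"` (indices of events given artifact
#'   transients) and `"blink_propagation"`.
#' @examples
#' seq <- generate_stimulus_sequence(10, seed = 1)
#' truth <- ground_truth(noise_sd = 0, blink_rate = 0,
#'                       artifact_epoch_fraction = 0)
#' raw <- simulate_subject_eeg(seq, truth, seed = 1, srate = 250)
#' @export
simulate_subject_eeg <- function(seq, truth, montage = standard_montage(),
                                 seed = 1, srate = 1000,
                                 blink_propagation = NULL) {
  stopifnot(inherits(seq, "stimulus_sequence"),
            inherits(truth, "ground_truth"))
  if (!"Cz" %in% montage$label || sum(montage$type == "eog") < 2) {
    stopf("montage must contain Cz and at least two EOG channels")
  }
  dur <- ceiling(max(seq$onsets) + 1)    # pad to whole seconds
  n <- as.integer(dur * srate)
  n_ch <- nrow(montage)
  topo <- aep_topography(montage)
  prop <- if (is.null(blink_propagation)) {
    default_blink_propagation(montage)
  } else {
    p <- default_blink_propagation(montage)
    p[names(blink_propagation)] <- blink_propagation
    p
  }
  eeg_idx <- which(montage$type == "eeg")
  eog_idx <- which(montage$type == "eog")
  with_seed(seed, {
    data <- matrix(0, n_ch, n)
    # evoked components
    sigma_s <- 0.015 * srate
    half <- as.integer(floor(5 * sigma_s))
    k <- (-half):half
    g <- exp(-k^2 / (2 * sigma_s^2))
    lat_n1 <- ms_to_samples(truth$n1_latency_ms, srate)
    lat_p2 <- ms_to_samples(truth$p2_latency_ms, srate)
    onset_idx <- as.integer(round(seq$onsets * srate)) + 1L
    tpl <- numeric(n)
    for (i in seq_len(seq$n_events)) {
      di <- seq$intensities[i] - 75
      a_n1 <- truth$amp_n1_75 + truth$slope_n1 * di
      a_p2 <- truth$amp_p2_75 + truth$slope_p2 * di
      for (comp in list(c(lat_n1, a_n1), c(lat_p2, a_p2))) {
        idx <- onset_idx[i] + comp[1] + k
        ok <- idx >= 1L & idx <= n
        tpl[idx[ok]] <- tpl[idx[ok]] + comp[2] * g[ok]
      }
    }
    data[eeg_idx, ] <- outer(topo[eeg_idx], tpl)
    # background noise on every channel
    if (truth$noise_sd > 0) {
      for (ch in seq_len(n_ch)) {
        data[ch, ] <- data[ch, ] + truth$noise_sd * background_noise(n, srate)
      }
    }
    # blinks
    if (truth$blink_rate > 0) {
      n_blinks <- stats::rpois(1, truth$blink_rate * dur / 60)
      if (n_blinks > 0) {
        bl_len <- as.integer(0.4 * srate)
        bl <- sin(pi * seq_len(bl_len) / bl_len)^2
        b_on <- sort(as.integer(stats::runif(n_blinks, 1, n - bl_len)))
        for (t0 in b_on) {
          amp <- stats::rnorm(1, 150, 25)
          idx <- t0:(t0 + bl_len - 1L)
          for (ch in eeg_idx) {
            data[ch, idx] <- data[ch, idx] + prop[ch] * amp * bl
          }
          sgn <- ifelse(montage$label[eog_idx] == "VEOGL", -0.6, 1)
          for (j in seq_along(eog_idx)) {
            f <- if (grepl("^H", montage$label[eog_idx[j]])) 0.15 else sgn[j]
            data[eog_idx[j], idx] <- data[eog_idx[j], idx] + f * amp * bl
          }
        }
      }
    }
    # high-amplitude artifact epochs
    n_art <- round(truth$artifact_epoch_fraction * seq$n_events)
    art_events <- integer(0)
    if (n_art > 0) {
      art_events <- sort(sample(seq$n_events, n_art))
      tr_len <- as.integer(0.03 * srate)
      tr <- sin(pi * seq_len(tr_len) / tr_len)^2
      for (i in art_events) {
        ch <- sample(eeg_idx, 1)
        t0 <- onset_idx[i] + as.integer(stats::runif(1, 0, 0.18 * srate))
        amp <- sample(c(-1, 1), 1) * stats::runif(1, 90, 150)
        idx <- t0:(t0 + tr_len - 1L)
        idx <- idx[idx <= n]
        data[ch, idx] <- data[ch, idx] + amp * tr[seq_along(idx)]
      }
    }
    raw <- eeg_recording(data, srate, montage, events_table(seq))
    attr(raw, "ground_truth") <- truth
    attr(raw, "artifact_events") <- art_events
    attr(raw, "blink_propagation") <- prop
    raw
  })
}
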