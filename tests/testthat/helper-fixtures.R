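# Shared fixtures: all built in code at test time.

#' Evoked set holding one waveform per intensity at every channel of a
#' minimal montage (Cz + mastoids + one EOG)
make_evoked <- function(waves, times, channels = c("Cz", "M1", "M2"),
                        intensities = c(55, 65, 75, 85, 95)[seq_along(waves)]) {
  data <- lapply(waves, function(w) {
    m <- matrix(0, length(channels), length(times))
    m[1, ] <- w
    m
  })
  structure(
    list(data = data, intensities = intensities,
         n_epochs_used = rep(1L, length(waves)),
         rejection_rate = rep(0, length(waves)),
         times = times, channels = channels, srate = 1000,
         reference = "none"),
    class = "evoked_set"
  )
}

gauss_bump <- function(times, center_ms, amp, sigma_ms = 15) {
  # same compact support (5 sigma) as the simulator's evoked template
  g <- amp * exp(-(times - center_ms)^2 / (2 * sigma_ms^2))
  g[abs(times - center_ms) > 5 * sigma_ms] <- 0
  g
}

#' Small noiseless simulated subject run through the scalp pipeline
#' (no filtering: the evoked template is already band-limited)
noiseless_scalp_run <- function(slope_n1 = -0.4, slope_p2 = 0.9,
                                n_events = 25, srate = 500, seed = 11) {
  seq <- generate_stimulus_sequence(n_events, seed = seed)
  truth <- ground_truth(slope_n1 = slope_n1, slope_p2 = slope_p2,
                        amp_n1_75 = -12, amp_p2_75 = 22,
                        noise_sd = 0, blink_rate = 0,
                        artifact_epoch_fraction = 0)
  raw <- simulate_subject_eeg(seq, truth, seed = seed + 1, srate = srate)
  raw <- set_reference(raw, "linked_mastoid")
  ep <- reject_artifact_epochs(extract_epochs(raw))
  list(truth = truth, evoked = average_by_intensity(ep))
}

#' White-noise recording with evenly spaced events
noise_recording <- function(n_events = 10, srate = 250, noise_sd = 1,
                            seed = 5, montage = standard_montage()) {
  onsets <- 1 + (seq_len(n_events) - 1) * 0.8
  dur <- ceiling(max(onsets) + 1)
  set.seed(seed)
  data <- matrix(rnorm(nrow(montage) * dur * srate, sd = noise_sd),
                 nrow(montage))
  eeg_recording(data, srate, montage,
                data.frame(onset_s = onsets,
                           intensity_db = rep_len(c(55, 65, 75, 85, 95),
                                                  n_events)))
}
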