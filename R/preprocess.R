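# Preprocessing: band-pass filtering, ocular correction, referencing,
# epoching, amplitude-based artifact rejection and per-intensity
# averaging.  The canonical order is
#   filter -> ocular correction -> (reference) -> epoch -> reject -> average
# and every step is deterministic.

#' Construct a raw EEG recording
#'
#' @param data channels x samples numeric matrix in microvolts.
#' @param srate sampling rate in Hz.
#' @param channels montage data frame ([standard_montage()] layout);
#'   its `label` order must match the rows of `data`.
#' @param events data frame with `onset_s` and `intensity_db`.
#' @param reference reference state label carried in provenance.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, channels, events,
                          reference = "none") {
  if (!is.matrix(data)) stopf("'data' must be a channels x samples matrix")
  if (nrow(data) != nrow(channels)) {
    stopf("%d data rows but %d channel entries", nrow(data), nrow(channels))
  }
  if (!is_number(srate) || srate <= 0) stopf("'srate' must be > 0")
  if (!all(c("onset_s", "intensity_db") %in% names(events))) {
    stopf("'events' needs columns onset_s and intensity_db")
  }
  dur <- ncol(data) / srate
  if (any(events$onset_s < 0 | events$onset_s > dur)) {
    stopf("event onset outside the recording (duration %.2f s)", dur)
  }
  structure(list(data = data, srate = srate, channels = channels,
                 events = events, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "EEG recording: %d channels x %d samples @ %g Hz (%.1f s), %d events, reference: %s\n",
    nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate,
    nrow(x$events), x$reference))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Applies a zero-phase Butterworth band-pass (default 1-30 Hz) to all
#' channels.  The filter is realized as a second-order high-pass
#' cascaded with a fourth-order low-pass, each applied
#' forward-backward (`signal::filtfilt`), so the passband phase shift
#' is zero and symmetric peaks keep their latency.
#'
#' @param raw an [eeg_recording()].
#' @param low,high band edges in Hz; must satisfy
#'   `0 < low < high < srate/2`.
#' @param hp_order,lp_order Butterworth orders of the two sections.
#' @return The filtered recording; event markers unchanged.
#' @export
bandpass_filter <- function(raw, low = 1, high = 30,
                            hp_order = 2, lp_order = 4) {
  stopifnot(inherits(raw, "eeg_recording"))
  nyq <- raw$srate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stopf("band [%g, %g] Hz invalid for Nyquist %g Hz", low, high, nyq)
  }
  hp <- signal::butter(hp_order, low / nyq, type = "high")
  lp <- signal::butter(lp_order, high / nyq, type = "low")
  out <- raw
  for (i in seq_len(nrow(raw$data))) {
    out$data[i, ] <- signal::filtfilt(lp, signal::filtfilt(hp, raw$data[i, ]))
  }
  out
}

#' Regression-based ocular artifact correction
#'
#' Estimates per-channel propagation of the electrooculogram onto the
#' EEG by least squares over blink segments (samples where the
#' vertical EOG exceeds a threshold) and subtracts the fitted EOG
#' contribution from every EEG channel over the whole recording.  EOG
#' channels and event markers pass through unchanged.  When the EOG
#' shows no blinks (or no variance) the recording is returned as is.
#'
#' @param raw an [eeg_recording()].
#' @param eog_channels labels of EOG channels used as regressors;
#'   default all channels of type `"eog"` in the montage.
#' @param blink_threshold amplitude (uV) on the first EOG channel
#'   above which a sample is treated as blink-contaminated
#'   (default 40).
#' @return Corrected recording with an attribute
#'   `"ocular_coefficients"` (channels x EOG matrix).
#' @export
remove_ocular_artifacts <- function(raw, eog_channels = NULL,
                                    blink_threshold = 40) {
  stopifnot(inherits(raw, "eeg_recording"))
  if (is.null(eog_channels)) {
    eog_channels <- raw$channels$label[raw$channels$type == "eog"]
  }
  if (!length(eog_channels)) stopf("no EOG channel available")
  require_channels(raw$channels, eog_channels)
  eog_idx <- match(eog_channels, raw$channels$label)
  eeg_idx <- which(raw$channels$type == "eeg")
  E <- raw$data[eog_idx, , drop = FALSE]
  if (all(apply(E, 1, stats::var) < .Machine$double.eps)) {
    out <- raw
    attr(out, "ocular_coefficients") <-
      matrix(0, length(eeg_idx), length(eog_idx),
             dimnames = list(raw$channels$label[eeg_idx], eog_channels))
    return(out)
  }
  blink <- abs(E[1, ]) > blink_threshold
  if (sum(blink) < 10L) blink <- rep(TRUE, ncol(E))  # fall back: whole record
  X <- t(E[, blink, drop = FALSE])
  Y <- t(raw$data[eeg_idx, blink, drop = FALSE])
  B <- tryCatch(stats::lsfit(X, Y, intercept = TRUE)$coefficients,
                error = function(e) NULL)
  out <- raw
  if (!is.null(B)) {
    # subtract slope terms only; the intercept is baseline, not blink
    slopes <- B[-1, , drop = FALSE]
    out$data[eeg_idx, ] <- raw$data[eeg_idx, ] - t(t(E) %*% slopes)
    attr(out, "ocular_coefficients") <-
      t(slopes)
  }
  out
}

#' Re-reference a recording
#'
#' @param raw an [eeg_recording()].
#' @param type `"linked_mastoid"` (subtract the M1/M2 average, the
#'   default scalp-analysis reference), `"average"` (common average of
#'   all non-mastoid EEG channels) or `"none"`.
#' @return Re-referenced recording (EOG channels untouched).
#' @export
set_reference <- function(raw, type = c("linked_mastoid", "average", "none")) {
  type <- match.arg(type)
  stopifnot(inherits(raw, "eeg_recording"))
  out <- raw
  eeg_idx <- which(raw$channels$type == "eeg")
  if (type == "linked_mastoid") {
    require_channels(raw$channels, c("M1", "M2"))
    m_idx <- match(c("M1", "M2"), raw$channels$label)
    ref <- colMeans(raw$data[m_idx, , drop = FALSE])
    out$data[eeg_idx, ] <- sweep(raw$data[eeg_idx, , drop = FALSE], 2, ref)
  } else if (type == "average") {
    use <- which(raw$channels$type == "eeg" & !raw$channels$mastoid)
    ref <- colMeans(raw$data[use, , drop = FALSE])
    out$data[eeg_idx, ] <- sweep(raw$data[eeg_idx, , drop = FALSE], 2, ref)
  }
  out$reference <- type
  out
}

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per event with inclusive millisecond bounds (0 ms =
#' stimulus onset) and subtracts the per-channel mean over the
#' baseline window.  Events too close to the recording edge are kept
#' in the set but flagged rejected with reason `"edge"`.
#'
#' @param raw an [eeg_recording()].
#' @param window epoch window in ms, default `c(-100, 400)`; must
#'   cover at least 0-230 ms (the P2 search bound).
#' @param baseline baseline window in ms within `window`,
#'   default `c(-100, 0)`.
#' @return Object of class `epoch_set`: list with `epochs`
#'   (epoch x channel x time array), `times` (ms), `intensity`,
#'   `rejected`, `reject_reason`, `baseline`, `channels`, `srate`.
#' @export
extract_epochs <- function(raw, window = c(-100, 400),
                           baseline = c(-100, 0)) {
  stopifnot(inherits(raw, "eeg_recording"))
  if (!(window[1] <= 0 && window[2] >= 230)) {
    stopf("epoch window must cover [0, 230] ms")
  }
  if (baseline[1] < window[1] || baseline[2] > window[2]) {
    stopf("baseline must lie within the epoch window")
  }
  s0 <- ms_to_samples(window[1], raw$srate)
  s1 <- ms_to_samples(window[2], raw$srate)
  times <- (s0:s1) / raw$srate * 1000
  n_ev <- nrow(raw$events)
  n_ch <- nrow(raw$data)
  n_t <- length(times)
  ep <- array(NA_real_, c(n_ev, n_ch, n_t))
  rejected <- logical(n_ev)
  reason <- rep(NA_character_, n_ev)
  onset_idx <- as.integer(round(raw$events$onset_s * raw$srate)) + 1L
  bsel <- times >= baseline[1] & times <= baseline[2]
  for (i in seq_len(n_ev)) {
    a <- onset_idx[i] + s0
    b <- onset_idx[i] + s1
    if (a < 1L || b > ncol(raw$data)) {
      rejected[i] <- TRUE
      reason[i] <- "edge"
      next
    }
    x <- raw$data[, a:b, drop = FALSE]
    if (any(bsel)) x <- x - rowMeans(x[, bsel, drop = FALSE])
    ep[i, , ] <- x
  }
  structure(
    list(epochs = ep, times = times,
         intensity = raw$events$intensity_db,
         rejected = rejected, reject_reason = reason,
         baseline = baseline, channels = raw$channels, srate = raw$srate,
         reference = raw$reference),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "Epoch set: %d epochs x %d channels x %d samples (%g to %g ms), %d rejected\n",
    dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
    min(x$times), max(x$times), sum(x$rejected)))
  invisible(x)
}

#' Amplitude-based artifact rejection
#'
#' Flags an epoch rejected when the absolute amplitude on any EEG
#' channel exceeds the threshold anywhere in the epoch window
#' (default 70 uV; EOG channels are not tested).  Emits a warning when
#' any intensity's rejection rate reaches 5%, and an error when every
#' epoch of an intensity is rejected, since averaging would then be
#' impossible.
#'
#' @param epochs an [extract_epochs()] object.
#' @param threshold rejection threshold in uV (> 0).
#' @return The epoch set with updated `rejected`/`reject_reason` and a
#'   `rejection_rate` element (per intensity, edge rejections
#'   included).
#' @export
reject_artifact_epochs <- function(epochs, threshold = 70) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is_number(threshold) || threshold <= 0) stopf("'threshold' must be > 0")
  eeg_idx <- which(epochs$channels$type == "eeg")
  n_ev <- dim(epochs$epochs)[1]
  for (i in seq_len(n_ev)) {
    if (epochs$rejected[i]) next
    mx <- max(abs(epochs$epochs[i, eeg_idx, ]))
    if (mx > threshold) {
      epochs$rejected[i] <- TRUE
      epochs$reject_reason[i] <- "amplitude"
    }
  }
  rates <- tapply(epochs$rejected, epochs$intensity, mean)
  if (any(is.na(rates))) rates <- rates[!is.na(rates)]
  for (int in names(rates)) {
    n_kept <- sum(!epochs$rejected & epochs$intensity == as.numeric(int))
    if (n_kept == 0L) {
      stopf("all epochs rejected at %s dB; averaging impossible", int)
    }
    if (rates[[int]] >= 0.05) {
      warning(sprintf("rejection rate %.1f%% at %s dB (>= 5%%)",
                      100 * rates[[int]], int), call. = FALSE)
    }
  }
  epochs$rejection_rate <- rates
  epochs$threshold <- threshold
  epochs
}

#' Average retained epochs by stimulus intensity
#'
#' @param epochs an [extract_epochs()] (typically after
#'   [reject_artifact_epochs()]) object.
#' @return Object of class `evoked_set`: list with `data` (one
#'   channels x time matrix per intensity), `intensities`,
#'   `n_epochs_used`, `rejection_rate`, `times`, `channels`, `srate`.
#' @export
average_by_intensity <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  ints <- sort(unique(epochs$intensity))
  data <- list()
  n_used <- integer(length(ints))
  for (k in seq_along(ints)) {
    sel <- which(epochs$intensity == ints[k] & !epochs$rejected)
    if (!length(sel)) stopf("no retained epochs at %g dB", ints[k])
    n_used[k] <- length(sel)
    sub <- epochs$epochs[sel, , , drop = FALSE]
    data[[k]] <- apply(sub, c(2, 3), mean)
  }
  rr <- tapply(epochs$rejected, epochs$intensity, mean)[as.character(ints)]
  structure(
    list(data = data, intensities = ints, n_epochs_used = n_used,
         rejection_rate = as.numeric(rr), times = epochs$times,
         channels = epochs$channels$label, srate = epochs$srate,
         reference = epochs$reference),
    class = "evoked_set"
  )
}

#' @export
print.evoked_set <- function(x, ...) {
  cat(sprintf(
    "Evoked set: %d intensities (%s dB), %s epochs averaged, %g to %g ms\n",
    length(x$intensities), paste(x$intensities, collapse = "/"),
    paste(x$n_epochs_used, collapse = "/"), min(x$times), max(x$times)))
  invisible(x)
}
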