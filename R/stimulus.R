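# Auditory stimulus sequences for the intensity-dependence paradigm.

#' Generate a randomized auditory stimulus sequence
#'
#' Produces the tone sequence of the LDAEP paradigm: 1 kHz tones of
#' 80 ms duration (10 ms rise/fall) at five intensities (55, 65, 75,
#' 85, 95 dB SPL), presented in seeded random order with a uniformly
#' drawn offset-to-onset gap of 500-900 ms (so successive onsets are
#' 580-980 ms apart).  Intensity labels are balanced: when `n_events`
#' is divisible by five each intensity occurs exactly `n_events / 5`
#' times; otherwise the remainder is distributed over the lowest
#' intensities before shuffling.
#'
#' @param n_events number of tones (>= 5).
#' @param seed integer seed; the same (`n_events`, `seed`) pair always
#'   yields an identical sequence.
#' @param isi_range offset-to-onset gap range in seconds
#'   (default `c(0.5, 0.9)`).
#' @param first_onset onset of the first tone in seconds (default 1).
#' @param intensities intensity labels in dB SPL.
#' @return An object of class `stimulus_sequence`: a list with
#'   `onsets` (s), `intensities` (dB per event), `tone` (carrier spec)
#'   and `n_events`.
#' @examples
#' s <- generate_stimulus_sequence(100, seed = 1)
#' table(s$intensities)
#' range(diff(s$onsets))
#' @export
generate_stimulus_sequence <- function(n_events, seed,
                                       isi_range = c(0.5, 0.9),
                                       first_onset = 1,
                                       intensities = c(55, 65, 75, 85, 95)) {
  if (!is_number(n_events) || n_events < 5) {
    stopf("'n_events' must be a single number >= 5 (got %s)",
          deparse(substitute(n_events)))
  }
  n_events <- as.integer(n_events)
  tone_dur <- 0.08
  with_seed(seed, {
    base <- rep(intensities, length.out = 5 * (n_events %/% 5))
    extra <- intensities[seq_len(n_events %% 5)]
    labels <- sample(c(base, extra))
    gaps <- stats::runif(n_events - 1L, isi_range[1], isi_range[2])
    onsets <- first_onset + c(0, cumsum(tone_dur + gaps))
    structure(
      list(
        onsets = onsets,
        intensities = labels,
        tone = list(freq_hz = 1000, duration_s = tone_dur,
                    rise_fall_s = 0.01),
        n_events = n_events
      ),
      class = "stimulus_sequence"
    )
  })
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("Stimulus sequence: %d tones, %.1f-%.1f s, intensities %s dB\n",
              x$n_events, min(x$onsets), max(x$onsets),
              paste(sort(unique(x$intensities)), collapse = "/")))
  invisible(x)
}

#' @noRd
events_table <- function(seq) {
  data.frame(onset_s = seq$onsets, intensity_db = seq$intensities)
}
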