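#' Synthetic EEG generation settings
#'
#' Parameters of the three-class synthetic EEG generator. The three classes
#' emulate the regimes the Bonn A/D/E sets represent: a normal alpha-band
#' background, an interictal background with sporadic biphasic spikes, and a
#' high-amplitude ictal spike-wave rhythm.
#'
#' @param n_per_class Segments per class.
#' @param n_samples Samples per segment (default 4096, divisible by
#'   \eqn{2^4} so the level-4 periodized transform is orthonormal).
#' @param sampling_rate Hz (default 173.61, the Bonn distribution's rate).
#' @param noise_sd Standard deviation of the additive white noise relative
#'   to the unit-amplitude background sinusoid.
#' @param spike_rate Interictal spike rate in spikes per second.
#' @param ictal_freq Spike-wave fundamental frequency in Hz (default 3, the
#'   classic 3 Hz spike-and-wave rhythm).
#' @param ictal_amp_ratio Ictal amplitude as a multiple of the background
#'   standard deviation (> 1).
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_per_class = 100, n_samples = 4096,
                       sampling_rate = 173.61, noise_sd = 0.8,
                       spike_rate = 1.5, ictal_freq = 3,
                       ictal_amp_ratio = 6, seed = 1) {
  stopifnot(n_per_class >= 1, n_samples >= 16, sampling_rate > 0,
            noise_sd > 0, spike_rate > 0, ictal_amp_ratio > 1)
  if (ictal_freq >= sampling_rate / 2) {
    stop_dmelm("ictal_freq must be below the Nyquist frequency")
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 n_samples = as.integer(n_samples),
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 spike_rate = spike_rate, ictal_freq = ictal_freq,
                 ictal_amp_ratio = ictal_amp_ratio, seed = as.integer(seed)),
            class = "synth_spec")
}

# Biphasic spike surrogate: difference of two Gaussians, ~60 ms wide.
biphasic_spike <- function(t, center, width = 0.06) {
  s1 <- width / 4
  s2 <- width / 2
  exp(-((t - center)^2) / (2 * s1^2)) - 0.6 * exp(-((t - center + width / 3)^2) / (2 * s2^2))
}

#' Generate one synthetic EEG segment
#'
#' The `normal` class is a unit-amplitude sinusoid at a frequency drawn
#' uniformly in the alpha band (8-13 Hz) plus white Gaussian noise of
#' standard deviation `noise_sd`. The `interictal` class adds Poisson-timed
#' biphasic spikes (difference-of-Gaussians, about 60 ms wide, amplitude 5
#' times the background standard deviation) to that background. The `ictal`
#' class is a spike-wave oscillation at `ictal_freq` with amplitude
#' `ictal_amp_ratio` times the background standard deviation, plus noise.
#'
#' @param class_kind `"normal"`, `"interictal"` or `"ictal"`.
#' @param spec A [synth_spec()].
#' @param seed Integer seed for this segment (deterministic output).
#' @param segment_id Identifier recorded on the segment.
#' @return An [eeg_segment] labelled with `class_kind`.
#' @export
synth_eeg_segment <- function(class_kind = c("normal", "interictal", "ictal"),
                              spec = synth_spec(), seed = spec$seed,
                              segment_id = NULL) {
  class_kind <- match.arg(class_kind)
  n <- spec$n_samples
  fs <- spec$sampling_rate
  t <- (seq_len(n) - 1L) / fs
  dur <- n / fs
  # background sd: unit sinusoid (var 1/2) plus independent noise
  bg_sd <- sqrt(0.5 + spec$noise_sd^2)
  x <- with_seed(seed, {
    f_alpha <- stats::runif(1, 8, 13)
    phase <- stats::runif(1, 0, 2 * pi)
    noise <- stats::rnorm(n, 0, spec$noise_sd)
    base <- switch(class_kind,
      normal = ,
      interictal = sin(2 * pi * f_alpha * t + phase) + noise,
      ictal = {
        ph <- 2 * pi * spec$ictal_freq * t + phase
        # spike-wave: sharpened sinusoid (fundamental + harmonics), unit peak
        sw <- sin(ph) + 0.5 * sin(2 * ph) + 0.25 * sin(3 * ph)
        sw <- sw / max(abs(sw))
        spec$ictal_amp_ratio * bg_sd * sw + noise
      })
    if (class_kind == "interictal") {
      n_spikes <- stats::rpois(1, spec$spike_rate * dur)
      if (n_spikes > 0) {
        centers <- sort(stats::runif(n_spikes, 0.1, dur - 0.1))
        signs <- sample(c(-1, 1), n_spikes, replace = TRUE)
        for (i in seq_len(n_spikes)) {
          base <- base + signs[i] * 5 * bg_sd * biphasic_spike(t, centers[i])
        }
      }
    }
    base
  })
  eeg_segment(x, sampling_rate = fs,
              segment_id = segment_id %||% sprintf("%s_%06d", class_kind, seed),
              label = class_kind)
}

#' Generate a labelled three-class synthetic EEG dataset
#'
#' Produces `n_per_class` segments of each class, in class order
#' (normal, interictal, ictal). The segment seeds are derived
#' deterministically from `spec$seed`, so a fixed spec yields a
#' byte-identical dataset on repeat.
#'
#' @param spec A [synth_spec()].
#' @return An [eeg_dataset] with class names
#'   `c("normal", "interictal", "ictal")`.
#' @export
synth_eeg_dataset <- function(spec = synth_spec()) {
  classes <- c("normal", "interictal", "ictal")
  segments <- list()
  k <- 0L
  for (ci in seq_along(classes)) {
    for (j in seq_len(spec$n_per_class)) {
      k <- k + 1L
      seg_seed <- (spec$seed * 10007L + ci * 1000003L + j * 7919L) %% 2147483647L
      segments[[k]] <- synth_eeg_segment(classes[ci], spec, seed = seg_seed,
                                         segment_id = sprintf("%s_%03d", classes[ci], j))
    }
  }
  eeg_dataset(segments, class_names = classes,
              set_name = sprintf("synthetic(seed=%d)", spec$seed))
}
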