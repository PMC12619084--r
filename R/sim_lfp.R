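#' Configuration for the synthetic LFP generator
#'
#' Describes a single-channel recording of background noise with injected
#' rhythmic high-amplitude events emulating hippocampal paroxysmal
#' discharges: a sinusoid at `event_freq_hz` under a trapezoidal envelope
#' (0.5 s ramps) whose plateau amplitude is `event_amplitude_factor` times
#' the background SD, added on top of the background.
#'
#' Defaults mirror the recording conditions the detector targets: 1 h
#' sessions sampled at 2 kHz, events at about 20 per hour with durations in
#' the tens of seconds and a dominant rhythm faster than the detector's
#' 5 Hz high-pass cutoff.
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param baseline_sd Background SD in microvolts.
#' @param background_model `"white"` (default), `"ar1"` or `"pink"`.
#'   The detector's baseline logic must not depend on spectral colour, so
#'   coloured backgrounds are offered for robustness checks.
#' @param background_param AR(1) coefficient (for `"ar1"`); ignored
#'   otherwise.
#' @param event_rate_per_hour Mean number of events per hour (Poisson).
#' @param event_duration_range Uniform bounds `c(min_s, max_s)` in seconds.
#' @param event_amplitude_factor Plateau amplitude as a multiple of
#'   `baseline_sd`.
#' @param event_freq_hz Dominant oscillation frequency in Hz; must be below
#'   `fs/2`.
#' @param min_gap_s Minimum separation enforced between placed events (and
#'   from a margin of twice the minimum duration at the recording edges),
#'   so that no truth event is truncated or abuts its neighbour.
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   recordings.
#' @return A `sim_lfp_config` list.
#' @export
sim_lfp_config <- function(duration_s = 3600, fs = 2000, baseline_sd = 20,
                           background_model = c("white", "ar1", "pink"),
                           background_param = 0.95,
                           event_rate_per_hour = 20,
                           event_duration_range = c(15, 60),
                           event_amplitude_factor = 5,
                           event_freq_hz = 8,
                           min_gap_s = 5,
                           seed = NULL) {
  background_model <- match.arg(background_model)
  stopifnot(duration_s > 0, fs > 0, baseline_sd > 0,
            event_rate_per_hour >= 0, event_amplitude_factor > 0,
            length(event_duration_range) == 2L,
            event_duration_range[1] > 0,
            event_duration_range[2] >= event_duration_range[1],
            min_gap_s >= 0)
  if (fs <= 2 * event_freq_hz)
    stop_srseize("fs must exceed twice event_freq_hz")
  structure(list(duration_s = duration_s, fs = fs, baseline_sd = baseline_sd,
                 background_model = background_model,
                 background_param = background_param,
                 event_rate_per_hour = event_rate_per_hour,
                 event_duration_range = event_duration_range,
                 event_amplitude_factor = event_amplitude_factor,
                 event_freq_hz = event_freq_hz, min_gap_s = min_gap_s,
                 seed = seed),
            class = "sim_lfp_config")
}

# Draw the ground-truth event schedule (count, durations, placements)
# without synthesising any waveform. Placement is uniform with rejection
# of overlaps, of gaps below min_gap_s and of positions within twice the
# minimum duration of the recording edges.
draw_event_schedule <- function(config) {
  dur <- config$duration_s
  n_events <- rpois(1L, config$event_rate_per_hour * dur / 3600)
  if (n_events == 0L)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      amplitude_factor = numeric(0),
                      dominant_freq = numeric(0)))
  margin <- 2 * config$event_duration_range[1]
  durs <- runif(n_events, config$event_duration_range[1],
                config$event_duration_range[2])
  onsets <- numeric(0); offsets <- numeric(0)
  max_tries <- 1000L * n_events
  tries <- 0L
  for (d in durs) {
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop_srseize("could not place ", n_events, " disjoint events of ",
                     "total duration ", round(sum(durs)), " s in ", dur,
                     " s after ", max_tries, " attempts; lower the event ",
                     "rate or durations")
      lo <- margin
      hi <- dur - margin - d
      if (hi <= lo)
        stop_srseize("recording too short for an event of ", round(d),
                     " s with ", margin, " s edge margins")
      on <- runif(1L, lo, hi)
      ok <- all(on >= offsets + config$min_gap_s |
                  on + d <= onsets - config$min_gap_s)
      if (ok) { onsets <- c(onsets, on); offsets <- c(offsets, on + d); break }
    }
  }
  o <- order(onsets)
  data.frame(onset_s = onsets[o], offset_s = offsets[o],
             amplitude_factor = rep(config$event_amplitude_factor, n_events),
             dominant_freq = rep(config$event_freq_hz, n_events))
}

sim_background <- function(config, n) {
  sd0 <- config$baseline_sd
  switch(config$background_model,
    white = rnorm(n, 0, sd0),
    ar1 = {
      phi <- config$background_param
      stopifnot(abs(phi) < 1)
      innov_sd <- sd0 * sqrt(1 - phi^2)  # stationary SD = sd0
      as.numeric(stats::filter(rnorm(n, 0, innov_sd), phi,
                               method = "recursive"))
    },
    pink = {
      # spectral synthesis: shape white noise by 1/sqrt(f), rescale to sd0
      w <- rnorm(n)
      W <- fft(w)
      f <- c(1, seq_len(n - 1))
      f <- pmin(f, n - f + 1)  # symmetric frequency index
      X <- W / sqrt(f)
      x <- Re(fft(X, inverse = TRUE)) / n
      x * sd0 / sd(x)
    })
}

#' Simulate an LFP recording with ground-truth seizure events
#'
#' Background noise plus injected sinusoidal discharges under a trapezoidal
#' envelope (0.5 s linear ramps, capped at half the event duration). Each
#' event's plateau amplitude is `event_amplitude_factor * baseline_sd` and
#' its phase is randomised.
#'
#' @param config A [sim_lfp_config].
#' @return A list with elements `recording` (an [lfp_recording]) and
#'   `events` (data frame `onset_s`, `offset_s`, `amplitude_factor`,
#'   `dominant_freq` — the simulator's ground truth).
#' @examples
#' sim <- simulate_lfp(sim_lfp_config(duration_s = 300, seed = 1))
#' nrow(sim$events)
#' @export
simulate_lfp <- function(config) {
  stopifnot(inherits(config, "sim_lfp_config"))
  with_seed(config$seed, {
    n <- round(config$duration_s * config$fs)
    x <- sim_background(config, n)
    truth <- draw_event_schedule(config)
    if (nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        i0 <- floor(truth$onset_s[i] * config$fs) + 1L
        i1 <- ceiling(truth$offset_s[i] * config$fs)
        t_rel <- (seq.int(i0, i1) - 1) / config$fs - truth$onset_s[i]
        d <- truth$offset_s[i] - truth$onset_s[i]
        ramp <- min(0.5, d / 2)
        env <- pmin(1, pmin(t_rel, d - t_rel) / ramp)
        env <- pmax(env, 0)
        phase <- runif(1L, 0, 2 * pi)
        amp <- truth$amplitude_factor[i] * config$baseline_sd
        x[i0:i1] <- x[i0:i1] +
          amp * env * sin(2 * pi * truth$dominant_freq[i] * t_rel + phase)
      }
    }
    prov <- sprintf("simulate_lfp(%s, rate=%g/h, amp=%gxSD, seed=%s)",
                    config$background_model, config$event_rate_per_hour,
                    config$event_amplitude_factor,
                    if (is.null(config$seed)) "NULL" else config$seed)
    list(recording = lfp_recording(x, fs = config$fs, channel_id = "sim",
                                   provenance = prov),
         events = truth)
  })
}

#' Simulate two groups of per-animal seizure metrics
#'
#' Independent normal draws, one value per animal, for exercising the
#' group-comparison statistics at realistic group sizes (e.g. 9 control vs
#' 5 treated mice).
#'
#' @param nA,nB Group sizes (each at least 2).
#' @param meanA,meanB Group means.
#' @param sd Common SD (> 0).
#' @param seed Integer seed.
#' @return A list with numeric vectors `A` and `B`.
#' @export
simulate_metric_groups <- function(nA, nB, meanA = 0, meanB = 0, sd = 1,
                                   seed = NULL) {
  stopifnot(nA >= 2, nB >= 2)
  if (!is.numeric(sd) || sd <= 0) stop_srseize("'sd' must be positive")
  with_seed(seed, list(A = rnorm(nA, meanA, sd), B = rnorm(nB, meanB, sd)))
}
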