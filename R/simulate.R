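#' Configuration of the synthetic dual-pathology SEEG cohort
#'
#' Bundles every parameter of the generative model with validated defaults
#' emulating the study cohort: 16 patients grouped 5/7/4 by
#' seizure-generating lesion, about 60 hippocampal and 124 neocortical
#' contacts cohort-wide, 1-h slow-wave-sleep segments sampled at 2 kHz with
#' an 800 Hz anti-aliasing low-pass.
#'
#' The generative model: each channel's true event rate (events/min) is a
#' gamma draw (shape `rate_shape`) around its lesion-level mean, rescaled so
#' the lesion contact-mean hits the target exactly; hippocampal baselines
#' exceed neocortical ones for every event type; for fast ripples the two
#' lesion means are rescaled (preserving their sum) so each patient's true
#' contact-mean ratio R equals the group's configured asymmetry. Event
#' counts are Poisson in the segment duration. Signals are pink
#' (`1/f^alpha`) Gaussian background with Gaussian-windowed sinusoid HFO
#' bursts and biphasic sharp transients injected at known times.
#'
#' @param n_patients Cohort size.
#' @param group_counts Patients per group (1 hippocampal, 2 both,
#'   3 neocortical); must sum to `n_patients`.
#' @param hip_total,neo_total Cohort-wide contact totals per lesion; split
#'   across patients uniformly at random subject to `min_hip`/`min_neo`
#'   contacts per patient.
#' @param min_hip,min_neo Minimum contacts per patient per lesion.
#' @param segment_duration Seconds of signal per patient (default 3600).
#' @param sampling_rate Hz (default 2000; Nyquist 1000 Hz covers the
#'   250--500 Hz fast-ripple band).
#' @param lowpass_hz Acquisition low-pass cut-off (default 800).
#' @param background_spectral_exponent `alpha` of the `1/f^alpha` background
#'   (1 = pink noise).
#' @param background_sd Background standard deviation, microvolt.
#' @param event_rate_params Named list over [event_types()], each
#'   `c(hip = , neo = )` baseline rates in events/min; hippocampal must
#'   exceed neocortical.
#' @param fastripple_asymmetry_by_group Target expected fast-ripple ratio R
#'   per group, each in \[-1, 1\]. Defaults (0.6, 0.1, -0.3): strongly
#'   hippocampal when seizures are hippocampal, near zero when both lesions
#'   generate seizures, moderately neocortical when seizures are
#'   neocortical.
#' @param rate_shape Gamma shape of channel-to-channel rate dispersion.
#' @param snr Event peak amplitude as a multiple of `background_sd`.
#' @param ripple_freq_range,fastripple_freq_range Hz ranges events are drawn
#'   from; defaults sit inside the nominal 80--250 / 250--500 Hz bands far
#'   enough from the edges that at least 99% of even a 6-cycle burst's
#'   energy stays in its band (a Gaussian-windowed burst of `n` cycles has
#'   spectral width of order `f/n`, so band-edge draws are inherently
#'   ambiguous to any detector).
#' @param hfo_cycles Range of oscillation cycles per HFO burst.
#' @param ies_duration_s Range of spike transient durations, seconds.
#' @param seed Integer seed; every derived quantity is deterministic in it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 16,
                       group_counts = c(5, 7, 4),
                       hip_total = 60, neo_total = 124,
                       min_hip = 2, min_neo = 3,
                       segment_duration = 3600,
                       sampling_rate = 2000,
                       lowpass_hz = 800,
                       background_spectral_exponent = 1,
                       background_sd = 15,
                       event_rate_params = list(
                         ies         = c(hip = 4.0, neo = 1.5),
                         ripple      = c(hip = 2.0, neo = 0.8),
                         ies_ripple  = c(hip = 1.0, neo = 0.4),
                         fast_ripple = c(hip = 1.5, neo = 0.6)),
                       fastripple_asymmetry_by_group = c(0.6, 0.1, -0.3),
                       rate_shape = 2,
                       snr = 6,
                       ripple_freq_range = c(100, 220),
                       fastripple_freq_range = c(330, 430),
                       hfo_cycles = c(6, 10),
                       ies_duration_s = c(0.05, 0.1),
                       seed = 1L) {
  cfg <- list(n_patients = n_patients, group_counts = group_counts,
              hip_total = hip_total, neo_total = neo_total,
              min_hip = min_hip, min_neo = min_neo,
              segment_duration = segment_duration,
              sampling_rate = sampling_rate, lowpass_hz = lowpass_hz,
              background_spectral_exponent = background_spectral_exponent,
              background_sd = background_sd,
              event_rate_params = event_rate_params,
              fastripple_asymmetry_by_group = fastripple_asymmetry_by_group,
              rate_shape = rate_shape, snr = snr,
              ripple_freq_range = ripple_freq_range,
              fastripple_freq_range = fastripple_freq_range,
              hfo_cycles = hfo_cycles, ies_duration_s = ies_duration_s,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(group_counts) != 3 || sum(group_counts) != n_patients)
      stop("group_counts must have length 3 and sum to n_patients")
    if (any(group_counts < 0)) stop("group_counts must be non-negative")
    if (!setequal(names(event_rate_params), event_types()))
      stop("event_rate_params must name every event type")
    for (ty in event_types()) {
      r <- event_rate_params[[ty]]
      if (any(r < 0)) stop("negative baseline rate for ", ty)
      if (r[["hip"]] <= r[["neo"]])
        stop("hippocampal baseline must exceed neocortical for ", ty)
    }
    if (any(abs(fastripple_asymmetry_by_group) > 1))
      stop("asymmetries must lie in [-1, 1]")
    if (sampling_rate < 2 * max(500, fastripple_freq_range[2]))
      stop("sampling_rate must be at least twice the 500 Hz fast-ripple ",
           "band edge (and twice the highest event frequency)")
    if (hip_total < n_patients * min_hip || neo_total < n_patients * min_neo)
      stop("contact totals incompatible with per-patient minima")
    if (segment_duration <= 0) stop("segment_duration must be positive")
  })
  invisible(cfg)
}

# random composition of `total` into n parts, each >= minimum
random_composition <- function(total, n, minimum) {
  extra <- stats::rmultinom(1, total - n * minimum, rep(1 / n, n))[, 1]
  as.integer(minimum + extra)
}

#' Generate per-patient cohort specifications
#'
#' Draws the cohort layout and per-channel true rates implied by a
#' [sim_config()]: group labels in order (1...1, 2...2, 3...3), channel
#' counts per lesion summing to the configured cohort totals, SOZ flags
#' (group 1: hippocampal contacts; group 3: neocortical; group 2: both), and
#' a true rate per channel and event type. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of patient specs, each with `patient_id`, `group`,
#'   `channels` (channel_id, lesion, soz) and `true_rates` (per-channel
#'   events/min per event type, columns `rate_<type>`).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  groups <- rep.int(1:3, config$group_counts)
  n <- config$n_patients
  hip_n <- random_composition(config$hip_total, n, config$min_hip)
  neo_n <- random_composition(config$neo_total, n, config$min_neo)
  lapply(seq_len(n), function(i) {
    g <- groups[i]
    lesion <- rep(c("hippocampal", "neocortical"), c(hip_n[i], neo_n[i]))
    soz <- switch(g,
                  lesion == "hippocampal",
                  rep(TRUE, length(lesion)),
                  lesion == "neocortical")
    channels <- data.frame(
      channel_id = sprintf("P%02d_%s%02d", i,
                           ifelse(lesion == "hippocampal", "H", "N"),
                           c(seq_len(hip_n[i]), seq_len(neo_n[i]))),
      lesion = lesion, soz = soz)
    tr <- channels[, "channel_id", drop = FALSE]
    for (ty in event_types()) {
      base <- config$event_rate_params[[ty]]
      h <- base[["hip"]]; nn <- base[["neo"]]
      if (ty == "fast_ripple") {
        # rescale lesion means, preserving their sum, so the patient's true
        # contact-mean ratio equals the group's configured asymmetry
        a <- config$fastripple_asymmetry_by_group[g]
        tot <- h + nn
        h <- tot * (1 + a) / 2
        nn <- tot * (1 - a) / 2
      }
      tr[[paste0("rate_", ty)]] <-
        draw_channel_rates(lesion, h, nn, config$rate_shape)
    }
    list(patient_id = sprintf("P%02d", i), group = g,
         channels = channels, true_rates = tr)
  })
}

# gamma draws around the lesion mean, rescaled so each lesion's sample
# contact-mean equals its target exactly (the ratio R is then exact too)
draw_channel_rates <- function(lesion, hip_mean, neo_mean, shape) {
  out <- numeric(length(lesion))
  for (les in c("hippocampal", "neocortical")) {
    m <- if (les == "hippocampal") hip_mean else neo_mean
    sel <- lesion == les
    if (!any(sel)) next
    if (m == 0) { out[sel] <- 0; next }
    x <- stats::rgamma(sum(sel), shape = shape, scale = m / shape)
    if (mean(x) == 0) x <- rep(m, sum(sel)) else x <- x * m / mean(x)
    out[sel] <- x
  }
  out
}

#' Simulate an observed rate table for a whole cohort (fast tier)
#'
#' Skips signal synthesis and detection: per-channel observed event counts
#' are drawn as Poisson(true rate x duration) and divided by the duration,
#' exactly the rates an ideal detector would report. This tier lets the
#' rate, ratio, statistics and prediction stages be exercised on thousands
#' of cohorts in seconds.
#'
#' @param config A [sim_config()].
#' @return List: `rates` (cohort channel-rate table with `patient_id`,
#'   `channel_id`, `lesion`, `soz`, `rate_<type>`), `groups`
#'   (`patient_id`, `group`), `true_rates` (same shape as `rates`, the
#'   underlying truth), `duration_min`.
#' @export
simulate_rate_table <- function(config) {
  specs <- generate_cohort(config)         # seeds the RNG
  dur_min <- config$segment_duration / 60
  rows <- lapply(specs, function(sp) {
    df <- cbind(patient_id = sp$patient_id, sp$channels)
    tru <- df
    for (ty in event_types()) {
      cl <- paste0("rate_", ty)
      lam <- sp$true_rates[[cl]] * dur_min
      df[[cl]] <- stats::rpois(length(lam), lam) / dur_min
      tru[[cl]] <- sp$true_rates[[cl]]
    }
    list(obs = df, tru = tru)
  })
  list(rates = do.call(rbind, lapply(rows, `[[`, "obs")),
       groups = data.frame(
         patient_id = vapply(specs, `[[`, "", "patient_id"),
         group = vapply(specs, `[[`, 0L, "group")),
       true_rates = do.call(rbind, lapply(rows, `[[`, "tru")),
       duration_min = dur_min)
}

#' Synthesize the SEEG signal for one patient
#'
#' Background is spectrally shaped (`1/f^alpha`) Gaussian noise, low-pass
#' filtered at the configured acquisition cut-off and scaled to
#' `background_sd`. For each channel and event type, the number of injected
#' events is Poisson(true rate x duration); onsets are uniform with same-type
#' overlap forbidden (different types may overlap — an IES-ripple *is* a
#' ripple on a spike). Morphologies: spikes are biphasic raised-cosine sharp
#' transients (50--100 ms); ripples and fast ripples are Gaussian-windowed
#' sinusoids of 6--10 cycles at a frequency uniform in the band; an
#' IES-ripple sums both at the same onset. Peak amplitudes are
#' `snr x background_sd`.
#'
#' @param patient_spec One element of [generate_cohort()] output.
#' @param config The same [sim_config()].
#' @param seed Integer seed for this recording (so patients can be simulated
#'   independently); defaults to `config$seed` + the patient index.
#' @return A `seeg_recording`: `patient_id`, `signals` (channels x samples
#'   matrix, microvolt), `sampling_rate`, `channels` metadata,
#'   `ground_truth` (data frame of injected events: `channel_id`,
#'   `event_type`, `onset`, `duration`, `center_frequency`, `amplitude`).
#' @export
simulate_recording <- function(patient_spec, config, seed = NULL) {
  validate_sim_config(config)
  if (is.null(seed))
    seed <- config$seed + as.integer(sub("P", "", patient_spec$patient_id))
  set.seed(seed)
  fs <- config$sampling_rate
  nsamp <- round(config$segment_duration * fs)
  nch <- nrow(patient_spec$channels)
  sig <- matrix(0, nrow = nch, ncol = nsamp)
  gt <- list()
  for (ci in seq_len(nch)) {
    x <- pink_noise(nsamp, config$background_spectral_exponent)
    x <- lowpass_signal(x, fs, config$lowpass_hz)
    x <- x / stats::sd(x) * config$background_sd
    for (ty in event_types()) {
      rate <- patient_spec$true_rates[[paste0("rate_", ty)]][ci]
      k <- stats::rpois(1, rate * config$segment_duration / 60)
      if (k == 0) next
      ev <- place_events(k, ty, config,
                         patient_spec$channels$channel_id[ci])
      for (j in seq_len(nrow(ev))) {
        wav <- event_waveform(ev$event_type[j], ev$duration[j],
                              ev$center_frequency[j], fs,
                              config$snr * config$background_sd)
        i0 <- round(ev$onset[j] * fs) + 1
        idx <- i0:(i0 + length(wav) - 1)
        x[idx] <- x[idx] + wav
      }
      ev$channel_id <- patient_spec$channels$channel_id[ci]
      gt[[length(gt) + 1]] <- ev
    }
    sig[ci, ] <- x
  }
  gt <- if (length(gt)) do.call(rbind, gt) else
    data.frame(event_type = character(), onset = numeric(),
               duration = numeric(), center_frequency = numeric(),
               amplitude = numeric(), channel_id = character())
  gt <- gt[order(gt$channel_id, gt$onset),
           c("channel_id", "event_type", "onset", "duration",
             "center_frequency", "amplitude")]
  rownames(gt) <- NULL
  structure(list(patient_id = patient_spec$patient_id, signals = sig,
                 sampling_rate = fs, channels = patient_spec$channels,
                 ground_truth = gt),
            class = "seeg_recording")
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf("seeg_recording %s: %d channels x %.0f s @ %g Hz, %d ground-truth events\n",
              x$patient_id, nrow(x$signals),
              ncol(x$signals) / x$sampling_rate, x$sampling_rate,
              nrow(x$ground_truth)))
  invisible(x)
}

# 1/f^alpha Gaussian noise via FFT amplitude shaping
pink_noise <- function(n, alpha) {
  white <- stats::rnorm(n)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / n                  # two-sided frequency axis
  f[1] <- 1 / n                            # avoid DC blow-up
  shape <- f^(-alpha / 2)
  Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / n
}

lowpass_signal <- function(x, fs, cutoff) {
  if (cutoff >= fs / 2) return(x)
  h <- signal::fir1(128, cutoff / (fs / 2), type = "low")
  signal::filtfilt(as.numeric(h), 1, x)
}

# draw k same-type events with uniform non-overlapping onsets
place_events <- function(k, type, config, channel_id = "?") {
  dur <- numeric(k); cf <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    if (type == "ies") {
      dur[j] <- stats::runif(1, config$ies_duration_s[1],
                             config$ies_duration_s[2])
    } else {
      band <- if (type == "fast_ripple") config$fastripple_freq_range
              else config$ripple_freq_range
      cf[j] <- stats::runif(1, band[1], band[2])
      ncyc <- sample(config$hfo_cycles[1]:config$hfo_cycles[2], 1)
      dur[j] <- ncyc / cf[j]
      if (type == "ies_ripple")            # spike underneath sets the span
        dur[j] <- max(dur[j], stats::runif(1, config$ies_duration_s[1],
                                           config$ies_duration_s[2]))
    }
  }
  onset <- numeric(k)
  placed_start <- numeric(0); placed_end <- numeric(0)
  for (j in order(-dur)) {                 # longest first eases packing
    ok <- FALSE
    for (try in 1:1000) {
      o <- stats::runif(1, 0.5, config$segment_duration - dur[j] - 0.5)
      if (!any(o < placed_end & o + dur[j] > placed_start)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("cannot place non-overlapping ", type, " events on channel ",
           channel_id, ": rate too high")
    onset[j] <- o
    placed_start <- c(placed_start, o); placed_end <- c(placed_end, o + dur[j])
  }
  data.frame(event_type = type, onset = onset, duration = dur,
             center_frequency = cf,
             amplitude = config$snr * config$background_sd)
}

event_waveform <- function(type, duration, center_freq, fs, amplitude) {
  n <- max(3, round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  if (type == "ies") return(ies_waveform(n, amplitude))
  burst <- hfo_waveform(t, duration, center_freq, amplitude)
  if (type == "ies_ripple") burst <- burst + ies_waveform(n, amplitude)
  burst
}

# Gaussian-windowed sinusoid; window sd = duration/4 trades a small
# envelope truncation step (13.5% at the window edge) for a spectrum
# narrow enough that short bursts stay band-confined
hfo_waveform <- function(t, duration, freq, amplitude) {
  env <- exp(-(t - duration / 2)^2 / (2 * (duration / 4)^2))
  amplitude * env * sin(2 * pi * freq * t)
}

# biphasic sharp transient: dominant raised-cosine peak (60% of the
# duration) followed by a shallower opposite phase (40% counter-amplitude)
ies_waveform <- function(n, amplitude) {
  n1 <- max(2, round(0.6 * n)); n2 <- max(2, n - n1)
  main <- amplitude * (1 - cos(2 * pi * seq(0, 1, length.out = n1))) / 2
  counter <- -0.4 * amplitude *
    (1 - cos(2 * pi * seq(0, 1, length.out = n2))) / 2
  c(main, counter)[seq_len(n)]
}
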