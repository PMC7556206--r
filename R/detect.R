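#' Detection parameters
#'
#' Parameters of the band-energy event detectors: a classical RMS-envelope
#' threshold detector (Staba-style) for high-frequency oscillations and an
#' amplitude/width rule for interictal epileptic spikes. Every threshold is
#' exposed so users can calibrate against their own recordings.
#'
#' @param ripple_band,fastripple_band,spike_band Band edges, Hz.
#' @param envelope_window_ripple_ms,envelope_window_fastripple_ms RMS
#'   envelope windows per HFO band, milliseconds.
#' @param threshold_k Envelope threshold in robust-SD multiples above the
#'   median envelope. The default 3.75 is calibrated so that false
#'   detections on pure pink-noise background stay well below 1 event/min
#'   in every band while single bursts at 6x background SD are still
#'   detected.
#' @param min_cycles Minimum oscillation cycles per HFO event.
#' @param merge_gap_ms Events of one type closer than this are merged.
#' @param spike_amp_k Spike amplitude threshold, robust-SD multiples of the
#'   spike-band signal; default 5 is calibrated like `threshold_k`.
#' @param spike_duration_ms Admissible half-amplitude envelope widths, ms.
#'   Widths are measured on the spike-band envelope, which the 10--60 Hz
#'   band-pass narrows to roughly a third of the transient's duration; the
#'   lower default of 15 ms corresponds to transients of about 50 ms.
#' @param spike_refractory_ms Minimum separation between spike peaks; the
#'   counter-phase of one biphasic transient must not count as a second
#'   spike.
#' @param cooccurrence_window_ms Ripple/spike overlap dilation for the
#'   IES-ripple label, ms (applied to each side of the spike interval,
#'   boundary exclusive).
#' @return A validated `detection_params` list.
#' @export
detection_params <- function(ripple_band = c(80, 250),
                             fastripple_band = c(250, 500),
                             spike_band = c(10, 60),
                             envelope_window_ripple_ms = 10,
                             envelope_window_fastripple_ms = 5,
                             threshold_k = 3.75,
                             min_cycles = 4,
                             merge_gap_ms = 10,
                             spike_amp_k = 5,
                             spike_duration_ms = c(15, 200),
                             spike_refractory_ms = 150,
                             cooccurrence_window_ms = 50) {
  p <- list(ripple_band = ripple_band, fastripple_band = fastripple_band,
            spike_band = spike_band,
            envelope_window_ripple_ms = envelope_window_ripple_ms,
            envelope_window_fastripple_ms = envelope_window_fastripple_ms,
            threshold_k = threshold_k, min_cycles = min_cycles,
            merge_gap_ms = merge_gap_ms, spike_amp_k = spike_amp_k,
            spike_duration_ms = spike_duration_ms,
            spike_refractory_ms = spike_refractory_ms,
            cooccurrence_window_ms = cooccurrence_window_ms)
  for (b in list(ripple_band, fastripple_band, spike_band))
    if (b[1] >= b[2]) stop("band low edge must be below high edge")
  if (ripple_band[2] > fastripple_band[1])
    stop("ripple band must not extend above the fast-ripple band low edge")
  if (threshold_k <= 0 || spike_amp_k <= 0) stop("thresholds must be positive")
  class(p) <- "detection_params"
  p
}

empty_events <- function() {
  data.frame(channel_id = character(), event_type = character(),
             start = numeric(), end = numeric(),
             peak_envelope = numeric(), n_cycles = numeric())
}

# zero-phase FIR band-pass; tap count scales with the low edge so the
# impulse response spans a few cycles of the slowest band component
bandpass <- function(x, fs, band) {
  if (fs < 2 * band[2]) stop("band incompatible with sampling rate")
  ntaps <- min(512, max(64, round(3 * fs / band[1])))
  if (ntaps %% 2 == 1) ntaps <- ntaps + 1
  hi <- min(band[2], 0.99 * fs / 2)
  h <- signal::fir1(ntaps, c(band[1], hi) / (fs / 2), type = "pass")
  signal::filtfilt(as.numeric(h), 1, x)
}

# RMS envelope over a centred moving window
rms_envelope <- function(x, fs, window_ms) {
  w <- max(3, round(window_ms / 1000 * fs))
  if (w %% 2 == 0) w <- w + 1
  p <- stats::filter(x^2, rep(1 / w, w), sides = 2)
  p[is.na(p)] <- 0
  sqrt(pmax(as.numeric(p), 0))
}

#' Detect oscillatory events in one frequency band
#'
#' Band-passes the channel with a zero-phase (forward-backward) FIR filter,
#' computes a rectified-RMS envelope, and thresholds it at
#' `median + threshold_k x robust SD` (robust SD = 1.4826 x median absolute
#' deviation, so the baseline is insensitive to the events themselves).
#' A maximal supra-threshold interval is kept if it contains at least
#' `min_cycles` oscillation cycles, counted as pairs of rectified-signal
#' peaks above half the threshold; intervals closer than `merge_gap_ms` are
#' merged first.
#'
#' @param x Single-channel signal, microvolt.
#' @param fs Sampling rate, Hz; must be at least twice the band's high edge.
#' @param band Length-2 Hz vector.
#' @param params A [detection_params()].
#' @param envelope_window_ms RMS window; defaults to the ripple or
#'   fast-ripple setting depending on which configured band `band` matches.
#' @return Data frame of events sorted by start: `start`, `end` (seconds,
#'   half-open), `peak_envelope`, `n_cycles`.
#' @export
detect_band_events <- function(x, fs, band, params = detection_params(),
                               envelope_window_ms = NULL) {
  if (fs < 2 * band[2]) stop("band incompatible with sampling rate")
  if (length(x) < 10 * fs) stop("need >= 10 s of signal to estimate baseline")
  if (stats::sd(x) == 0)
    return(empty_events()[, c("start", "end", "peak_envelope", "n_cycles")])
  if (is.null(envelope_window_ms))
    envelope_window_ms <- if (band[1] >= params$fastripple_band[1])
      params$envelope_window_fastripple_ms else params$envelope_window_ripple_ms
  xf <- bandpass(x, fs, band)
  env <- rms_envelope(xf, fs, envelope_window_ms)
  thr <- stats::median(env) + params$threshold_k * stats::mad(env)
  above <- env > thr
  runs <- run_intervals(above)
  if (nrow(runs) == 0)
    return(empty_events()[, c("start", "end", "peak_envelope", "n_cycles")])
  runs <- merge_close(runs, gap = params$merge_gap_ms / 1000 * fs)
  half <- thr / 2
  keep <- logical(nrow(runs)); ncyc <- numeric(nrow(runs))
  peak <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    seg <- abs(xf[runs$from[i]:runs$to[i]])
    npk <- count_peaks(seg, half)
    ncyc[i] <- npk %/% 2
    peak[i] <- max(env[runs$from[i]:runs$to[i]])
    keep[i] <- ncyc[i] >= params$min_cycles
  }
  out <- data.frame(start = (runs$from[keep] - 1) / fs,
                    end = runs$to[keep] / fs,
                    peak_envelope = peak[keep], n_cycles = ncyc[keep])
  out[order(out$start), , drop = FALSE]
}

# maximal runs of TRUE as [from, to] sample indices
run_intervals <- function(flag) {
  r <- rle(flag)
  to <- cumsum(r$lengths)
  from <- to - r$lengths + 1
  data.frame(from = from[r$values], to = to[r$values])
}

merge_close <- function(runs, gap) {
  if (nrow(runs) <= 1) return(runs)
  out <- runs[1, ]
  for (i in 2:nrow(runs)) {
    if (runs$from[i] - out$to[nrow(out)] <= gap)
      out$to[nrow(out)] <- runs$to[i]
    else out <- rbind(out, runs[i, ])
  }
  out
}

# local maxima strictly above `level`
count_peaks <- function(seg, level) {
  n <- length(seg)
  if (n < 3) return(0L)
  mid <- seg[2:(n - 1)]
  sum(mid > level & mid >= seg[1:(n - 2)] & mid >= seg[3:n])
}

#' Detect interictal epileptic spikes
#'
#' Band-passes to the spike band and finds local extrema whose absolute
#' amplitude exceeds `spike_amp_k` robust SDs and whose half-amplitude width
#' lies within `spike_duration_ms`. Width and event interval are measured on
#' the RMS envelope of the band-passed signal (a sharp biphasic transient is
#' one event, not one per lobe): the interval is the half-amplitude crossing
#' pair of the envelope around the extremum. Candidates within the
#' refractory window of a larger one are suppressed.
#'
#' @inheritParams detect_band_events
#' @return Data frame of events sorted by start: `start`, `end`,
#'   `peak_envelope` (absolute band-passed peak amplitude).
#' @export
detect_spikes <- function(x, fs, params = detection_params()) {
  if (fs < 2 * params$spike_band[2]) stop("band incompatible with sampling rate")
  if (length(x) < 10 * fs) stop("need >= 10 s of signal to estimate baseline")
  if (stats::sd(x) == 0)
    return(empty_events()[, c("start", "end", "peak_envelope")])
  xf <- bandpass(x, fs, params$spike_band)
  rsd <- stats::mad(xf)
  thr <- params$spike_amp_k * rsd
  a <- abs(xf)
  env <- rms_envelope(xf, fs, 10)
  n <- length(a)
  cand <- which(a > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[a[cand] >= a[cand - 1] & a[cand] >= a[cand + 1]]
  if (!length(cand))
    return(empty_events()[, c("start", "end", "peak_envelope")])
  wmin <- params$spike_duration_ms[1] / 1000 * fs
  wmax <- params$spike_duration_ms[2] / 1000 * fs
  ev <- list()
  for (pk in cand) {
    # envelope peak in a 40 ms neighbourhood anchors the width measurement
    nb <- max(1, pk - round(0.02 * fs)):min(n, pk + round(0.02 * fs))
    pe <- nb[which.max(env[nb])]
    half <- env[pe] / 2
    lo <- pe; while (lo > 1 && env[lo - 1] > half) lo <- lo - 1
    hi <- pe; while (hi < n && env[hi + 1] > half) hi <- hi + 1
    width <- hi - lo + 1
    if (width < wmin || width > wmax) next
    ev[[length(ev) + 1]] <- c(lo, hi, pk, a[pk])
  }
  if (!length(ev))
    return(empty_events()[, c("start", "end", "peak_envelope")])
  m <- do.call(rbind, ev)
  out <- data.frame(from = m[, 1], to = m[, 2], peak = m[, 3], amp = m[, 4])
  # refractory: accept candidates largest-first, suppressing any peak
  # (e.g. the counter-phase of an accepted biphasic transient) too close
  # to an already accepted one
  out <- out[order(-out$amp), ]
  refr <- params$spike_refractory_ms / 1000 * fs
  acc <- integer(0)
  for (i in seq_len(nrow(out))) {
    if (!length(acc) || all(abs(out$peak[i] - out$peak[acc]) > refr))
      acc <- c(acc, i)
  }
  out <- out[acc, ]
  res <- data.frame(start = (out$from - 1) / fs, end = out$to / fs,
                    peak_envelope = out$amp)
  res[order(res$start), , drop = FALSE]
}

#' Label ripples that co-occur with spikes
#'
#' A ripple is an IES-ripple iff its interval overlaps a spike interval
#' dilated by the co-occurrence window on each side; the comparison is
#' strict, so a ripple starting exactly at `spike_end + window` stays
#' isolated. The partition is exhaustive and disjoint.
#'
#' @param ripples,spikes Event data frames (`start`, `end`) from one channel.
#' @param params A [detection_params()].
#' @return Logical vector along `ripples`: `TRUE` for IES-ripples.
#' @export
classify_cooccurrence <- function(ripples, spikes,
                                  params = detection_params()) {
  w <- params$cooccurrence_window_ms / 1000
  if (nrow(ripples) == 0) return(logical(0))
  if (nrow(spikes) == 0) return(rep(FALSE, nrow(ripples)))
  vapply(seq_len(nrow(ripples)), function(i)
    any(ripples$start[i] < spikes$end + w &
          ripples$end[i] > spikes$start - w),
    logical(1))
}

#' Detect all interictal event types across a recording
#'
#' Runs the spike, ripple-band and fast-ripple-band detectors on every
#' channel and labels ripples co-occurring with spikes as IES-ripples.
#' When a ripple-band and a fast-ripple-band detection overlap in time, the
#' weaker one is discarded: a burst near the 250 Hz band edge raises the
#' envelope of the neighbouring band through its spectral skirt, and the
#' band with the larger peak envelope holds the event's true frequency.
#' Event types in the output are disjoint (`ripple` means isolated ripple);
#' rate computation re-aggregates IES-ripples into the ripple count (see
#' [compute_channel_rates()]).
#'
#' @param recording A `seeg_recording` (from [simulate_recording()] or
#'   [read_recording()]).
#' @param params A [detection_params()].
#' @return Data frame: `channel_id`, `event_type`, `start`, `end`,
#'   `peak_envelope`, `n_cycles` (`NA` for spikes).
#' @export
detect_all <- function(recording, params = detection_params()) {
  fs <- recording$sampling_rate
  out <- list()
  for (ci in seq_len(nrow(recording$channels))) {
    cid <- recording$channels$channel_id[ci]
    x <- recording$signals[ci, ]
    spikes <- detect_spikes(x, fs, params)
    rip <- detect_band_events(x, fs, params$ripple_band, params)
    fr <- detect_band_events(x, fs, params$fastripple_band, params)
    arb <- arbitrate_bands(rip, fr)
    rip <- arb$a; fr <- arb$b
    isr <- classify_cooccurrence(rip, spikes, params)
    add <- function(df, type, ncyc) {
      if (nrow(df) == 0) return(NULL)
      data.frame(channel_id = cid, event_type = type,
                 start = df$start, end = df$end,
                 peak_envelope = df$peak_envelope, n_cycles = ncyc)
    }
    out[[length(out) + 1]] <- add(spikes, "ies", NA_real_)
    out[[length(out) + 1]] <- add(rip[!isr, , drop = FALSE], "ripple",
                                  rip$n_cycles[!isr])
    out[[length(out) + 1]] <- add(rip[isr, , drop = FALSE], "ies_ripple",
                                  rip$n_cycles[isr])
    out[[length(out) + 1]] <- add(fr, "fast_ripple", fr$n_cycles)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_events())
  res <- do.call(rbind, out)
  res <- res[order(res$channel_id, res$start), ]
  rownames(res) <- NULL
  res
}

# drop events in either band that overlap a stronger event in the other
arbitrate_bands <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(list(a = a, b = b))
  drop_a <- logical(nrow(a)); drop_b <- logical(nrow(b))
  for (i in seq_len(nrow(a))) {
    j <- which(b$start < a$end[i] & b$end > a$start[i])
    if (!length(j)) next
    if (max(b$peak_envelope[j]) > a$peak_envelope[i]) drop_a[i] <- TRUE
    drop_b[j[b$peak_envelope[j] < a$peak_envelope[i]]] <- TRUE
  }
  list(a = a[!drop_a, , drop = FALSE], b = b[!drop_b, , drop = FALSE])
}

#' Score detections against ground truth
#'
#' Matches detected events to injected ground-truth events by interval
#' overlap with compatible type, and reports per-type sensitivity and
#' precision. Because an injected IES-ripple physically contains a spike, a
#' detected spike may match either an `ies` or an `ies_ripple` truth event.
#'
#' @param detected Output of [detect_all()].
#' @param truth Ground-truth data frame (`channel_id`, `event_type`,
#'   `onset`, `duration`).
#' @return Data frame per event type: `n_truth`, `n_detected`, `n_matched`,
#'   `sensitivity`, `precision`.
#' @export
evaluate_detection <- function(detected, truth) {
  compat <- list(ies = c("ies", "ies_ripple"),
                 ripple = "ripple",
                 ies_ripple = "ies_ripple",
                 fast_ripple = "fast_ripple")
  truth$end_t <- truth$onset + truth$duration
  res <- lapply(event_types(), function(ty) {
    det <- detected[detected$event_type == ty, , drop = FALSE]
    tru <- truth[truth$event_type %in% compat[[ty]], , drop = FALSE]
    hit_det <- logical(nrow(det)); hit_tru <- logical(nrow(tru))
    for (i in seq_len(nrow(det))) {
      j <- which(!hit_tru & tru$channel_id == det$channel_id[i] &
                   tru$onset < det$end[i] & tru$end_t > det$start[i])
      if (length(j)) { hit_det[i] <- TRUE; hit_tru[j[1]] <- TRUE }
    }
    # sensitivity counts only truth of the type itself (an ies_ripple need
    # not be found by the spike detector for spike sensitivity)
    tru_own <- truth$event_type == ty
    n_tru <- sum(tru_own)
    matched_own <- sum(hit_tru[tru$event_type[seq_len(nrow(tru))] == ty])
    data.frame(event_type = ty, n_truth = n_tru, n_detected = nrow(det),
               n_matched = sum(hit_det),
               sensitivity = if (n_tru > 0) matched_own / n_tru else NA_real_,
               precision = if (nrow(det) > 0) mean(hit_det) else NA_real_)
  })
  do.call(rbind, res)
}
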