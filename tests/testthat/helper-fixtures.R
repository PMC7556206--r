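# shared helpers: small cohorts, independent brute-force oracles

# miniature simulation config for fast signal-tier tests
tiny_sim_config <- function(segment_duration = 60, seed = 5, ...) {
  sim_config(n_patients = 3, group_counts = c(1, 1, 1),
             hip_total = 8, neo_total = 12, min_hip = 2, min_neo = 3,
             segment_duration = segment_duration, seed = seed, ...)
}

# pink-noise background channel, as the simulator builds it
background_channel <- function(n_sec = 60, fs = 2000, sd_uv = 15) {
  ns <- asNamespace("dualhfo")
  x <- ns$pink_noise(n_sec * fs, 1)
  x <- ns$lowpass_signal(x, fs, 800)
  x / stats::sd(x) * sd_uv
}

inject <- function(x, wav, at_s, fs = 2000) {
  i0 <- round(at_s * fs) + 1
  x[i0:(i0 + length(wav) - 1)] <- x[i0:(i0 + length(wav) - 1)] + wav
  x
}

hfo_burst <- function(freq, n_cycles = 8, fs = 2000, amp = 150) {
  ns <- asNamespace("dualhfo")
  dur <- n_cycles / freq
  ns$hfo_waveform((0:round(dur * fs)) / fs, dur, freq, amp)
}

spike_wave <- function(dur_s = 0.08, fs = 2000, amp = 120) {
  asNamespace("dualhfo")$ies_waveform(round(dur_s * fs), amp)
}

# brute-force two-sided Mann-Whitney p over all rank arrangements
brute_force_mw_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  wobs <- sum(r[seq_len(na)])
  ws <- apply(utils::combn(n, na), 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(ws <= wobs + 1e-9), mean(ws >= wobs - 1e-9)))
}

# brute-force match-count distribution by enumerating distinct label
# arrangements position by position (independent of the closed form)
brute_force_match_distribution <- function(zone_counts, label_counts) {
  pattern <- rep.int(1:3, zone_counts)
  n <- sum(zone_counts)
  counts <- integer(n + 1)
  recurse <- function(remaining, pos, matches) {
    if (pos > n) {
      counts[matches + 1] <<- counts[matches + 1] + 1L
      return(invisible())
    }
    for (g in 1:3) {
      if (remaining[g] == 0) next
      remaining[g] <- remaining[g] - 1L
      recurse(remaining, pos + 1, matches + (g == pattern[pos]))
      remaining[g] <- remaining[g] + 1L
    }
  }
  recurse(as.integer(label_counts), 1L, 0L)
  counts / sum(counts)
}
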