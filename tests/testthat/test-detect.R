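fs <- 2000

test_that("a single injected burst is found in its band and only there", {
  set.seed(61)
  x <- background_channel(60)
  mid <- 30 + (8 / 150) / 2
  x2 <- inject(x, hfo_burst(150, 8), 30)
  p <- detection_params()
  rip <- detect_band_events(x2, fs, p$ripple_band, p)
  expect_equal(nrow(rip), 1)
  expect_true(rip$start <= mid && rip$end >= mid)  # interval covers injection
  expect_gte(rip$n_cycles, p$min_cycles)
  expect_equal(nrow(detect_band_events(x2, fs, p$fastripple_band, p)), 0)

  x3 <- inject(x, hfo_burst(300, 8), 30)
  expect_equal(nrow(detect_band_events(x3, fs, p$fastripple_band, p)), 1)
  expect_equal(nrow(detect_band_events(x3, fs, p$ripple_band, p)), 0)
})

test_that("degenerate signals and incompatible bands are handled", {
  p <- detection_params()
  expect_equal(nrow(detect_band_events(rep(3, 30 * fs), fs, c(80, 250), p)), 0)
  expect_equal(nrow(detect_spikes(rep(0, 30 * fs), fs, p)), 0)
  expect_error(detect_band_events(rnorm(30 * fs), 800, c(250, 500), p),
               "incompatible")
  expect_error(detect_band_events(rnorm(fs), fs, c(80, 250), p), "10 s")
})

test_that("raising the threshold never increases the event count", {
  set.seed(67)
  x <- background_channel(60)
  for (at in c(10, 20, 35, 50)) x <- inject(x, hfo_burst(200, 8, amp = 60), at)
  counts <- vapply(c(2, 3, 4, 6), function(k) {
    p <- detection_params(threshold_k = k)
    nrow(detect_band_events(x, fs, p$ripple_band, p))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detected intervals stay inside the signal and never overlap", {
  set.seed(71)
  x <- background_channel(60)
  for (at in seq(5, 55, by = 2.5)) x <- inject(x, hfo_burst(180, 8), at)
  p <- detection_params()
  ev <- detect_band_events(x, fs, p$ripple_band, p)
  expect_gt(nrow(ev), 5)
  expect_true(all(ev$start >= 0 & ev$end <= 60))
  expect_true(all(ev$start[-1] >= ev$end[-nrow(ev)]))  # sorted, disjoint
})

test_that("an injected biphasic transient yields exactly one spike", {
  set.seed(73)
  x <- inject(background_channel(60), spike_wave(0.08), 30)
  s <- detect_spikes(x, fs)
  near <- s[s$start < 30.2 & s$end > 29.9, ]
  expect_equal(nrow(near), 1)
})

test_that("spike sensitivity is at least 0.9 at five background SDs", {
  set.seed(83)
  hits <- 0; n_inj <- 20
  for (i in 1:n_inj) {
    x <- background_channel(30, sd_uv = 15)
    dur <- runif(1, 0.05, 0.1)
    x <- inject(x, spike_wave(dur, amp = 5 * 15), 15)
    s <- detect_spikes(x, fs)
    hits <- hits + any(s$start < 15 + dur & s$end > 15)
  }
  expect_gte(hits / n_inj, 0.9)
})

test_that("co-occurrence uses a dilated, boundary-exclusive overlap", {
  p <- detection_params()                   # 50 ms window
  spikes <- data.frame(start = 10, end = 10.1)
  rip <- data.frame(start = c(10.02, 12, 10.12, 10.15),
                    end = c(10.06, 12.05, 10.17, 10.2))
  lab <- classify_cooccurrence(rip, spikes, p)
  expect_true(lab[1])                       # fully inside the spike
  expect_false(lab[2])                      # 2 s away
  expect_true(lab[3])                       # inside the +50 ms dilation
  expect_false(lab[4])                      # starts exactly at end + 50 ms
  expect_length(classify_cooccurrence(rip[0, ], spikes, p), 0)
  expect_false(any(classify_cooccurrence(rip, spikes[0, ], p)))
})

test_that("detect_all labels IES-ripples and keeps types disjoint", {
  set.seed(79)
  x <- background_channel(60)
  x <- inject(x, spike_wave(0.08), 20)                   # lone spike
  x <- inject(x, hfo_burst(150, 8), 40)                  # lone ripple
  x <- inject(x, spike_wave(0.08), 50)                   # spike + ripple
  x <- inject(x, hfo_burst(180, 8), 50.01)               # riding on it
  rec <- structure(list(patient_id = "T", signals = matrix(x, nrow = 1),
                        sampling_rate = fs,
                        channels = data.frame(channel_id = "c1",
                                              lesion = "hippocampal",
                                              soz = TRUE),
                        ground_truth = data.frame()),
                   class = "seeg_recording")
  ev <- detect_all(rec)
  types_near <- function(t0) ev$event_type[ev$start < t0 + 0.3 & ev$end > t0 - 0.1]
  expect_true("ies" %in% types_near(20))
  expect_true("ripple" %in% types_near(40))
  expect_true("ies_ripple" %in% types_near(50))
  expect_false("ripple" %in% types_near(50))             # disjoint labels
})

test_that("false detections on pure pink noise stay below 1 per minute", {
  p <- detection_params()
  fp <- matrix(0, nrow = 5, ncol = 3)
  for (i in 1:5) {
    set.seed(800 + i)
    x <- background_channel(60)
    fp[i, ] <- c(nrow(detect_band_events(x, fs, p$ripple_band, p)),
                 nrow(detect_band_events(x, fs, p$fastripple_band, p)),
                 nrow(detect_spikes(x, fs, p)))
  }
  expect_true(all(colMeans(fp) < 1))
})
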