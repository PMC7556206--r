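test_that("cohort generation honours group counts, layout and determinism", {
  cfg <- sim_config(seed = 17)
  specs <- generate_cohort(cfg)
  expect_length(specs, 16)
  expect_equal(as.vector(table(vapply(specs, `[[`, 0L, "group"))), c(5, 7, 4))
  hip <- sum(vapply(specs, function(s) sum(s$channels$lesion == "hippocampal"), 0))
  neo <- sum(vapply(specs, function(s) sum(s$channels$lesion == "neocortical"), 0))
  expect_equal(hip, cfg$hip_total)   # cohort totals are exact
  expect_equal(neo, cfg$neo_total)
  expect_identical(specs, generate_cohort(cfg))  # seeded determinism
  # SOZ assignment follows the group definition
  for (s in specs) {
    soz_lesions <- unique(s$channels$lesion[s$channels$soz])
    expect_true(switch(s$group,
                       identical(soz_lesions, "hippocampal"),
                       setequal(soz_lesions, c("hippocampal", "neocortical")),
                       identical(soz_lesions, "neocortical")))
  }
})

test_that("invalid configurations are rejected with a message", {
  expect_error(sim_config(group_counts = c(5, 7, 5)), "sum")
  expect_error(sim_config(event_rate_params = list(
    ies = c(hip = -1, neo = 0.5), ripple = c(hip = 2, neo = 1),
    ies_ripple = c(hip = 1, neo = 0.4), fast_ripple = c(hip = 1.5, neo = 0.6))),
    "negative")
  expect_error(sim_config(fastripple_asymmetry_by_group = c(2, 0, 0)), "-1")
  expect_error(sim_config(sampling_rate = 900), "twice")
})

test_that("zero configured asymmetry equalizes the lesion fast-ripple means", {
  cfg <- sim_config(fastripple_asymmetry_by_group = c(0, 0, 0), seed = 23)
  specs <- generate_cohort(cfg)
  for (s in specs) {
    h <- mean(s$true_rates$rate_fast_ripple[s$channels$lesion == "hippocampal"])
    n <- mean(s$true_rates$rate_fast_ripple[s$channels$lesion == "neocortical"])
    expect_equal(h, n, tolerance = 1e-12)
  }
})

test_that("true-rate ratios equal the configured group asymmetries", {
  cfg <- sim_config(seed = 29)
  sim <- simulate_rate_table(cfg)
  tr <- patient_ratios(sim$true_rates)
  ct <- build_cohort_table(tr, sim$groups)
  for (g in 1:3)
    expect_equal(ct$r_fast_ripple[ct$true_group == g],
                 rep(cfg$fastripple_asymmetry_by_group[g], sum(ct$true_group == g)),
                 tolerance = 1e-10)
})

test_that("observed rate tables recover the configured asymmetry on average", {
  # calibration of the pipeline's central assumption: over many cohorts the
  # mean realized fast-ripple ratio per group approaches the configured one
  cfg0 <- sim_config(fastripple_asymmetry_by_group = c(0.6, 0.1, -0.3))
  means <- matrix(0, nrow = 100, ncol = 3)
  for (i in 1:100) {
    cfg <- sim_config(fastripple_asymmetry_by_group = c(0.6, 0.1, -0.3),
                      seed = 1000 + i)
    sim <- simulate_rate_table(cfg)
    ct <- build_cohort_table(patient_ratios(sim$rates), sim$groups)
    means[i, ] <- tapply(ct$r_fast_ripple, ct$true_group, mean)
  }
  expect_lt(max(abs(colMeans(means) - cfg0$fastripple_asymmetry_by_group)), 0.05)
})

test_that("injected event counts per channel are Poisson (chi-square fit)", {
  # >= 200 simulated channels at one fixed true rate; the count of events
  # actually injected into the signal must follow Poisson(rate x duration)
  cfg <- tiny_sim_config(segment_duration = 30)
  spec <- generate_cohort(cfg)[[1]]
  spec$channels <- spec$channels[1, , drop = FALSE]
  spec$true_rates <- spec$true_rates[1, , drop = FALSE]
  spec$true_rates$rate_ies <- 0; spec$true_rates$rate_ripple <- 0
  spec$true_rates$rate_ies_ripple <- 0; spec$true_rates$rate_fast_ripple <- 4
  counts <- vapply(1:200, function(i)
    nrow(simulate_recording(spec, cfg, seed = 7000 + i)$ground_truth),
    numeric(1))
  lambda <- 4 * 30 / 60                     # rate x duration = 2
  cells <- c(0, 1, 2, 3, 4)                 # 0,1,2,3,>=4 events
  obs <- c(vapply(cells[1:4], function(k) sum(counts == k), 0),
           sum(counts >= 4))
  expp <- c(dpois(0:3, lambda), 1 - ppois(3, lambda))
  chi <- suppressWarnings(chisq.test(obs, p = expp))
  expect_gt(chi$p.value, 0.01)
})

test_that("signal synthesis injects what the ground truth says", {
  cfg <- tiny_sim_config()
  spec <- generate_cohort(cfg)[[1]]
  rec <- simulate_recording(spec, cfg)
  expect_equal(ncol(rec$signals), cfg$segment_duration * cfg$sampling_rate)
  expect_equal(nrow(rec$signals), nrow(spec$channels))
  gt <- rec$ground_truth
  expect_true(all(gt$onset + gt$duration <= cfg$segment_duration))
  expect_true(all(gt$event_type %in% event_types()))
  # HFO centre frequencies inside their nominal bands
  expect_true(all(gt$center_frequency[gt$event_type == "fast_ripple"] >= 250 &
                    gt$center_frequency[gt$event_type == "fast_ripple"] <= 500))
  rip_cf <- gt$center_frequency[gt$event_type %in% c("ripple", "ies_ripple")]
  expect_true(all(rip_cf >= 80 & rip_cf <= 250))
  # no same-type overlap on a channel
  for (cid in unique(gt$channel_id)) for (ty in unique(gt$event_type)) {
    g <- gt[gt$channel_id == cid & gt$event_type == ty, ]
    if (nrow(g) < 2) next
    g <- g[order(g$onset), ]
    expect_true(all(g$onset[-1] >= (g$onset + g$duration)[-nrow(g)]))
  }
  # determinism
  rec2 <- simulate_recording(spec, cfg)
  expect_identical(rec$signals, rec2$signals)
  expect_identical(rec$ground_truth, rec2$ground_truth)
})

test_that("zero rates give pure background and an empty ground truth", {
  cfg <- tiny_sim_config()
  spec <- generate_cohort(cfg)[[1]]
  for (cl in paste0("rate_", event_types())) spec$true_rates[[cl]][] <- 0
  rec <- simulate_recording(spec, cfg)
  expect_equal(nrow(rec$ground_truth), 0)
  expect_equal(unname(round(apply(rec$signals, 1, sd))),
               rep(cfg$background_sd, nrow(spec$channels)))
})

test_that("injected event counts follow the configured Poisson mean", {
  cfg <- tiny_sim_config(segment_duration = 60)
  spec <- generate_cohort(cfg)[[1]]
  # one channel, fast ripples only, 2/min for 1 min
  spec$channels <- spec$channels[1, , drop = FALSE]
  spec$true_rates <- spec$true_rates[1, , drop = FALSE]
  spec$true_rates$rate_ies <- 0; spec$true_rates$rate_ripple <- 0
  spec$true_rates$rate_ies_ripple <- 0; spec$true_rates$rate_fast_ripple <- 2
  counts <- vapply(1:60, function(i)
    nrow(simulate_recording(spec, cfg, seed = 5000 + i)$ground_truth),
    numeric(1))
  lambda <- 2
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("injected HFO energy is confined to its band", {
  # band power of the waveform itself, within the event window
  ns <- asNamespace("dualhfo")
  fs <- 2000
  cfg <- sim_config()
  set.seed(4)
  for (i in 1:20) {
    f0 <- runif(1, cfg$ripple_freq_range[1], cfg$ripple_freq_range[2])
    nc <- sample(6:10, 1); dur <- nc / f0
    w <- ns$hfo_waveform((0:round(dur * fs)) / fs, dur, f0, 90)
    spec_w <- Mod(fft(w))^2
    freqs <- (seq_along(w) - 1) / length(w) * fs
    half <- freqs <= fs / 2
    inband <- freqs >= 80 & freqs <= 250
    expect_gt(sum(spec_w[half & inband]) / sum(spec_w[half]), 0.99)
  }
  for (i in 1:20) {
    f0 <- runif(1, cfg$fastripple_freq_range[1], cfg$fastripple_freq_range[2])
    nc <- sample(6:10, 1); dur <- nc / f0
    w <- ns$hfo_waveform((0:round(dur * fs)) / fs, dur, f0, 90)
    spec_w <- Mod(fft(w))^2
    freqs <- (seq_along(w) - 1) / length(w) * fs
    half <- freqs <= fs / 2
    inband <- freqs >= 250 & freqs <= 500
    expect_gt(sum(spec_w[half & inband]) / sum(spec_w[half]), 0.99)
  }
})

test_that("rate-table tier is reproducible and respects zero rates", {
  cfg <- sim_config(seed = 53)
  s1 <- simulate_rate_table(cfg)
  s2 <- simulate_rate_table(cfg)
  expect_identical(s1, s2)
  zero <- sim_config(seed = 53, fastripple_asymmetry_by_group = c(0, 0, 0),
                     event_rate_params = list(
                       ies = c(hip = 1e-9, neo = 0),
                       ripple = c(hip = 1e-9, neo = 0),
                       ies_ripple = c(hip = 1e-9, neo = 0),
                       fast_ripple = c(hip = 1e-9, neo = 0)))
  sz <- simulate_rate_table(zero)
  expect_true(all(as.matrix(sz$rates[, paste0("rate_", event_types())]) == 0))
})
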