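test_that("a perfect biomarker yields a perfect prediction", {
  coh <- data.frame(patient_id = sprintf("P%02d", 1:8),
                    true_group = c(1, 1, 2, 2, 2, 3, 3, 3),
                    r_fast_ripple = c(0.9, 0.8, 0.4, 0.3, 0.2, -0.1, -0.2, -0.4))
  pr <- rank_and_predict(coh)
  expect_equal(pr$n_correct, 8)
  expect_equal(pr$accuracy, 1)
  expect_false(pr$tie_warning)
  # zone-count conservation: predicted multiset equals true multiset
  expect_equal(sort(pr$ranking$predicted_group), sort(coh$true_group))
})

test_that("zones generalize to the cohort's group counts and ties warn", {
  coh <- data.frame(patient_id = c("a", "b", "c", "d"),
                    true_group = c(1, 2, 2, 3),
                    r_fast_ripple = c(0.5, 0.5, 0.1, 0))
  pr <- rank_and_predict(coh)                 # tie 0.5 straddles zones 1|2
  expect_equal(pr$zone_counts, c(1L, 2L, 1L))
  expect_true(pr$tie_warning)
  expect_equal(pr$ranking$patient_id[1], "a") # patient-id tiebreak
  expect_error(rank_and_predict(coh[coh$true_group != 3, ]), "three groups")
  coh$r_fast_ripple[2] <- NA
  expect_warning(rank_and_predict(coh), "undefined")
})

test_that("match counting is positionwise equality", {
  expect_equal(count_matches(c(1, 2, 3), c(1, 2, 3)), 3)
  expect_equal(count_matches(c(1, 1, 2), c(3, 3, 3)), 0)
  expect_equal(count_matches(c(1, 1, 2, 2, 3), c(1, 2, 2, 3, 3)), 3)
})

test_that("exact match distribution equals hand and brute-force enumeration", {
  d <- exact_match_distribution(c(1, 0, 0), c(1, 0, 0))
  expect_equal(d$prob[d$matches == 1], 1)

  d <- exact_match_distribution(c(1, 1, 0), c(1, 1, 0))
  expect_equal(d$prob[d$matches == 2], 0.5)   # (1,2) vs {(1,2),(2,1)}
  expect_equal(d$prob[d$matches == 0], 0.5)
  expect_equal(d$prob[d$matches == 1], 0)

  for (zc in list(c(2, 2, 1), c(3, 2, 2), c(2, 4, 1))) {
    d <- exact_match_distribution(zc, zc)
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    expect_equal(d$prob, brute_force_match_distribution(zc, zc),
                 tolerance = 1e-12)
    expect_equal(attr(d, "mean"), sum(zc^2) / sum(zc), tolerance = 1e-12)
  }
})

test_that("study-size null distribution has the closed-form mean", {
  d <- exact_match_distribution(c(5, 7, 4), c(5, 7, 4))
  expect_equal(attr(d, "mean"), 90 / 16, tolerance = 1e-12)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
})

test_that("permutation p is 1 when the observed match count is minimal", {
  coh <- data.frame(patient_id = c("a", "b", "c"),
                    true_group = c(2, 3, 1),
                    r_fast_ripple = c(0.9, 0.5, 0.1))
  # ranking predicts 1,2,3 but true are 2,3,1: zero matches observed
  pr <- rank_and_predict(coh)
  expect_equal(pr$n_correct, 0)
  pt <- permutation_test(coh, n_shuffles = 2000, seed = 1)
  expect_equal(pt$p_value, 1)
  expect_equal(sum(pt$null_counts), 2000)
})

test_that("Monte-Carlo null converges to the exact distribution", {
  fix <- load_fixture("table2")
  pt <- permutation_test(fix, n_shuffles = 100000, seed = 123)
  d <- exact_match_distribution(c(5, 7, 4), c(5, 7, 4))
  tv <- 0.5 * sum(abs(pt$null_counts / pt$n_shuffles - d$prob))
  expect_lt(tv, 0.01)
  # determinism given seed
  pt2 <- permutation_test(fix, n_shuffles = 5000, seed = 99)
  pt3 <- permutation_test(fix, n_shuffles = 5000, seed = 99)
  expect_identical(pt2$null_counts, pt3$null_counts)
  expect_identical(pt2$p_value, pt3$p_value)
})

test_that("fixture accuracy is invariant under every tie order", {
  fix <- load_fixture("table2")
  base <- rank_and_predict(fix)$n_correct
  expect_false(rank_and_predict(fix)$tie_warning)
  # enumerate permutations within each tied r value
  ties <- split(seq_len(nrow(fix)), fix$r_fast_ripple)
  ties <- ties[vapply(ties, length, 0L) > 1]
  swap_orders <- expand.grid(lapply(ties, function(ix) list(ix, rev(ix))))
  for (k in seq_len(nrow(swap_orders))) {
    perm <- seq_len(nrow(fix))
    for (j in seq_along(ties)) perm[ties[[j]]] <- swap_orders[k, j][[1]]
    shuffled <- fix[perm, ]
    # neutralize the patient-id tiebreak by relabelling in new order
    shuffled$patient_id <- seq_len(nrow(shuffled))
    expect_equal(rank_and_predict(shuffled)$n_correct, base)
  }
})
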