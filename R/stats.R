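#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two unpaired samples. For small samples
#' (`n_a + n_b <= exact_limit`) the p-value is exact: the null distribution of
#' the rank sum over all `choose(n_a + n_b, n_a)` assignments of the pooled
#' midranks is computed by a count-generating-function recursion (midranks are
#' doubled so tied half-ranks stay integral), which handles ties exactly.
#' Larger samples use the tie-corrected normal approximation without
#' continuity correction.
#'
#' The two-sided p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))` where `W`
#' is the rank sum of the first sample.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_limit Largest `n_a + n_b` for which the exact branch is used.
#' @return A `stat_result` list: `statistic_name` ("U"), `statistic_value`
#'   (U of sample `a`), `p_value`, `n_per_group`, `method_note`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 11, 12))$p_value  # exact: 0.1
#' @export
mann_whitney_u <- function(a, b, exact_limit = 40) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])                 # rank sum of sample a
  u <- w - na * (na + 1) / 2               # Mann-Whitney U of sample a
  if (n <= exact_limit) {
    dist <- ranksum_exact_distribution(r, na)
    ples <- sum(dist$prob[dist$w <= w + 1e-9])
    pges <- sum(dist$prob[dist$w >= w - 1e-9])
    p <- min(1, 2 * min(ples, pges))
    note <- "exact (rank-sum enumeration, ties exact)"
  } else {
    mu <- na * nb / 2
    tie <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sig2 <= 0) {                       # all values tied
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    note <- "tie-corrected normal approximation"
  }
  stat_result("U", u, p, c(n_a = na, n_b = nb), note)
}

# Exact null distribution of the rank sum of a size-na subset of midranks r.
# Doubled midranks are integers; count subsets by size and doubled sum with
# the classic two-dimensional recursion, then normalise by choose(n, na).
ranksum_exact_distribution <- function(r, na) {
  r2 <- as.integer(round(2 * r))
  n <- length(r2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(na)])
  cnt <- matrix(0, nrow = na + 1, ncol = smax + 1)  # cnt[k+1, s+1]
  cnt[1, 1] <- 1
  for (x in r2) {
    for (k in na:1) {                      # descending: each item used once
      nz <- which(cnt[k, ] > 0)
      if (length(nz)) cnt[k + 1, nz + x] <- cnt[k + 1, nz + x] + cnt[k, nz]
    }
  }
  counts <- cnt[na + 1, ]
  s <- which(counts > 0) - 1
  data.frame(w = s / 2, prob = counts[s + 1] / choose(n, na))
}

stat_result <- function(name, value, p, n_per_group, note) {
  stopifnot(p >= 0, p <= 1)
  structure(list(statistic_name = name, statistic_value = value,
                 p_value = p, n_per_group = n_per_group,
                 method_note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g (%s; n = %s)\n", x$statistic_name,
              x$statistic_value, x$p_value, x$method_note,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of average (midrank) ranks. The p-value uses the
#' t approximation with `n - 2` degrees of freedom (two-sided); for small
#' samples an exact permutation p-value over all `n!` orderings is available.
#'
#' @param x,y Numeric vectors of equal length `>= 4`; `x` is typically
#'   ordinal (e.g. a group label).
#' @param exact Use exhaustive permutation of `y` for the p-value
#'   (supported for `n <= 8`).
#' @return A `stat_result` with `statistic_name = "rho"`. Constant `x` or `y`
#'   gives `NA` rho and p 1, flagged in `method_note`.
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  if (anyNA(x) || anyNA(y)) stop("NA values not supported")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(stat_result("rho", NA_real_, 1, c(n = n),
                       "undefined: constant input"))
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact permutation p supported for n <= 8 only")
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    note <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    note <- "t approximation, df = n - 2"
  }
  stat_result("rho", rho, p, c(n = n), note)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Channelwise lesion comparison of event rates
#'
#' Pools channels across patients and compares, for each event type, rates in
#' hippocampal vs. neocortical lesion contacts with the two-sided
#' Mann-Whitney U test, optionally restricted to SOZ or non-SOZ contacts.
#' Channels are treated as independent observations.
#'
#' @param rates Cohort channel-rate table (see [compute_channel_rates()]).
#' @param subset `"all"`, `"soz_only"` or `"nonsoz_only"`.
#' @return Named list over event types of `stat_result`s.
#' @export
compare_lesion_rates <- function(rates,
                                 subset = c("all", "soz_only", "nonsoz_only")) {
  subset <- match.arg(subset)
  keep <- rep(TRUE, nrow(rates))
  if (subset == "soz_only") keep <- rates$soz
  if (subset == "nonsoz_only") keep <- !rates$soz
  sub <- rates[keep, , drop = FALSE]
  out <- lapply(event_types(), function(ty) {
    cl <- paste0("rate_", ty)
    h <- sub[[cl]][sub$lesion == "hippocampal"]
    n <- sub[[cl]][sub$lesion == "neocortical"]
    if (length(h) == 0 || length(n) == 0)
      return(stat_result("U", NA_real_, 1,
                         c(n_hip = length(h), n_neo = length(n)),
                         "undefined: empty lesion subset"))
    mann_whitney_u(h, n)
  })
  names(out) <- event_types()
  out
}

#' Correlation of the asymmetry ratio with the seizure-generating group
#'
#' Spearman correlation between the true group (1 hippocampal, 2 both,
#' 3 neocortical) and the per-patient ratio R for one event type. Patients
#' with undefined R (no events in either lesion) are excluded with a warning.
#'
#' @param cohort Cohort table from [build_cohort_table()].
#' @param event_type One of [event_types()].
#' @return A `stat_result` with rho and its p-value.
#' @export
correlate_group_with_ratio <- function(cohort, event_type = "fast_ripple") {
  event_type <- match.arg(event_type, event_types())
  rcol <- paste0("r_", event_type)
  r <- cohort[[rcol]]
  ok <- !is.na(r)
  if (!all(ok))
    warning(sum(!ok), " patient(s) with undefined R excluded from correlation")
  spearman_rho(cohort$true_group[ok], r[ok])
}
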