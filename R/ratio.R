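#' Event types analysed by the pipeline
#'
#' The four interictal event classes: epileptic spikes (`ies`), ripples
#' (80--250 Hz), ripples co-occurring with spikes (`ies_ripple`), and fast
#' ripples (250--500 Hz). Rate columns in channel-rate tables are named
#' `rate_<type>`.
#'
#' @export
event_types <- function() c("ies", "ripple", "ies_ripple", "fast_ripple")

rate_cols <- function() paste0("rate_", event_types())

#' Hippocampo-neocortical asymmetry ratio
#'
#' The lesion-asymmetry statistic
#' \deqn{R = \frac{h - n}{h + n}}{R = (h - n) / (h + n)}
#' where `h` and `n` are the mean event rates over contacts in the
#' hippocampal and neocortical lesion. `R` is close to 1 when events are
#' concentrated in the hippocampal lesion, close to -1 when concentrated in
#' the neocortical lesion, and close to 0 when rates are similar. When both
#' means are zero the ratio carries no information and `NA` is returned.
#'
#' @param h,n Non-negative mean rates (events/min); vectorised.
#' @return Numeric vector in \[-1, 1\], `NA` where `h == n == 0`.
#' @examples
#' compute_ratio(3, 1)   # 0.5
#' compute_ratio(2, 0)   # 1
#' compute_ratio(0, 0)   # NA: undefined
#' @export
compute_ratio <- function(h, n) {
  if (any(h < 0, na.rm = TRUE) || any(n < 0, na.rm = TRUE))
    stop("rates must be non-negative")
  tot <- h + n
  out <- ifelse(tot > 0, (h - n) / tot, NA_real_)
  out
}

#' Per-channel event rates
#'
#' Converts detected (or ground-truth) events into per-channel rates in
#' events/min, one row per channel in `channels` (channels with no events get
#' rate 0). Because an IES-ripple is a ripple, the `rate_ripple` column by
#' default counts all ripples (isolated + IES-ripples) with `rate_ies_ripple`
#' the co-occurring subset; set `ripple_includes_ies_ripple = FALSE` to count
#' isolated ripples only.
#'
#' @param events Data frame with columns `channel_id`, `event_type`
#'   (values from [event_types()]).
#' @param channels Data frame with columns `channel_id`, `lesion`, `soz`
#'   (and optionally `patient_id`), one row per channel.
#' @param duration_min Recording duration in minutes (default 60, one hour).
#' @param ripple_includes_ies_ripple Count IES-ripples inside `rate_ripple`?
#' @return Data frame: `channels` columns plus `rate_ies`, `rate_ripple`,
#'   `rate_ies_ripple`, `rate_fast_ripple`.
#' @export
compute_channel_rates <- function(events, channels, duration_min = 60,
                                  ripple_includes_ies_ripple = TRUE) {
  stopifnot(duration_min > 0)
  if (anyDuplicated(channels$channel_id))
    stop("duplicated channel_id in channel metadata")
  if (nrow(events) > 0) {
    unknown <- setdiff(unique(events$channel_id), channels$channel_id)
    if (length(unknown))
      stop("events on channels absent from metadata: ",
           paste(unknown, collapse = ", "))
    bad <- setdiff(unique(events$event_type), event_types())
    if (length(bad))
      stop("unknown event type: ", paste(bad, collapse = ", "))
  }
  out <- channels
  for (ty in event_types()) {
    cnt <- if (nrow(events) > 0) {
      keep <- if (ty == "ripple" && ripple_includes_ies_ripple)
        events$event_type %in% c("ripple", "ies_ripple")
      else events$event_type == ty
      tab <- table(factor(events$channel_id[keep], levels = channels$channel_id))
      as.numeric(tab)
    } else rep(0, nrow(channels))
    out[[paste0("rate_", ty)]] <- cnt / duration_min
  }
  out
}

#' Mean event rates over the contacts of one lesion
#'
#' Arithmetic mean of per-contact rates over the selected contacts
#' (equal weight per contact), optionally restricted to seizure-onset-zone
#' (SOZ) or non-SOZ contacts.
#'
#' @param rates Channel-rate table from [compute_channel_rates()].
#' @param lesion `"hippocampal"`, `"neocortical"` or `"other"`.
#' @param soz_filter `"all"`, `"soz_only"` or `"nonsoz_only"`.
#' @return List with `n_contacts` and `mean_rate`, a named vector over event
#'   types (`NA` with zero contacts, when the mean is undefined).
#' @export
lesion_mean_rates <- function(rates, lesion,
                              soz_filter = c("all", "soz_only", "nonsoz_only")) {
  soz_filter <- match.arg(soz_filter)
  keep <- rates$lesion == lesion
  if (soz_filter == "soz_only") keep <- keep & rates$soz
  if (soz_filter == "nonsoz_only") keep <- keep & !rates$soz
  sub <- rates[keep, , drop = FALSE]
  mr <- vapply(rate_cols(), function(cl)
    if (nrow(sub) == 0) NA_real_ else mean(sub[[cl]]), numeric(1))
  names(mr) <- event_types()
  list(n_contacts = nrow(sub), mean_rate = mr)
}

#' Per-patient asymmetry ratios for every event type
#'
#' For each patient, computes the ratio R of mean rates
#' (hippocampus - neocortex) / (hippocampus + neocortex) for each event type,
#' using all contacts located in either lesion (the ratio is computed with no
#' reference to seizure information). Lesion means are contact means by
#' default; `pooled = TRUE` instead pools event counts over the lesion's
#' contacts (total events / total contact-minutes).
#'
#' @param rates Channel-rate table with a `patient_id` column.
#' @param pooled Pool counts rather than average per-contact rates.
#' @return Data frame: `patient_id`, `r_ies`, `r_ripple`, `r_ies_ripple`,
#'   `r_fast_ripple` (`NA` where both lesion means are zero).
#' @export
patient_ratios <- function(rates, pooled = FALSE) {
  stopifnot("patient_id" %in% names(rates))
  pids <- unique(rates$patient_id)
  res <- lapply(pids, function(pid) {
    pr <- rates[rates$patient_id == pid, , drop = FALSE]
    row <- list(patient_id = pid)
    for (ty in event_types()) {
      cl <- paste0("rate_", ty)
      hsel <- pr$lesion == "hippocampal"
      nsel <- pr$lesion == "neocortical"
      if (!any(hsel) || !any(nsel))
        stop("patient ", pid, " lacks contacts in one lesion")
      h <- if (pooled) sum(pr[[cl]][hsel]) / sum(hsel) else mean(pr[[cl]][hsel])
      n <- if (pooled) sum(pr[[cl]][nsel]) / sum(nsel) else mean(pr[[cl]][nsel])
      row[[paste0("r_", ty)]] <- compute_ratio(h, n)
    }
    as.data.frame(row)
  })
  do.call(rbind, res)
}

#' Assemble the per-patient cohort table
#'
#' Joins per-patient ratios with the true seizure-generating-lesion group
#' (1 = hippocampal, 2 = both, 3 = neocortical); the analogue of the clinical
#' per-patient summary consumed by prediction and the permutation test.
#'
#' @param ratios Output of [patient_ratios()].
#' @param groups Data frame `patient_id`, `group` with groups in \{1,2,3\}.
#' @return Data frame: `patient_id`, `true_group`, `r_ies`, `r_ripple`,
#'   `r_ies_ripple`, `r_fast_ripple`.
#' @export
build_cohort_table <- function(ratios, groups) {
  stopifnot(all(c("patient_id", "group") %in% names(groups)))
  if (!all(groups$group %in% 1:3)) stop("groups must be in {1, 2, 3}")
  if (anyDuplicated(groups$patient_id)) stop("duplicated patient_id")
  m <- merge(ratios, groups, by = "patient_id")
  if (nrow(m) != nrow(ratios)) stop("group label missing for some patients")
  data.frame(patient_id = m$patient_id, true_group = m$group,
             m[, paste0("r_", event_types())])
}
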