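#' Write a multichannel recording to an EDF file
#'
#' Minimal standard EDF (16-bit) writer: one data record per second,
#' per-channel physical scaling chosen symmetrically around zero from the
#' data range. Signal length is truncated to whole seconds (EDF stores an
#' integer number of records).
#'
#' @param signals Channels x samples numeric matrix, microvolt.
#' @param fs Sampling rate, Hz (integer; samples per 1-s record).
#' @param labels Channel labels (unique, at most 16 ASCII characters).
#' @param path Output file path.
#' @param patient_id Free-text patient field.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, labels, path, patient_id = "X") {
  stopifnot(is.matrix(signals), nrow(signals) == length(labels))
  fs <- as.integer(round(fs))
  ns <- nrow(signals)
  n_rec <- ncol(signals) %/% fs
  if (n_rec < 1) stop("signal shorter than one 1-s data record")
  signals <- signals[, seq_len(n_rec * fs), drop = FALSE]

  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    formatC(x, width = -w)                 # left-justified, space-padded
  }
  num8 <- function(x) pad(formatC(x, format = "g", digits = 7), 8)

  pmaxv <- apply(abs(signals), 1, max)
  pmaxv[pmaxv == 0] <- 1
  pmaxv <- signif(pmaxv * 1.0001, 6)       # headroom against rounding
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(paste0(s, collapse = ""), con, eos = NULL)
  wr(pad("0", 8))
  wr(pad(patient_id, 80))
  wr(pad("dualhfo synthetic SEEG", 80))
  wr(pad("01.01.20", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 * (1 + ns), 8))
  wr(pad("", 44))
  wr(pad(n_rec, 8))
  wr(pad(1, 8))                            # record duration, s
  wr(pad(ns, 4))
  wr(pad(labels, 16))
  wr(pad(rep("", ns), 80))                 # transducer
  wr(pad(rep("uV", ns), 8))
  wr(num8(-pmaxv)); wr(num8(pmaxv))
  wr(pad(rep(dmin, ns), 8)); wr(pad(rep(dmax, ns), 8))
  wr(pad(rep("LP:800Hz", ns), 80))
  wr(pad(rep(fs, ns), 8))
  wr(pad(rep("", ns), 32))

  gain <- (2 * pmaxv) / (dmax - dmin)
  for (rec in seq_len(n_rec)) {
    cols <- ((rec - 1) * fs + 1):(rec * fs)
    for (ch in seq_len(ns)) {
      dig <- round((signals[ch, cols] + pmaxv[ch]) / gain[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads standard 16-bit EDF written by [write_edf()] or any EDF whose
#' channels share one sampling rate.
#'
#' @param path EDF file path.
#' @return List: `signals` (channels x samples matrix, physical units),
#'   `sampling_rate`, `labels`, `patient_id`, `n_records`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("unsupported EDF variant (version field '",
                           version, "')")
  patient_id <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  replicate(ns, rd(80))                    # transducer
  replicate(ns, rd(8))                     # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  replicate(ns, rd(80))                    # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  replicate(ns, rd(32))
  if (length(unique(spr)) != 1)
    stop("unsupported EDF variant: per-channel sampling rates differ")
  fs <- spr[1] / rec_dur
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  gain <- (pmax - pmin) / (dmax - dmin)
  for (rec in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      cols <- ((rec - 1) * spr[ch] + 1):(rec * spr[ch])
      sig[ch, cols] <- (dig - dmin[ch]) * gain[ch] + pmin[ch]
    }
  }
  list(signals = sig, sampling_rate = fs, labels = labels,
       patient_id = patient_id, n_records = n_rec)
}

#' Write a simulated recording to disk
#'
#' Writes the signal as EDF plus two plain-text sidecars: a channel metadata
#' TSV (`channel_id`, `lesion`, `soz`) and a ground-truth events CSV
#' (`patient_id`, `channel_id`, `event_type`, `onset_s`, `duration_s`,
#' `center_freq_hz`, `amplitude_uv`).
#'
#' @param recording A `seeg_recording`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pid <- recording$patient_id
  edf <- file.path(dir, paste0(pid, ".edf"))
  tsv <- file.path(dir, paste0(pid, "_channels.tsv"))
  csv <- file.path(dir, paste0(pid, "_events.csv"))
  write_edf(recording$signals, recording$sampling_rate,
            recording$channels$channel_id, edf, patient_id = pid)
  utils::write.table(recording$channels, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  gt <- recording$ground_truth
  utils::write.csv(data.frame(patient_id = pid, channel_id = gt$channel_id,
                              event_type = gt$event_type, onset_s = gt$onset,
                              duration_s = gt$duration,
                              center_freq_hz = gt$center_frequency,
                              amplitude_uv = gt$amplitude),
                   csv, row.names = FALSE)
  invisible(c(edf = edf, channels = tsv, events = csv))
}

#' Read a recording from EDF plus channel metadata TSV
#'
#' @param edf_path EDF file.
#' @param channels_tsv TSV with columns `channel_id`, `lesion`, `soz`; every
#'   EDF channel must have a row.
#' @return A `seeg_recording` (empty `ground_truth`).
#' @export
read_recording <- function(edf_path, channels_tsv) {
  e <- read_edf(edf_path)
  meta <- utils::read.delim(channels_tsv, stringsAsFactors = FALSE)
  need <- c("channel_id", "lesion", "soz")
  if (!all(need %in% names(meta)))
    stop("channels TSV must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(e$labels, meta$channel_id)
  if (length(missing))
    stop("channels TSV missing rows for EDF channel(s): ",
         paste(missing, collapse = ", "))
  meta <- meta[match(e$labels, meta$channel_id), , drop = FALSE]
  rownames(meta) <- NULL
  meta$soz <- as.logical(meta$soz)
  structure(list(patient_id = e$patient_id, signals = e$signals,
                 sampling_rate = e$sampling_rate, channels = meta,
                 ground_truth = data.frame()),
            class = "seeg_recording")
}

#' Load a packaged clinical fixture table
#'
#' Transcriptions of the study's printed per-patient tables:
#' `"table1"` — clinical metadata (patient_id, hemisphere, lesion
#' pathologies, surgery, 12-month outcome, seizure-generating group);
#' `"table2"` — per-patient fast-ripple ratio analysis (`r_fast_ripple`,
#' `true_group`, printed `predicted_group` and `correct`), 16 rows with
#' group counts 5/7/4.
#'
#' @param name `"table1"` or `"table2"`.
#' @return Data frame.
#' @export
load_fixture <- function(name = c("table2", "table1")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, ".tsv"), package = "dualhfo",
                   mustWork = TRUE)
  df <- utils::read.delim(f, stringsAsFactors = FALSE)
  if (name == "table2") {
    stopifnot(nrow(df) == 16)
    df$correct <- df$correct == "Yes"
  }
  df
}
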