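#' Construct an SEEG recording object
#'
#' A recording holds a contacts-by-samples signal matrix in microvolts,
#' together with its sampling rate, channel names and montage state.
#'
#' @param signal numeric matrix, one row per channel, microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_names character vector of unique channel labels.
#' @param montage `"referential"` or `"bipolar"`.
#' @return An object of class `seeg_recording`.
#' @export
seeg_recording <- function(signal, sampling_rate, channel_names,
                           montage = c("referential", "bipolar")) {
  montage <- match.arg(montage)
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1L)
  if (length(channel_names) != nrow(signal))
    stop("channel_names must have one entry per signal row")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  structure(
    list(signal = signal, sampling_rate = sampling_rate,
         channel_names = as.character(channel_names), montage = montage),
    class = "seeg_recording")
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf("SEEG recording: %d channel(s) x %d samples (%.1f s at %g Hz), %s montage\n",
              nrow(x$signal), ncol(x$signal),
              ncol(x$signal) / x$sampling_rate, x$sampling_rate, x$montage))
  invisible(x)
}

# fixed-width ASCII field, right-padded
.edf_field <- function(x, width) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  s <- substr(s, 1L, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer: 16-bit samples, one-second data
#' records, identical sampling rate on every channel. Physical scaling is
#' chosen per channel from the signal range, so the round trip is exact up to
#' 16-bit quantization.
#'
#' @param recording a [seeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "seeg_recording"))
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  n_samp <- ncol(recording$signal)
  if (n_samp %% fs != 0)
    stop("write_edf requires a whole number of seconds of signal")
  n_rec <- n_samp / fs
  ns <- nrow(recording$signal)

  # round the physical range up at the printed precision so no sample clips
  phys_max <- ceiling(apply(abs(recording$signal), 1L, max) * 10) / 10
  phys_max <- ifelse(phys_max <= 0, 1, phys_max)
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8L),
    .edf_field("synthetic", 80L),
    .edf_field("sozloc", 80L),
    .edf_field("01.01.00", 8L),
    .edf_field("00.00.00", 8L),
    .edf_field(256L * (1L + ns), 8L),
    .edf_field("", 44L),
    .edf_field(n_rec, 8L),
    .edf_field(1L, 8L),
    .edf_field(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- paste0(
    paste(vapply(recording$channel_names, .edf_field, "", width = 16L), collapse = ""),
    paste(rep(.edf_field("", 80L), ns), collapse = ""),
    paste(rep(.edf_field("uV", 8L), ns), collapse = ""),
    paste(vapply(sprintf("%.1f", -phys_max), .edf_field, "", width = 8L), collapse = ""),
    paste(vapply(sprintf("%.1f", phys_max), .edf_field, "", width = 8L), collapse = ""),
    paste(rep(.edf_field(-dig_max, 8L), ns), collapse = ""),
    paste(rep(.edf_field(dig_max, 8L), ns), collapse = ""),
    paste(rep(.edf_field("", 80L), ns), collapse = ""),
    paste(rep(.edf_field(fs, 8L), ns), collapse = ""),
    paste(rep(.edf_field("", 32L), ns), collapse = ""))
  writeChar(sig_hdr, con, eos = NULL)

  # physical range is re-parsed from its printed form so write/read scaling agree
  pm <- as.numeric(sprintf("%.1f", phys_max))
  scale <- dig_max / pm
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round(recording$signal[ch, idx] * scale[ch]))
      dig <- pmin(pmax(dig, -dig_max), dig_max)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports the subset written by [write_edf()] and standard single-rate EDF:
#' all channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @return A [seeg_recording()] in referential montage, microvolts.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("malformed EDF header: file too short")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8L)                       # version
  rd(80L); rd(80L); rd(8L); rd(8L)
  hdr_bytes <- suppressWarnings(as.integer(rd(8L)))
  rd(44L)
  n_rec <- suppressWarnings(as.integer(rd(8L)))
  rec_dur <- suppressWarnings(as.numeric(rd(8L)))
  ns <- suppressWarnings(as.integer(rd(4L)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns)) || ns < 1L)
    stop("malformed EDF header")
  if (sz < hdr_bytes) stop("malformed EDF header: truncated signal headers")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16L), ""))
  for (i in seq_len(ns)) rd(80L)                      # transducer
  for (i in seq_len(ns)) rd(8L)                       # phys dim
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  for (i in seq_len(ns)) rd(80L)                      # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), ""))
  for (i in seq_len(ns)) rd(32L)
  if (anyNA(spr)) stop("malformed EDF header: samples per record")
  if (length(unique(spr)) != 1L)
    stop("unsupported EDF: mixed sampling rates across channels")
  fs <- spr[1L] / rec_dur

  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2L,
                     signed = TRUE, endian = "little")
      if (length(dig) < spr[ch]) stop("malformed EDF: truncated data record")
      gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      idx <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      sig[ch, idx] <- phys_min[ch] + (dig - dig_min[ch]) * gain
    }
  }
  seeg_recording(sig, fs, labels, "referential")
}

#' Infer electrode shafts from channel names
#'
#' Depth-electrode contacts are conventionally labelled with a shaft prefix
#' and a 1-based along-shaft number (`A1..A12`, `TP'3`). Returns a grouping
#' usable by [to_bipolar()]; channels that do not match the convention each
#' form a singleton shaft (with a warning).
#'
#' @param channel_names character vector of contact labels.
#' @return A data frame with columns `channel`, `shaft`, `order`.
#' @export
infer_shafts <- function(channel_names) {
  m <- regmatches(channel_names,
                  regexec("^([A-Za-z']+)([0-9]+)$", channel_names))
  shaft <- vapply(m, function(g) if (length(g) == 3L) g[2L] else NA_character_, "")
  num <- vapply(m, function(g) if (length(g) == 3L) as.integer(g[3L]) else NA_integer_, 1L)
  bad <- is.na(shaft)
  if (any(bad)) {
    warning("channels not matching the <shaft><number> convention form singleton shafts: ",
            paste(channel_names[bad], collapse = ", "))
    shaft[bad] <- channel_names[bad]
    num[bad] <- 1L
  }
  data.frame(channel = channel_names, shaft = shaft, order = num,
             stringsAsFactors = FALSE)
}

#' Convert a referential recording to adjacent bipolar montage
#'
#' Each output channel is the difference of two contacts that are adjacent on
#' the same electrode shaft (`A1-A2 = A1 - A2`). Contacts are never mixed
#' across shafts; a shaft with a single contact contributes no channel.
#'
#' @param recording a referential [seeg_recording()].
#' @param shaft_grouping optional data frame as returned by [infer_shafts()];
#'   inferred from the channel names when omitted.
#' @return A bipolar [seeg_recording()].
#' @export
to_bipolar <- function(recording, shaft_grouping = NULL) {
  stopifnot(inherits(recording, "seeg_recording"))
  if (recording$montage != "referential")
    stop("to_bipolar expects a referential recording")
  if (is.null(shaft_grouping)) shaft_grouping <- infer_shafts(recording$channel_names)
  stopifnot(all(c("channel", "shaft", "order") %in% names(shaft_grouping)))

  out_sig <- list(); out_names <- character(0)
  for (sh in unique(shaft_grouping$shaft)) {
    g <- shaft_grouping[shaft_grouping$shaft == sh, , drop = FALSE]
    g <- g[order(g$order), , drop = FALSE]
    if (nrow(g) < 2L) {
      warning("shaft '", sh, "' has a single contact and contributes no bipolar channel")
      next
    }
    for (k in seq_len(nrow(g) - 1L)) {
      i1 <- match(g$channel[k], recording$channel_names)
      i2 <- match(g$channel[k + 1L], recording$channel_names)
      out_sig[[length(out_sig) + 1L]] <-
        recording$signal[i1, ] - recording$signal[i2, ]
      out_names <- c(out_names, paste0(g$channel[k], "-", g$channel[k + 1L]))
    }
  }
  if (length(out_sig) == 0L) stop("no bipolar channels could be formed")
  seeg_recording(do.call(rbind, out_sig), recording$sampling_rate,
                 out_names, "bipolar")
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(what, " is missing required column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}

#' Read a contact metadata table
#'
#' Tab-separated table with columns `contact`, `patient_id`, `region`, `x`,
#' `y`, `z` and optionally `soz_label`.
#'
#' @param path TSV file path.
#' @return A data frame.
#' @export
read_contact_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("contact", "patient_id", "region", "x", "y", "z"),
                   "contact table")
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("contact table has non-finite coordinates")
  df
}

#' @rdname read_contact_table
#' @param contacts data frame of contact metadata.
#' @export
write_contact_table <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read biomarker event annotations
#'
#' Events are stored as a TSV with columns `contact`, `kind`, `onset_s`,
#' `duration_s`, `frequency_hz`. Reading returns events sorted by onset.
#'
#' @param events data frame of events.
#' @param path TSV file path.
#' @export
write_events <- function(events, path) {
  .require_columns(events,
                   c("contact", "kind", "onset_s", "duration_s", "frequency_hz"),
                   "event table")
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("contact", "kind", "onset_s", "duration_s", "frequency_hz"),
                   "event table")
  df[order(df$onset_s), , drop = FALSE]
}
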