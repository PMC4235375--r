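## Import of externally recorded data: EEG from EDF (European Data Format,
## parsed directly - the fixed-layout 16-bit format), fNIRS from a documented
## wide CSV layout (one row per sample, two columns per channel), and the
## event schedule from CSV (onset_s, duration_s, label, block[, segment]).

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read an EDF (European Data Format) recording
#'
#' Minimal reader for uncompressed EDF: parses the fixed 256-byte header and
#' the per-signal headers, reads the 16-bit little-endian data records and
#' applies the physical calibration.
#'
#' @param path EDF file path.
#' @return list with `labels`, `fs` (Hz per signal) and `signals` (list of
#'   numeric vectors in physical units).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8)
  if (!identical(version, "0")) stop_param("not an EDF file (version '", version, "')")
  invisible(readBin(con, "raw", 80 + 80 + 8 + 8))  # patient/recording/date/time
  invisible(read_ascii(con, 8))                    # header bytes
  invisible(readBin(con, "raw", 44))               # reserved
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop_param("corrupt EDF header")
  fld <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), character(1))
  labels <- fld(16)
  invisible(fld(80))                               # transducer
  invisible(fld(8))                                # dimension
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8));  dig_max <- as.numeric(fld(8))
  invisible(fld(80))                               # prefilter
  spr <- as.integer(fld(8))                        # samples per record
  invisible(fld(32))                               # reserved
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  signals <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      if (length(raw) < spr[i]) stop_param("truncated EDF data record")
      signals[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        phys_min[i] + gain[i] * (raw - dig_min[i])
    }
  }
  list(labels = labels, fs = spr / rec_dur, signals = signals)
}

resample_linear <- function(x, t_in, fs_out, t_end) {
  t_out <- seq(0, t_end - 1 / fs_out, by = 1 / fs_out)
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

#' Read a schedule CSV
#'
#' Expected columns: `onset_s, duration_s, label, block[, segment]`.
#' Overlapping or unordered events fail validation.
#'
#' @param path CSV path.
#' @return a [event_schedule()].
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "label", "block")
  if (!all(need %in% names(df)))
    stop_param("schedule CSV must have columns ", paste(need, collapse = ", "))
  event_schedule(df$onset_s, df$duration_s, df$label, df$block,
                 segment = df$segment %||% rep("trial", nrow(df)))
}

#' Import an externally recorded session
#'
#' fNIRS comes from a wide CSV with a `time_s` column and two columns per
#' montage channel (`<channel>_wl1`, `<channel>_wl2`); EEG from EDF with
#' signal labels matching the montage electrodes; events from a schedule CSV.
#' Signals are linearly resampled to the internal rates (19.5 Hz / 256 Hz).
#' Extra fNIRS columns and EDF signals are dropped with a warning; missing
#' electrodes or channels are an error naming the absences.
#'
#' @param fnirs_path,eeg_path,schedule_path input files.
#' @param montage target [make_montage()].
#' @return a `bci_session`.
#' @export
import_external <- function(fnirs_path, eeg_path, schedule_path,
                            montage = make_montage()) {
  schedule <- read_schedule_csv(schedule_path)
  span <- max(schedule$onset_s + schedule$duration_s)

  ## fNIRS CSV
  df <- utils::read.csv(fnirs_path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop_param("fNIRS CSV needs a time_s column")
  want <- c(paste0(montage$channel_names, "_wl1"),
            paste0(montage$channel_names, "_wl2"))
  missing <- setdiff(want, names(df))
  if (length(missing) > 0)
    stop_param("fNIRS CSV lacks channel column(s): ",
               paste(utils::head(missing, 8), collapse = ", "))
  extra <- setdiff(names(df), c("time_s", want))
  if (length(extra) > 0)
    warning(length(extra), " unmapped fNIRS column(s) dropped")
  t_end <- max(df$time_s)
  if (t_end < span) stop_param("fNIRS record shorter than the schedule span")
  fnirs <- lapply(1:2, function(w) {
    cols <- paste0(montage$channel_names, "_wl", w)
    t(vapply(cols, function(cn)
      resample_linear(df[[cn]], df$time_s, FS_FNIRS, t_end),
      numeric(length(seq(0, t_end - 1 / FS_FNIRS, by = 1 / FS_FNIRS)))))
  })
  names(fnirs) <- c("wl1", "wl2")

  ## EEG EDF
  edf <- read_edf(eeg_path)
  idx <- match(montage$electrodes, edf$labels)
  if (anyNA(idx))
    stop_param("EDF lacks required electrode(s): ",
               paste(montage$electrodes[is.na(idx)], collapse = ", "))
  if (length(edf$labels) > length(montage$electrodes))
    warning(length(edf$labels) - length(montage$electrodes),
            " unmapped EDF signal(s) dropped")
  eeg <- t(vapply(idx, function(i) {
    x <- edf$signals[[i]]
    t_in <- (seq_along(x) - 1) / edf$fs[i]
    tl <- min(max(t_in), t_end)
    resample_linear(x, t_in, FS_EEG, tl)
  }, numeric(length(seq(0, min((length(edf$signals[[idx[1]]]) - 1) / edf$fs[idx[1]],
                               t_end) - 1 / FS_EEG, by = 1 / FS_EEG)))))

  new_session(subject = basename(eeg_path), fnirs_ac = fnirs, eeg = eeg,
              schedule = schedule, montage = montage,
              provenance = list(source = list(fnirs = fnirs_path,
                                              eeg = eeg_path,
                                              schedule = schedule_path)))
}
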