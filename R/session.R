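## A Session is one subject's synchronized multimodal recording: two-wavelength
## fNIRS AC intensities at 19.5 Hz, EEG voltages at 256 Hz, the event
## schedule, the montage, and provenance. Preprocessing stages attach derived
## signal blocks (haemoglobin concentrations at 1 Hz, cleaned EEG).

FS_FNIRS <- 19.5
FS_EEG <- 256
SESSION_SCHEMA_VERSION <- 1L

#' Construct a Session
#'
#' @param subject subject identifier.
#' @param fnirs_ac list with one `channels x samples` matrix per wavelength
#'   (names `"wl1"`, `"wl2"`), AC intensities at 19.5 Hz.
#' @param eeg `electrodes x samples` matrix (uV) at 256 Hz, rownames set to
#'   electrode names.
#' @param schedule a [event_schedule()].
#' @param montage a [make_montage()].
#' @param provenance list (seed, generator etc.).
#' @return object of class `bci_session`.
#' @export
new_session <- function(subject, fnirs_ac, eeg, schedule, montage,
                        provenance = list()) {
  stopifnot(inherits(schedule, "bci_schedule"), inherits(montage, "bci_montage"))
  stopifnot(is.list(fnirs_ac), length(fnirs_ac) == 2L)
  if (nrow(fnirs_ac[[1]]) != montage$n_channels)
    stop_param("fNIRS rows must match the montage channel count")
  if (!identical(dim(fnirs_ac[[1]]), dim(fnirs_ac[[2]])))
    stop_param("both wavelength blocks must have identical shape")
  if (nrow(eeg) != length(montage$electrodes))
    stop_param("EEG rows must match the montage electrode count")
  span <- if (nrow(schedule) > 0) max(schedule$onset_s + schedule$duration_s) else 0
  if (ncol(fnirs_ac[[1]]) / FS_FNIRS < span - 1e-9 ||
      ncol(eeg) / FS_EEG < span - 1e-9)
    stop_param("signals do not cover the schedule's full time span")
  if (anyNA(fnirs_ac[[1]]) || anyNA(fnirs_ac[[2]]) || anyNA(eeg))
    stop_param("missing samples in signal blocks")
  rownames(eeg) <- montage$electrodes
  structure(list(subject = subject,
                 fnirs_ac = fnirs_ac,
                 fs_fnirs = FS_FNIRS,
                 eeg = eeg,
                 fs_eeg = FS_EEG,
                 schedule = schedule,
                 montage = montage,
                 provenance = provenance,
                 schema_version = SESSION_SCHEMA_VERSION),
            class = "bci_session")
}

#' @export
print.bci_session <- function(x, ...) {
  cat("Hybrid fNIRS/EEG session - subject", x$subject, "\n")
  cat(sprintf("  fNIRS: %d channels x 2 wavelengths, %.1f s at %.1f Hz\n",
              nrow(x$fnirs_ac[[1]]), ncol(x$fnirs_ac[[1]]) / x$fs_fnirs,
              x$fs_fnirs))
  cat(sprintf("  EEG:   %d electrodes, %.1f s at %d Hz\n",
              nrow(x$eeg), ncol(x$eeg) / x$fs_eeg, x$fs_eeg))
  print(x$schedule)
  if (!is.null(x$hb)) cat("  + haemoglobin block (1 Hz)\n")
  if (!is.null(x$eeg_clean)) cat("  + cleaned EEG block\n")
  invisible(x)
}

#' Save / load a Session
#'
#' Sessions are stored with R serialization plus an explicit schema version;
#' the round trip is bit-exact for all arrays and metadata.
#'
#' @param session a `bci_session`.
#' @param path file path.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "bci_session"))
  saveRDS(session, path)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop_param("session format error: ",
                                                 conditionMessage(e)))
  if (!inherits(obj, "bci_session"))
    stop_param("session format error: not a session container")
  if (!identical(obj$schema_version, SESSION_SCHEMA_VERSION))
    stop_param("unknown session schema version: ",
               format(obj$schema_version))
  obj
}
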