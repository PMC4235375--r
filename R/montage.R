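## Montage: the fixed sensor geometry of the recording setup. Three fNIRS
## probes (one occipital over the visual cortex, one over each temporal lobe)
## with multi-distance overlapping channels, plus ten analysis EEG electrodes
## after mastoid referencing.

#' Default EEG analysis electrodes (after M1/M2 referencing)
#' @export
EEG_ELECTRODES <- c("Fz", "Cz", "Pz", "Oz", "O1", "O2",
                    "FT7", "FT8", "TP7", "TP8")

#' Construct an fNIRS/EEG montage specification
#'
#' The default montage has 60 channels on the occipital probe and 55 on each
#' temporal probe (170 in total), two wavelengths (690 and 830 nm), and
#' source-detector separations in the 1.7-2.5 cm multi-distance range.
#' Channel geometry is configured by per-probe counts and distances only; the
#' exact optode grid enumeration is not part of the model.
#'
#' @param n_occipital,n_left_temporal,n_right_temporal channels per probe.
#' @param wavelengths two near-infrared wavelengths in nm.
#' @param distances optional numeric vector of per-channel source-detector
#'   distances (cm). Defaults to an even spread over 1.7-2.5 cm per probe.
#' @param electrodes EEG electrode names.
#' @return an object of class `bci_montage`.
#' @export
make_montage <- function(n_occipital = 60L, n_left_temporal = 55L,
                         n_right_temporal = 55L,
                         wavelengths = c(690, 830),
                         distances = NULL,
                         electrodes = EEG_ELECTRODES) {
  counts <- c(occipital = as.integer(n_occipital),
              left_temporal = as.integer(n_left_temporal),
              right_temporal = as.integer(n_right_temporal))
  if (any(counts < 1L)) stop_param("each probe needs at least one channel")
  if (length(wavelengths) != 2L || any(wavelengths <= 0))
    stop_param("exactly two positive wavelengths required")
  probe <- rep(names(counts), counts)
  n_c <- sum(counts)
  if (is.null(distances)) {
    distances <- unlist(lapply(counts, function(k) {
      if (k == 1L) 2.1 else seq(1.7, 2.5, length.out = k)
    }), use.names = FALSE)
  }
  if (length(distances) != n_c)
    stop_param("need one source-detector distance per channel")
  if (any(distances < 1.7 - 1e-9 | distances > 2.5 + 1e-9))
    stop_param("source-detector distances must lie within [1.7, 2.5] cm")
  structure(list(
    probes = names(counts),
    probe_channels = counts,
    n_channels = n_c,
    channel_probe = probe,
    channel_names = paste0("ch", seq_len(n_c)),
    distance_cm = distances,
    wavelengths_nm = sort(wavelengths),
    electrodes = electrodes
  ), class = "bci_montage")
}

#' @export
print.bci_montage <- function(x, ...) {
  cat("fNIRS/EEG montage\n")
  cat("  fNIRS channels:", x$n_channels,
      sprintf("(%s)", paste(sprintf("%s=%d", x$probes, x$probe_channels),
                            collapse = ", ")), "\n")
  cat("  wavelengths:", paste(x$wavelengths_nm, collapse = "/"), "nm\n")
  cat("  EEG electrodes:", paste(x$electrodes, collapse = " "), "\n")
  invisible(x)
}

## Channel indices of one probe
probe_channels <- function(montage, probe) {
  which(montage$channel_probe == probe)
}

## Electrode groups used by the simulator and by reporting
occipital_electrodes <- function() c("Oz", "O1", "O2", "Pz")
frontal_electrodes   <- function() c("Fz", "Cz")
temporal_electrodes  <- function() c("FT7", "FT8", "TP7", "TP8")
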