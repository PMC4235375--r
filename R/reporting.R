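## Grand averages, correlation-based feature rankings with rank averaging and
## Friedman tests, and fNIRS best-channel probe localization.

#' Grand-average haemodynamic response curves
#'
#' Per-label average of baseline-subtracted haemoglobin epochs over the given
#' channels; the baseline is the prestimulus mean (2 s context captured at
#' epoching).
#'
#' @param trials a `bci_trials` object or a list of them (pooled).
#' @param channels channel indices (default: all).
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return object of class `bci_grand_average` with per-label mean and
#'   standard-error curves (time in s relative to onset).
#' @export
grand_average_hrf <- function(trials, channels = NULL,
                              chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  if (inherits(trials, "bci_trials")) trials <- list(trials)
  npre <- trials[[1]]$n_hb_prestim
  if (npre < 1L) stop_param("epochs carry no prestimulus baseline")
  if (is.null(channels)) channels <- seq_len(dim(trials[[1]]$hbo)[2])
  arr <- do.call(rbind, lapply(trials, function(tr) {
    a <- tr[[chromophore]][, channels, , drop = FALSE]
    ## baseline-subtract, then average over channels -> trial x time
    t(vapply(seq_len(dim(a)[1]), function(i) {
      ep <- matrix(a[i, , ], nrow = length(channels))
      colMeans(ep - rowMeans(ep[, seq_len(npre), drop = FALSE]))
    }, numeric(dim(a)[3])))
  }))
  labels <- unlist(lapply(trials, `[[`, "label"))
  time <- seq_len(ncol(arr)) - 1 - npre
  curves <- lapply(split(seq_along(labels), labels), function(i) {
    m <- arr[i, , drop = FALSE]
    list(mean = colMeans(m),
         se = apply(m, 2, stats::sd) / sqrt(nrow(m)),
         n = nrow(m))
  })
  structure(list(time_s = time, curves = curves, what = toupper(chromophore)),
            class = "bci_grand_average")
}

#' Grand-average event-related potentials
#'
#' Per-label, per-electrode average of the first second of the EEG epochs.
#'
#' @param trials a `bci_trials` (or list), baseline-corrected.
#' @param electrodes electrode names (default: all).
#' @return `bci_grand_average` whose curves are electrode x time matrices.
#' @export
grand_average_erp <- function(trials, electrodes = NULL) {
  if (inherits(trials, "bci_trials")) trials <- list(trials)
  mont <- trials[[1]]$montage
  if (is.null(electrodes)) electrodes <- mont$electrodes
  el_idx <- match(electrodes, mont$electrodes)
  if (anyNA(el_idx)) stop_param("unknown electrode(s)")
  npre <- trials[[1]]$n_eeg_prestim
  fs <- trials[[1]]$fs_eeg
  idx <- (npre + 1):(npre + fs)
  labels <- unlist(lapply(trials, `[[`, "label"))
  eps <- lapply(trials, function(tr) tr$eeg[, el_idx, idx, drop = FALSE])
  curves <- lapply(split(seq_along(labels), labels), function(ii) {
    acc <- 0; k <- 0L; off <- 0L
    m <- matrix(0, length(el_idx), length(idx))
    for (tr in eps) {
      n_i <- dim(tr)[1]
      take <- ii[ii > off & ii <= off + n_i] - off
      for (i in take) m <- m + matrix(tr[i, , ], nrow = length(el_idx))
      k <- k + length(take); off <- off + n_i
    }
    list(mean = m / k, n = k)
  })
  structure(list(time_s = (seq_along(idx) - 1) / fs, curves = curves,
                 electrodes = electrodes, what = "ERP"),
            class = "bci_grand_average")
}

#' @export
print.bci_grand_average <- function(x, ...) {
  cat(x$what, "grand average:",
      paste(sprintf("%s (n=%d)", names(x$curves),
                    vapply(x$curves, `[[`, numeric(1), "n")), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.bci_grand_average <- function(x, ...) {
  cols <- c(AUD = "blue", VIS = "red", IDLE = "black", MIX = "darkgreen")
  curves <- lapply(x$curves, function(cv)
    if (is.matrix(cv$mean)) colMeans(cv$mean) else cv$mean)
  ylim <- range(unlist(curves))
  graphics::plot(NULL, xlim = range(x$time_s), ylim = ylim,
                 xlab = "time from onset (s)", ylab = x$what, ...)
  for (l in names(curves))
    graphics::lines(x$time_s, curves[[l]], col = cols[[l]] %||% "grey40")
  graphics::legend("topright", legend = names(curves),
                   col = unlist(cols[names(curves)]), lty = 1, bty = "n")
  invisible(x)
}

#' Label-wise average power spectral density
#'
#' Welch PSD of each 10 s epoch at the chosen electrode, averaged within
#' label, returned log10-scaled.
#'
#' @param trials a `bci_trials` (or list).
#' @param electrode one electrode name.
#' @return list with `freq` and per-label `log_psd` curves.
#' @export
average_psd <- function(trials, electrode = "Oz") {
  if (inherits(trials, "bci_trials")) trials <- list(trials)
  mont <- trials[[1]]$montage
  e <- match(electrode, mont$electrodes)
  if (is.na(e)) stop_param("unknown electrode: ", electrode)
  npre <- trials[[1]]$n_eeg_prestim
  fs <- trials[[1]]$fs_eeg
  labels <- unlist(lapply(trials, `[[`, "label"))
  psds <- do.call(rbind, lapply(trials, function(tr) {
    t(vapply(seq_along(tr$label), function(i)
      welch_psd(tr$eeg[i, e, (npre + 1):dim(tr$eeg)[3]], fs)$psd,
      numeric(floor(2 * fs / 2) + 1)))
  }))
  freq <- welch_psd(numeric(2 * fs), fs)$freq
  by_label <- lapply(split(seq_along(labels), labels), function(i) {
    m <- colMeans(psds[i, , drop = FALSE])
    if (all(m == 0)) {
      warning("degenerate (all-zero) spectrum for a label")
      rep(NA_real_, length(m))
    } else log10(m)
  })
  list(freq = freq, log_psd = by_label, electrode = electrode)
}

## ---- correlation-based feature ranking -------------------------------------

## Point-biserial correlation magnitude of each feature with the binary labels;
## constant features score 0.
feature_label_correlation <- function(X, y) {
  y01 <- as.numeric(factor(y)) - 1
  apply(X, 2, function(col) {
    if (stats::sd(col) < 1e-14 || stats::sd(y01) == 0) return(0)
    abs(stats::cor(col, y01))
  })
}

#' Rank feature groups by their correlation with the class labels
#'
#' For each subject, the score of an item (electrode, frequency component,
#' time window or fNIRS probe) is the maximum absolute Pearson correlation
#' between any of its features and the binary labels; items are ranked
#' descending (rank 1 = highest correlation, deterministic index tie-break)
#' and ranks are averaged across subjects.
#'
#' @param features_by_subject list (one per subject) of feature matrices with
#'   `labels` and `provenance` attributes (see [pow_feature()] etc.).
#' @param group_by provenance column defining the items.
#' @return object of class `bci_ranking` with the rank matrix, mean rank and
#'   SD per item.
#' @export
rank_features <- function(features_by_subject, group_by = "electrode") {
  if (length(features_by_subject) < 2L) stop_param("needs >= 2 subjects")
  prov <- attr(features_by_subject[[1]], "provenance")
  if (!group_by %in% names(prov)) stop_param("unknown provenance column: ", group_by)
  items <- unique(prov[[group_by]])
  ranks <- t(vapply(features_by_subject, function(fm) {
    p <- attr(fm, "provenance")
    y <- attr(fm, "labels")
    if (length(unique(y)) != 2L) stop_param("ranking needs binary labels")
    r <- feature_label_correlation(unclass(fm), y)
    score <- vapply(items, function(it) max(r[p[[group_by]] == it]), numeric(1))
    rank(-score, ties.method = "first")
  }, numeric(length(items))))
  colnames(ranks) <- as.character(items)
  tab <- data.frame(item = as.character(items),
                    mean_rank = colMeans(ranks),
                    sd_rank = apply(ranks, 2, stats::sd),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$mean_rank), ]
  rownames(tab) <- NULL
  structure(list(ranks = ranks, table = tab, group_by = group_by),
            class = "bci_ranking")
}

#' @export
print.bci_ranking <- function(x, ...) {
  cat("Average feature ranking by", x$group_by,
      sprintf("(%d subjects)\n", nrow(x$ranks)))
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %2d. %-8s mean rank %.2f (SD %.2f)\n", i, tab$item[i],
                tab$mean_rank[i], tab$sd_rank[i]))
  invisible(x)
}

#' Friedman test on a ranking
#'
#' Tests whether the per-subject rankings agree on a consistent ordering of
#' the items (chi-square approximation, k - 1 degrees of freedom, mid-rank
#' tie correction via [stats::friedman.test()]).
#'
#' @param ranking a [rank_features()] result or a subjects x items rank
#'   matrix.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
friedman_rank_test <- function(ranking) {
  m <- if (inherits(ranking, "bci_ranking")) ranking$ranks else as.matrix(ranking)
  if (nrow(m) < 2L) stop_param("Friedman test needs >= 2 subjects")
  if (ncol(m) < 3L) stop_param("Friedman test needs >= 3 items")
  ft <- stats::friedman.test(m)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p.value = ft$p.value)
}

#' fNIRS best-channel probe localization
#'
#' For each subject and chromophore, finds the channel whose slope feature
#' correlates most with the labels and reports how often the best channel
#' falls on each probe (averaged over HbO and HbR, as a fraction of
#' subject-chromophore pairs).
#'
#' @param features_by_subject list (per subject) of lists with `hbo` and
#'   `hbr` slope feature matrices.
#' @param montage the [make_montage()] the features came from.
#' @return named vector of per-probe fractions (sums to 1).
#' @export
localize_best_probe <- function(features_by_subject, montage) {
  hits <- c()
  for (fs in features_by_subject) {
    for (ch in c("hbo", "hbr")) {
      fm <- fs[[ch]]
      r <- feature_label_correlation(unclass(fm), attr(fm, "labels"))
      hits <- c(hits, montage$channel_probe[which.max(r)])
    }
  }
  out <- vapply(montage$probes, function(p) mean(hits == p), numeric(1))
  names(out) <- montage$probes
  out
}
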