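## Event schedules: the block design of a recording session. Block 1 holds
## three fixed continuous 60 s clips (AUD, VIS, MIX) separated by 20 s gaps;
## blocks 2-5 hold randomized stimulus/rest sequences with no two consecutive
## stimuli of the same modality.

STIMULUS_LABELS <- c("AUD", "VIS", "MIX", "IDLE")

#' Construct an event schedule
#'
#' @param onset_s,duration_s,label,block parallel vectors describing events.
#' @param segment `"trial"` for stimulus-locked events, `"continuous"` for
#'   the block-1 clips.
#' @return a data.frame of class `bci_schedule`, time-sorted.
#' @export
event_schedule <- function(onset_s, duration_s, label, block,
                           segment = rep("trial", length(onset_s))) {
  n <- length(onset_s)
  stopifnot(length(duration_s) == n, length(label) == n,
            length(block) == n, length(segment) == n)
  if (n == 0L) {
    sched <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                        label = character(0), block = integer(0),
                        segment = character(0), stringsAsFactors = FALSE)
    class(sched) <- c("bci_schedule", "data.frame")
    return(sched)
  }
  if (!all(label %in% STIMULUS_LABELS))
    stop_param("labels must be in {", paste(STIMULUS_LABELS, collapse = ", "), "}")
  if (any(duration_s <= 0)) stop_param("event durations must be positive")
  ord <- order(onset_s)
  sched <- data.frame(onset_s = onset_s[ord], duration_s = duration_s[ord],
                      label = label[ord], block = as.integer(block[ord]),
                      segment = segment[ord], stringsAsFactors = FALSE)
  ends <- sched$onset_s + sched$duration_s
  if (any(sched$onset_s[-1] < ends[-n] - 1e-9))
    stop_param("events overlap in time")
  class(sched) <- c("bci_schedule", "data.frame")
  sched
}

#' @export
print.bci_schedule <- function(x, ...) {
  cat("Event schedule:", nrow(x), "events")
  if (nrow(x) > 0) {
    cat(sprintf(" over %.1f s; ", max(x$onset_s + x$duration_s)))
    cat(paste(sprintf("%s=%d", names(table(x$label)), as.integer(table(x$label))),
              collapse = " "))
  }
  cat("\n")
  invisible(x)
}

#' Simulation configuration for a synthetic session cohort
#'
#' Defaults reproduce the study design: 30 trials per label in blocks 2-5,
#' stimulus durations uniform on 12.5 +/- 2.5 s, rests uniform on 20 +/- 5 s,
#' and a first block of three continuous 60 s clips (AUD, VIS, MIX) with 20 s
#' gaps.
#'
#' @param n_subjects cohort size.
#' @param trials_per_label stimulus-locked trials per label over blocks 2-5.
#' @param stim_duration_s,rest_duration_s `c(min, max)` of the uniform
#'   duration distributions.
#' @param clip_duration_s,clip_gap_s block-1 continuous clip length and gap.
#' @param n_blocks number of randomized blocks (trials are split evenly).
#' @return a list of class `bci_sim_config`.
#' @export
sim_config <- function(n_subjects = 12L, trials_per_label = 30L,
                       stim_duration_s = c(10, 15),
                       rest_duration_s = c(15, 25),
                       clip_duration_s = 60, clip_gap_s = 20,
                       n_blocks = 4L) {
  stopifnot(n_subjects >= 1L, trials_per_label >= 1L,
            stim_duration_s[1] > 0, stim_duration_s[2] >= stim_duration_s[1],
            rest_duration_s[1] > 0, rest_duration_s[2] >= rest_duration_s[1])
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_label = as.integer(trials_per_label),
                 stim_duration_s = stim_duration_s,
                 rest_duration_s = rest_duration_s,
                 clip_duration_s = clip_duration_s,
                 clip_gap_s = clip_gap_s,
                 n_blocks = as.integer(n_blocks)),
            class = "bci_sim_config")
}

## Randomize one block's label order under the no-repeat constraint:
## sequential sampling proportional to remaining counts, excluding the
## previous label; dead ends are rejected and retried (cap 1e4).
randomize_labels <- function(counts, max_tries = 1e4) {
  n <- sum(counts)
  for (i in seq_len(max_tries)) {
    left <- counts
    out <- character(n)
    prev <- ""
    ok <- TRUE
    for (j in seq_len(n)) {
      allowed <- names(left)[left > 0 & names(left) != prev]
      if (length(allowed) == 0L) { ok <- FALSE; break }
      pick <- if (length(allowed) == 1L) allowed
              else sample(allowed, 1L, prob = left[allowed])
      out[j] <- pick
      left[pick] <- left[pick] - 1L
      prev <- pick
    }
    if (ok) return(out)
  }
  stop_param("could not satisfy the no-consecutive-repeat constraint after ",
             max_tries, " tries")
}

#' Generate a randomized session schedule
#'
#' Block 1 holds the three continuous clips; blocks 2 onward hold the
#' stimulus-locked trials, `trials_per_label` of each label, in randomized
#' order with no two consecutive stimuli sharing a label (enforced per block).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the schedule is a pure function of
#'   `(config, seed)`.
#' @return a [event_schedule()] data.frame.
#' @export
generate_schedule <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "bci_sim_config"))
  with_seed(derive_seed(seed, "schedule"), {
    ## block 1: continuous clips
    t <- 0
    onset <- c(); dur <- c(); lab <- c(); blk <- c(); seg <- c()
    for (l in c("AUD", "VIS", "MIX")) {
      onset <- c(onset, t); dur <- c(dur, config$clip_duration_s)
      lab <- c(lab, l); blk <- c(blk, 1L); seg <- c(seg, "continuous")
      t <- t + config$clip_duration_s + config$clip_gap_s
    }
    ## blocks 2..: split trials as evenly as possible over blocks
    per_block <- matrix(0L, nrow = config$n_blocks, ncol = 4,
                        dimnames = list(NULL, STIMULUS_LABELS))
    for (l in STIMULUS_LABELS) {
      k <- config$trials_per_label
      base <- k %/% config$n_blocks
      extra <- k %% config$n_blocks
      per_block[, l] <- base + (seq_len(config$n_blocks) <= extra)
    }
    for (b in seq_len(config$n_blocks)) {
      counts <- per_block[b, ][per_block[b, ] > 0]
      if (length(counts) == 0L) next
      order_b <- randomize_labels(counts)
      t <- t + stats::runif(1, config$rest_duration_s[1], config$rest_duration_s[2])
      for (l in order_b) {
        d <- stats::runif(1, config$stim_duration_s[1], config$stim_duration_s[2])
        onset <- c(onset, t); dur <- c(dur, d); lab <- c(lab, l)
        blk <- c(blk, b + 1L); seg <- c(seg, "trial")
        t <- t + d + stats::runif(1, config$rest_duration_s[1],
                                  config$rest_duration_s[2])
      }
    }
    event_schedule(onset, dur, lab, blk, seg)
  })
}
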