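#' Paired pre/post window design around drug additions
#'
#' The drug-epoch design: around each addition at time `t`, contraction
#' frequency is measured in two windows of `window_length_s` seconds -- the
#' pre-window `[t - W, t)` ending immediately at the addition, and the
#' post-window `[t + delay, t + delay + W)` starting `post_delay_s` seconds
#' after it (defaults 120 s and 10 s).
#'
#' @param schedule a [drug_schedule()] (or data.frame with `time_s`,
#'   `label`).
#' @param window_length_s window length, seconds.
#' @param post_delay_s delay between addition and post-window start, seconds.
#' @return object of class `epoch_design`.
#' @export
epoch_design <- function(schedule, window_length_s = 120, post_delay_s = 10) {
  if (!is.data.frame(schedule) || !all(c("time_s", "label") %in% names(schedule))) {
    stopf("schedule must be a drug_schedule (columns time_s, label)")
  }
  if (nrow(schedule) == 0) stopf("schedule needs at least one addition")
  if (any(diff(schedule$time_s) <= 0)) stopf("schedule times must be strictly increasing")
  if (window_length_s <= 0) stopf("window_length_s must be > 0")
  if (post_delay_s < 0) stopf("post_delay_s must be >= 0")
  structure(list(schedule = schedule, window_length_s = window_length_s,
                 post_delay_s = post_delay_s),
            class = "epoch_design")
}

design_windows <- function(design) {
  s <- design$schedule
  W <- design$window_length_s; d <- design$post_delay_s
  data.frame(label = s$label, time_s = s$time_s,
             pre_start = s$time_s - W, pre_end = s$time_s,
             post_start = s$time_s + d, post_end = s$time_s + d + W,
             stringsAsFactors = FALSE)
}

#' Per-condition contraction frequencies of one segment
#'
#' Builds one row of the frequency table: the spontaneous baseline
#' (`"Spont"`) from the pre-window of the *first* addition, and one value
#' per drug from its post-window, all half-open. Later pre-windows are
#' returned in the `pre_bpm` attribute but not entered into the table.
#'
#' Window violations (a window leaving the recording, or a post-window
#' overlapping the next addition's pre-window) are errors naming the
#' offending addition.
#'
#' @param events a `contraction_events` data.frame or numeric event times
#'   for one segment.
#' @param design an `epoch_design`.
#' @param recording_duration_s recording length, seconds.
#' @return named numeric vector `c(Spont = ..., <label> = ...)` with
#'   attribute `pre_bpm`.
#' @export
epoch_frequencies <- function(events, design, recording_duration_s) {
  stopifnot(inherits(design, "epoch_design"))
  w <- design_windows(design)
  for (i in seq_len(nrow(w))) {
    if (w$pre_start[i] < 0) {
      stopf("addition \"%s\" at %g s: pre-window [%g, %g) starts before the recording",
            w$label[i], w$time_s[i], w$pre_start[i], w$pre_end[i])
    }
    if (w$post_end[i] > recording_duration_s) {
      stopf("addition \"%s\" at %g s: post-window [%g, %g) leaves the %g s recording",
            w$label[i], w$time_s[i], w$post_start[i], w$post_end[i], recording_duration_s)
    }
    if (i < nrow(w) && w$post_end[i] > w$pre_start[i + 1]) {
      stopf("addition \"%s\" at %g s: post-window [%g, %g) overlaps the pre-window of \"%s\" at %g s",
            w$label[i], w$time_s[i], w$post_start[i], w$post_end[i],
            w$label[i + 1], w$time_s[i + 1])
    }
  }
  post <- vapply(seq_len(nrow(w)), function(i) {
    contraction_frequency(events, w$post_start[i], w$post_end[i])
  }, 0)
  pre <- vapply(seq_len(nrow(w)), function(i) {
    contraction_frequency(events, w$pre_start[i], w$pre_end[i])
  }, 0)
  out <- c(Spont = pre[1], stats::setNames(post, make.unique(w$label)))
  attr(out, "pre_bpm") <- stats::setNames(pre, make.unique(w$label))
  out
}

#' Assemble the frequency table across segments and run the paired tests
#'
#' One row per segment via [epoch_frequencies()], then [friedman_test()]
#' and [dunns_posthoc()] on the resulting blocks x conditions table.
#'
#' @param event_sets_by_segment list (one entry per segment) of
#'   `contraction_events` data.frames or numeric event-time vectors.
#' @param design an `epoch_design` shared by all segments.
#' @param recording_duration_s recording length, seconds (scalar or one per
#'   segment).
#' @param comparisons,p_adjust passed to [dunns_posthoc()].
#' @param exact passed to [friedman_test()].
#' @return object of class `condition_comparison`: `frequency_table`
#'   (matrix, segments x conditions, beats/min), `friedman`, `pairwise`.
#' @export
compare_conditions <- function(event_sets_by_segment, design,
                               recording_duration_s, comparisons = NULL,
                               p_adjust = "bonferroni", exact = FALSE) {
  ns <- length(event_sets_by_segment)
  if (ns < 2) stopf("need >= 2 segments for the paired tests, got %d", ns)
  dur <- rep_len(recording_duration_s, ns)
  rows <- lapply(seq_len(ns), function(i) {
    epoch_frequencies(event_sets_by_segment[[i]], design, dur[i])
  })
  cn <- names(rows[[1]])
  same <- vapply(rows, function(r) identical(names(r), cn), TRUE)
  if (!all(same)) stopf("segments yield differing condition sets")
  tab <- do.call(rbind, lapply(rows, as.numeric))
  colnames(tab) <- cn
  rownames(tab) <- names(event_sets_by_segment) %||% sprintf("segment%d", seq_len(ns))
  fr <- friedman_test(tab, exact = exact)
  dn <- dunns_posthoc(tab, comparisons = comparisons, p_adjust = p_adjust)
  structure(list(frequency_table = tab, friedman = fr, pairwise = dn),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Frequency table (beats/min):\n")
  print(round(x$frequency_table, 3))
  cat("\n")
  print(x$friedman)
  cat("\nDunn's multiple comparisons (adjusted p):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
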