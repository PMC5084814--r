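# Absolute-pitch session scoring: response validation, error measures with
# octave correction, AP score, confusion matrices, and group comparisons.

#' Validate the key-press events of one test session
#'
#' Applies the response-validity rules of the AP test. Each trial has a 4 s
#' response window; the first key press later than 100 ms after stimulus
#' onset is the trial's valid response. A first press at or before 100 ms is
#' regarded as a late response to the previous trial and discarded (it never
#' overwrites the previous trial's response). Later presses within the
#' window are ignored; a trial with no valid press is a timeout.
#'
#' @param events Data frame with one row per key-press event (or one row
#'   with `NA` press for unanswered trials). Required columns: `trial`
#'   (ordinal), `timbre` (`"pure"`/`"piano"`), `target_note` (label) or
#'   `target_midi`, `pressed_note` or `response_midi` (NA if none),
#'   `latency_s` (seconds from stimulus onset, NA if none). An optional
#'   `subject` column labels the session.
#' @param window_s Response window length in seconds (default 4).
#' @param min_latency_s Validity floor in seconds; a press must be strictly
#'   later than this (default 0.1).
#' @return A `validated_session`: list with `subject_id`, `trials` (one row
#'   per trial with `valid` flag and the accepted response), `n_valid`,
#'   `n_timeout`, `n_late_reassigned`.
#' @export
validate_session <- function(events, window_s = 4, min_latency_s = 0.1) {
  stopifnot(is.data.frame(events), nrow(events) > 0)
  if (is.null(events$target_midi)) events$target_midi <- note_to_midi(events$target_note)
  if (is.null(events$response_midi)) {
    events$response_midi <- NA_integer_
    pressed <- !is.na(events$pressed_note)
    events$response_midi[pressed] <-
      note_to_midi(as.character(events$pressed_note[pressed]))
  }
  if (any(events$latency_s < 0, na.rm = TRUE)) stop("negative latency in event log")
  subject <- if (!is.null(events$subject)) as.character(events$subject[1]) else NA_character_

  trial_ids <- unique(events$trial)
  trial_ids <- trial_ids[order(trial_ids)]
  n_late <- 0L
  rows <- lapply(trial_ids, function(tr) {
    ev <- events[events$trial == tr, , drop = FALSE]
    ev <- ev[order(ev$latency_s, na.last = TRUE), , drop = FALSE]
    presses <- ev[!is.na(ev$latency_s), , drop = FALSE]
    if (nrow(presses) > 0 && presses$latency_s[1] <= min_latency_s) {
      n_late <<- n_late + 1L
      presses <- presses[presses$latency_s > min_latency_s, , drop = FALSE]
    }
    presses <- presses[presses$latency_s <= window_s, , drop = FALSE]
    if (nrow(presses) > 0) {
      data.frame(trial = tr, timbre = as.character(ev$timbre[1]),
                 target_midi = ev$target_midi[1],
                 response_midi = presses$response_midi[1],
                 latency_s = presses$latency_s[1], valid = TRUE)
    } else {
      data.frame(trial = tr, timbre = as.character(ev$timbre[1]),
                 target_midi = ev$target_midi[1],
                 response_midi = NA_integer_, latency_s = NA_real_, valid = FALSE)
    }
  })
  trials <- do.call(rbind, rows)
  structure(list(subject_id = subject, trials = trials,
                 n_valid = sum(trials$valid),
                 n_timeout = sum(!trials$valid),
                 n_late_reassigned = n_late),
            class = "validated_session")
}

#' @export
print.validated_session <- function(x, ...) {
  cat("AP test session", if (!is.na(x$subject_id)) paste0("'", x$subject_id, "'"), "\n")
  cat(sprintf("  %d trials: %d valid, %d timeout (%d late presses reassigned)\n",
              nrow(x$trials), x$n_valid, x$n_timeout, x$n_late_reassigned))
  invisible(x)
}

.score_trials <- function(tr, hit_on) {
  v <- tr[tr$valid, , drop = FALSE]
  if (nrow(v) == 0) stop("no valid trials to score")
  ae <- abs(v$target_midi - v$response_midi)
  e <- octave_corrected_error(chroma_of(v$target_midi), chroma_of(v$response_midi))
  ace <- abs(e)
  hit_err <- if (hit_on == "ace") ace else ae
  data.frame(
    n_valid = nrow(v),
    mean_ae = mean(ae),
    mean_ace = mean(ace),
    octave_error_measure = mean(ae) - mean(ace),
    octave_error_rate = mean(e == 0L & v$target_midi != v$response_midi),
    aps = aps_from_ace(mean(ace)),
    hit_rate = mean(hit_err <= 1),
    mean_rt = mean(v$latency_s)
  )
}

#' Score a validated AP session
#'
#' Computes, per timbre and pooled over timbres: mean absolute error (AE,
#' semitones), mean absolute octave-corrected error (ACE), the octave-error
#' measure (mean AE - mean ACE), the octave-error rate (valid answers with
#' correct chroma but wrong octave), the AP score APS = 1 - meanACE/6, the
#' hit rate, and mean reaction time.
#'
#' @param session A `validated_session` from [validate_session()].
#' @param hit_on Count a hit when the error is at most one semitone on the
#'   octave-corrected error (`"ace"`, default) or on the raw absolute error
#'   (`"ae"`).
#' @return A `session_score`: data frame with rows `pure`, `piano`, `all`
#'   (as available) and the measures above as columns; the subject id is
#'   kept as an attribute.
#' @export
score_session <- function(session, hit_on = c("ace", "ae")) {
  hit_on <- match.arg(hit_on)
  stopifnot(inherits(session, "validated_session"))
  tr <- session$trials
  timbres <- intersect(c("pure", "piano"), unique(tr$timbre))
  out <- lapply(timbres, function(tb) .score_trials(tr[tr$timbre == tb, ], hit_on))
  out <- c(out, list(.score_trials(tr, hit_on)))
  res <- cbind(data.frame(timbre = c(timbres, "all")), do.call(rbind, out))
  structure(res, class = c("session_score", "data.frame"),
            subject_id = session$subject_id, hit_on = hit_on)
}

#' @export
print.session_score <- function(x, digits = 3, ...) {
  sid <- attr(x, "subject_id")
  cat("AP performance", if (!is.na(sid)) paste0("for '", sid, "'"),
      sprintf("(hit on %s <= 1)\n", toupper(attr(x, "hit_on"))))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Score several sessions into one long table
#'
#' @param sessions List of `validated_session` objects.
#' @param hit_on Passed to [score_session()].
#' @return Data frame with columns `subject`, `timbre`, and the measures of
#'   [score_session()], one row per subject and timbre level.
#' @export
score_sessions <- function(sessions, hit_on = c("ace", "ae")) {
  hit_on <- match.arg(hit_on)
  do.call(rbind, lapply(sessions, function(s) {
    sc <- score_session(s, hit_on = hit_on)
    cbind(data.frame(subject = attr(sc, "subject_id")), as.data.frame(sc))
  }))
}

#' Target-by-answer confusion matrix over sessions
#'
#' Cell (i, j) is the number of valid trials with target note i answered
#' with note j, divided by the subject's total trial count for that timbre,
#' averaged over subjects. Columns span the full 88-key range. The
#' octave-corrected variant first maps each answer into the target's octave
#' (chroma-only reading), so octave errors fall on the diagonal.
#'
#' @param sessions List of `validated_session` objects sharing one design.
#' @param timbre `"pure"`, `"piano"`, or `"all"`.
#' @param corrected Logical; fold answers by octave before binning.
#' @param key_range MIDI range of the response keyboard (default 88 keys,
#'   A0..C8).
#' @return A `confusion_matrix`: numeric matrix (targets x answers) with
#'   note-name dimnames and attributes `timbre`, `corrected`,
#'   `prop_unanswered` (timeout/invalid mass so that total mass + timeouts
#'   sums to 1).
#' @export
confusion_matrix <- function(sessions, timbre = "all", corrected = FALSE,
                             key_range = c(21L, 108L)) {
  stopifnot(length(sessions) > 0)
  keep <- function(tr) if (timbre == "all") tr else tr[tr$timbre == timbre, , drop = FALSE]
  targets <- sort(unique(unlist(lapply(sessions, function(s) keep(s$trials)$target_midi))))
  answers <- seq(key_range[1], key_range[2])
  acc <- matrix(0, length(targets), length(answers),
                dimnames = list(midi_to_note(targets), midi_to_note(answers)))
  miss <- 0
  for (s in sessions) {
    tr <- keep(s$trials)
    n_tot <- nrow(tr)
    v <- tr[tr$valid, , drop = FALSE]
    resp <- v$response_midi
    if (corrected) {
      resp <- v$target_midi + octave_corrected_error(chroma_of(v$target_midi),
                                                     chroma_of(v$response_midi))
    }
    m <- matrix(0, length(targets), length(answers))
    inside <- resp >= key_range[1] & resp <= key_range[2]
    idx <- cbind(match(v$target_midi[inside], targets), match(resp[inside], answers))
    for (k in seq_len(nrow(idx))) m[idx[k, 1], idx[k, 2]] <- m[idx[k, 1], idx[k, 2]] + 1
    acc <- acc + m / n_tot
    miss <- miss + (n_tot - sum(inside)) / n_tot
  }
  structure(acc / length(sessions), class = c("confusion_matrix", "matrix"),
            timbre = timbre, corrected = corrected,
            prop_unanswered = miss / length(sessions))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (%s tones, %s): %d targets x %d answer keys\n",
              attr(x, "timbre"),
              if (attr(x, "corrected")) "pitch chroma only" else "pitch chroma & height",
              nrow(x), ncol(x)))
  cat(sprintf("  answered mass %.3f, unanswered %.3f\n",
              sum(x), attr(x, "prop_unanswered")))
  invisible(x)
}

#' @describeIn confusion_matrix Gray-scale image of the matrix (dark = high
#'   proportion), targets on rows from bottom.
#' @param x A `confusion_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.confusion_matrix <- function(x, ...) {
  z <- t(unclass(x))
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z,
                  col = grDevices::gray(seq(1, 0, length.out = 64)),
                  xlab = "answer key", ylab = "target note", axes = FALSE, ...)
  graphics::axis(1, at = pretty(seq_len(nrow(z))))
  graphics::axis(2, at = seq_len(ncol(z)), labels = rownames(x), las = 2,
                 cex.axis = 0.5)
  graphics::box()
  invisible(x)
}

#' Two-group comparison of a behavioral or demographic variable
#'
#' Continuous variables are compared with a two-sample t test (Welch by
#' default; pooled-variance Student optional); binary variables with a
#' pooled two-proportion z test. Two-sided p-values.
#'
#' @param x Numeric vector (continuous) or 0/1 vector (binary).
#' @param group Two-level factor or vector aligned with `x`.
#' @param kind `"t"` or `"z"`.
#' @param var_equal For `kind = "t"`: pooled-variance Student t instead of
#'   Welch.
#' @param variable Optional label for printing.
#' @return A `group_comparison` list: group means/SDs (SD `NA` for
#'   proportions), `statistic`, `kind`, `df` (t only), `p_value`.
#' @export
compare_groups <- function(x, group, kind = c("t", "z"), var_equal = FALSE,
                           variable = deparse(substitute(x))) {
  kind <- match.arg(kind)
  group <- factor(group)
  stopifnot(nlevels(group) == 2, length(x) == length(group))
  xs <- split(x, group)
  if (kind == "t") {
    if (stats::sd(xs[[1]]) == 0 && stats::sd(xs[[2]]) == 0)
      stop("zero variance in both groups: t test degenerate")
    ht <- stats::t.test(xs[[1]], xs[[2]], var.equal = var_equal)
    out <- list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value)
  } else {
    stopifnot(all(x %in% c(0, 1)))
    n <- lengths(xs); k <- vapply(xs, sum, 0)
    p_pool <- sum(k) / sum(n)
    if (p_pool %in% c(0, 1)) stop("degenerate proportions: z test undefined")
    se <- sqrt(p_pool * (1 - p_pool) * (1 / n[1] + 1 / n[2]))
    z <- (k[1] / n[1] - k[2] / n[2]) / se
    out <- list(statistic = unname(z), df = NA_real_,
                p_value = 2 * stats::pnorm(-abs(z)))
  }
  structure(c(list(variable = variable, groups = levels(group),
                   means = vapply(xs, mean, 0),
                   sds = if (kind == "t") vapply(xs, stats::sd, 0) else c(NA, NA),
                   n = lengths(xs), kind = kind), out),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s %.3f vs %s %.3f; %s = %.3f%s, p = %.4g\n",
              x$variable, x$groups[1], x$means[1], x$groups[2], x$means[2],
              x$kind, x$statistic,
              if (!is.na(x$df)) sprintf(" (df %.1f)", x$df) else "",
              x$p_value))
  invisible(x)
}

#' Read session event logs from delimited files
#'
#' Each file holds one session: one row per key-press event with columns
#' `subject, trial, timbre, target_note, pressed_note, latency_s`
#' (unanswered trials as rows with empty press fields).
#'
#' @param paths Character vector of CSV paths.
#' @param ... Passed to [validate_session()].
#' @return List of `validated_session` objects.
#' @export
read_sessions <- function(paths, ...) {
  lapply(paths, function(p) {
    ev <- utils::read.csv(p, stringsAsFactors = FALSE)
    ev$pressed_note[ev$pressed_note == ""] <- NA
    validate_session(ev, ...)
  })
}
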