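# Containers for multichannel recordings and conditioned 25-min segments.

#' Construct a multichannel recording
#'
#' @param samples Channels x time numeric matrix (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param hemisphere Per-channel tag, `"L"` or `"R"`.
#' @param annotations Data frame with columns `time` (seconds) and `label`
#'   (e.g. `"seizure_onset"`, a condition tag); may be empty.
#' @return An `ecog_recording` object.
#' @export
ecog_recording <- function(samples, fs, channel_labels = NULL,
                           hemisphere = NULL, annotations = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric channels x time matrix")
  if (any(!is.finite(samples))) stop("samples must not contain missing values")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive sampling rate in Hz")
  n <- nrow(samples)
  if (is.null(channel_labels))
    channel_labels <- sprintf("CH%02d", seq_len(n))
  if (is.null(hemisphere))
    hemisphere <- rep(c("L", "R"), length.out = n)
  stopifnot(length(channel_labels) == n, length(hemisphere) == n,
            all(hemisphere %in% c("L", "R")))
  if (is.null(annotations))
    annotations <- data.frame(time = numeric(), label = character())
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 hemisphere = hemisphere,
                 annotations = annotations),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %.1f s @ %g Hz (%d L / %d R)\n",
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs,
              sum(x$hemisphere == "L"), sum(x$hemisphere == "R")))
  if (nrow(x$annotations))
    cat("  annotations:",
        paste(sprintf("%s@%gs", x$annotations$label, x$annotations$time),
              collapse = ", "), "\n")
  invisible(x)
}

#' Extract a conditioned segment around a seizure onset
#'
#' Cuts the span `[onset - pre, onset + post)` out of a recording and
#' returns it as an `ecog_segment` with `onset_time = pre` seconds from
#' segment start (900 s under the default 15-min/10-min split). A warning
#' is raised if more than one seizure-onset annotation falls inside the
#' span, since each segment is meant to contain exactly one seizure.
#'
#' @param rec An `ecog_recording`.
#' @param onset Seizure onset time in seconds from recording start.
#' @param pre,post Seconds kept before/after the onset (defaults 900/600).
#' @param condition Condition label (`"focal"`, `"bilateral"` or
#'   `"interictal"`); defaults to the label of the onset annotation when
#'   present, else `"focal"`.
#' @return An `ecog_segment`: an `ecog_recording` plus `condition`,
#'   `onset_time` and `segment_id` fields.
#' @export
extract_segment <- function(rec, onset, pre = 900, post = 600,
                            condition = NULL) {
  stopifnot(inherits(rec, "ecog_recording"))
  total <- ncol(rec$samples) / rec$fs
  if (onset - pre < 0 || onset + post > total)
    stop(sprintf("requested span [%g, %g) s exceeds recording bounds [0, %g) s",
                 onset - pre, onset + post, total))
  i0 <- round((onset - pre) * rec$fs) + 1L
  i1 <- i0 + round((pre + post) * rec$fs) - 1L
  onsets <- rec$annotations[rec$annotations$label == "seizure_onset", , drop = FALSE]
  inside <- onsets$time >= onset - pre & onsets$time < onset + post
  if (sum(inside) > 1)
    warning(sum(inside), " seizure onsets inside one segment; ",
            "each segment should contain only one seizure")
  if (is.null(condition)) {
    hit <- which(rec$annotations$time == onset &
                   rec$annotations$label %in% c("focal", "bilateral", "interictal"))
    condition <- if (length(hit)) rec$annotations$label[hit[1L]] else "focal"
  }
  as_segment(ecog_recording(rec$samples[, i0:i1, drop = FALSE], rec$fs,
                            rec$channel_labels, rec$hemisphere,
                            data.frame(time = pre, label = "seizure_onset")),
             condition = condition, onset_time = pre)
}

#' @rdname extract_segment
#' @param segment_id Optional identifier carried through to output tables.
#' @export
as_segment <- function(rec, condition, onset_time, segment_id = NA_character_) {
  stopifnot(inherits(rec, "ecog_recording"),
            condition %in% c("focal", "bilateral", "interictal"))
  rec$condition <- condition
  rec$onset_time <- onset_time
  rec$segment_id <- segment_id
  class(rec) <- c("ecog_segment", "ecog_recording")
  rec
}

#' @export
print.ecog_segment <- function(x, ...) {
  cat(sprintf("<ecog_segment> %s | %d channels x %.1f s @ %g Hz | onset at %g s\n",
              x$condition, nrow(x$samples), ncol(x$samples) / x$fs, x$fs,
              x$onset_time))
  invisible(x)
}

#' Select interictal segments far from any seizure
#'
#' Returns non-overlapping candidate segments of `duration` seconds whose
#' every sample is at least `min_gap` seconds away from every seizure onset
#' and offset (i.e. outside `[onset - min_gap, offset + min_gap]` for each
#' seizure). Each returned segment is tagged `condition = "interictal"`
#' with a pseudo-onset of 900 s.
#'
#' @param rec An `ecog_recording`.
#' @param seizure_spans Data frame or 2-column matrix of seizure
#'   `(onset, offset)` times in seconds.
#' @param min_gap Minimum distance to any seizure (default 3600 s).
#' @param duration Segment length (default 1500 s).
#' @param pseudo_onset Pseudo-onset position within each segment (900 s).
#' @return List of `ecog_segment`s (possibly empty, with a message).
#' @export
select_interictal <- function(rec, seizure_spans, min_gap = 3600,
                              duration = 1500, pseudo_onset = 900) {
  stopifnot(inherits(rec, "ecog_recording"))
  total <- ncol(rec$samples) / rec$fs
  spans <- as.matrix(seizure_spans)
  forbidden <- if (nrow(spans)) cbind(spans[, 1] - min_gap, spans[, 2] + min_gap)
               else matrix(numeric(), 0, 2)
  # allowed intervals = [0, total] minus the union of forbidden intervals
  allowed <- list(c(0, total))
  if (nrow(forbidden)) {
    for (i in seq_len(nrow(forbidden))) {
      lo <- forbidden[i, 1]; hi <- forbidden[i, 2]
      allowed <- unlist(lapply(allowed, function(iv) {
        out <- list()
        if (iv[1] < lo) out <- c(out, list(c(iv[1], min(iv[2], lo))))
        if (iv[2] > hi) out <- c(out, list(c(max(iv[1], hi), iv[2])))
        out
      }), recursive = FALSE)
    }
  }
  segments <- list()
  idx <- 1L
  for (iv in allowed) {
    n_fit <- floor((iv[2] - iv[1]) / duration)
    for (j in seq_len(n_fit)) {
      start <- iv[1] + (j - 1) * duration
      i0 <- round(start * rec$fs) + 1L
      i1 <- i0 + round(duration * rec$fs) - 1L
      if (i1 > ncol(rec$samples)) next
      seg <- as_segment(
        ecog_recording(rec$samples[, i0:i1, drop = FALSE], rec$fs,
                       rec$channel_labels, rec$hemisphere,
                       data.frame(time = pseudo_onset, label = "pseudo_onset")),
        condition = "interictal", onset_time = pseudo_onset,
        segment_id = sprintf("interictal_%02d", idx))
      segments[[idx]] <- seg
      idx <- idx + 1L
    }
  }
  if (!length(segments))
    message("no qualifying interictal span of ", duration, " s found")
  segments
}
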