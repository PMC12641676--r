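# Temporal window segmentation, baselines and irregular-gaze-event detection.

# Feature channels usable for baselines / event detection.
.event_channels <- c("SACCADE_MAG", "SACCADE_DIR", "LPUPIL_DIAM",
                     "RPUPIL_DIAM", "AVG_PUPIL_DIAM", "FIXATION_DUR",
                     "BLINK_RATE")

#' Window-strategy specification
#'
#' Describes one of the four segmentation strategies. All intervals are
#' half-open `[start, end)` with time zero at recording start.
#' \describe{
#'   \item{tumbling}{non-overlapping, fixed size `size_s`}
#'   \item{expanding}{`[0, k * size_s)` for growing k, always anchored at 0}
#'   \item{hopping}{fixed size `size_s`, advanced by `hop_s`}
#'   \item{session}{event-driven: opens at an irregular gaze event, the
#'     `timeout_s` renews with each further event, capped at
#'     `max_duration_s`; the baseline for event detection is the channel
#'     mean over the first `baseline_s` seconds}
#' }
#'
#' @param kind One of `"tumbling"`, `"expanding"`, `"hopping"`, `"session"`.
#' @param size_s Window size (tumbling/hopping) or expansion step.
#' @param hop_s Hop size (hopping only).
#' @param timeout_s,max_duration_s,baseline_s Session-window parameters.
#' @param event_channel Session feature channel, one of `SACCADE_MAG`,
#'   `SACCADE_DIR`, `LPUPIL_DIAM`, `RPUPIL_DIAM`, `AVG_PUPIL_DIAM`,
#'   `FIXATION_DUR`, `BLINK_RATE`.
#' @param multiplier Event threshold multiplier on the baseline (default 1:
#'   any value strictly above the baseline is an event).
#' @param min_fill Minimum fill fraction of a final partial tumbling/hopping
#'   window for it to be emitted (0 = always emit).
#' @return A `window_spec` list.
#' @export
window_spec <- function(kind = c("tumbling", "expanding", "hopping", "session"),
                        size_s = NULL, hop_s = NULL, timeout_s = NULL,
                        max_duration_s = NULL, baseline_s = NULL,
                        event_channel = "SACCADE_MAG", multiplier = 1,
                        min_fill = 0) {
  kind <- match.arg(kind)
  if (kind %in% c("tumbling", "expanding", "hopping")) {
    if (is.null(size_s) || !is.numeric(size_s) || size_s <= 0) {
      stop("window_spec: size_s must be a positive number for ", kind,
           " windows")
    }
  }
  if (kind == "hopping") {
    if (is.null(hop_s) || hop_s <= 0) {
      stop("window_spec: hop_s must be positive for hopping windows")
    }
  }
  if (kind == "session") {
    if (is.null(timeout_s) || is.null(max_duration_s) || is.null(baseline_s) ||
        timeout_s <= 0 || max_duration_s <= 0 || baseline_s <= 0) {
      stop("window_spec: session windows need positive timeout_s, ",
           "max_duration_s and baseline_s")
    }
    if (timeout_s > max_duration_s) {
      stop("window_spec: timeout_s must not exceed max_duration_s")
    }
    if (!event_channel %in% .event_channels) {
      stop("window_spec: unknown event channel '", event_channel,
           "'; choose one of ", paste(.event_channels, collapse = ", "))
    }
  }
  structure(list(kind = kind, size_s = size_s, hop_s = hop_s,
                 timeout_s = timeout_s, max_duration_s = max_duration_s,
                 baseline_s = baseline_s, event_channel = event_channel,
                 multiplier = multiplier, min_fill = min_fill),
            class = "window_spec")
}

.slice_frame <- function(start, end, kind) {
  data.frame(index = seq_along(start), start_s = start, end_s = end,
             kind = if (length(start)) kind else character(0),
             stringsAsFactors = FALSE)
}

#' Tumbling windows
#'
#' Non-overlapping, fixed-size, contiguous slices `[0, W), [W, 2W), ...`
#' covering the recording; a final partial window is emitted when its fill
#' fraction reaches `min_fill`.
#'
#' @param total_duration_s Recording duration.
#' @param size_s Window size, > 0.
#' @param min_fill Minimum fill fraction for the last partial window.
#' @return data.frame `index`, `start_s`, `end_s`, `kind`.
#' @export
tumbling_windows <- function(total_duration_s, size_s, min_fill = 0) {
  if (!is.numeric(size_s) || size_s <= 0) stop("tumbling: size_s must be > 0")
  if (total_duration_s <= 0) return(.slice_frame(numeric(0), numeric(0), "tumbling"))
  starts <- seq(0, total_duration_s, by = size_s)
  starts <- starts[starts < total_duration_s - 1e-9]
  ends <- pmin(starts + size_s, total_duration_s)
  fill <- (ends - starts) / size_s
  keep <- fill >= min_fill | ends - starts == size_s
  .slice_frame(starts[keep], ends[keep], "tumbling")
}

#' Expanding windows
#'
#' Overlapping, growing slices anchored at 0: `[0, s), [0, 2s), ...`, the
#' last always covering the full recording.
#'
#' @param total_duration_s Recording duration.
#' @param step_s Expansion step, > 0.
#' @return data.frame `index`, `start_s`, `end_s`, `kind`.
#' @export
expanding_windows <- function(total_duration_s, step_s) {
  if (!is.numeric(step_s) || step_s <= 0) stop("expanding: step_s must be > 0")
  if (total_duration_s <= 0) return(.slice_frame(numeric(0), numeric(0), "expanding"))
  ends <- if (step_s >= total_duration_s) numeric(0)
          else seq(step_s, total_duration_s, by = step_s)
  if (!length(ends) || max(ends) < total_duration_s - 1e-9) {
    ends <- c(ends, total_duration_s)
  } else {
    ends[length(ends)] <- max(ends[length(ends)], total_duration_s)
  }
  .slice_frame(rep(0, length(ends)), ends, "expanding")
}

#' Hopping windows
#'
#' Overlapping fixed-size slices `[k*hop, k*hop + size)` for k = 0, 1, ...,
#' while the start lies inside the recording; ends are clamped to the
#' recording duration. `hop_s = size_s` reproduces tumbling windows exactly.
#'
#' @param total_duration_s Recording duration.
#' @param size_s Window size, > 0.
#' @param hop_s Hop size, > 0.
#' @param min_fill Minimum fill fraction for final partial windows.
#' @return data.frame `index`, `start_s`, `end_s`, `kind`.
#' @export
hopping_windows <- function(total_duration_s, size_s, hop_s, min_fill = 0) {
  if (!is.numeric(size_s) || size_s <= 0 || !is.numeric(hop_s) || hop_s <= 0) {
    stop("hopping: size_s and hop_s must be > 0")
  }
  if (total_duration_s <= 0) return(.slice_frame(numeric(0), numeric(0), "hopping"))
  starts <- seq(0, total_duration_s, by = hop_s)
  starts <- starts[starts < total_duration_s - 1e-9]
  ends <- pmin(starts + size_s, total_duration_s)
  fill <- (ends - starts) / size_s
  keep <- fill >= min_fill | ends - starts == size_s
  .slice_frame(starts[keep], ends[keep], "hopping")
}

#' Extract a feature-channel time series from gaze data
#'
#' Builds the `(time_s, value)` stream a baseline or event detector operates
#' on: saccade magnitude (px, at saccade onset), saccade direction change
#' (the absolute turn angle, since raw direction has no "higher" ordering),
#' per-eye / averaged pupil diameter (per sample), fixation duration (at
#' fixation start) or blink rate (rolling count over the trailing
#' `rolling_s` seconds, per sample).
#'
#' @param channel One of the supported channel names.
#' @param fixations `fixation_records`.
#' @param samples `gaze_samples` (needed for pupil and blink channels).
#' @param geometry A [screen_geometry()].
#' @param rolling_s Horizon of the rolling blink-rate estimate.
#' @return data.frame `time_s`, `value` (rows with `NA` values dropped).
#' @export
channel_stream <- function(channel, fixations, samples = NULL,
                           geometry = screen_geometry(), rolling_s = 60) {
  channel <- match.arg(channel, .event_channels)
  out <- switch(
    channel,
    SACCADE_MAG = {
      s <- derive_saccades(fixations, geometry)
      data.frame(time_s = s$start_s, value = s$magnitude_px)
    },
    SACCADE_DIR = {
      s <- derive_saccades(fixations, geometry)
      data.frame(time_s = s$start_s, value = s$relative_direction_deg)
    },
    FIXATION_DUR = data.frame(time_s = fixations$start_s,
                              value = fixations$duration_s),
    LPUPIL_DIAM = data.frame(time_s = samples$time_s,
                             value = samples$left_pupil_mm),
    RPUPIL_DIAM = data.frame(time_s = samples$time_s,
                             value = samples$right_pupil_mm),
    AVG_PUPIL_DIAM = data.frame(
      time_s = samples$time_s,
      value = (samples$left_pupil_mm + samples$right_pupil_mm) / 2),
    BLINK_RATE = {
      if (is.null(samples) || !nrow(samples)) {
        data.frame(time_s = numeric(0), value = numeric(0))
      } else {
        t <- samples$time_s
        ids <- samples$blink_id
        onset <- !is.na(ids) & ids > 0 &
          c(TRUE, diff(ifelse(is.na(ids), 0, ids)) != 0)
        onset_t <- t[onset]
        val <- vapply(t, function(tt) {
          sum(onset_t > tt - rolling_s & onset_t <= tt) * 60 /
            min(rolling_s, max(tt, 1e-9))
        }, numeric(1))
        data.frame(time_s = t, value = val)
      }
    }
  )
  out <- out[!is.na(out$value) & !is.na(out$time_s), , drop = FALSE]
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Establish a per-person baseline for a feature channel
#'
#' The baseline is the mean of all channel observations with
#' `time_s < baseline_duration_s` — typical behaviour captured during the
#' initial, low-demand phase of a task. An empty baseline period is an
#' error, since event detection (and session windows) cannot run without it.
#'
#' @param stream data.frame `time_s`, `value` from [channel_stream()].
#' @param channel Channel name recorded in the profile.
#' @param baseline_duration_s Length of the baseline period, > 0.
#' @return A `baseline_profile` list: `channel`, `value`, `baseline_s`, `n`.
#' @export
establish_baseline <- function(stream, channel, baseline_duration_s) {
  stopifnot(baseline_duration_s > 0)
  sel <- stream$time_s < baseline_duration_s & !is.na(stream$value)
  if (!any(sel)) {
    stop("establish_baseline: no ", channel,
         " observations inside the baseline period [0, ",
         baseline_duration_s, ")")
  }
  structure(list(channel = channel, value = mean(stream$value[sel]),
                 baseline_s = baseline_duration_s, n = sum(sel)),
            class = "baseline_profile")
}

#' Detect irregular gaze events against a baseline
#'
#' Every post-baseline observation whose value is strictly greater than
#' `multiplier * baseline` is flagged as an irregular gaze event, in time
#' order. With the default multiplier of 1 this is "any value higher than
#' the baseline mean".
#'
#' @param stream data.frame `time_s`, `value`.
#' @param baseline A `baseline_profile` from [establish_baseline()].
#' @param multiplier Threshold multiplier (> raises, < lowers sensitivity).
#' @return data.frame `time_s`, `value`, `baseline`, `channel`.
#' @export
detect_events <- function(stream, baseline, multiplier = 1) {
  sel <- stream$time_s >= baseline$baseline_s & !is.na(stream$value) &
    stream$value > multiplier * baseline$value
  ev <- stream[sel, c("time_s", "value"), drop = FALSE]
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev$baseline <- rep(baseline$value, nrow(ev))
  ev$channel <- rep(baseline$channel, nrow(ev))
  ev
}

#' Event-driven session windows
#'
#' A window opens at the first unconsumed event. Each further event arriving
#' within `timeout_s` of the previous one renews the timeout; the window
#' closes at `last_event + timeout_s` or at `open + max_duration_s`,
#' whichever comes first. The next window opens at the first event after the
#' close, so windows never overlap.
#'
#' @param event_times Numeric vector of event times (any order; events from
#'   [detect_events()] pass their `time_s` column).
#' @param timeout_s Renewal timeout, > 0.
#' @param max_duration_s Hard cap on window length, >= `timeout_s`.
#' @return data.frame `index`, `start_s`, `end_s`, `kind`, `n_events`.
#' @export
session_windows <- function(event_times, timeout_s, max_duration_s) {
  stopifnot(timeout_s > 0, max_duration_s >= timeout_s)
  ev <- sort(event_times[!is.na(event_times)])
  starts <- numeric(0); ends <- numeric(0); nev <- integer(0)
  i <- 1
  n <- length(ev)
  while (i <= n) {
    open <- ev[i]
    cap <- open + max_duration_s
    close <- min(open + timeout_s, cap)
    count <- 1L
    j <- i + 1
    while (j <= n && ev[j] < close) {
      count <- count + 1L
      close <- min(ev[j] + timeout_s, cap)
      j <- j + 1
    }
    starts <- c(starts, open); ends <- c(ends, close)
    nev <- c(nev, count)
    i <- j
  }
  out <- .slice_frame(starts, ends, "session")
  out$n_events <- nev
  out
}

#' Materialize window slices for any strategy
#'
#' Dispatches on the spec kind; session windows run the full baseline /
#' event-detection chain on the configured channel.
#'
#' @param spec A [window_spec()].
#' @param total_duration_s Recording duration.
#' @param fixations,samples Gaze data (needed for session windows).
#' @param geometry A [screen_geometry()].
#' @return Slice data.frame as returned by the strategy functions.
#' @export
make_windows <- function(spec, total_duration_s, fixations = NULL,
                         samples = NULL, geometry = screen_geometry()) {
  switch(
    spec$kind,
    tumbling = tumbling_windows(total_duration_s, spec$size_s, spec$min_fill),
    expanding = expanding_windows(total_duration_s, spec$size_s),
    hopping = hopping_windows(total_duration_s, spec$size_s, spec$hop_s,
                              spec$min_fill),
    session = {
      stream <- channel_stream(spec$event_channel, fixations, samples,
                               geometry)
      bl <- establish_baseline(stream, spec$event_channel, spec$baseline_s)
      ev <- detect_events(stream, bl, spec$multiplier)
      session_windows(ev$time_s, spec$timeout_s, spec$max_duration_s)
    }
  )
}

#' Per-window DGM records
#'
#' Computes one full DGM record per window slice. An item (fixation or
#' sample) belongs to a slice iff its start time lies in
#' `[start_s, end_s)`; saccades are re-derived within each slice. Slices
#' containing no fixations still produce a record (all measures `NA`,
#' flagged `empty`).
#'
#' @param fixations Cleaned `fixation_records`.
#' @param samples Optional cleaned `gaze_samples`.
#' @param spec A [window_spec()].
#' @param geometry A [screen_geometry()].
#' @param total_duration_s Recording duration; defaults to the observed span.
#' @param scope Participant id recorded in the output rows.
#' @param include_aoi Include AOI measures.
#' @return A `dgm_record` data.frame, one row per window, with scope columns
#'   plus `window_index`, `window_start_s`, `window_end_s`, `empty`.
#' @export
windowed_dgms <- function(fixations, samples = NULL, spec,
                          geometry = screen_geometry(),
                          total_duration_s = NULL, scope = "participant",
                          include_aoi = TRUE) {
  if (is.null(total_duration_s)) {
    ends <- c(fixations$start_s + fixations$duration_s,
              if (!is.null(samples)) samples$time_s)
    total_duration_s <- if (length(ends)) max(ends, na.rm = TRUE) else 0
  }
  slices <- make_windows(spec, total_duration_s, fixations, samples, geometry)
  if (!nrow(slices)) {
    out <- data.frame()
    attr(out, "slices") <- slices
    return(out)
  }
  rows <- lapply(seq_len(nrow(slices)), function(k) {
    s <- slices$start_s[k]; e <- slices$end_s[k]
    fx <- fixations[fixations$start_s >= s & fixations$start_s < e, ,
                    drop = FALSE]
    class(fx) <- class(fixations)
    sm <- if (!is.null(samples)) {
      keep <- samples$time_s >= s & samples$time_s < e
      out <- samples[keep, , drop = FALSE]
      class(out) <- class(samples)
      out
    } else NULL
    rec <- summative_dgms(fx, sm, geometry, duration_s = e - s,
                          include_aoi = include_aoi, scope = scope)
    rec$window <- paste0(spec$kind, "_w", slices$index[k])
    rec$window_index <- slices$index[k]
    rec$window_start_s <- s
    rec$window_end_s <- e
    rec$empty <- nrow(fx) == 0
    rec
  })
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[all_names]
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dgm_record", "data.frame")
  attr(out, "slices") <- slices
  out
}
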