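# Saccade derivation and the non-AOI descriptive gaze measures (DGMs).

#' Six-number descriptive statistics
#'
#' The summary applied to every gaze value channel: sum, mean, median,
#' sample standard deviation (n-1 denominator; 0 for a single value), min and
#' max. `NA`s are dropped first; an empty (or all-`NA`) input yields all-`NA`
#' statistics, never zeros.
#'
#' @param values Numeric vector.
#' @return Named numeric vector `c(sum, mean, median, sd, min, max)`.
#' @export
describe <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) {
    return(c(sum = NA_real_, mean = NA_real_, median = NA_real_,
             sd = NA_real_, min = NA_real_, max = NA_real_))
  }
  c(sum = sum(v), mean = mean(v), median = stats::median(v),
    sd = if (length(v) == 1) 0 else stats::sd(v),
    min = min(v), max = max(v))
}

#' Derive saccades from an ordered fixation stream
#'
#' A saccade is the movement between two consecutive fixations: it spans from
#' the end of fixation k (`start_s + duration_s`) to the start of fixation
#' k+1. Magnitude is the Euclidean pixel distance between the fixation
#' positions; amplitude converts that distance to visual angle; velocity is
#' amplitude over duration. Overlapping fixation records (non-positive gaps)
#' are clamped to zero duration and flagged. When the raw sample stream is
#' supplied, peak velocity is the maximum smoothed sample-to-sample angular
#' speed within the saccade span (central differences, 3-sample moving
#' average); otherwise it is `NA`.
#'
#' Directions use a y-up convention: 0 deg = rightward, 90 deg = upward,
#' absolute direction in [0, 360); relative direction is the absolute turn
#' angle versus the previous saccade, folded into [0, 180], `NA` for the
#' first saccade.
#'
#' @param fixations `fixation_records`, sorted by `start_s`.
#' @param geometry A [screen_geometry()].
#' @param samples Optional `gaze_samples` for peak-velocity estimation.
#' @return A data.frame of class `saccade_records`; empty for fewer than two
#'   fixations.
#' @export
derive_saccades <- function(fixations, geometry = screen_geometry(),
                            samples = NULL) {
  n <- nrow(fixations)
  empty <- data.frame(from_fixation_id = integer(0), to_fixation_id = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      magnitude_px = numeric(0), duration_s = numeric(0),
                      amplitude_deg = numeric(0), velocity_deg_s = numeric(0),
                      peak_velocity_deg_s = numeric(0),
                      absolute_direction_deg = numeric(0),
                      relative_direction_deg = numeric(0),
                      clamped = logical(0))
  if (is.null(n) || n < 2) {
    class(empty) <- c("saccade_records", "data.frame")
    return(empty)
  }
  i <- seq_len(n - 1)
  start_s <- fixations$start_s[i] + fixations$duration_s[i]
  end_s <- fixations$start_s[i + 1]
  gap <- end_s - start_s
  clamped <- gap < 0
  duration_s <- pmax(gap, 0)
  dx <- fixations$x_px[i + 1] - fixations$x_px[i]
  dy <- fixations$y_px[i + 1] - fixations$y_px[i]
  magnitude_px <- sqrt(dx^2 + dy^2)
  amplitude_deg <- px_to_degrees(magnitude_px, geometry)
  velocity_deg_s <- ifelse(duration_s > 0, amplitude_deg / duration_s,
                           NA_real_)
  # screen y grows downward; flip so angles follow the mathematical convention
  abs_dir <- atan2(-dy, dx) * 180 / pi
  abs_dir <- (abs_dir + 360) %% 360
  abs_dir[magnitude_px == 0] <- NA_real_
  rel_dir <- rep(NA_real_, n - 1)
  if (n > 2) {
    d <- abs(diff(abs_dir)) %% 360
    rel_dir[-1] <- pmin(d, 360 - d)
  }
  peak <- rep(NA_real_, n - 1)
  if (!is.null(samples) && nrow(samples) > 0) {
    for (k in i) {
      peak[k] <- .peak_velocity(samples, start_s[k], end_s[k], geometry)
    }
  }
  out <- data.frame(
    from_fixation_id = fixations$fixation_id[i],
    to_fixation_id = fixations$fixation_id[i + 1],
    start_s = start_s, end_s = end_s,
    magnitude_px = magnitude_px, duration_s = duration_s,
    amplitude_deg = amplitude_deg, velocity_deg_s = velocity_deg_s,
    peak_velocity_deg_s = peak,
    absolute_direction_deg = abs_dir,
    relative_direction_deg = rel_dir,
    clamped = clamped
  )
  class(out) <- c("saccade_records", "data.frame")
  out
}

# Maximum smoothed angular speed of the point of gaze within [t0, t1].
.peak_velocity <- function(samples, t0, t1, geometry) {
  sel <- !is.na(samples$time_s) & samples$time_s >= t0 & samples$time_s <= t1 &
    !is.na(samples$pog_x) & !is.na(samples$pog_y)
  t <- samples$time_s[sel]
  if (length(t) < 3) return(NA_real_)
  x <- samples$pog_x[sel] * geometry$width_px
  y <- samples$pog_y[sel] * geometry$height_px
  m <- length(t)
  idx <- 2:(m - 1)
  dpx <- sqrt((x[idx + 1] - x[idx - 1])^2 + (y[idx + 1] - y[idx - 1])^2)
  dt <- t[idx + 1] - t[idx - 1]
  ok <- dt > 0
  if (!any(ok)) return(NA_real_)
  speed <- px_to_degrees(dpx[ok], geometry) / dt[ok]
  if (length(speed) >= 3) {
    speed <- stats::filter(speed, rep(1 / 3, 3), sides = 2)
    speed <- speed[!is.na(speed)]
  }
  if (!length(speed)) return(NA_real_)
  max(speed)
}

#' Convex-hull area of a point set
#'
#' The area of the smallest convex polygon containing all points, used as a
#' gaze-dispersion measure over fixation positions. Fewer than three distinct
#' points, or a fully collinear set, has area 0.
#'
#' @param x,y Point coordinates (pixels).
#' @return Area in squared pixels.
#' @export
convex_hull_area <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  pts <- unique(cbind(x[ok], y[ok]))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  # shoelace formula
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Blink rate in blinks per minute
#'
#' Counts distinct blink identifiers in the sample stream (id 0 or `NA`
#' means "no ongoing blink") and scales to a per-minute rate. When the
#' tracker export already carries a blink-rate channel, `use_export = TRUE`
#' returns the mean of that channel instead.
#'
#' @param samples `gaze_samples`.
#' @param duration_s Recording (or window) duration in seconds, > 0.
#' @param use_export Use the tracker-exported rate channel if present.
#' @return Blinks per minute.
#' @export
blink_rate <- function(samples, duration_s, use_export = FALSE) {
  if (!is.numeric(duration_s) || is.na(duration_s) || duration_s <= 0) {
    stop("blink_rate: duration_s must be positive")
  }
  if (use_export) {
    v <- samples$blink_rate_export
    v <- v[!is.na(v)]
    if (length(v)) return(mean(v))
    return(NA_real_)
  }
  ids <- samples$blink_id
  ids <- ids[!is.na(ids) & ids > 0]
  length(unique(ids)) * 60 / duration_s
}

#' Pupil-diameter measures
#'
#' Mean left, mean right, and combined pupil diameter; the combined mean
#' averages the per-sample two-eye means over samples where both eyes are
#' present. When a baseline is given (per-eye means observed during a
#' low-demand period), dilation change = mean - baseline is reported per eye
#' and combined. Sessions without pupil data yield all-`NA` measures.
#'
#' @param samples Cleaned `gaze_samples`.
#' @param baseline Optional list with elements `left` and `right` (mm).
#' @return Named numeric vector of pupil measures.
#' @export
pupil_dgms <- function(samples, baseline = NULL) {
  l <- samples$left_pupil_mm
  r <- samples$right_pupil_mm
  lmean <- if (any(!is.na(l))) mean(l, na.rm = TRUE) else NA_real_
  rmean <- if (any(!is.na(r))) mean(r, na.rm = TRUE) else NA_real_
  both <- (l + r) / 2
  bmean <- if (any(!is.na(both))) mean(both, na.rm = TRUE) else NA_real_
  out <- c(pupil_left_mean_mm = lmean,
           pupil_right_mean_mm = rmean,
           pupil_both_mean_mm = bmean)
  if (!is.null(baseline)) {
    bl <- baseline$left
    br <- baseline$right
    bb <- mean(c(bl, br))
    out <- c(out,
             pupil_left_change_mm = lmean - bl,
             pupil_right_change_mm = rmean - br,
             pupil_both_change_mm = bmean - bb)
  }
  out
}

#' Fixation-to-saccade ratio
#'
#' Total fixation time divided by total saccade time: time spent processing
#' information relative to time spent searching for it. Undefined (`NA`)
#' when there is no saccade time.
#'
#' @param fixations `fixation_records`.
#' @param saccades `saccade_records`.
#' @return A single ratio, or `NA`.
#' @export
fixation_saccade_ratio <- function(fixations, saccades) {
  st <- sum(saccades$duration_s, na.rm = TRUE)
  if (nrow(saccades) == 0 || st <= 0) return(NA_real_)
  sum(fixations$duration_s, na.rm = TRUE) / st
}

#' Scanpath duration
#'
#' Total time of eye movements: the sum of all fixation and saccade
#' durations.
#'
#' @inheritParams fixation_saccade_ratio
#' @return Seconds.
#' @export
scanpath_duration <- function(fixations, saccades) {
  sum(fixations$duration_s, na.rm = TRUE) +
    sum(saccades$duration_s, na.rm = TRUE)
}

# prefix a describe() vector: saccade_magnitude_sum, ...
.stats_block <- function(prefix, values) {
  s <- describe(values)
  names(s) <- paste0(prefix, "_", names(s))
  s
}

#' The full summative DGM record for one recording
#'
#' Computes every measure in the catalogue over the whole recording:
#' fixation count and duration statistics, saccade count plus six-number
#' statistics of magnitude, duration, amplitude, velocity, peak velocity and
#' both direction channels, convex-hull area, blink rate, pupil means (and
#' baseline-relative changes when a baseline is given), fixation-to-saccade
#' ratio and scanpath duration. When fixations carry AOI labels, stationary
#' and transition entropy and per-AOI fixation proportions are included.
#' Undefined measures are `NA`, never 0.
#'
#' @param fixations `fixation_records` (cleaned).
#' @param samples Optional cleaned `gaze_samples` (enables blink, pupil and
#'   peak-velocity measures).
#' @param geometry A [screen_geometry()].
#' @param duration_s Recording duration; defaults to the observed span.
#' @param pupil_baseline Optional per-eye baseline list for dilation change.
#' @param include_aoi Include AOI measures when labels are present.
#' @param scope Participant identifier recorded in the output.
#' @return A one-row data.frame (class `dgm_record`): scope columns
#'   (`participant`, `window`, `aoi`) plus the flat measure map.
#' @export
summative_dgms <- function(fixations, samples = NULL,
                           geometry = screen_geometry(),
                           duration_s = NULL, pupil_baseline = NULL,
                           include_aoi = TRUE, scope = "participant") {
  saccades <- derive_saccades(fixations, geometry, samples)
  if (is.null(duration_s)) {
    ends <- c(fixations$start_s + fixations$duration_s,
              if (!is.null(samples)) samples$time_s)
    duration_s <- if (length(ends)) max(ends, na.rm = TRUE) else NA_real_
  }
  m <- c(
    fixation_count = as.numeric(nrow(fixations)),
    .stats_block("fixation_duration", fixations$duration_s),
    saccade_count = as.numeric(nrow(saccades)),
    .stats_block("saccade_magnitude", saccades$magnitude_px),
    .stats_block("saccade_duration", saccades$duration_s),
    .stats_block("saccade_amplitude", saccades$amplitude_deg),
    .stats_block("saccade_velocity", saccades$velocity_deg_s),
    .stats_block("saccade_peak_velocity", saccades$peak_velocity_deg_s),
    .stats_block("saccade_abs_direction", saccades$absolute_direction_deg),
    .stats_block("saccade_rel_direction", saccades$relative_direction_deg),
    convex_hull_area_px2 = convex_hull_area(fixations$x_px, fixations$y_px),
    blink_rate_per_min = if (!is.null(samples) && !is.na(duration_s) &&
                             duration_s > 0) {
      blink_rate(samples, duration_s)
    } else NA_real_,
    fixation_saccade_ratio = fixation_saccade_ratio(fixations, saccades),
    scanpath_duration_s = scanpath_duration(fixations, saccades)
  )
  if (!is.null(samples)) {
    m <- c(m, pupil_dgms(samples, pupil_baseline))
  } else {
    m <- c(m, pupil_left_mean_mm = NA_real_, pupil_right_mean_mm = NA_real_,
           pupil_both_mean_mm = NA_real_)
  }
  if (include_aoi && any(!is.na(fixations$aoi_label))) {
    tm <- transition_counts(fixations$aoi_label)
    m <- c(m,
           stationary_entropy_bits = stationary_entropy(fixations$aoi_label),
           transition_entropy_bits = transition_entropy(tm))
    props <- aoi_fixation_proportions(fixations)
    if (nrow(props)) {
      pv <- c(stats::setNames(props$prop_count,
                              paste0("aoi_", props$aoi, "_fixation_prop")),
              stats::setNames(props$prop_duration,
                              paste0("aoi_", props$aoi, "_duration_prop")))
      m <- c(m, pv)
    }
  }
  rec <- data.frame(participant = scope, window = "summative", aoi = "all",
                    t(m), stringsAsFactors = FALSE, check.names = FALSE)
  class(rec) <- c("dgm_record", "data.frame")
  rec
}

#' Group-level DGMs for a batch of participants
#'
#' Two aggregation modes are provided. `"pooled"` derives each participant's
#' fixations and saccades individually (so no artificial saccade spans
#' participant boundaries), pools the resulting event values and computes the
#' statistics over the pooled values; counts are additive and the convex
#' hull covers all fixations. `"mean_of_persons"` computes each person's
#' summative record and averages the records measure-by-measure.
#'
#' @param participants Named list; each element a list with `fixations` and
#'   optionally `samples`.
#' @param mode `"pooled"` or `"mean_of_persons"`.
#' @param geometry A [screen_geometry()].
#' @param include_aoi Include AOI measures.
#' @return A one-row `dgm_record` with `participant = "group:<mode>"`.
#' @export
group_dgms <- function(participants, mode = c("pooled", "mean_of_persons"),
                       geometry = screen_geometry(), include_aoi = TRUE) {
  mode <- match.arg(mode)
  if (!length(participants)) stop("group_dgms: empty group")
  records <- lapply(names(participants), function(id) {
    p <- participants[[id]]
    summative_dgms(p$fixations, p$samples, geometry,
                   include_aoi = include_aoi, scope = id)
  })
  if (mode == "mean_of_persons") {
    all_names <- unique(unlist(lapply(records, names)))
    meas <- setdiff(all_names, c("participant", "window", "aoi"))
    vals <- vapply(meas, function(nm) {
      v <- vapply(records, function(r) {
        if (nm %in% names(r)) as.numeric(r[[nm]]) else NA_real_
      }, numeric(1))
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    rec <- data.frame(participant = "group:mean_of_persons",
                      window = "summative", aoi = "all", t(vals),
                      stringsAsFactors = FALSE, check.names = FALSE)
    class(rec) <- c("dgm_record", "data.frame")
    return(rec)
  }
  # pooled
  fx <- lapply(participants, function(p) as.data.frame(p$fixations))
  sc <- lapply(participants, function(p) {
    as.data.frame(derive_saccades(p$fixations, geometry, p$samples))
  })
  fx_all <- do.call(rbind, fx)
  sc_all <- do.call(rbind, sc)
  class(sc_all) <- c("saccade_records", "data.frame")
  durations <- vapply(participants, function(p) {
    ends <- c(p$fixations$start_s + p$fixations$duration_s,
              if (!is.null(p$samples)) p$samples$time_s)
    if (length(ends)) max(ends, na.rm = TRUE) else 0
  }, numeric(1))
  total_dur <- sum(durations)
  n_blinks <- sum(vapply(participants, function(p) {
    if (is.null(p$samples)) return(0L)
    ids <- p$samples$blink_id
    length(unique(ids[!is.na(ids) & ids > 0]))
  }, integer(1)))
  m <- c(
    fixation_count = as.numeric(nrow(fx_all)),
    .stats_block("fixation_duration", fx_all$duration_s),
    saccade_count = as.numeric(nrow(sc_all)),
    .stats_block("saccade_magnitude", sc_all$magnitude_px),
    .stats_block("saccade_duration", sc_all$duration_s),
    .stats_block("saccade_amplitude", sc_all$amplitude_deg),
    .stats_block("saccade_velocity", sc_all$velocity_deg_s),
    .stats_block("saccade_peak_velocity", sc_all$peak_velocity_deg_s),
    .stats_block("saccade_abs_direction", sc_all$absolute_direction_deg),
    .stats_block("saccade_rel_direction", sc_all$relative_direction_deg),
    convex_hull_area_px2 = convex_hull_area(fx_all$x_px, fx_all$y_px),
    blink_rate_per_min = if (total_dur > 0) n_blinks * 60 / total_dur
                         else NA_real_,
    fixation_saccade_ratio = {
      st <- sum(sc_all$duration_s, na.rm = TRUE)
      if (st > 0) sum(fx_all$duration_s, na.rm = TRUE) / st else NA_real_
    },
    scanpath_duration_s = sum(fx_all$duration_s, na.rm = TRUE) +
      sum(sc_all$duration_s, na.rm = TRUE)
  )
  pl <- unlist(lapply(participants,
                      function(p) p$samples$left_pupil_mm))
  pr <- unlist(lapply(participants,
                      function(p) p$samples$right_pupil_mm))
  pool_samples <- data.frame(left_pupil_mm = if (is.null(pl)) numeric(0) else pl,
                             right_pupil_mm = if (is.null(pr)) numeric(0) else pr)
  m <- c(m, pupil_dgms(pool_samples))
  if (include_aoi && any(!is.na(fx_all$aoi_label))) {
    # transitions within, never across, participants
    tms <- lapply(fx, function(f) transition_counts(f$aoi_label))
    tm <- .merge_transition_matrices(tms)
    m <- c(m,
           stationary_entropy_bits = stationary_entropy(fx_all$aoi_label),
           transition_entropy_bits = transition_entropy(tm))
    props <- aoi_fixation_proportions(fx_all)
    if (nrow(props)) {
      m <- c(m,
             stats::setNames(props$prop_count,
                             paste0("aoi_", props$aoi, "_fixation_prop")),
             stats::setNames(props$prop_duration,
                             paste0("aoi_", props$aoi, "_duration_prop")))
    }
  }
  rec <- data.frame(participant = "group:pooled", window = "summative",
                    aoi = "all", t(m), stringsAsFactors = FALSE,
                    check.names = FALSE)
  class(rec) <- c("dgm_record", "data.frame")
  rec
}

.merge_transition_matrices <- function(mats) {
  labs <- sort(unique(unlist(lapply(mats, rownames))))
  out <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  for (m in mats) {
    if (length(m)) out[rownames(m), colnames(m)] <-
        out[rownames(m), colnames(m)] + m
  }
  out
}
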