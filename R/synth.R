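# Synthetic gaze sessions with known ground truth, in the Gazepoint-style
# CSV dialect, so every analysis stage is testable without recorded data.

#' Recipe for a synthetic gaze session
#'
#' Defines the generative model: a first-order Markov scanpath over
#' rectangular AOIs (so the stationary and transition entropies of the
#' generated data have analytically known targets), log-normal fixation
#' durations, saccade gaps that grow with amplitude (main-sequence-like),
#' a Poisson blink process, a slowly drifting noisy pupil trace, and
#' optional injected artifacts whose counts the rejection audit must
#' reproduce exactly.
#'
#' Defaults emulate a typical desktop-tracker session: 60 Hz sampling,
#' 250 ms mean fixation duration, four quadrant AOIs, 12 blinks/min,
#' 3.5 mm pupils.
#'
#' @param duration_s Session length in seconds.
#' @param sample_rate_hz Tracker sampling rate.
#' @param aoi_layout Named list of AOI rectangles
#'   `c(x0, y0, x1, y1)` in normalized screen coordinates.
#' @param fixation_mean_s,fixation_sd_s Mean and SD of the log-normal
#'   fixation-duration distribution (seconds).
#' @param transition_matrix Row-stochastic AOI transition matrix (rows and
#'   columns in `names(aoi_layout)` order); default: uniform over the other
#'   AOIs with a 0.1 self-transition probability.
#' @param blink_rate_per_min Poisson blink rate.
#' @param pupil_left_mm,pupil_right_mm Per-eye baseline pupil diameters.
#' @param pupil_drift_mm,pupil_noise_sd Amplitude of the slow sinusoidal
#'   pupil drift and SD of the per-sample noise.
#' @param invalid_rate,off_screen_rate,pupil_spike_rate Artifact rates as a
#'   fraction of sample rows (each artifact hits a distinct row).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `session_recipe` list.
#' @export
session_recipe <- function(duration_s = 300, sample_rate_hz = 60,
                           aoi_layout = list(
                             A = c(0.05, 0.05, 0.45, 0.45),
                             B = c(0.55, 0.05, 0.95, 0.45),
                             C = c(0.05, 0.55, 0.45, 0.95),
                             D = c(0.55, 0.55, 0.95, 0.95)),
                           fixation_mean_s = 0.25, fixation_sd_s = 0.1,
                           transition_matrix = NULL,
                           blink_rate_per_min = 12,
                           pupil_left_mm = 3.5, pupil_right_mm = 3.5,
                           pupil_drift_mm = 0.2, pupil_noise_sd = 0.05,
                           invalid_rate = 0, off_screen_rate = 0,
                           pupil_spike_rate = 0, seed = 1) {
  if (duration_s <= 0) stop("session_recipe: duration_s must be > 0")
  if (!length(aoi_layout)) stop("session_recipe: need at least one AOI")
  stopifnot(sample_rate_hz > 0, fixation_mean_s > 0, fixation_sd_s >= 0,
            blink_rate_per_min >= 0, invalid_rate >= 0,
            off_screen_rate >= 0, pupil_spike_rate >= 0)
  k <- length(aoi_layout)
  for (r in aoi_layout) {
    if (length(r) != 4 || any(r < 0) || any(r > 1) || r[1] >= r[3] ||
        r[2] >= r[4]) {
      stop("session_recipe: AOI rectangles must be c(x0,y0,x1,y1) in [0,1]")
    }
  }
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(if (k > 1) 0.9 / (k - 1) else 0, k, k,
                                dimnames = list(names(aoi_layout),
                                                names(aoi_layout)))
    diag(transition_matrix) <- if (k > 1) 0.1 else 1
  }
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-8)) {
    stop("session_recipe: transition matrix rows must sum to 1")
  }
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 aoi_layout = aoi_layout,
                 fixation_mean_s = fixation_mean_s,
                 fixation_sd_s = fixation_sd_s,
                 transition_matrix = transition_matrix,
                 blink_rate_per_min = blink_rate_per_min,
                 pupil_left_mm = pupil_left_mm,
                 pupil_right_mm = pupil_right_mm,
                 pupil_drift_mm = pupil_drift_mm,
                 pupil_noise_sd = pupil_noise_sd,
                 invalid_rate = invalid_rate,
                 off_screen_rate = off_screen_rate,
                 pupil_spike_rate = pupil_spike_rate, seed = seed),
            class = "session_recipe")
}

# run code under the recipe's seed without touching the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic gaze session
#'
#' Simulates the scanpath, the 60 Hz sample stream consistent with it
#' (samples jitter around the current fixation; saccade traversals follow a
#' smooth symmetric velocity profile, so peak velocity exceeds mean velocity
#' by construction), the pupil and blink channels, and any configured
#' artifacts. Deterministic given the recipe seed.
#'
#' @param recipe A [session_recipe()].
#' @param geometry A [screen_geometry()] for the pixel conversion of
#'   fixation positions.
#' @return A list: `samples` (`gaze_samples`), `fixations`
#'   (`fixation_records`) and `truth`, a ground-truth summary with the
#'   realized AOI sequence and counts, mean fixation duration, mean saccade
#'   magnitude, blink count and injected artifact counts.
#' @export
generate_session <- function(recipe, geometry = screen_geometry()) {
  stopifnot(inherits(recipe, "session_recipe"))
  .with_seed(recipe$seed, {
    labs <- names(recipe$aoi_layout)
    k <- length(labs)
    # log-normal parameters from the target mean/sd on the seconds scale
    m <- recipe$fixation_mean_s; s <- recipe$fixation_sd_s
    sdlog <- sqrt(log(1 + (s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2

    fix_start <- numeric(0); fix_dur <- numeric(0)
    fix_x <- numeric(0); fix_y <- numeric(0); fix_aoi <- character(0)
    t <- 0
    aoi <- sample.int(k, 1)
    while (t < recipe$duration_s) {
      dur <- if (s > 0) stats::rlnorm(1, meanlog, sdlog) else m
      rect <- recipe$aoi_layout[[aoi]]
      x <- stats::runif(1, rect[1], rect[3])
      y <- stats::runif(1, rect[2], rect[4])
      fix_start <- c(fix_start, t); fix_dur <- c(fix_dur, dur)
      fix_x <- c(fix_x, x); fix_y <- c(fix_y, y)
      fix_aoi <- c(fix_aoi, labs[aoi])
      t <- t + dur
      nxt <- sample.int(k, 1, prob = recipe$transition_matrix[aoi, ])
      aoi <- nxt
      # inter-fixation gap: 20-50 ms, the realistic saccade-duration range
      t <- t + 0.02 + 0.03 * stats::runif(1)
    }
    # drop fixations that start beyond the session; the recording stops at
    # duration_s, so a fixation still in progress is truncated there
    keep <- fix_start < recipe$duration_s
    fix_start <- fix_start[keep]; fix_dur <- fix_dur[keep]
    fix_x <- fix_x[keep]; fix_y <- fix_y[keep]; fix_aoi <- fix_aoi[keep]
    fix_dur <- pmin(fix_start + fix_dur, recipe$duration_s) - fix_start
    nf <- length(fix_start)
    fix_end <- fix_start + fix_dur

    fixations <- data.frame(
      fixation_id = seq_len(nf),
      start_s = fix_start, duration_s = fix_dur,
      x_px = fix_x * geometry$width_px,
      y_px = fix_y * geometry$height_px,
      aoi_label = fix_aoi, stringsAsFactors = FALSE)
    class(fixations) <- c("fixation_records", "data.frame")

    # ---- sample stream -------------------------------------------------
    tt <- seq(0, recipe$duration_s, by = 1 / recipe$sample_rate_hz)
    tt <- tt[tt < recipe$duration_s]
    ns <- length(tt)
    px <- numeric(ns); py <- numeric(ns); in_aoi <- rep(NA_character_, ns)
    fi <- findInterval(tt, fix_start)
    for (i in seq_len(ns)) {
      j <- fi[i]
      if (j >= 1 && tt[i] < fix_end[j]) {
        px[i] <- fix_x[j] + stats::rnorm(1, 0, 0.003)
        py[i] <- fix_y[j] + stats::rnorm(1, 0, 0.003)
        in_aoi[i] <- fix_aoi[j]
      } else if (j >= 1 && j < nf) {
        # inside the saccade from fixation j to j+1: smoothstep trajectory,
        # peak velocity 1.5x the mean by construction
        u <- (tt[i] - fix_end[j]) / (fix_start[j + 1] - fix_end[j])
        u <- min(max(u, 0), 1)
        w <- u * u * (3 - 2 * u)
        px[i] <- fix_x[j] + w * (fix_x[j + 1] - fix_x[j])
        py[i] <- fix_y[j] + w * (fix_y[j + 1] - fix_y[j])
      } else {
        px[i] <- fix_x[max(j, 1)]; py[i] <- fix_y[max(j, 1)]
      }
    }
    px <- pmin(pmax(px, 0), 1)
    py <- pmin(pmax(py, 0), 1)

    drift <- recipe$pupil_drift_mm * sin(2 * pi * tt / 60)
    lp <- recipe$pupil_left_mm + drift +
      stats::rnorm(ns, 0, recipe$pupil_noise_sd)
    rp <- recipe$pupil_right_mm + drift +
      stats::rnorm(ns, 0, recipe$pupil_noise_sd)

    # blink process: Poisson count, uniform onset times, 150 ms each
    n_blinks <- stats::rpois(1, recipe$blink_rate_per_min *
                               recipe$duration_s / 60)
    blink_id <- rep(NA_real_, ns)
    if (n_blinks > 0) {
      onsets <- sort(stats::runif(n_blinks, 0, recipe$duration_s - 0.2))
      for (b in seq_len(n_blinks)) {
        sel <- tt >= onsets[b] & tt < onsets[b] + 0.15
        blink_id[sel] <- b
      }
      # a blink must cover at least one sample to be countable
      n_blinks <- length(unique(blink_id[!is.na(blink_id)]))
    }

    samples <- data.frame(
      time_s = tt, pog_x = px, pog_y = py,
      left_valid = 1, right_valid = 1,
      left_pupil_mm = lp, right_pupil_mm = rp,
      blink_id = blink_id,
      blink_rate_export = n_blinks * 60 / recipe$duration_s,
      aoi_label = in_aoi, stringsAsFactors = FALSE)

    # ---- artifacts ------------------------------------------------------
    n_invalid <- round(recipe$invalid_rate * ns)
    n_off <- round(recipe$off_screen_rate * ns)
    n_spike <- round(recipe$pupil_spike_rate * ns)
    total_art <- n_invalid + n_off + n_spike
    if (total_art > ns) stop("generate_session: artifact rates exceed 1")
    art_rows <- sample.int(ns, total_art)
    inv_rows <- art_rows[seq_len(n_invalid)]
    off_rows <- art_rows[n_invalid + seq_len(n_off)]
    spike_rows <- art_rows[n_invalid + n_off + seq_len(n_spike)]
    if (n_invalid) {
      samples$left_valid[inv_rows] <- 0
      samples$right_valid[inv_rows] <- 0
    }
    if (n_off) samples$pog_x[off_rows] <- 1.5
    if (n_spike) samples$left_pupil_mm[spike_rows] <- 12

    class(samples) <- c("gaze_samples", "data.frame")

    sacc_mag <- if (nf >= 2) {
      sqrt(diff(fix_x * geometry$width_px)^2 +
             diff(fix_y * geometry$height_px)^2)
    } else numeric(0)

    truth <- list(
      n_fixations = nf,
      mean_fixation_duration_s = mean(fix_dur),
      se_fixation_duration_s = stats::sd(fix_dur) / sqrt(nf),
      mean_saccade_magnitude_px = if (length(sacc_mag)) mean(sacc_mag)
                                  else NA_real_,
      se_saccade_magnitude_px = if (length(sacc_mag) > 1) {
        stats::sd(sacc_mag) / sqrt(length(sacc_mag))
      } else NA_real_,
      aoi_sequence = fix_aoi,
      aoi_counts = table(factor(fix_aoi, levels = labs)),
      blink_count = n_blinks,
      n_samples = ns,
      artifact_counts = c(invalid_flag = n_invalid, off_screen = n_off,
                          pupil_out_of_range = n_spike),
      recipe = recipe)

    list(samples = samples, fixations = fixations, truth = truth)
  })
}

#' Write a synthetic session in the Gazepoint-style CSV dialect
#'
#' Produces `all_gaze.csv` and `fixations.csv` with vendor-style headers
#' that [read_all_gaze()] / [read_fixations()] parse back into equal records
#' (round trip). Fixation pixel positions are converted back to normalized
#' coordinates for the file.
#'
#' @param samples `gaze_samples`.
#' @param fixations `fixation_records`.
#' @param dir Output directory (created if needed).
#' @param geometry The [screen_geometry()] used for the conversion.
#' @return Named character vector with the two file paths.
#' @export
write_gazepoint_csv <- function(samples, fixations, dir,
                                geometry = screen_geometry()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gaze_path <- file.path(dir, "all_gaze.csv")
  fix_path <- file.path(dir, "fixations.csv")
  g <- data.frame(
    TIME = samples$time_s,
    BPOGX = samples$pog_x, BPOGY = samples$pog_y,
    LPV = samples$left_valid, RPV = samples$right_valid,
    LPMM = samples$left_pupil_mm, RPMM = samples$right_pupil_mm,
    BKID = samples$blink_id, BKPMIN = samples$blink_rate_export,
    AOI = samples$aoi_label)
  f <- data.frame(
    FPOGID = fixations$fixation_id,
    FPOGS = fixations$start_s, FPOGD = fixations$duration_s,
    FPOGX = fixations$x_px / geometry$width_px,
    FPOGY = fixations$y_px / geometry$height_px,
    AOI = fixations$aoi_label)
  utils::write.csv(g, gaze_path, row.names = FALSE, na = "")
  utils::write.csv(f, fix_path, row.names = FALSE, na = "")
  c(all_gaze = gaze_path, fixations = fix_path)
}
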