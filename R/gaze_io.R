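# Reading, validating and de-noising raw gaze / fixation CSV exports.

# Canonical column -> accepted header aliases (Gazepoint-style dialect first).
# Matching is case-insensitive; the canonical name itself always matches.
.default_aliases <- list(
  time_s            = c("TIME", "TIME(2000/01/01 00:00:00.000)"),
  pog_x             = c("BPOGX", "FPOGX"),
  pog_y             = c("BPOGY", "FPOGY"),
  left_valid        = c("LPV", "LPOGV"),
  right_valid       = c("RPV", "RPOGV"),
  left_pupil_mm     = c("LPMM"),
  right_pupil_mm    = c("RPMM"),
  blink_id          = c("BKID"),
  blink_rate_export = c("BKPMIN"),
  aoi_label         = c("AOI"),
  # fixation file
  fixation_id       = c("FPOGID"),
  start_s           = c("FPOGS"),
  duration_s        = c("FPOGD"),
  x_norm            = c("FPOGX"),
  y_norm            = c("FPOGY")
)

#' Cleaning configuration for raw gaze de-noising
#'
#' Plausibility limits used when rejecting corrupted samples. The defaults
#' span the physiological pupil range (roughly 2-4 mm in bright light, 4-8 mm
#' in the dark); between-eye pupil asymmetry (anisocoria) beyond 1 mm is rare
#' and treated as artifact when the check is on.
#'
#' @param pupil_min_mm,pupil_max_mm Plausible pupil-diameter window (mm).
#' @param anisocoria_max_mm Maximum tolerated |left - right| pupil difference.
#' @param anisocoria_check If `TRUE`, rows exceeding `anisocoria_max_mm` are
#'   rejected; if `FALSE`, the difference is ignored.
#' @param require_both_eyes If `TRUE`, rows where only one eye was captured
#'   are rejected as incomplete.
#' @return A `cleaning_config` list.
#' @export
cleaning_config <- function(pupil_min_mm = 2.0, pupil_max_mm = 8.0,
                            anisocoria_max_mm = 1.0, anisocoria_check = TRUE,
                            require_both_eyes = TRUE) {
  stopifnot(pupil_min_mm > 0, pupil_min_mm < pupil_max_mm,
            anisocoria_max_mm > 0)
  structure(
    list(pupil_min_mm = pupil_min_mm, pupil_max_mm = pupil_max_mm,
         anisocoria_max_mm = anisocoria_max_mm,
         anisocoria_check = isTRUE(anisocoria_check),
         require_both_eyes = isTRUE(require_both_eyes)),
    class = "cleaning_config"
  )
}

# Fixed precedence of rejection rules; a row is logged once under the first
# rule it violates, so audits are deterministic.
.rejection_reasons <- c("invalid_flag", "negative_value", "off_screen",
                        "incomplete_one_eye", "missing_coordinates",
                        "pupil_out_of_range", "anisocoria_exceeded")

# Map raw headers onto canonical names. Returns a named character vector
# canonical -> raw header (only for columns present).
.match_columns <- function(headers, aliases = .default_aliases) {
  upper <- toupper(trimws(headers))
  out <- character(0)
  for (canon in names(aliases)) {
    cand <- toupper(c(canon, aliases[[canon]]))
    hit <- match(cand, upper)
    hit <- hit[!is.na(hit)]
    if (length(hit)) out[canon] <- headers[hit[1]]
  }
  out
}

# Parse a character column to numeric, reporting which rows fail.
.parse_numeric <- function(x) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  val <- suppressWarnings(as.numeric(x))
  list(value = val, bad = !is.na(x) & is.na(val))
}

.read_raw_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  raw
}

# Re-base timestamps that look like absolute clock time (e.g. epoch seconds)
# so that every recording starts at 0.
.rebase_time <- function(time_s) {
  if (length(time_s) && !is.na(time_s[1]) && time_s[1] >= 3600) {
    time_s <- time_s - time_s[1]
  }
  time_s
}

#' Read a raw all-gaze samples export
#'
#' Parses a comma-separated tracker export (Gazepoint-style headers or the
#' canonical names used by this package) into one row per tracker sample.
#' No cleaning is applied; use [denoise()] afterwards. Unknown extra columns
#' are ignored; rows with unparseable numeric cells are skipped with a
#' warning.
#'
#' @param path Path to the samples CSV (header row required).
#' @param geometry A [screen_geometry()] (kept for interface symmetry with
#'   [read_fixations()]; samples stay in normalized coordinates).
#' @return A data.frame of class `gaze_samples` with columns `time_s`,
#'   `pog_x`, `pog_y`, `left_valid`, `right_valid`, `left_pupil_mm`,
#'   `right_pupil_mm`, `blink_id`, `blink_rate_export`, `aoi_label`.
#' @export
read_all_gaze <- function(path, geometry = screen_geometry()) {
  raw <- .read_raw_csv(path)
  cols <- .match_columns(names(raw))
  required <- c("time_s", "pog_x", "pog_y")
  missing <- setdiff(required, names(cols))
  if (length(missing)) {
    stop("samples file ", path, " lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(raw)
  num_fields <- c("time_s", "pog_x", "pog_y", "left_valid", "right_valid",
                  "left_pupil_mm", "right_pupil_mm", "blink_id",
                  "blink_rate_export")
  out <- list()
  bad <- logical(n)
  for (f in num_fields) {
    if (f %in% names(cols)) {
      p <- .parse_numeric(raw[[cols[[f]]]])
      out[[f]] <- p$value
      bad <- bad | p$bad
    } else {
      out[[f]] <- rep(NA_real_, n)
    }
  }
  out$aoi_label <- if ("aoi_label" %in% names(cols)) {
    lab <- trimws(raw[[cols[["aoi_label"]]]])
    lab[lab == ""] <- NA_character_
    lab
  } else rep(NA_character_, n)
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable numeric cells skipped")
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  # validity flags: absent column means "assume valid"
  for (f in c("left_valid", "right_valid")) {
    if (!(f %in% names(cols))) df[[f]] <- 1
  }
  df$time_s <- .rebase_time(df$time_s)
  class(df) <- c("gaze_samples", "data.frame")
  df
}

#' Read a raw fixations export
#'
#' Parses a fixation CSV (one row per detected fixation) and converts the
#' normalized point-of-gaze coordinates to screen pixels using the supplied
#' geometry. Fixations are returned sorted by start time.
#'
#' @param path Path to the fixations CSV.
#' @param geometry A [screen_geometry()] used for the pixel conversion.
#' @return A data.frame of class `fixation_records` with columns
#'   `fixation_id`, `start_s`, `duration_s`, `x_px`, `y_px`, `aoi_label`.
#' @export
read_fixations <- function(path, geometry = screen_geometry()) {
  raw <- .read_raw_csv(path)
  cols <- .match_columns(names(raw))
  required <- c("fixation_id", "start_s", "duration_s", "x_norm", "y_norm")
  missing <- setdiff(required, names(cols))
  if (length(missing)) {
    stop("fixations file ", path, " lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(raw)
  out <- list()
  bad <- logical(n)
  for (f in required) {
    p <- .parse_numeric(raw[[cols[[f]]]])
    out[[f]] <- p$value
    bad <- bad | p$bad
  }
  out$aoi_label <- if ("aoi_label" %in% names(cols)) {
    lab <- trimws(raw[[cols[["aoi_label"]]]])
    lab[lab == ""] <- NA_character_
    lab
  } else rep(NA_character_, n)
  df <- data.frame(
    fixation_id = out$fixation_id,
    start_s = out$start_s,
    duration_s = out$duration_s,
    x_px = out$x_norm * geometry$width_px,
    y_px = out$y_norm * geometry$height_px,
    aoi_label = out$aoi_label,
    stringsAsFactors = FALSE
  )
  if (any(bad)) {
    warning(sum(bad), " fixation row(s) with unparseable cells skipped")
    df <- df[!bad, , drop = FALSE]
  }
  df$start_s <- .rebase_time(df$start_s)
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("fixation_records", "data.frame")
  df
}

#' De-noise a gaze sample stream
#'
#' Applies the fixed sequence of rejection rules and returns the surviving
#' samples together with a per-row rejection audit. Each removed row is
#' logged exactly once, under the first rule it violates, in this order:
#' `invalid_flag` (both eyes flagged invalid), `negative_value`,
#' `off_screen`, `incomplete_one_eye`, `missing_coordinates`,
#' `pupil_out_of_range`, `anisocoria_exceeded`. Relative order of kept rows
#' is preserved, so `rows_in = rows_kept + rows_rejected` always holds.
#'
#' @param samples A `gaze_samples` data.frame from [read_all_gaze()].
#' @param config A [cleaning_config()].
#' @return A list with elements `samples` (clean rows), `log` (data.frame
#'   `row_index`, `reason`) and `counts` (named integer vector over all seven
#'   reason codes).
#' @export
denoise <- function(samples, config = cleaning_config()) {
  n <- nrow(samples)
  reason <- rep(NA_character_, n)
  lv <- samples$left_valid
  rv <- samples$right_valid
  # absent validity information counts as valid
  lv_ok <- is.na(lv) | lv > 0
  rv_ok <- is.na(rv) | rv > 0

  mark <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- code
  }

  mark(!lv_ok & !rv_ok, "invalid_flag")
  neg <- (samples$time_s < 0) | (samples$pog_x < 0) | (samples$pog_y < 0) |
    (samples$left_pupil_mm < 0) | (samples$right_pupil_mm < 0)
  mark(neg, "negative_value")
  mark(samples$pog_x > 1 | samples$pog_y > 1, "off_screen")
  if (config$require_both_eyes) {
    mark(xor(lv_ok, rv_ok), "incomplete_one_eye")
  }
  mark(is.na(samples$pog_x) | is.na(samples$pog_y), "missing_coordinates")
  pupil_bad <- function(p) {
    !is.na(p) & (p < config$pupil_min_mm | p > config$pupil_max_mm)
  }
  mark(pupil_bad(samples$left_pupil_mm) | pupil_bad(samples$right_pupil_mm),
       "pupil_out_of_range")
  if (config$anisocoria_check) {
    d <- abs(samples$left_pupil_mm - samples$right_pupil_mm)
    mark(!is.na(d) & d > config$anisocoria_max_mm, "anisocoria_exceeded")
  }

  keep <- is.na(reason)
  log <- data.frame(row_index = which(!keep),
                    reason = reason[!keep],
                    stringsAsFactors = FALSE)
  counts <- vapply(.rejection_reasons,
                   function(r) sum(log$reason == r), integer(1))
  clean <- samples[keep, , drop = FALSE]
  rownames(clean) <- NULL
  class(clean) <- class(samples)
  list(samples = clean, log = log, counts = counts)
}

#' Write cleaned samples and a rejection log to CSV
#'
#' @param samples Clean `gaze_samples`.
#' @param log The rejection log data.frame from [denoise()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_clean_gaze <- function(samples, log, dir, prefix = "clean") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- file.path(dir, paste0(prefix, "_gaze.csv"))
  lp <- file.path(dir, paste0(prefix, "_rejections.csv"))
  utils::write.csv(as.data.frame(samples), sp, row.names = FALSE, na = "")
  utils::write.csv(log, lp, row.names = FALSE, na = "")
  invisible(c(samples = sp, rejections = lp))
}
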