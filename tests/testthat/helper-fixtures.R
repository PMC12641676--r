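# Shared fixture builders (everything generated in code; no stored data).

# minimal fixation table in pixel coordinates
make_fixations <- function(start_s, duration_s, x_px, y_px,
                           aoi_label = NA_character_) {
  n <- length(start_s)
  df <- data.frame(fixation_id = seq_len(n), start_s = start_s,
                   duration_s = duration_s, x_px = x_px, y_px = y_px,
                   aoi_label = rep_len(aoi_label, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("fixation_records", "data.frame")
  df
}

# minimal sample table in canonical columns
make_samples <- function(time_s, pog_x = 0.5, pog_y = 0.5,
                         left_valid = 1, right_valid = 1,
                         left_pupil_mm = NA_real_, right_pupil_mm = NA_real_,
                         blink_id = NA_real_, aoi_label = NA_character_) {
  n <- length(time_s)
  df <- data.frame(time_s = time_s,
                   pog_x = rep_len(pog_x, n), pog_y = rep_len(pog_y, n),
                   left_valid = rep_len(left_valid, n),
                   right_valid = rep_len(right_valid, n),
                   left_pupil_mm = rep_len(left_pupil_mm, n),
                   right_pupil_mm = rep_len(right_pupil_mm, n),
                   blink_id = rep_len(blink_id, n),
                   blink_rate_export = rep_len(NA_real_, n),
                   aoi_label = rep_len(aoi_label, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("gaze_samples", "data.frame")
  df
}

write_temp_csv <- function(df, name = "tmp.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# brute-force six-number summary, independent of describe()
oracle_describe <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0) return(rep(NA_real_, 6))
  sv <- sort(v)
  med <- if (n %% 2 == 1) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
  mu <- sum(v) / n
  sdv <- if (n == 1) 0 else sqrt(sum((v - mu)^2) / (n - 1))
  c(sum(v), mu, med, sdv, sv[1], sv[n])
}

# naive overlapping-substring pattern mining oracle
oracle_mine <- function(strings, min_len, max_len) {
  pats <- character(0)
  for (s in strings) {
    n <- nchar(s)
    for (L in min_len:max_len) {
      if (n < L) next
      for (i in 1:(n - L + 1)) pats <- c(pats, substr(s, i, i + L - 1))
    }
  }
  pats <- sort(unique(pats))
  count_in <- function(p, s) {
    L <- nchar(p); n <- nchar(s)
    if (n < L) return(0L)
    sum(vapply(1:(n - L + 1), function(i) substr(s, i, i + L - 1) == p,
               logical(1)))
  }
  freq <- vapply(pats, function(p) sum(vapply(strings, count_in, integer(1),
                                              p = p)), integer(1))
  hits <- vapply(pats, function(p) {
    sum(vapply(strings, function(s) count_in(p, s) > 0, logical(1)))
  }, integer(1))
  data.frame(pattern = pats, frequency = freq,
             support = hits / length(strings),
             mean_pattern_frequency = freq / length(strings),
             proportional_pattern_frequency = freq / sum(freq),
             stringsAsFactors = FALSE)
}

# a small synthetic session everyone can share (cheap to regenerate)
demo_session <- function(seed = 11, duration_s = 120, ...) {
  generate_session(session_recipe(duration_s = duration_s, seed = seed, ...))
}
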