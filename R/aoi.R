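# AOI-specific analytics: entropies, transitions, sequences, patterns.

# Pull the AOI label vector out of fixation records or accept one directly.
.aoi_labels <- function(x) {
  if (is.data.frame(x)) x$aoi_label else as.character(x)
}

#' Stationary gaze entropy
#'
#' Shannon entropy (base 2, bits) of the distribution of fixation counts
#' across AOIs: how evenly visual attention is spread. 0 when all fixations
#' land in one AOI; log2(k) at uniform counts over k AOIs. Unlabelled
#' fixations are ignored; no labelled fixation at all yields `NA`.
#'
#' @param fixations `fixation_records` or a character vector of AOI labels.
#' @param normalize Divide by log2(number of AOIs present) so the result
#'   lies in [0, 1] (single-AOI input stays 0).
#' @return Entropy in bits (or normalized units).
#' @export
stationary_entropy <- function(fixations, normalize = FALSE) {
  lab <- .aoi_labels(fixations)
  lab <- lab[!is.na(lab)]
  if (!length(lab)) return(NA_real_)
  p <- as.numeric(table(lab))
  p <- p / sum(p)
  h <- -sum(ifelse(p > 0, p * log2(p), 0))
  if (normalize && length(p) > 1) h <- h / log2(length(p))
  h
}

#' AOI transition-count matrix
#'
#' Counts transitions over consecutive AOI-labelled fixations; unlabelled
#' fixations are skipped (the next labelled fixation continues the chain).
#' The matrix is order-sensitive: `C["A","B"]` counts A-to-B moves only.
#' Same-AOI consecutive pairs are counted on the diagonal as
#' self-transitions.
#'
#' @inheritParams stationary_entropy
#' @return An integer matrix with AOI labels as dimnames (0x0 if fewer than
#'   two labelled fixations).
#' @export
transition_counts <- function(fixations) {
  lab <- .aoi_labels(fixations)
  lab <- lab[!is.na(lab)]
  labs <- sort(unique(lab))
  m <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  if (length(lab) >= 2) {
    from <- lab[-length(lab)]
    to <- lab[-1]
    for (k in seq_along(from)) m[from[k], to[k]] <- m[from[k], to[k]] + 1L
  }
  m
}

#' Transition (conditional) gaze entropy
#'
#' The randomness of attention shifts: the conditional Shannon entropy of the
#' next AOI given the current one, `sum_i pi_i * H(row_i)` in bits, where the
#' source weights `pi` are the empirical distribution of transition origins
#' and each row of the count matrix is normalized to probabilities.
#' Deterministic rows contribute 0; a matrix with no transitions yields `NA`.
#'
#' @param matrix A transition-count matrix from [transition_counts()].
#' @param source_weights `"transitions"` (origin distribution of the counted
#'   transitions, the default) or `"uniform"` over AOIs with outgoing
#'   transitions.
#' @return Conditional entropy in bits.
#' @export
transition_entropy <- function(matrix,
                               source_weights = c("transitions", "uniform")) {
  source_weights <- match.arg(source_weights)
  total <- sum(matrix)
  if (!length(matrix) || total == 0) return(NA_real_)
  rs <- rowSums(matrix)
  active <- rs > 0
  pi_w <- if (source_weights == "transitions") {
    rs[active] / total
  } else {
    rep(1 / sum(active), sum(active))
  }
  row_h <- apply(matrix[active, , drop = FALSE], 1, function(row) {
    p <- row / sum(row)
    -sum(ifelse(p > 0, p * log2(p), 0))
  })
  sum(pi_w * row_h)
}

#' Transition proportions between AOI pairs
#'
#' Each cell of the count matrix divided by the total number of transitions.
#' With `include_self = FALSE`, self-transitions (diagonal) are removed from
#' both numerator and denominator. Proportions over the retained cells sum
#' to 1; an empty denominator yields an all-`NA` matrix.
#'
#' @param matrix A transition-count matrix.
#' @param include_self Keep self-transitions in the computation.
#' @return A numeric matrix of proportions, same dimnames as the input.
#' @export
transition_proportions <- function(matrix, include_self = TRUE) {
  m <- matrix
  if (!include_self) diag(m) <- 0L
  total <- sum(m)
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  if (total > 0) out[] <- m / total
  if (!include_self) diag(out) <- NA_real_
  out
}

#' Per-AOI fixation proportions
#'
#' For every AOI: the share of fixation counts and of fixation duration that
#' fell in it, relative to ALL fixations captured (unlabelled fixations count
#' in the denominators but form no AOI of their own).
#'
#' @param fixations `fixation_records` with `aoi_label` and `duration_s`.
#' @return data.frame with columns `aoi`, `n`, `duration_s`, `prop_count`,
#'   `prop_duration`.
#' @export
aoi_fixation_proportions <- function(fixations) {
  total_n <- nrow(fixations)
  total_d <- sum(fixations$duration_s, na.rm = TRUE)
  lab <- fixations$aoi_label
  keep <- !is.na(lab)
  if (!any(keep) || total_n == 0) {
    return(data.frame(aoi = character(0), n = integer(0),
                      duration_s = numeric(0), prop_count = numeric(0),
                      prop_duration = numeric(0)))
  }
  agg_n <- table(lab[keep])
  agg_d <- tapply(fixations$duration_s[keep], lab[keep], sum)
  aoi <- sort(names(agg_n))
  data.frame(
    aoi = aoi,
    n = as.integer(agg_n[aoi]),
    duration_s = as.numeric(agg_d[aoi]),
    prop_count = as.numeric(agg_n[aoi]) / total_n,
    prop_duration = if (total_d > 0) as.numeric(agg_d[aoi]) / total_d
                    else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Collapse an AOI sequence
#'
#' Removes adjacent repetitions: `"ACCDEABAAAABC"` becomes `"ACDEABABC"`.
#' Idempotent; an empty sequence stays empty. Accepts a single string (one
#' symbol per character) or a character vector of tokens (for AOI sets too
#' large for single letters).
#'
#' @param expanded The expanded sequence.
#' @return The collapsed sequence, same representation as the input.
#' @export
collapse_sequence <- function(expanded) {
  if (length(expanded) == 1 && !is.na(expanded)) {
    tokens <- strsplit(expanded, "", fixed = TRUE)[[1]]
    if (!length(tokens)) return("")
    return(paste(rle(tokens)$values, collapse = ""))
  }
  if (!length(expanded)) return(character(0))
  rle(expanded)$values
}

#' Build AOI sequences per participant
#'
#' One symbol per AOI-labelled fixation, in time order; unlabelled fixations
#' are skipped. Labels are used as tokens directly; when every label is a
#' single character the sequences are returned as plain strings.
#'
#' @param fixations_by_participant Named list of `fixation_records`.
#' @return data.frame with columns `participant`, `expanded`, `collapsed`
#'   (token sequences joined without separator when single-character,
#'   otherwise with `"|"`).
#' @export
aoi_sequences <- function(fixations_by_participant) {
  rows <- lapply(names(fixations_by_participant), function(id) {
    lab <- fixations_by_participant[[id]]$aoi_label
    lab <- lab[!is.na(lab)]
    sep <- if (length(lab) && all(nchar(lab) == 1)) "" else "|"
    data.frame(participant = id,
               expanded = paste(lab, collapse = sep),
               collapsed = paste(rle(lab)$values, collapse = sep),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# tokenize a sequence: single string -> characters; keeps token vectors
.tokens <- function(s) {
  if (length(s) == 1) strsplit(s, "", fixed = TRUE)[[1]] else s
}

#' Mine contiguous subsequence patterns from AOI sequences
#'
#' Enumerates every contiguous substring with length in
#' `[min_len, max_len]` occurring in at least one sequence, counting
#' occurrences with overlaps allowed. For each pattern the group-level
#' statistics are reported: `frequency` (total occurrences over all
#' sequences), `support` (share of sequences containing the pattern),
#' `mean_pattern_frequency` (total occurrences / number of sequences) and
#' `proportional_pattern_frequency` (this pattern's occurrences over the
#' total occurrences of all mined patterns; sums to 1 over the result).
#'
#' @param sequences Character vector of sequence strings (one symbol per
#'   character), or a list of token vectors.
#' @param form Label recorded in the output: `"collapsed"` or `"expanded"`.
#' @param min_len,max_len Pattern length bounds (`min_len >= 2`).
#' @return data.frame `pattern`, `form`, `frequency`, `support`,
#'   `mean_pattern_frequency`, `proportional_pattern_frequency`, sorted by
#'   decreasing frequency.
#' @export
mine_patterns <- function(sequences, form = c("collapsed", "expanded"),
                          min_len = 2, max_len = 5) {
  form <- match.arg(form)
  stopifnot(min_len >= 2, max_len >= min_len)
  if (!length(sequences)) {
    return(data.frame(pattern = character(0), form = character(0),
                      frequency = integer(0), support = numeric(0),
                      mean_pattern_frequency = numeric(0),
                      proportional_pattern_frequency = numeric(0)))
  }
  toks <- if (is.list(sequences)) sequences else lapply(sequences, .tokens)
  n_seq <- length(toks)
  all_single <- all(vapply(toks, function(t) {
    !length(t) || all(nchar(t) == 1)
  }, logical(1)))
  sep <- if (all_single) "" else "|"
  counts <- new.env(parent = emptyenv())
  seq_hits <- new.env(parent = emptyenv())
  for (si in seq_len(n_seq)) {
    tk <- toks[[si]]
    n <- length(tk)
    seen_here <- character(0)
    for (L in min_len:max_len) {
      if (n < L) break
      for (i in seq_len(n - L + 1)) {
        pat <- paste(tk[i:(i + L - 1)], collapse = sep)
        counts[[pat]] <- (if (is.null(counts[[pat]])) 0L else counts[[pat]]) + 1L
        if (!(pat %in% seen_here)) {
          seq_hits[[pat]] <- (if (is.null(seq_hits[[pat]])) 0L
                              else seq_hits[[pat]]) + 1L
          seen_here <- c(seen_here, pat)
        }
      }
    }
  }
  pats <- ls(counts)
  if (!length(pats)) {
    return(data.frame(pattern = character(0), form = character(0),
                      frequency = integer(0), support = numeric(0),
                      mean_pattern_frequency = numeric(0),
                      proportional_pattern_frequency = numeric(0)))
  }
  freq <- vapply(pats, function(p) counts[[p]], integer(1))
  hits <- vapply(pats, function(p) seq_hits[[p]], integer(1))
  out <- data.frame(
    pattern = pats,
    form = form,
    frequency = freq,
    support = hits / n_seq,
    mean_pattern_frequency = freq / n_seq,
    proportional_pattern_frequency = freq / sum(freq),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$frequency, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write AOI analytics tables to CSV
#'
#' Long-form transition table (`from`, `to`, `count`, `proportion_incl_self`,
#' `proportion_excl_self`), the sequence table and the pattern table.
#'
#' @param fixations_by_participant Named list of `fixation_records`.
#' @param dir Output directory.
#' @param min_len,max_len Pattern length bounds passed to [mine_patterns()].
#' @return Invisibly, the written paths.
#' @export
write_aoi_tables <- function(fixations_by_participant, dir,
                             min_len = 2, max_len = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_fix <- do.call(rbind, lapply(fixations_by_participant, as.data.frame))
  tm <- transition_counts(all_fix$aoi_label)
  pin <- transition_proportions(tm, include_self = TRUE)
  pex <- transition_proportions(tm, include_self = FALSE)
  long <- expand.grid(from = rownames(tm), to = colnames(tm),
                      stringsAsFactors = FALSE)
  long$count <- tm[cbind(long$from, long$to)]
  long$proportion_incl_self <- pin[cbind(long$from, long$to)]
  long$proportion_excl_self <- pex[cbind(long$from, long$to)]
  seqs <- aoi_sequences(fixations_by_participant)
  pats <- rbind(
    mine_patterns(seqs$expanded, "expanded", min_len, max_len),
    mine_patterns(seqs$collapsed, "collapsed", min_len, max_len)
  )
  paths <- c(transitions = file.path(dir, "aoi_transitions.csv"),
             sequences = file.path(dir, "aoi_sequences.csv"),
             patterns = file.path(dir, "aoi_patterns.csv"))
  utils::write.csv(long, paths["transitions"], row.names = FALSE, na = "")
  utils::write.csv(seqs, paths["sequences"], row.names = FALSE, na = "")
  utils::write.csv(pats, paths["patterns"], row.names = FALSE, na = "")
  invisible(paths)
}
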