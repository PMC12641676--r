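# AOI entropies, transitions, sequences and pattern mining.

test_that("stationary entropy covers degenerate, uniform and closed-form cases", {
  expect_equal(stationary_entropy(rep("A", 5)), 0)
  expect_equal(stationary_entropy(rep(c("A", "B", "C", "D"), 3)), 2)
  # proportions (0.5, 0.25, 0.25) -> 1.5 bits
  expect_equal(stationary_entropy(c("A", "A", "B", "C")), 1.5)
  expect_true(is.na(stationary_entropy(c(NA_character_, NA))))
  expect_equal(stationary_entropy(rep(c("A", "B"), 4), normalize = TRUE), 1)
})

test_that("entropy bounds hold and uniform attains the maximum", {
  set.seed(13)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    lab <- sample(LETTERS[1:k], 50, replace = TRUE)
    h <- stationary_entropy(lab)
    expect_gte(h, 0)
    expect_lte(h, log2(length(unique(lab))) + 1e-12)
  }
})

test_that("transition counts are order-sensitive and skip unlabelled rows", {
  m <- transition_counts(c("A", "B"))
  expect_equal(m["A", "B"], 1L)
  expect_equal(m["B", "A"], 0L)
  expect_equal(sum(transition_counts("A")), 0)
  m2 <- transition_counts(strsplit("ABAAC", "")[[1]])
  expect_equal(m2["A", "B"], 1L)
  expect_equal(m2["B", "A"], 1L)
  expect_equal(m2["A", "A"], 1L)
  expect_equal(m2["A", "C"], 1L)
  expect_equal(sum(m2), 4L)
  # NA labels bridge the chain rather than break the count
  m3 <- transition_counts(c("A", NA, "B"))
  expect_equal(m3["A", "B"], 1L)
})

test_that("transition entropy matches hand-computed conditional entropy", {
  # strict alternation: deterministic rows -> 0 bits
  expect_equal(transition_entropy(transition_counts(
    strsplit("ABABAB", "")[[1]])), 0)
  # uniform rows over 2 AOIs -> 1 bit
  u <- matrix(2L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(transition_entropy(u), 1)
  # toy matrix [[2,2],[1,3]]: pi = (1/2, 1/2); H(row1)=1, H(row2)=H(1/4)
  m <- matrix(c(2L, 1L, 2L, 3L), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  hand <- 0.5 * 1 + 0.5 * (-(1 / 4) * log2(1 / 4) - (3 / 4) * log2(3 / 4))
  expect_equal(transition_entropy(m), hand)
  expect_true(is.na(transition_entropy(matrix(0L, 2, 2))))
})

test_that("conditioning never exceeds the next-AOI marginal entropy", {
  set.seed(17)
  ent <- function(p) -sum(ifelse(p > 0, p * log2(p), 0))
  for (i in 1:200) {
    k <- sample(2:5, 1)
    m <- matrix(stats::rpois(k * k, 2), k, k,
                dimnames = list(LETTERS[1:k], LETTERS[1:k]))
    if (sum(m) == 0) next
    # H(next | current) <= H(next)
    expect_lte(transition_entropy(m), ent(colSums(m) / sum(m)) + 1e-12)
  }
  # for sequence-derived matrices of long sequences, the source-AOI
  # stationary entropy also bounds the conditional entropy
  for (i in 1:50) {
    lab <- sample(LETTERS[1:4], 500, replace = TRUE)
    m <- transition_counts(lab)
    src <- rowSums(m) / sum(m)
    expect_lte(transition_entropy(m), ent(src) + 0.05)
  }
})

test_that("transition proportions normalize with and without self-moves", {
  seqs <- strsplit("ABAB", "")[[1]]
  p <- transition_proportions(transition_counts(seqs), include_self = TRUE)
  expect_equal(p["A", "B"], 2 / 3)
  expect_equal(p["B", "A"], 1 / 3)
  expect_equal(sum(p), 1)
  p2 <- transition_proportions(transition_counts(strsplit("AAB", "")[[1]]),
                               include_self = FALSE)
  expect_equal(p2["A", "B"], 1)
  expect_equal(sum(p2, na.rm = TRUE), 1)
})

test_that("per-AOI proportions are relative to all fixations", {
  fx <- make_fixations(0:3, rep(0.5, 4), 1:4, 1:4,
                       aoi_label = c("A", "A", "B", "B"))
  pr <- aoi_fixation_proportions(fx)
  expect_equal(pr$prop_count[pr$aoi == "A"], 0.5)
  expect_equal(pr$prop_duration[pr$aoi == "A"], 0.5)
  # unlabelled fixations count in the denominator only
  fx2 <- make_fixations(0:3, c(1, 1, 1, 1), 1:4, 1:4,
                        aoi_label = c("A", NA, NA, NA))
  pr2 <- aoi_fixation_proportions(fx2)
  expect_equal(pr2$prop_count, 0.25)
  # mixed durations
  fx3 <- make_fixations(0:2, c(0.2, 0.3, 0.5), 1:3, 1:3,
                        aoi_label = c("A", "A", "B"))
  pr3 <- aoi_fixation_proportions(fx3)
  expect_equal(pr3$prop_duration[pr3$aoi == "A"], 0.5)
  expect_equal(pr3$prop_count[pr3$aoi == "B"], 1 / 3)
})

test_that("sequence collapse removes adjacent repeats and is idempotent", {
  expect_equal(collapse_sequence("ACCDEABAAAABC"), "ACDEABABC")
  expect_equal(collapse_sequence("AAAA"), "A")
  expect_equal(collapse_sequence("ABAB"), "ABAB")
  expect_equal(collapse_sequence(""), "")
  set.seed(29)
  for (i in 1:1000) {
    s <- paste(sample(LETTERS[1:4], sample(0:20, 1), replace = TRUE),
               collapse = "")
    c1 <- collapse_sequence(s)
    toks <- strsplit(c1, "")[[1]]
    if (length(toks) > 1) expect_false(any(toks[-1] == toks[-length(toks)]))
    expect_equal(collapse_sequence(c1), c1)
    # collapsed is a subsequence of expanded
    expect_true(grepl(paste(strsplit(c1, "")[[1]], collapse = ".*"), s) ||
                  c1 == "")
  }
})

test_that("pattern mining matches a naive enumeration oracle", {
  out <- mine_patterns(c("ABC", "BCA"), min_len = 2, max_len = 2)
  ab <- out[out$pattern == "AB", ]
  expect_equal(ab$frequency, 1L)
  expect_equal(ab$support, 0.5)
  expect_equal(ab$mean_pattern_frequency, 0.5)
  out2 <- mine_patterns("ABAB", min_len = 2, max_len = 2)
  expect_equal(out2$frequency[out2$pattern == "AB"], 2L)  # overlaps count
  expect_equal(out2$support[out2$pattern == "AB"], 1)
  # over-long patterns never appear
  expect_false(any(nchar(mine_patterns(c("AB", "BA"), min_len = 2,
                                       max_len = 5)$pattern) > 2))

  set.seed(31)
  for (i in 1:40) {
    n <- sample(1:10, 1)
    strs <- vapply(seq_len(n), function(j) {
      paste(sample(LETTERS[1:4], sample(2:30, 1), replace = TRUE),
            collapse = "")
    }, character(1))
    got <- mine_patterns(strs, min_len = 2, max_len = 4)
    want <- oracle_mine(strs, 2, 4)
    got <- got[order(got$pattern), ]
    expect_equal(got$pattern, want$pattern)
    expect_equal(got$frequency, want$frequency)
    expect_equal(got$support, want$support)
    expect_equal(got$mean_pattern_frequency, want$mean_pattern_frequency)
    expect_equal(got$proportional_pattern_frequency,
                 want$proportional_pattern_frequency)
    expect_equal(sum(got$proportional_pattern_frequency), 1)
  }
})

test_that("sequences build per participant in expanded and collapsed form", {
  fx1 <- make_fixations(0:4, rep(0.2, 5), 1:5, 1:5,
                        aoi_label = c("A", "A", "B", NA, "B"))
  fx2 <- make_fixations(0:1, rep(0.2, 2), 1:2, 1:2, aoi_label = c("C", "C"))
  seqs <- aoi_sequences(list(p1 = fx1, p2 = fx2))
  expect_equal(seqs$expanded, c("AABB", "CC"))
  expect_equal(seqs$collapsed, c("AB", "C"))
})
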