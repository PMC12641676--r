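# Saccade derivation, angle conversion, descriptive statistics, hull.

test_that("saccades span fixation gaps with 3-4-5 magnitudes", {
  fx <- make_fixations(start_s = c(0, 1.2), duration_s = c(1.0, 0.5),
                       x_px = c(0, 3), y_px = c(0, 4))
  s <- derive_saccades(fx)
  expect_equal(nrow(s), 1)
  expect_equal(s$magnitude_px, 5)
  expect_equal(s$duration_s, 0.2)
  expect_equal(s$start_s, 1.0)
  # single fixation -> none
  expect_equal(nrow(derive_saccades(fx[1, ])), 0)
  # overlapping records clamp to zero duration and get flagged
  fx2 <- make_fixations(c(0, 0.5), c(1.0, 0.5), c(0, 10), c(0, 0))
  s2 <- derive_saccades(fx2)
  expect_equal(s2$duration_s, 0)
  expect_true(s2$clamped)
  expect_true(is.na(s2$velocity_deg_s))
})

test_that("directions use y-up convention; collinear chain turns zero", {
  # left-to-right chain on a horizontal line
  fx <- make_fixations(c(0, 1, 2), rep(0.5, 3), c(0, 100, 200), rep(300, 3))
  s <- derive_saccades(fx)
  expect_equal(s$absolute_direction_deg, c(0, 0))
  expect_equal(s$relative_direction_deg[2], 0)
  # upward on screen (decreasing y_px) is 90 degrees
  fxu <- make_fixations(c(0, 1), rep(0.5, 2), c(0, 0), c(300, 200))
  expect_equal(derive_saccades(fxu)$absolute_direction_deg, 90)
  # right angle turn folds to 90
  fxr <- make_fixations(c(0, 1, 2), rep(0.4, 3), c(0, 100, 100),
                        c(300, 300, 200))
  expect_equal(derive_saccades(fxr)$relative_direction_deg[2], 90)
})

test_that("px_to_degrees matches the closed form and is monotone", {
  geom <- screen_geometry()
  pitch <- sqrt((24 * 25.4)^2 / (1920^2 + 1080^2))
  expect_equal(geom$pitch_mm, pitch)
  hand <- 2 * atan(100 * pitch / (2 * 650)) * 180 / pi
  expect_equal(px_to_degrees(100, geom), hand)
  expect_equal(px_to_degrees(0, geom), 0)
  far <- screen_geometry(viewing_distance_mm = 1300)
  expect_lt(px_to_degrees(100, far), px_to_degrees(100, geom))
  expect_error(px_to_degrees(-1, geom), "non-negative")
})

test_that("describe matches a brute-force oracle on random arrays", {
  expect_equal(unname(describe(5)), c(5, 5, 5, 0, 5, 5))
  expect_equal(unname(describe(c(1, 2, 3, 4))[c("sum", "mean", "median",
                                                "min", "max")]),
               c(10, 2.5, 2.5, 1, 4))
  expect_true(all(is.na(describe(numeric(0)))))
  set.seed(42)
  for (i in 1:1000) {
    v <- stats::rnorm(sample(1:30, 1), sd = 10^stats::runif(1, -2, 2))
    expect_equal(unname(describe(v)), oracle_describe(v), tolerance = 1e-9)
  }
  v <- stats::rnorm(17)
  expect_equal(describe(v), describe(sample(v)))
})

test_that("convex hull area handles toy shapes and stays invariant", {
  expect_equal(convex_hull_area(c(0, 4, 0), c(0, 0, 3)), 6)
  expect_equal(convex_hull_area(c(0, 1, 2), c(0, 1, 2)), 0)       # collinear
  expect_equal(convex_hull_area(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5)), 1)
  set.seed(7)
  for (i in 1:50) {
    x <- stats::runif(10); y <- stats::runif(10)
    a0 <- convex_hull_area(x, y)
    # translation invariance
    expect_equal(convex_hull_area(x + 100, y - 50), a0, tolerance = 1e-6)
    # rotation invariance
    th <- stats::runif(1, 0, 2 * pi)
    xr <- x * cos(th) - y * sin(th); yr <- x * sin(th) + y * cos(th)
    expect_equal(convex_hull_area(xr, yr), a0, tolerance = 1e-6)
    # adding a point never shrinks the hull
    expect_gte(convex_hull_area(c(x, stats::runif(1)),
                                c(y, stats::runif(1))), a0 - 1e-12)
  }
})

test_that("blink, pupil, ratio and scanpath measures follow their formulas", {
  s <- make_samples(seq(0, 59.9, 0.1),
                    blink_id = rep(c(NA, 1, NA, 2, NA, 3), each = 100))
  expect_equal(blink_rate(s, 60), 3)
  expect_equal(blink_rate(make_samples(0:59), 60), 0)
  expect_equal(blink_rate(s, 120), 1.5)
  expect_error(blink_rate(s, 0), "positive")

  p <- make_samples(1:10, left_pupil_mm = 3, right_pupil_mm = 4)
  m <- pupil_dgms(p)
  expect_equal(unname(m["pupil_both_mean_mm"]), 3.5)
  m2 <- pupil_dgms(p, baseline = list(left = 3, right = 3))
  expect_equal(unname(m2["pupil_left_change_mm"]), 0)
  expect_equal(unname(m2["pupil_right_change_mm"]), 1)
  expect_true(all(is.na(pupil_dgms(make_samples(1:3))[1:3])))

  fx <- make_fixations(c(0, 1.5), c(1, 1), c(0, 10), c(0, 0))
  sc <- data.frame(duration_s = c(0.5, 1.5))
  expect_equal(fixation_saccade_ratio(fx, sc), 1)
  expect_equal(scanpath_duration(fx, sc), 4)
  expect_true(is.na(fixation_saccade_ratio(fx, data.frame(duration_s = numeric(0)))))
})

test_that("peak velocity dominates mean velocity on synthetic traversals", {
  ses <- demo_session(seed = 21, duration_s = 60)
  s <- derive_saccades(ses$fixations, samples = ses$samples)
  ok <- !is.na(s$peak_velocity_deg_s) & !is.na(s$velocity_deg_s)
  expect_gt(sum(ok), 10)
  expect_true(all(s$peak_velocity_deg_s[ok] >= s$velocity_deg_s[ok]))
})

test_that("summative record recovers generator parameters and matches the
           full-span expanding window", {
  ses <- demo_session(seed = 9, duration_s = 150)
  truth <- ses$truth
  expect_gte(truth$n_fixations, 200)
  rec <- summative_dgms(ses$fixations, ses$samples)
  expect_equal(rec$saccade_count, rec$fixation_count - 1)
  # realized-vs-recovered (identity on the same records) and
  # generator-mean recovery within 2 standard errors
  expect_equal(rec$fixation_duration_mean, truth$mean_fixation_duration_s)
  expect_lt(abs(rec$fixation_duration_mean - 0.25),
            2 * truth$se_fixation_duration_s + 1e-9)
  expect_equal(rec$saccade_magnitude_mean, truth$mean_saccade_magnitude_px)
  # cross-module equivalence: one expanding window spanning everything
  w <- windowed_dgms(ses$fixations, ses$samples,
                     window_spec("expanding", size_s = 1e6))
  expect_equal(nrow(w), 1)
  shared <- intersect(names(rec), names(w))
  meas <- setdiff(shared, c("participant", "window", "aoi"))
  for (nm in meas) expect_equal(w[[nm]], rec[[nm]], tolerance = 1e-9,
                                label = nm)
})

test_that("group batching pools counts or averages person records", {
  a <- demo_session(seed = 1, duration_s = 40)
  b <- demo_session(seed = 2, duration_s = 60)
  pa <- list(fixations = a$fixations, samples = a$samples)
  pb <- list(fixations = b$fixations, samples = b$samples)
  ra <- summative_dgms(a$fixations, a$samples, scope = "a")
  rb <- summative_dgms(b$fixations, b$samples, scope = "b")
  pooled <- group_dgms(list(a = pa, b = pb), mode = "pooled")
  expect_equal(pooled$fixation_count, ra$fixation_count + rb$fixation_count)
  mop <- group_dgms(list(a = pa, b = pb), mode = "mean_of_persons")
  expect_equal(mop$fixation_duration_mean,
               (ra$fixation_duration_mean + rb$fixation_duration_mean) / 2)
  # duplicated participant: both modes reduce to the single record
  dup_p <- group_dgms(list(a = pa, a2 = pa), mode = "pooled")
  expect_equal(dup_p$fixation_duration_mean, ra$fixation_duration_mean)
  dup_m <- group_dgms(list(a = pa, a2 = pa), mode = "mean_of_persons")
  expect_equal(dup_m$saccade_magnitude_mean, ra$saccade_magnitude_mean)
  expect_error(group_dgms(list()), "empty")
})
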