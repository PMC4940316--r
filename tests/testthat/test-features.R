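test_that("moving average is centered with boundary truncation", {
  expect_equal(moving_average(rep(3.7, 50), 10), rep(3.7, 50))
  # window longer than the signal collapses every value to the global mean
  expect_equal(moving_average(toy_signal, 100), rep(9 / 7, 7))
  expect_equal(moving_average(c(0, 3, 0), 1), c(0, 3, 0))
  expect_equal(moving_average(c(0, 2, 4), 3), c(1, 2, 3))
  expect_equal(moving_average(c(0, 2, 4), 2, align = "trailing"), c(0, 1, 3))
  expect_error(moving_average(c(1, 2, 3), 0), "window")
})

test_that("half point is the index midpoint, ties rounding toward the peak", {
  expect_identical(locate_half_point(4, 2), 3L)
  expect_identical(locate_half_point(4, 1), 3L)  # 2.5 rounds toward pp
  expect_identical(locate_half_point(5, 6), 5L)  # adjacency rounds to pp
  expect_identical(locate_half_point(5, 4), 5L)
  expect_identical(locate_half_point(2, 4), 3L)
  expect_identical(locate_half_point(1, 4), 2L)  # right-side tie toward pp
  expect_error(locate_half_point(3, 3))
})

test_that("turning point fires on a strict >50% slope drop, else falls back to the valley", {
  # steps 2 then 1: exactly 50% is not 'more than 50%' -> fallback
  expect_identical(locate_turning_point(c(2, 0, 1, 3), 4, 2), 2L)
  # steps 2.9 then 0.1 -> drop fires at the far point of the qualifying step
  expect_identical(locate_turning_point(c(0, 0.1, 3), 3, 1), 1L)
  # adjacent peak and valley: no preceding slope to compare
  expect_identical(locate_turning_point(c(0, 1, 0), 2, 1), 1L)
  expect_identical(locate_turning_point(c(0, 1, 0), 2, 3), 3L)
  # interior break on the right half wave
  expect_identical(locate_turning_point(c(5, 2, 1.9, 1.8, 0), 1, 5), 3L)
})

test_that("the eight points of the toy peak compose as hand-derived", {
  cd <- detect_candidates(toy_signal)
  pts <- locate_points(toy_signal, cd[1, ])
  expect_identical(pts$pp, 4L)
  expect_identical(pts$vp1, 2L)
  expect_identical(pts$vp2, 6L)
  expect_identical(pts$hp1, 3L)
  expect_identical(pts$hp2, 5L)
  expect_identical(pts$tp1, 2L)
  expect_identical(pts$tp2, 6L)
  expect_equal(pts$mac_at_pp, 9 / 7)
  # invariants
  expect_true(pts$vp1 <= pts$hp1 && pts$hp1 <= pts$pp)
  expect_true(pts$pp <= pts$hp2 && pts$hp2 <= pts$vp2)
})

test_that("the 16 features of the toy peak match the hand-worked values exactly", {
  cd <- detect_candidates(toy_signal)
  pts <- locate_points(toy_signal, cd[1, ])
  fv <- extract_features(toy_signal, pts)
  expect_equal(fv, toy_features)
  # width additivity
  expect_identical(unname(fv["f6"]), unname(fv["f7"] + fv["f8"]))
})

test_that("half points of a symmetric triangle peak are symmetric about it", {
  x <- c(0, 1, 2, 3, 4, 3, 2, 1, 0)
  cd <- detect_candidates(x)
  pts <- locate_points(x, cd[1, ])
  expect_equal(pts$pp - pts$hp1, pts$hp2 - pts$pp)
  fv <- extract_features(x, pts)
  expect_equal(fv[["f1"]], fv[["f2"]])
  expect_equal(fv[["f7"]], fv[["f8"]])
  expect_equal(fv[["f13"]], fv[["f14"]])
})

test_that("features are non-negative and additive on random signals", {
  set.seed(21)
  for (i in 1:25) {
    x <- cumsum(stats::rnorm(200))  # smooth-ish random walk
    fm <- feature_matrix(x)
    expect_true(all(fm >= 0))
    expect_equal(fm[, "f6"], fm[, "f7"] + fm[, "f8"])
  }
})

test_that("features are translation-invariant; amplitudes and slopes scale, widths do not", {
  set.seed(22)
  x <- cumsum(stats::rnorm(300))
  fm <- feature_matrix(x)
  expect_equal(feature_matrix(x + 17.3), fm, ignore_attr = TRUE)

  fm_scaled <- feature_matrix(x * 2.5)
  amp_slope <- paste0("f", c(1:5, 13:16))
  widths <- paste0("f", 6:12)
  expect_equal(fm_scaled[, amp_slope], 2.5 * fm[, amp_slope])
  expect_equal(fm_scaled[, widths], fm[, widths])
})

test_that("peak models select the published feature subsets in order", {
  fv <- stats::setNames(as.numeric(1:16), paste0("f", 1:16))
  expect_equal(unname(select_model_features(fv, "dumpala")), c(1, 6, 13, 14))
  expect_equal(unname(select_model_features(fv, "dingle")), c(5, 6, 13, 14))
  expect_equal(unname(select_model_features(fv, "acir")), c(1, 2, 7, 8, 13, 14))
  expect_equal(unname(select_model_features(fv, "liu")),
               c(1, 2, 3, 4, 6, 9, 12, 13, 14, 15, 16))
  expect_equal(unname(select_model_features(fv, "all16")), as.numeric(1:16))
  expect_error(peak_model("bogus"), "dumpala, dingle, acir, liu, all16")
})

test_that("Dumpala and Dingle vectors differ only in the amplitude component", {
  set.seed(23)
  x <- cumsum(stats::rnorm(300))
  fm <- feature_matrix(x)
  du <- select_model_features(fm, "dumpala")
  di <- select_model_features(fm, "dingle")
  expect_equal(du[, -1], di[, -1], ignore_attr = TRUE)
})
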