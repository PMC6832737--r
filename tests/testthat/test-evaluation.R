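test_that("greedy matching handles exact, distant and contested cases", {
  truth <- data.frame(plant_id = 1:3, x = c(0, 1, 2), y = 0)
  det <- data.frame(id = 1:3, x = c(0, 1, 2), y = 0)
  m <- match_detections(det, truth, 0.05)
  expect_equal(c(m$TP, m$FP, m$FN), c(3L, 0L, 0L))
  # one pair 0.08 m apart with tolerance 0.05: unmatched on both sides
  m2 <- match_detections(data.frame(id = 1, x = 0.08, y = 0),
                         data.frame(plant_id = 1, x = 0, y = 0), 0.05)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(0L, 1L, 1L))
  # two detections near one truth: the closer wins, the other is FP
  m3 <- match_detections(data.frame(id = 1:2, x = c(0.03, 0.01), y = 0),
                         data.frame(plant_id = 1, x = 0, y = 0), 0.05)
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(1L, 1L, 0L))
  expect_equal(m3$pairs$detected_id, 2L)
  # order invariance
  set.seed(4)
  truth4 <- data.frame(plant_id = 1:6, x = runif(6), y = runif(6))
  det4 <- data.frame(id = 1:6, x = truth4$x + rnorm(6, 0, 0.01),
                     y = truth4$y + rnorm(6, 0, 0.01))
  perm <- sample(6)
  a <- match_detections(det4, truth4, 0.05)
  b <- match_detections(det4[perm, ], truth4[sample(6), ], 0.05)
  expect_equal(c(a$TP, a$FP, a$FN), c(b$TP, b$FP, b$FN))
})

test_that("precision and recall reproduce the plot-count table", {
  counts <- example_plot_counts()
  prec <- with(counts, TP / (TP + FP))
  rec <- with(counts, TP / (TP + FN))
  # every printed percentage, half-up integer rounding (9 plots x 2 metrics)
  expect_equal(floor(100 * prec + 0.5), c(96, 97, 97, 99, 96, 96, 98, 97, 98))
  expect_equal(floor(100 * rec + 0.5), c(100, 100, 97, 100, 99, 100, 100, 100, 100))
  # via the metric functions on count lists
  expect_equal(precision(list(TP = 126, FP = 5)), 126 / 131)
  expect_equal(recall(list(TP = 131, FN = 4)), 131 / 135)
  expect_equal(precision(list(TP = 10, FP = 0)), 1)
  expect_equal(recall(list(TP = 7, FN = 0)), 1)
  expect_warning(p0 <- precision(list(TP = 0, FP = 0)), "undefined")
  expect_true(is.nan(p0))
})

test_that("spacing agreement excludes FP/FN-adjacent intervals", {
  # 4 truth plants in one row at 0.2 m; plant 3 is missed by detection
  truth <- data.frame(plant_id = 1:4, row_index = 1, x = 0,
                      y = c(0, 0.2, 0.4, 0.6))
  det <- data.frame(id = c(11, 12, 14), x = 0, y = c(0, 0.205, 0.6))
  m <- match_detections(det, truth, 0.05)
  expect_equal(m$FN, 1L)
  fit <- fit_rows(det, row_params())
  sp <- spacing_along_rows(fit)       # records 11-12 (0.205) and 12-14 (0.395)
  ev <- spacing_agreement(sp, truth, m)
  expect_equal(ev$n, 1L)              # the span over the missed plant is out
  expect_equal(ev$per_pair$est, 0.205, tolerance = 1e-12)
  expect_equal(ev$per_pair$meas, 0.2, tolerance = 1e-12)
  expect_equal(ev$d_e, 0.005, tolerance = 1e-12)
})

test_that("agreement index and relative error match hand values", {
  truth <- data.frame(plant_id = 1:3, row_index = 1, x = 0,
                      y = c(0, 0.22, 0.46))      # true spacings 0.22, 0.24
  det <- data.frame(id = 1:3, x = 0, y = c(0, 0.20, 0.45))
  m <- match_detections(det, truth, 0.05)
  sp <- spacing_along_rows(fit_rows(det, row_params()))
  ev <- spacing_agreement(sp, truth, m)
  expect_equal(ev$n, 2L)
  expect_equal(ev$d_e, 0.015, tolerance = 1e-12)  # (0.02 + 0.01)/2
  expect_equal(ev$r, 0.06521739130434782, tolerance = 1e-9)
  # exact estimates -> zero error
  det2 <- data.frame(id = 1:3, x = 0, y = truth$y)
  ev2 <- spacing_agreement(spacing_along_rows(fit_rows(det2, row_params())),
                           truth, match_detections(det2, truth, 0.05))
  expect_equal(ev2$d_e, 0)
  expect_equal(ev2$r, 0)
})

test_that("d_e is symmetric, translation-invariant and scales linearly", {
  est <- c(0.20, 0.25, 0.19)
  meas <- c(0.22, 0.24, 0.20)
  d_e <- mean(abs(est - meas))
  expect_equal(mean(abs(meas - est)), d_e)                    # symmetry
  expect_equal(mean(abs((est + 1) - (meas + 1))), d_e)        # translation
  expect_equal(mean(abs(3 * est - 3 * meas)), 3 * d_e)        # scaling
  expect_equal(abs(3 * est - 3 * meas) / (3 * meas),
               abs(est - meas) / meas)  # per-pair relative errors unchanged
})

test_that("errors are raised when nothing can be evaluated", {
  truth <- data.frame(plant_id = 1:2, row_index = 1, x = 0, y = c(0, 0.2))
  det <- data.frame(id = 1:2, x = 5, y = c(0, 0.2))   # all FP
  m <- match_detections(det, truth, 0.05)
  sp <- spacing_along_rows(fit_rows(det, row_params()))
  expect_error(spacing_agreement(sp, truth, m), "no valid")
})
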