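test_that("buffer-averaging row fit recovers simple vertical rows", {
  # self-consistent fixed point: all centroids on x = 1
  cen <- data.frame(id = 1:5, x = 1, y = seq(0, 2, 0.5))
  fit <- fit_rows(cen, row_params())
  expect_equal(nrow(fit$rows), 1L)
  expect_equal(fit$rows$anchor_x, 1)
  # lateral scatter 0.95/1.00/1.05 with w = 0.5: buffer catches all, mean 1.0
  cen2 <- data.frame(id = 1:3, x = c(0.95, 1.00, 1.05), y = c(0, 1, 2))
  fit2 <- fit_rows(cen2, row_params(row_spacing_w = 0.5))
  expect_equal(nrow(fit2$rows), 1L)
  expect_equal(fit2$rows$anchor_x, 1.00, tolerance = 1e-12)
  expect_error(fit_rows(cen2[0, ], row_params()), "no centroids")
})

test_that("two separated clusters become two rows with no shared members", {
  set.seed(5)
  n <- 12
  cen <- data.frame(id = 1:(2 * n),
                    x = c(rnorm(n, 0, 0.03), rnorm(n, 0.508, 0.03)),
                    y = runif(2 * n, 0, 5))
  fit <- fit_rows(cen, row_params())
  expect_equal(nrow(fit$rows), 2L)
  expect_equal(sort(as.integer(table(fit$assignments$row_id))), c(n, n))
  # brute-force check: every member within w/2 of its row line
  for (i in seq_len(nrow(fit$assignments))) {
    a <- fit$assignments[i, ]
    r <- fit$rows[fit$rows$row_id == a$row_id, ]
    expect_lte(abs(a$offset - r$offset), 0.508 / 2 + 1e-12)
  }
  # partition: every id in exactly one row
  expect_setequal(fit$assignments$id, cen$id)
  expect_equal(sum(fit$rows$n_members), nrow(cen))
})

test_that("random seed policy yields the same partition on separated rows", {
  cam <- test_camera()
  sc <- simulate_scene(clean_plan(17), cam)
  cen <- data.frame(id = sc$truth$plant_id, x = sc$truth$x, y = sc$truth$y)
  ref <- fit_rows(cen, row_params())
  key <- function(f) {
    m <- split(f$assignments$id, f$assignments$row_id)
    unname(m[order(vapply(m, min, numeric(1)))])
  }
  for (s in 1:5) {
    rf <- fit_rows(cen, row_params(seed_policy = "random", rng_seed = s))
    expect_identical(key(rf), key(ref))
  }
})

test_that("spacings are adjacent differences of projected coordinates", {
  # lateral offset is discarded by perpendicular projection
  cen <- data.frame(id = 1:2, x = c(0, 0.05), y = c(0, 0.20))
  fit <- fit_rows(cen, row_params())
  sp <- spacing_along_rows(fit)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$distance, 0.20, tolerance = 1e-12)
  # three equally spaced plants -> two identical records
  cen3 <- data.frame(id = 1:3, x = 0, y = c(0.1, 0.4, 0.7))
  sp3 <- spacing_along_rows(fit_rows(cen3, row_params()))
  expect_equal(sp3$distance, c(0.3, 0.3), tolerance = 1e-12)
  # a row with a single member emits no records
  lone <- fit_rows(data.frame(id = 1, x = 0, y = 0), row_params())
  expect_equal(nrow(spacing_along_rows(lone)), 0L)
})

test_that("spacing records are translation-invariant and rotation-equivariant", {
  set.seed(8)
  cen <- data.frame(id = 1:30, x = rep(c(0, 0.508, 1.016), each = 10),
                    y = rep(sort(runif(10, 0, 4)), 3))
  cen$x <- cen$x + rnorm(30, 0, 0.02)
  base <- spacing_along_rows(fit_rows(cen, row_params()))
  # translation
  tr <- cen; tr$x <- tr$x + 3.2; tr$y <- tr$y - 1.7
  sp_tr <- spacing_along_rows(fit_rows(tr, row_params()))
  expect_equal(sp_tr$distance, base$distance, tolerance = 1e-9)
  # rotation of both the points and the row angle
  th <- 25 * pi / 180
  rot <- data.frame(id = cen$id,
                    x = cen$x * cos(th) - cen$y * sin(th),
                    y = cen$x * sin(th) + cen$y * cos(th))
  sp_rot <- spacing_along_rows(fit_rows(rot, row_params(row_angle = 115)))
  expect_equal(sp_rot$distance, base$distance, tolerance = 1e-9)
})

test_that("row angle must match convention bounds", {
  expect_error(row_params(row_angle = 180), "\\[0, 180\\)")
  expect_error(row_params(row_spacing_w = 0), "positive")
})
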