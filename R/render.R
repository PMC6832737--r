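## Scene rendering: plants as balanced rosettes of elliptical leaves on a
## soil background with residue streaks and weed blobs. All geometry is laid
## out in ground metres, displaced to apparent position by the forward
## parallax model, and rasterised at the camera's ground sample distance.

# bilinear upscale of a small matrix to h x w (used for low-frequency noise)
upscale_bilinear <- function(s, h, w) {
  m <- nrow(s); n <- ncol(s)
  ri <- seq(1, m, length.out = h)
  ci <- seq(1, n, length.out = w)
  r0 <- pmin(floor(ri), m - 1L); rf <- ri - r0
  c0 <- pmin(floor(ci), n - 1L); cf <- ci - c0
  if (m == 1L) { r0 <- rep(1L, h); rf <- rep(0, h) }
  if (n == 1L) { c0 <- rep(1L, w); cf <- rep(0, w) }
  a <- s[r0, c0, drop = FALSE]; b <- s[pmin(r0 + 1L, m), c0, drop = FALSE]
  cc <- s[r0, pmin(c0 + 1L, n), drop = FALSE]
  d <- s[pmin(r0 + 1L, m), pmin(c0 + 1L, n), drop = FALSE]
  rfm <- matrix(rf, h, w); cfm <- matrix(cf, h, w, byrow = TRUE)
  a * (1 - rfm) * (1 - cfm) + b * rfm * (1 - cfm) +
    cc * (1 - rfm) * cfm + d * rfm * cfm
}

# matrix (row, col) 1-based indices of pixels inside an ellipse centred at
# 0-based pixel (cx, cy), semi-axes a >= b in pixels, rotated by theta
ellipse_pixels <- function(cx, cy, a, b, theta, h, w) {
  r <- max(a, b)
  rlo <- max(0, floor(cy - r)); rhi <- min(h - 1, ceiling(cy + r))
  clo <- max(0, floor(cx - r)); chi <- min(w - 1, ceiling(cx + r))
  if (rlo > rhi || clo > chi) return(integer(0))
  rows <- rlo:rhi; cols <- clo:chi
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / max(b, 0.5)
  inside <- which(u * u + v * v <= 1)
  if (!length(inside)) return(integer(0))
  ir <- ((inside - 1L) %% length(rows)) + rlo + 1L
  ic <- ((inside - 1L) %/% length(rows)) + clo + 1L
  ir + (ic - 1L) * h  # linear index into an h x w matrix
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' Render a synthetic plot image
#'
#' Rasterises a truth table into an 8-bit RGB nadir image. Each plant is
#' drawn at its *apparent* position (forward parallax displacement away from
#' nadir, so the centroid correction is genuinely exercised downstream) as a
#' balanced whorl of 2-6 elliptical leaves (major axis 3-6 cm ground units)
#' overlapping at the stem, so the object centroid coincides with the seed
#' point up to rasterisation error. Soil is brown multiscale noise whose
#' excess-green index stays below zero; crop residue is rendered as pale
#' elongated streaks (near-grey, slight red excess) and weeds as small green
#' blobs. Deterministic given the plan's `rng_seed`.
#'
#' @param truth A `truth_table` from [plan_scene()].
#' @param cam A [camera_model()]. The plot footprint (after parallax
#'   expansion) must fit inside the camera footprint.
#' @param plan The [scene_plan()] that produced `truth`.
#' @return A list of class `maize_scene`: `image` (h x w x 3 array, DN
#'   0-255), `truth` (the input with apparent-position pixel columns
#'   `col_px`, `row_px` appended), `cam`, and `plan`.
#' @export
render_scene <- function(truth, cam, plan) {
  stopifnot(is.data.frame(truth), inherits(cam, "camera_model"),
            inherits(plan, "scene_plan"))
  g <- ground_sample_distance(cam)
  h <- cam$image_height; w <- cam$image_width
  half_w_m <- w * g / 2; half_h_m <- h * g / 2
  # apparent plot corners must fall inside the footprint
  hmax <- max(plan$plant_height, if (nrow(truth)) max(truth$height) else 0)
  stretch <- cam$flight_height / (cam$flight_height - hmax)
  px <- (max(abs(row_positions(plan))) + 0.05) * stretch
  py <- (plan$plot_length / 2 + 0.05) * stretch
  if (px > half_w_m || py > half_h_m)
    stop("plot footprint exceeds camera footprint at this flight height")

  with_seed(plan$rng_seed + 1000003L, {
    area <- plan$plot_length * plan$n_rows * plan$row_spacing
    # soil background: base brown scaled by multiscale brightness noise
    coarse <- upscale_bilinear(matrix(stats::runif(ceiling(h / 32) *
                                                   ceiling(w / 32)),
                                      ceiling(h / 32)), h, w)
    fine <- matrix(stats::runif(h * w), h, w)
    bright <- 0.75 + 0.35 * coarse + 0.15 * fine
    R <- 125 * bright + stats::rnorm(h * w, 0, 2)
    G <- 95 * bright + stats::rnorm(h * w, 0, 2)
    B <- 70 * bright + stats::rnorm(h * w, 0, 2)

    paint <- function(idx, col) {
      if (!length(idx)) return()
      jit <- stats::rnorm(length(idx), 0, 3)
      R[idx] <<- clamp255(col[1] + jit)
      G[idx] <<- clamp255(col[2] + jit + stats::rnorm(length(idx), 0, 2))
      B[idx] <<- clamp255(col[3] + jit)
    }

    # crop residue: pale elongated streaks, ExG kept <= 0 unless greenish
    n_res <- stats::rpois(1, plan$residue_density * area)
    for (i in seq_len(n_res)) {
      gx <- stats::runif(1, -half_w_m * 0.95, half_w_m * 0.95)
      gy <- stats::runif(1, -half_h_m * 0.95, half_h_m * 0.95)
      p <- ground_to_pixel(gx, gy, cam)
      a <- stats::runif(1, 0.025, 0.075) / g
      b <- stats::runif(1, 0.004, 0.010) / g
      col <- c(168, 157, 150) + stats::rnorm(3, 0, 5)
      if (plan$residue_greenish) col[2] <- col[2] + 25
      else col[2] <- min(col[2], (col[1] + col[3]) / 2 - 2)
      paint(ellipse_pixels(p$col, p$row, a, b, stats::runif(1, 0, pi), h, w),
            col)
    }

    # weeds: small green blobs, on- and off-row, low canopy (2 cm parallax)
    n_weed <- stats::rpois(1, plan$weed_density * area)
    wx <- max(abs(row_positions(plan))) + plan$row_spacing / 2
    for (i in seq_len(n_weed)) {
      gx <- stats::runif(1, -wx, wx)
      gy <- stats::runif(1, -plan$plot_length / 2, plan$plot_length / 2)
      s <- cam$flight_height / (cam$flight_height - 0.02)
      p <- ground_to_pixel(gx * s, gy * s, cam)
      r <- stats::runif(1, 0.005, 0.015) / g
      paint(ellipse_pixels(p$col, p$row, r, r * stats::runif(1, 0.6, 1),
                           stats::runif(1, 0, pi), h, w),
            c(70, 130, 60) + stats::rnorm(3, 0, 6))
    }

    # maize plants: balanced whorl of leaves overlapping at the stem
    col_px <- row_px <- rep(NA_real_, nrow(truth))
    for (i in seq_len(nrow(truth))) {
      s <- cam$flight_height / (cam$flight_height - truth$height[i])
      p <- ground_to_pixel(truth$x[i] * s, truth$y[i] * s, cam)
      col_px[i] <- p$col; row_px[i] <- p$row
      nl <- sample(2:6, 1)
      rot <- stats::runif(1, 0, 2 * pi)
      # leaf length anti-correlated with leaf count so total projected leaf
      # area is roughly constant across plants (V2 stands are even-sized;
      # a wide area spread would make the relative area filter drop real
      # plants even in clean scenes); vigor jitter +-15% on length
      len <- sqrt(0.0071 / nl) * stats::runif(1, 0.85, 1.15)
      len <- min(max(len, 0.03), 0.06) / g         # major axis, px
      base <- c(60, 140, 55) + stats::rnorm(3, 0, 8)
      base[2] <- max(base[2], (base[1] + base[3]) / 2 + 25)  # keep ExG high
      for (k in seq_len(nl)) {
        th <- rot + (k - 1) * 2 * pi / nl + stats::rnorm(1, 0, 0.09)
        a <- len / 2; b <- max(a / 3, 0.8)
        cx <- p$col + 0.35 * len * cos(th)
        cy <- p$row + 0.35 * len * sin(th)
        paint(ellipse_pixels(cx, cy, a, b, th, h, w), base)
      }
    }

    if (plan$illumination) {
      grad <- upscale_bilinear(matrix(stats::runif(4, 0.9, 1.1), 2), h, w)
      mult <- stats::runif(1, 0.85, 1.1) * grad
      R <- R * mult; G <- G * mult; B <- B * mult
    }

    img <- array(0, dim = c(h, w, 3))
    img[, , 1] <- round(clamp255(R))
    img[, , 2] <- round(clamp255(G))
    img[, , 3] <- round(clamp255(B))
    truth$col_px <- col_px
    truth$row_px <- row_px
    structure(list(image = img, truth = truth, cam = cam, plan = plan),
              class = "maize_scene")
  })
}

#' Simulate a complete synthetic scene
#'
#' Convenience wrapper: [plan_scene()] then [render_scene()].
#'
#' @inheritParams render_scene
#' @param plan A [scene_plan()].
#' @return A `maize_scene` (see [render_scene()]).
#' @examples
#' cam <- camera_model(4, 78.8, 600, 800)
#' sc <- simulate_scene(scene_plan(rng_seed = 7), cam)
#' dim(sc$image)
#' @export
simulate_scene <- function(plan, cam) {
  render_scene(plan_scene(plan), cam, plan)
}

#' @export
print.maize_scene <- function(x, ...) {
  cat(sprintf("Synthetic plot scene: %d x %d px, %d plants (%d doubles)\n",
              dim(x$image)[2], dim(x$image)[1], nrow(x$truth),
              sum(x$truth$is_double)))
  invisible(x)
}

#' @export
plot.maize_scene <- function(x, truth = TRUE, ...) {
  op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, dim(x$image)[2]), c(0, dim(x$image)[1]),
                        asp = 1, xaxs = "i", yaxs = "i")
  graphics::rasterImage(x$image / 255, 0, 0, dim(x$image)[2], dim(x$image)[1])
  if (truth && nrow(x$truth))
    graphics::points(x$truth$col_px, dim(x$image)[1] - x$truth$row_px,
                     col = "red", pch = 3, cex = 0.6)
  invisible(x)
}
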