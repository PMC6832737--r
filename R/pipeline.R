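#' Detect a maize stand and estimate plant spacing in one call
#'
#' Runs the full pipeline on one plot image: ExG segmentation with relative
#' filters and dilation merging ([detect_plants()]), parallax-corrected
#' centroids, buffer-averaging row assignment ([fit_rows()]), within-row
#' spacing ([spacing_along_rows()]), and — when ground truth is supplied —
#' accuracy evaluation ([evaluate_stand()]).
#'
#' @param image h x w x 3 digital-number array, a `maize_scene`, or the path
#'   to an 8-bit RGB PNG.
#' @param cam A [camera_model()]. When `image` is a `maize_scene` its own
#'   camera is used and `cam` may be omitted.
#' @param seg A [segmentation_params()].
#' @param rows A [row_params()].
#' @param truth Optional truth table (`plant_id`, `row_index`, `x`, `y`);
#'   taken from a `maize_scene` automatically.
#' @param tolerance Match tolerance for evaluation, metres.
#' @param plot_length,n_rows,row_spacing Plot geometry for density.
#' @return An object of class `maize_stand`: detections, row fit, spacing
#'   records, plot summary, camera/parameters, and (with truth) the
#'   evaluation. Methods: `print`, `summary`, `plot`, `residuals`.
#' @examples
#' cam <- camera_model(4, 78.8, 600, 800)
#' sc <- simulate_scene(scene_plan(rng_seed = 42), cam)
#' fit <- maize_stand(sc, seg = segmentation_params(dilation_size = 5))
#' fit
#' @export
maize_stand <- function(image, cam = NULL, seg = segmentation_params(),
                        rows = row_params(), truth = NULL, tolerance = 0.05,
                        plot_length = 5, n_rows = 6, row_spacing = 0.508) {
  if (inherits(image, "maize_scene")) {
    if (is.null(cam)) cam <- image$cam
    if (is.null(truth)) truth <- image$truth
    image <- image$image
  } else if (is.character(image)) {
    image <- read_image_png(image)
  }
  if (is.null(cam)) stop("a camera_model is required")
  det <- detect_plants(image, cam, seg)
  if (nrow(det) == 0L) {
    fit <- NULL
    spac <- data.frame(row_id = integer(0), plant_a = integer(0),
                       plant_b = integer(0), distance = numeric(0),
                       valid = logical(0))
  } else {
    cent <- data.frame(id = det$label, x = det$x, y = det$y)
    fit <- fit_rows(cent, rows)
    spac <- spacing_along_rows(fit)
  }
  ev <- NULL
  if (!is.null(truth) && nrow(det) > 0L) {
    ev <- evaluate_stand(data.frame(id = det$label, x = det$x, y = det$y),
                         truth, spac, tolerance)
    if (!is.null(ev$spacing)) spac <- ev$spacing$records
  }
  summ <- summarize_plot(nrow(det), spac, plot_length, n_rows, row_spacing)
  structure(list(detections = det, rows = fit, spacings = spac,
                 summary = summ, camera = cam, seg_params = seg,
                 row_params = rows, eval = ev, truth = truth,
                 image_dim = dim(image)),
            class = "maize_stand")
}

#' @export
print.maize_stand <- function(x, ...) {
  cat("Maize stand analysis\n")
  cat(sprintf("  plants detected : %d (%s rows)\n", nrow(x$detections),
              if (is.null(x$rows)) 0 else nrow(x$rows$rows)))
  cat(sprintf("  stand density   : %.2f plants/m2 (%.2f m2 plot)\n",
              x$summary$density, x$summary$plot_area))
  if (!is.na(x$summary$spacing_mean))
    cat(sprintf("  spacing         : mean %.3f m, sd %.3f m (%d intervals)\n",
                x$summary$spacing_mean, x$summary$spacing_sd,
                sum(x$spacings$valid)))
  if (!is.null(x$eval)) {
    cat("  vs ground truth :\n    ")
    print(x$eval)
  }
  invisible(x)
}

#' @export
summary.maize_stand <- function(object, ...) {
  s <- object$summary
  if (!is.null(object$eval)) {
    s$precision <- object$eval$precision
    s$recall <- object$eval$recall
    if (!is.null(object$eval$spacing)) {
      s$d_e <- object$eval$spacing$d_e
      s$rel_error <- object$eval$spacing$r
    }
  }
  s
}

#' @export
residuals.maize_stand <- function(object, ...) {
  if (is.null(object$eval) || is.null(object$eval$spacing))
    stop("spacing residuals need ground truth (fit with truth =)")
  with(object$eval$spacing$per_pair, est - meas)
}

#' @export
plot.maize_stand <- function(x, image = NULL, ...) {
  h <- x$image_dim[1]; w <- x$image_dim[2]
  op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, w), c(0, h), asp = 1, xaxs = "i", yaxs = "i")
  if (!is.null(image)) {
    if (inherits(image, "maize_scene")) image <- image$image
    graphics::rasterImage(image / 255, 0, 0, w, h)
  }
  det <- x$detections
  if (nrow(det)) {
    graphics::points(det$centroid_col, h - det$centroid_row,
                     col = "yellow", pch = 4, cex = 0.7)
    if (!is.null(x$rows)) {
      a <- x$row_params$row_angle * pi / 180
      g <- ground_sample_distance(x$camera)
      for (i in seq_len(nrow(x$rows$rows))) {
        anc <- ground_to_pixel(x$rows$rows$anchor_x[i],
                               x$rows$rows$anchor_y[i], x$camera)
        # row direction in display coords (y up): angle preserved
        len <- max(h, w)
        graphics::segments(anc$col - len * cos(a), (h - anc$row) - len * sin(a),
                           anc$col + len * cos(a), (h - anc$row) + len * sin(a),
                           col = "cyan", lty = 2)
      }
    }
  }
  invisible(x)
}
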