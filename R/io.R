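#' Read / write 8-bit RGB images as PNG
#'
#' Thin wrappers over the png package converting between files and the
#' h x w x 3 digital-number arrays (0-255) used throughout.
#'
#' @param path File path.
#' @return `read_image_png`: h x w x 3 numeric array of digital numbers.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) stop("image must be RGB, not greyscale")
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  a * 255
}

#' @rdname read_image_png
#' @param image h x w x 3 array of digital numbers (0-255).
#' @export
write_image_png <- function(image, path) {
  stopifnot(length(dim(image)) == 3L)
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Write / read a truth table as CSV
#'
#' Columns: `plant_id`, `row_index`, `x_m`, `y_m`, `height_m`, `is_double`.
#'
#' @param truth A `truth_table` from [plan_scene()].
#' @param path File path.
#' @export
write_truth_csv <- function(truth, path) {
  out <- data.frame(plant_id = truth$plant_id, row_index = truth$row_index,
                    x_m = truth$x, y_m = truth$y, height_m = truth$height,
                    is_double = truth$is_double)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  d <- utils::read.csv(path)
  tt <- data.frame(plant_id = d$plant_id, row_index = d$row_index,
                   x = d$x_m, y = d$y_m, height = d$height_m,
                   is_double = as.logical(d$is_double))
  class(tt) <- c("truth_table", "data.frame")
  tt
}

#' Write / read detected objects as CSV
#'
#' Columns: `label`, `area_px`, `perimeter_px`, `centroid_col`,
#' `centroid_row`, `x_m`, `y_m` (parallax-corrected ground coordinates).
#'
#' @param objects Object table from [detect_plants()].
#' @param path File path.
#' @export
write_objects_csv <- function(objects, path) {
  out <- data.frame(label = objects$label, area_px = objects$area_px,
                    perimeter_px = objects$perimeter_px,
                    centroid_col = objects$centroid_col,
                    centroid_row = objects$centroid_row,
                    x_m = objects$x, y_m = objects$y)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_objects_csv
#' @export
read_objects_csv <- function(path) {
  d <- utils::read.csv(path)
  d$x <- d$x_m
  d$y <- d$y_m
  d
}

#' Read a YAML run configuration
#'
#' Builds the pipeline's parameter objects from a YAML file with optional
#' top-level blocks `camera` (keys `flight_height_m`, `fov_diagonal_deg`,
#' `image_width_px`, `image_height_px`, `plant_height_m`), `segmentation`,
#' `rows` and `scene` (keys matching the corresponding constructor
#' arguments). Missing blocks and keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return List with elements `camera`, `segmentation`, `rows`, `scene`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cam_args <- list()
  if (!is.null(cfg$camera)) {
    cmap <- c(flight_height_m = "flight_height",
              fov_diagonal_deg = "fov_diagonal",
              image_width_px = "image_width",
              image_height_px = "image_height",
              plant_height_m = "plant_height",
              height_fraction = "height_fraction")
    for (k in names(cfg$camera))
      if (k %in% names(cmap)) cam_args[[cmap[[k]]]] <- cfg$camera[[k]]
  }
  take <- function(block, fn) {
    args <- cfg[[block]]
    if (is.null(args)) args <- list()
    args <- args[names(args) %in% names(formals(fn))]
    do.call(fn, args)
  }
  list(camera = do.call(camera_model, cam_args),
       segmentation = take("segmentation", segmentation_params),
       rows = take("rows", row_params),
       scene = take("scene", scene_plan))
}
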