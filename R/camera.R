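#' Nadir camera / flight geometry
#'
#' Describes the pinhole geometry of a nadir-pointing UAV camera: flight
#' height above ground, diagonal field of view, sensor pixel dimensions, and
#' the uniform canopy height used for parallax correction of plant centroids.
#'
#' The ground frame has its origin at the nadir point (the image centre),
#' x in metres along the image column axis and y in metres along the
#' *decreasing* row axis (north-up display convention). Pixel indices are
#' 0-based with pixel centres at integer coordinates.
#'
#' @param flight_height Flight height above ground in metres (H).
#' @param fov_diagonal Diagonal field-of-view angle in degrees (78.8 for the
#'   consumer quadcopter camera this package was designed around).
#' @param image_width,image_height Sensor size in pixels (default 4000 x 3000).
#' @param plant_height Uniform canopy height in metres used for the parallax
#'   correction (default 0.10, a second-leaf-collar maize stand).
#' @param height_fraction Fraction of `plant_height` at which the correction
#'   is applied (1 = canopy top, 0.5 = mid-canopy). Default 1.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(flight_height = 4)
#' ground_sample_distance(cam)  # ~1.31 mm per pixel
#' @export
camera_model <- function(flight_height = 4, fov_diagonal = 78.8,
                         image_width = 4000L, image_height = 3000L,
                         plant_height = 0.10, height_fraction = 1.0) {
  stopifnot(is.numeric(flight_height), length(flight_height) == 1L,
            is.numeric(fov_diagonal), length(fov_diagonal) == 1L)
  image_width <- as.integer(image_width)
  image_height <- as.integer(image_height)
  if (!is.finite(flight_height) || flight_height <= 0)
    stop("flight_height must be positive and finite")
  if (fov_diagonal <= 0 || fov_diagonal >= 180)
    stop("fov_diagonal must lie in (0, 180) degrees")
  if (image_width < 1L || image_height < 1L)
    stop("image dimensions must be positive integers")
  if (plant_height < 0) stop("plant_height must be >= 0")
  if (plant_height >= flight_height)
    stop("plant_height must be smaller than flight_height")
  if (height_fraction < 0 || height_fraction > 1)
    stop("height_fraction must lie in [0, 1]")
  structure(list(flight_height = flight_height,
                 fov_diagonal = fov_diagonal,
                 image_width = image_width,
                 image_height = image_height,
                 plant_height = plant_height,
                 height_fraction = height_fraction),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("Nadir camera model\n")
  cat(sprintf("  flight height : %.2f m\n", x$flight_height))
  cat(sprintf("  diagonal FOV  : %.1f deg\n", x$fov_diagonal))
  cat(sprintf("  sensor        : %d x %d px\n", x$image_width, x$image_height))
  cat(sprintf("  canopy height : %.3f m (fraction %.2f)\n",
              x$plant_height, x$height_fraction))
  cat(sprintf("  GSD           : %.3f mm/px\n",
              1000 * ground_sample_distance(x)))
  invisible(x)
}

#' Ground sample distance
#'
#' Ground size of one pixel: the ground span of the image diagonal,
#' \eqn{2 H \tan(\theta_d / 2)}, divided by the pixel diagonal
#' \eqn{\sqrt{w^2 + h^2}}. Scales linearly with flight height.
#'
#' @param cam A [camera_model()].
#' @return Metres per pixel.
#' @export
ground_sample_distance <- function(cam) {
  stopifnot(inherits(cam, "camera_model"))
  diag_px <- sqrt(cam$image_width^2 + cam$image_height^2)
  2 * cam$flight_height * tan(cam$fov_diagonal * pi / 360) / diag_px
}

#' Pixel / ground coordinate mapping
#'
#' Affine map between 0-based sub-pixel image coordinates and metric ground
#' coordinates centred on the nadir point. The image centre (pixel
#' `((w-1)/2, (h-1)/2)`) maps to ground (0, 0); ground y increases with
#' decreasing row index. `pixel_to_ground` and `ground_to_pixel` are exact
#' inverses.
#'
#' @param col,row 0-based pixel coordinates (vectors, sub-pixel allowed).
#' @param cam A [camera_model()].
#' @return `pixel_to_ground`: a data.frame with columns `x`, `y` (metres).
#' @export
pixel_to_ground <- function(col, row, cam) {
  stopifnot(inherits(cam, "camera_model"), length(col) == length(row))
  if (any(col < 0 | col >= cam$image_width | row < 0 | row >= cam$image_height))
    stop("pixel coordinates outside image bounds")
  g <- ground_sample_distance(cam)
  data.frame(x = (col - (cam$image_width - 1) / 2) * g,
             y = -(row - (cam$image_height - 1) / 2) * g)
}

#' @rdname pixel_to_ground
#' @param x,y Ground coordinates in metres (vectors).
#' @return `ground_to_pixel`: a data.frame with columns `col`, `row`.
#' @export
ground_to_pixel <- function(x, y, cam) {
  stopifnot(inherits(cam, "camera_model"), length(x) == length(y))
  g <- ground_sample_distance(cam)
  col <- x / g + (cam$image_width - 1) / 2
  row <- -y / g + (cam$image_height - 1) / 2
  data.frame(col = col, row = row)
}

#' Parallax correction of apparent ground positions
#'
#' A canopy at height h above ground photographed from height H appears
#' displaced radially *away* from the nadir point. `correct_centroid` maps an
#' apparent (image-derived) ground position back to the true field position
#' by scaling radially toward nadir by `(H - h)/H`; `apparent_position` is
#' the exact forward model, scaling by `H/(H - h)`. The bearing from nadir is
#' preserved; only the radius changes. With `plant_height = 0` both are the
#' identity. `height_fraction` rescales h before use.
#'
#' @param x,y Ground coordinates in metres (vectors).
#' @param cam A [camera_model()] with `plant_height` set.
#' @return A data.frame with corrected (or forward-displaced) columns `x`, `y`.
#' @export
correct_centroid <- function(x, y, cam) {
  correction_factor(cam) * cbind_xy(x, y)
}

#' @rdname correct_centroid
#' @export
apparent_position <- function(x, y, cam) {
  cbind_xy(x, y) / correction_factor(cam)
}

# radial scale factor (H - h)/H, h already multiplied by height_fraction
correction_factor <- function(cam) {
  stopifnot(inherits(cam, "camera_model"))
  h <- cam$plant_height * cam$height_fraction
  H <- cam$flight_height
  if (h >= H) stop("effective plant height must be smaller than flight height")
  (H - h) / H
}

cbind_xy <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  data.frame(x = as.numeric(x), y = as.numeric(y))
}
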