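#' Segmentation parameters
#'
#' Tunables of the plant-segmentation stage: the excess-green threshold that
#' separates vegetation from soil, the relative area/shape filter factor, the
#' dilation merge element, band normalization, pixel connectivity, and the
#' direction of the shape filter.
#'
#' @param exg_threshold ExG value above which (strictly) a pixel is
#'   vegetation. Default 0.1.
#' @param filter_factor Relative filter constant: objects with area below
#'   `filter_factor` times the mean area are removed, and likewise for the
#'   shape criterion. Default 0.3.
#' @param dilation_size Side of the square structuring element (pixels) used
#'   to merge fragments of one plant. Default 10, suited to ~1.3 mm GSD
#'   imagery; scale with ground sample distance for coarser images.
#' @param normalization `"bit_depth_max"` (divide each band by 255;
#'   deterministic across crops of a scene) or `"per_band_image_max"`
#'   (divide by each band's observed maximum).
#' @param connectivity Pixel connectivity for object extraction, 4 or 8.
#' @param shape_filter_mode `"literal_less_than"` removes objects whose
#'   perimeter/area ratio is below `filter_factor` times the mean ratio;
#'   `"thin_object"` removes objects whose ratio exceeds the mean ratio
#'   divided by `filter_factor` (targets thin streak-like residue).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(exg_threshold = 0.1, filter_factor = 0.3,
                                dilation_size = 10L,
                                normalization = c("bit_depth_max",
                                                  "per_band_image_max"),
                                connectivity = 8L,
                                shape_filter_mode = c("literal_less_than",
                                                      "thin_object")) {
  stopifnot(is.finite(exg_threshold), filter_factor > 0, dilation_size >= 1)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(exg_threshold = exg_threshold,
                 filter_factor = filter_factor,
                 dilation_size = as.integer(dilation_size),
                 normalization = match.arg(normalization),
                 connectivity = connectivity,
                 shape_filter_mode = match.arg(shape_filter_mode)),
            class = "segmentation_params")
}

#' Excess-green vegetation index
#'
#' Computes ExG = (2g - r - b) / (r + g + b) per pixel, with r, g, b the
#' digital numbers divided by the configured normalizer (the 8-bit maximum
#' 255, or each band's image maximum). With equal normalizers the quotient
#' equals (2G - R - B)/(R + G + B) on raw digital numbers. Pixels whose
#' normalized bands sum to zero map to 0.
#'
#' @param image h x w x 3 array of digital numbers (>= 0).
#' @param params A [segmentation_params()].
#' @return h x w numeric matrix in `[-1, 2]` under `bit_depth_max`.
#' @export
compute_exg <- function(image, params = segmentation_params()) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be a 3-band (h x w x 3) array")
  if (min(image) < 0) stop("digital numbers must be >= 0")
  norm <- switch(params$normalization,
                 bit_depth_max = c(255, 255, 255),
                 per_band_image_max = pmax(apply(image, 3, max), 1e-12))
  h <- dim(image)[1]; w <- dim(image)[2]
  r <- matrix(image[, , 1], h, w) / norm[1]
  g <- matrix(image[, , 2], h, w) / norm[2]
  b <- matrix(image[, , 3], h, w) / norm[3]
  s <- r + g + b
  out <- (2 * g - r - b) / ifelse(s > 0, s, 1)
  out[s <= 0] <- 0
  matrix(out, h, w)
}

#' Threshold an ExG raster into a vegetation mask
#'
#' A pixel is vegetation iff its ExG value strictly exceeds
#' `params$exg_threshold`.
#'
#' @param exg Numeric matrix from [compute_exg()].
#' @inheritParams compute_exg
#' @return Logical matrix.
#' @export
binarize_exg <- function(exg, params = segmentation_params()) {
  stopifnot(is.matrix(exg))
  exg > params$exg_threshold
}

# per-component area, perimeter, shape ratio and pixel-mean centroid
# (0-based pixel coordinates) from a label matrix
object_stats <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  k <- max(lab)
  if (k == 0L)
    return(data.frame(label = integer(0), area_px = integer(0),
                      perimeter_px = integer(0), shape_ratio = numeric(0),
                      centroid_col = numeric(0), centroid_row = numeric(0)))
  idx <- which(lab > 0L)
  lv <- lab[idx]
  area <- tabulate(lv, k)
  # boundary pixel: some 4-neighbour has a different label (or off-image)
  up <- rbind(0L, lab[-h, , drop = FALSE])
  dn <- rbind(lab[-1, , drop = FALSE], 0L)
  lf <- cbind(0L, lab[, -w, drop = FALSE])
  rt <- cbind(lab[, -1, drop = FALSE], 0L)
  bnd <- lab > 0L & (up != lab | dn != lab | lf != lab | rt != lab)
  per <- tabulate(lab[bnd], k)
  rows0 <- ((idx - 1L) %% h)        # 0-based
  cols0 <- ((idx - 1L) %/% h)
  crow <- rowsum(rows0, lv)[, 1] / area
  ccol <- rowsum(cols0, lv)[, 1] / area
  data.frame(label = seq_len(k), area_px = area, perimeter_px = per,
             shape_ratio = per / area, centroid_col = ccol,
             centroid_row = crow)
}

#' Extract connected plant objects from a vegetation mask
#'
#' Labels connected vegetation pixels under the configured connectivity and
#' summarises each component: area (pixel count), perimeter (count of member
#' pixels with at least one 4-neighbour outside the component), their ratio,
#' and the unweighted pixel-mean centroid in 0-based image coordinates.
#'
#' @param mask Logical matrix from [binarize_exg()].
#' @inheritParams compute_exg
#' @return A data.frame of objects (columns `label`, `area_px`,
#'   `perimeter_px`, `shape_ratio`, `centroid_col`, `centroid_row`) carrying
#'   the label matrix as attribute `"labels"`.
#' @export
extract_objects <- function(mask, params = segmentation_params()) {
  lab <- label_components(mask, params$connectivity)
  obj <- object_stats(lab)
  attr(obj, "labels") <- lab
  obj
}

#' Remove relatively small / anomalously shaped objects
#'
#' Both criteria are evaluated against the means of the *input* list in a
#' single pass: objects with `area < filter_factor * mean(area)` are removed,
#' together with objects failing the shape criterion
#' (`shape_filter_mode`, see [segmentation_params()]). A single object is
#' never removed (it sits at the mean).
#'
#' @param objects Object table from [extract_objects()].
#' @inheritParams compute_exg
#' @return Filtered object table; the `"labels"` attribute (if present) has
#'   removed objects zeroed out.
#' @export
filter_objects <- function(objects, params = segmentation_params()) {
  if (nrow(objects) == 0L) return(objects)
  f <- params$filter_factor
  a_bar <- mean(objects$area_px)
  s_bar <- mean(objects$shape_ratio)
  drop <- objects$area_px < f * a_bar
  drop <- drop | switch(params$shape_filter_mode,
                        literal_less_than = objects$shape_ratio < f * s_bar,
                        thin_object = objects$shape_ratio > s_bar / f)
  out <- objects[!drop, , drop = FALSE]
  rownames(out) <- NULL
  lab <- attr(objects, "labels")
  if (!is.null(lab)) {
    lab[lab %in% objects$label[drop]] <- 0L
    attr(out, "labels") <- lab
  }
  out
}

#' Merge fragmented plants by dilation overlap
#'
#' Dilates the surviving vegetation mask with a square
#' `dilation_size` x `dilation_size` element; original objects whose dilated
#' footprints form one connected region are merged into a single object.
#' Statistics are recomputed from the union of the *original* (undilated)
#' pixels, so no dilated pixels enter areas, perimeters or centroids.
#'
#' @param objects Filtered object table from [filter_objects()] (must carry
#'   the `"labels"` attribute).
#' @inheritParams compute_exg
#' @return Object table of merged objects with a relabelled `"labels"`
#'   attribute.
#' @export
merge_fragments <- function(objects, params = segmentation_params()) {
  lab <- attr(objects, "labels")
  if (is.null(lab)) stop("objects must carry a 'labels' attribute")
  if (nrow(objects) == 0L) return(objects)
  mask <- lab > 0L
  dil <- dilate_square(mask, params$dilation_size)
  dlab <- label_components(dil, params$connectivity)
  newlab <- matrix(0L, nrow(lab), ncol(lab))
  idx <- which(mask)
  newlab[idx] <- dlab[idx]          # original pixels, dilated component id
  # relabel consecutively in discovery order
  u <- unique(newlab[idx])
  newlab[idx] <- match(newlab[idx], u)
  obj <- object_stats(newlab)
  attr(obj, "labels") <- newlab
  obj
}

#' Detect maize plants in a plot image
#'
#' Full segmentation chain: ExG computation, thresholding, connected-object
#' extraction, relative area/shape filtering, dilation merging, then mapping
#' of each object centroid to ground coordinates and parallax correction to
#' its true field position.
#'
#' @param image h x w x 3 digital-number array (see [read_image_png()]), or a
#'   `maize_scene`.
#' @param cam A [camera_model()] matching the image dimensions.
#' @inheritParams compute_exg
#' @return Object table with additional columns `x_apparent`, `y_apparent`
#'   (ground metres, uncorrected) and `x`, `y` (parallax-corrected), plus the
#'   `"labels"` attribute.
#' @examples
#' cam <- camera_model(4, 78.8, 600, 800)
#' sc <- simulate_scene(scene_plan(weed_density = 0, rng_seed = 1), cam)
#' det <- detect_plants(sc$image, cam, segmentation_params(dilation_size = 5))
#' nrow(det)  # close to nrow(sc$truth)
#' @export
detect_plants <- function(image, cam, params = segmentation_params()) {
  if (inherits(image, "maize_scene")) image <- image$image
  stopifnot(inherits(cam, "camera_model"))
  if (!all(dim(image)[1:2] == c(cam$image_height, cam$image_width)))
    stop("image dimensions do not match the camera model")
  exg <- compute_exg(image, params)
  mask <- binarize_exg(exg, params)
  obj <- extract_objects(mask, params)
  obj <- filter_objects(obj, params)
  obj <- merge_fragments(obj, params)
  if (nrow(obj)) {
    app <- pixel_to_ground(obj$centroid_col, obj$centroid_row, cam)
    corr <- correct_centroid(app$x, app$y, cam)
    obj$x_apparent <- app$x
    obj$y_apparent <- app$y
    obj$x <- corr$x
    obj$y <- corr$y
  } else {
    obj$x_apparent <- obj$y_apparent <- obj$x <- obj$y <- numeric(0)
  }
  obj
}
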