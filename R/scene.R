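#' Synthetic plot scene plan
#'
#' Parameters describing a simulated maize plot: layout (row count and
#' spacing, optional planter-wheel gap), target seeding density, stochastic
#' stand defects (spacing noise, missing plants, doubles) and background
#' confounders (weeds, crop residue). Defaults emulate a commercial maize
#' stand at second leaf collar stage: 5 m x 6-row plots, 50.8 cm row
#' spacing, 9.8 plants m-2 target population, 10 cm canopy height.
#'
#' @param plot_length Plot length along the rows, metres.
#' @param n_rows Number of crop rows.
#' @param row_spacing Distance between adjacent rows, metres (0.508 =
#'   20 inches).
#' @param wheel_gap Optional widened gap in metres (e.g. 0.6096 between the
#'   planter wheel rows); `NULL` for uniform spacing.
#' @param wheel_gap_after Row index after which the widened gap is inserted.
#' @param target_density Seeding density, plants per square metre. The mean
#'   within-row seed interval is `1 / (target_density * row_spacing)`.
#' @param spacing_sd Standard deviation of within-row seed intervals, metres.
#'   Intervals are Normal, truncated below at 0.05 m.
#' @param p_missing Probability that a seed position produced no plant.
#' @param p_double Probability of an extra plant ("double") next to a seed,
#'   offset Uniform(0.05, 0.12) m along the row.
#' @param weed_density Weeds per square metre of plot area.
#' @param residue_density Crop-residue streaks per square metre.
#' @param residue_greenish If `TRUE`, residue colour is drawn green-shifted so
#'   some residue pixels pass the ExG threshold (stresses the object filters).
#' @param plant_height Canopy height assigned to every plant, metres.
#' @param illumination If `TRUE`, apply a global brightness multiplier plus a
#'   low-frequency gradient (sun/cloud variation).
#' @param rng_seed Integer seed; identical plans with identical seeds produce
#'   bit-identical scenes.
#' @return An object of class `scene_plan`.
#' @seealso [plan_scene()], [render_scene()], [simulate_scene()]
#' @export
scene_plan <- function(plot_length = 5.0, n_rows = 6L, row_spacing = 0.508,
                       wheel_gap = NULL, wheel_gap_after = NULL,
                       target_density = 9.8, spacing_sd = 0.05,
                       p_missing = 0.03, p_double = 0.01,
                       weed_density = 0.5, residue_density = 1.0,
                       residue_greenish = FALSE,
                       plant_height = 0.10, illumination = FALSE,
                       rng_seed = 1L) {
  n_rows <- as.integer(n_rows)
  if (plot_length <= 0) stop("plot_length must be positive")
  if (n_rows < 1L) stop("n_rows must be >= 1")
  stopifnot(row_spacing > 0, target_density >= 0, spacing_sd >= 0,
            weed_density >= 0, residue_density >= 0, plant_height >= 0)
  for (p in c(p_missing, p_double))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (!is.null(wheel_gap) && wheel_gap <= 0) stop("wheel_gap must be positive")
  if (is.null(wheel_gap_after)) wheel_gap_after <- n_rows %/% 2L
  structure(list(plot_length = plot_length, n_rows = n_rows,
                 row_spacing = row_spacing, wheel_gap = wheel_gap,
                 wheel_gap_after = as.integer(wheel_gap_after),
                 target_density = target_density, spacing_sd = spacing_sd,
                 p_missing = p_missing, p_double = p_double,
                 weed_density = weed_density,
                 residue_density = residue_density,
                 residue_greenish = isTRUE(residue_greenish),
                 plant_height = plant_height,
                 illumination = isTRUE(illumination),
                 rng_seed = as.integer(rng_seed)),
            class = "scene_plan")
}

#' @export
print.scene_plan <- function(x, ...) {
  cat(sprintf("Scene plan: %.1f m x %d rows @ %.3f m, %.1f plants/m2 target\n",
              x$plot_length, x$n_rows, x$row_spacing, x$target_density))
  cat(sprintf("  spacing sd %.3f m, P(missing) %.2f, P(double) %.2f\n",
              x$spacing_sd, x$p_missing, x$p_double))
  cat(sprintf("  weeds %.2f /m2, residue %.2f /m2, seed %d\n",
              x$weed_density, x$residue_density, x$rng_seed))
  invisible(x)
}

# run a block with a private, seeded RNG stream; caller's state untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# x positions of the row lines, centred on the nadir origin
row_positions <- function(plan) {
  gaps <- rep(plan$row_spacing, max(plan$n_rows - 1L, 0L))
  if (!is.null(plan$wheel_gap) && plan$wheel_gap_after >= 1L &&
      plan$wheel_gap_after < plan$n_rows)
    gaps[plan$wheel_gap_after] <- plan$wheel_gap
  pos <- cumsum(c(0, gaps))
  pos - (min(pos) + max(pos)) / 2
}

#' Lay out the true plant positions of a synthetic plot
#'
#' Places seed points row by row. Within each row, intervals between
#' consecutive seeds are drawn Normal(mu, `spacing_sd`) truncated below at
#' 0.05 m, where `mu = 1 / (target_density * row_spacing)`. Each seed is
#' independently dropped with probability `p_missing`; surviving seeds spawn
#' an extra plant with probability `p_double` at a Uniform(0.05, 0.12) m
#' along-row offset. Rows run along the ground y axis; the plot rectangle is
#' centred on the nadir origin. Deterministic given `rng_seed`.
#'
#' @param plan A [scene_plan()].
#' @return A `truth_table`: data.frame with columns `plant_id`, `row_index`,
#'   `x`, `y` (ground metres), `height` (metres) and `is_double`, carrying the
#'   plan as attribute `plan`. Use [true_spacings()] for the per-row ordered
#'   adjacent intervals.
#' @export
plan_scene <- function(plan) {
  stopifnot(inherits(plan, "scene_plan"))
  with_seed(plan$rng_seed, {
    mu <- 1 / (plan$target_density * plan$row_spacing)
    half <- plan$plot_length / 2
    xs <- row_positions(plan)
    out <- vector("list", plan$n_rows)
    for (r in seq_len(plan$n_rows)) {
      # seed positions along the row
      y <- -half + mu / 2
      ys <- numeric(0)
      while (y <= half) {
        ys <- c(ys, y)
        step <- stats::rnorm(1, mu, plan$spacing_sd)
        while (step < 0.05) step <- stats::rnorm(1, mu, plan$spacing_sd)
        y <- y + step
      }
      keep <- stats::runif(length(ys)) >= plan$p_missing
      ys <- ys[keep]
      dbl <- logical(length(ys))
      if (length(ys) && plan$p_double > 0) {
        extra <- which(stats::runif(length(ys)) < plan$p_double)
        for (i in extra) {
          off <- stats::runif(1, 0.05, 0.12) * sample(c(-1, 1), 1)
          yd <- ys[i] + off
          if (abs(yd) > half) yd <- ys[i] - off
          yd <- min(max(yd, -half), half)
          ys <- c(ys, yd)
          dbl <- c(dbl, TRUE)
        }
      }
      out[[r]] <- if (length(ys))
        data.frame(row_index = r, x = xs[r], y = ys, is_double = dbl)
      else NULL
    }
    tt <- do.call(rbind, out)
    if (is.null(tt))
      tt <- data.frame(row_index = integer(0), x = numeric(0),
                       y = numeric(0), is_double = logical(0))
    tt <- tt[order(tt$row_index, tt$y), , drop = FALSE]
    tt <- data.frame(plant_id = seq_len(nrow(tt)),
                     row_index = tt$row_index, x = tt$x, y = tt$y,
                     height = rep(plan$plant_height, nrow(tt)),
                     is_double = tt$is_double)
    rownames(tt) <- NULL
    attr(tt, "plan") <- plan
    class(tt) <- c("truth_table", "data.frame")
    tt
  })
}

#' True adjacent-plant spacings of a truth table
#'
#' Per row, plants are ordered by their along-row coordinate and the
#' differences between consecutive positions are returned.
#'
#' @param truth A `truth_table` from [plan_scene()].
#' @return data.frame with columns `row_index`, `plant_a`, `plant_b`
#'   (truth plant ids, `a` preceding `b` along the row) and `distance` (m).
#' @export
true_spacings <- function(truth) {
  stopifnot(is.data.frame(truth))
  res <- lapply(split(truth, truth$row_index), function(d) {
    d <- d[order(d$y), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    data.frame(row_index = d$row_index[-1],
               plant_a = d$plant_id[-nrow(d)], plant_b = d$plant_id[-1],
               distance = diff(d$y))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(row_index = integer(0), plant_a = integer(0),
                      plant_b = integer(0), distance = numeric(0))
  rownames(out) <- NULL
  out
}
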