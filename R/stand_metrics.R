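#' Plot-level stand summary
#'
#' Stand density and within-row spacing statistics for one plot. Plot area
#' uses the agronomic width `n_rows * row_spacing` (the ground actually
#' allocated to the rows), not a nominal plot width.
#'
#' @param n_plants Number of detected plants (or an object table, in which
#'   case its row count is used).
#' @param spacings Spacing records ([spacing_along_rows()]); only records
#'   with `valid = TRUE` enter the statistics. `NULL` for none.
#' @param plot_length,n_rows,row_spacing Plot geometry, metres / count /
#'   metres (defaults 5, 6, 0.508).
#' @param plot_id,zone_label Optional identifiers carried into the summary.
#' @return One-row data.frame: `plot_id`, `zone_label`, `n_plants`,
#'   `plot_area` (m^2), `density` (plants m^-2), `spacing_mean`,
#'   `spacing_sd` (m; `NA` when fewer than 1 resp. 2 valid records).
#' @examples
#' summarize_plot(131)$density  # 131 plants on 15.24 m^2 -> 8.60
#' @export
summarize_plot <- function(n_plants, spacings = NULL, plot_length = 5,
                           n_rows = 6, row_spacing = 0.508,
                           plot_id = NA, zone_label = NA_character_) {
  if (is.data.frame(n_plants)) n_plants <- nrow(n_plants)
  stopifnot(n_plants >= 0, plot_length > 0, n_rows >= 1, row_spacing > 0)
  area <- plot_length * n_rows * row_spacing
  sm <- ssd <- NA_real_
  if (!is.null(spacings) && nrow(spacings)) {
    d <- spacings$distance[spacings$valid]
    if (length(d) >= 1L) sm <- mean(d)
    if (length(d) >= 2L) ssd <- stats::sd(d)
  }
  data.frame(plot_id = plot_id, zone_label = zone_label,
             n_plants = as.integer(n_plants), plot_area = area,
             density = n_plants / area, spacing_mean = sm, spacing_sd = ssd)
}

#' One-way analysis of variance across zones
#'
#' Classical fixed-effects one-way ANOVA (via [stats::aov()]) of plot-level
#' values grouped by zone: F = MSB/MSW on (k - 1, N - k) degrees of freedom.
#'
#' @param groups A list (optionally named) of numeric vectors, one per group.
#' @return List with `F`, `p`, `df` (length-2), and the fitted `aov` object.
#' @examples
#' one_way_anova(list(c(1, 2), c(3, 4)))$F  # 8 on (1, 2) df
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(v ~ g)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]), fit = fit)
}

#' Simple linear regression
#'
#' Ordinary least squares of y on x (via [stats::lm()]) with
#' `R^2 = 1 - SSres/SStot`.
#'
#' @param x,y Numeric vectors of equal length (>= 3 points, `var(x) > 0`).
#' @return List with `slope`, `intercept`, `r_squared`, `p` (slope test),
#'   and the fitted `lm` object.
#' @export
simple_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sstot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       p = unname(s$coefficients[2, 4]),
       fit = fit)
}

#' Example plot-level detection counts
#'
#' Detection results for nine 5 m x 6-row maize plots, three in each of
#' three yield-stability zones (stable-high SH, stable-medium SM, stable-low
#' SL) of a commercial field: visually counted plants, true positives, false
#' positives and false negatives of the UAV detection. Useful for exercising
#' the evaluation and stand-statistics functions without imagery.
#'
#' @return data.frame with columns `zone`, `plot`, `n_plants`, `TP`, `FP`,
#'   `FN`.
#' @examples
#' counts <- example_plot_counts()
#' with(counts, TP / (TP + FP))  # per-plot precision
#' @export
example_plot_counts <- function() {
  data.frame(
    zone = rep(c("SH", "SM", "SL"), each = 3),
    plot = rep(1:3, times = 3),
    n_plants = c(131L, 129L, 135L, 138L, 141L, 139L, 136L, 132L, 139L),
    TP = c(126L, 125L, 131L, 136L, 135L, 134L, 133L, 129L, 136L),
    FP = c(5L, 4L, 4L, 2L, 6L, 5L, 3L, 4L, 3L),
    FN = c(0L, 0L, 4L, 0L, 1L, 0L, 0L, 0L, 0L)
  )
}

# half-up rounding to integer percent, as used in report tables
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
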