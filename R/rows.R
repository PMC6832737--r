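#' Row-fitting parameters
#'
#' @param row_angle Crop-row direction, degrees counter-clockwise from the
#'   ground +x axis; 90 = rows parallel to the image vertical axis.
#' @param row_spacing_w Nominal distance between adjacent rows, metres; the
#'   assignment buffer extends `w/2` either side of a candidate row line.
#' @param seed_policy How the seed centroid of each new row is chosen:
#'   `"lowest_id"` (deterministic) or `"random"` (uses `rng_seed`).
#' @param rng_seed Integer seed for `seed_policy = "random"`.
#' @param refine_iters Number of buffer-averaging line moves per row
#'   (default 1: collect members in the seed line's buffer, move the line to
#'   their mean position once).
#' @return An object of class `row_params`.
#' @export
row_params <- function(row_angle = 90, row_spacing_w = 0.508,
                       seed_policy = c("lowest_id", "random"),
                       rng_seed = 1L, refine_iters = 1L) {
  if (row_angle < 0 || row_angle >= 180) stop("row_angle must lie in [0, 180)")
  if (row_spacing_w <= 0) stop("row_spacing_w must be positive")
  structure(list(row_angle = row_angle, row_spacing_w = row_spacing_w,
                 seed_policy = match.arg(seed_policy),
                 rng_seed = as.integer(rng_seed),
                 refine_iters = as.integer(refine_iters)),
            class = "row_params")
}

#' Assign plant centroids to crop rows
#'
#' Iterative buffer-averaging row detection. While unassigned centroids
#' remain: a seed centroid is selected and an initial line through it is
#' drawn at the predetermined row angle; unassigned centroids within a
#' perpendicular distance of `w/2` (half the row spacing) are collected and
#' the line is moved to pass through their mean position; membership is then
#' re-collected against the moved line and those centroids are assigned to
#' the new row. Every centroid ends up in exactly one row.
#'
#' @param centroids data.frame with columns `id`, `x`, `y` (corrected ground
#'   coordinates, metres), e.g. [detect_plants()] output with
#'   `id = label`.
#' @param params A [row_params()].
#' @return An object of class `row_fit`: list with `rows` (data.frame
#'   `row_id`, `anchor_x`, `anchor_y`, `angle_deg`, `offset`, `n_members`,
#'   ordered by cross-row offset) and `assignments` (data.frame `id`,
#'   `row_id`, `t` along-row coordinate, `offset` cross-row coordinate).
#' @export
fit_rows <- function(centroids, params = row_params()) {
  stopifnot(is.data.frame(centroids),
            all(c("id", "x", "y") %in% names(centroids)))
  if (nrow(centroids) == 0L) stop("no centroids to assign")
  a <- params$row_angle * pi / 180
  d <- c(cos(a), sin(a))             # along-row direction
  nv <- c(-sin(a), cos(a))           # cross-row normal
  t_along <- centroids$x * d[1] + centroids$y * d[2]
  off <- centroids$x * nv[1] + centroids$y * nv[2]
  n <- nrow(centroids)
  half_w <- params$row_spacing_w / 2

  run <- function() {
    assigned <- rep(NA_integer_, n)
    row_id <- 0L
    while (anyNA(assigned)) {
      un <- which(is.na(assigned))
      seed <- switch(params$seed_policy,
                     lowest_id = un[which.min(centroids$id[un])],
                     random = un[sample.int(length(un), 1L)])
      c0 <- off[seed]
      for (it in seq_len(max(params$refine_iters, 0L))) {
        mem <- un[abs(off[un] - c0) <= half_w]
        if (!length(mem)) break
        c0 <- mean(off[mem])
      }
      mem <- un[abs(off[un] - c0) <= half_w]
      if (!length(mem)) mem <- seed   # degenerate: keep the seed
      row_id <- row_id + 1L
      assigned[mem] <- row_id
      }
    assigned
  }
  assigned <- if (params$seed_policy == "random")
    with_seed(params$rng_seed, run()) else run()

  rows <- do.call(rbind, lapply(split(seq_len(n), assigned), function(i) {
    data.frame(row_id = assigned[i[1]],
               anchor_x = mean(centroids$x[i]),
               anchor_y = mean(centroids$y[i]),
               angle_deg = params$row_angle,
               offset = mean(off[i]),
               n_members = length(i))
  }))
  # renumber rows left-to-right by cross-row offset
  ord <- order(rows$offset)
  remap <- integer(nrow(rows))
  remap[rows$row_id[ord]] <- seq_len(nrow(rows))
  rows <- rows[ord, , drop = FALSE]
  rows$row_id <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  assignments <- data.frame(id = centroids$id, row_id = remap[assigned],
                            t = t_along, offset = off)
  assignments <- assignments[order(assignments$row_id, assignments$t), ]
  rownames(assignments) <- NULL
  structure(list(rows = rows, assignments = assignments, params = params),
            class = "row_fit")
}

#' @export
print.row_fit <- function(x, ...) {
  cat(sprintf("Crop-row fit: %d rows, %d plants\n",
              nrow(x$rows), nrow(x$assignments)))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Adjacent-plant distances along fitted rows
#'
#' Each row's member centroids are perpendicularly projected onto the row
#' line; sorted along-line coordinates yield one spacing record per adjacent
#' pair. The projection discards the cross-row offset component, so only
#' along-row separation enters the distance.
#'
#' @param fit A `row_fit` from [fit_rows()].
#' @return data.frame of spacing records: `row_id`, `plant_a`, `plant_b`
#'   (member ids, `a` preceding `b` along the line), `distance` (metres),
#'   `valid` (all `TRUE`; evaluation may invalidate records adjacent to
#'   detection errors). Rows with fewer than two members contribute none.
#' @export
spacing_along_rows <- function(fit) {
  stopifnot(inherits(fit, "row_fit"))
  asg <- fit$assignments
  res <- lapply(split(asg, asg$row_id), function(d) {
    d <- d[order(d$t), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    data.frame(row_id = d$row_id[-1], plant_a = d$id[-nrow(d)],
               plant_b = d$id[-1], distance = diff(d$t))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(row_id = integer(0), plant_a = integer(0),
                      plant_b = integer(0), distance = numeric(0))
  out$valid <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
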